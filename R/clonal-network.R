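#' Find all single-substitution neighbour pairs
#'
#' Returns every unordered pair of sequences at Hamming distance exactly 1
#' (equal length, one mismatching position). Pairs are found by
#' position-masked key hashing: each sequence emits one key per position
#' with that position wildcarded; two sequences share a key if and only if
#' they are identical everywhere except (necessarily, since the input is
#' unique) at the masked position. The result is identical to brute-force
#' all-pairs comparison but runs in expected near-linear time.
#'
#' @param sequences Character vector of unique A/C/G/T sequences.
#' @return A two-column integer matrix of index pairs (`i < j`), zero rows
#'   if there are no neighbours.
#' @examples
#' neighbor_pairs(c("ACG", "ACT", "TTT"))
#' @export
neighbor_pairs <- function(sequences) {
  n <- length(sequences)
  if (anyDuplicated(sequences)) {
    stop("`sequences` must be unique", call. = FALSE)
  }
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))))
  pairs <- list()
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) < 2) next
    pairs[[length(pairs) + 1]] <- masked_key_pairs(sequences[idx], idx, L)
  }
  if (length(pairs) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  out <- unique(do.call(rbind, pairs))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

# Masked-key search within one length class. Sequences are encoded as
# base-4 digit vectors packed into two exact double-precision words
# (<= 26 digits each, well below 2^53); masking a position zeroes its
# digit. Two unique sequences share the key of position p iff they are
# identical everywhere else, i.e. differ exactly at p.
masked_key_pairs <- function(seqs, idx, L) {
  n <- length(seqs)
  digits <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)),
                         BASES) - 1, nrow = n, byrow = TRUE)
  if (anyNA(digits)) {
    stop("sequences must contain only A/C/G/T", call. = FALSE)
  }
  h1 <- seq_len(min(L, 26L))
  h2 <- setdiff(seq_len(L), h1)
  pow1 <- 4^(h1 - 1)
  pow2 <- if (length(h2)) 4^(seq_along(h2) - 1) else numeric(0)
  v1 <- as.vector(digits[, h1, drop = FALSE] %*% pow1)
  v2 <- if (length(h2)) {
    as.vector(digits[, h2, drop = FALSE] %*% pow2)
  } else numeric(n)
  k1 <- matrix(v1, n, L)
  k2 <- matrix(v2, n, L)
  for (p in h1) k1[, p] <- v1 - digits[, p] * pow1[p]
  for (p in h2) k2[, p] <- v2 - digits[, p] * pow2[p - 26L]
  ord <- order(rep(seq_len(L), each = n), k1, k2, method = "radix")
  pos <- rep(seq_len(L), each = n)[ord]
  k1 <- as.vector(k1)[ord]
  k2 <- as.vector(k2)[ord]
  owners <- rep(idx, L)[ord]
  m <- length(k1)
  same <- pos[-1] == pos[-m] & k1[-1] == k1[-m] & k2[-1] == k2[-m]
  grp <- cumsum(c(TRUE, !same))
  glen <- tabulate(grp)
  ends <- cumsum(glen)
  starts <- ends - glen + 1
  multi <- which(glen > 1)
  if (length(multi) == 0) return(matrix(integer(0), ncol = 2))
  res <- lapply(multi, function(g) {
    members <- sort(owners[starts[g]:ends[g]])
    t(utils::combn(members, 2))
  })
  do.call(rbind, res)
}

# Pairs at Levenshtein distance exactly 1. Equal-length pairs at edit
# distance 1 are exactly the Hamming-1 pairs; pairs with length difference
# 1 match when the shorter sequence equals a single-deletion variant of the
# longer one.
levenshtein1_pairs <- function(sequences) {
  sub_pairs <- neighbor_pairs(sequences)
  lens <- nchar(sequences)
  indel <- list()
  for (L in sort(unique(lens))) {
    longer <- which(lens == L)
    shorter <- which(lens == L - 1)
    if (length(longer) == 0 || length(shorter) == 0) next
    short_seqs <- sequences[shorter]
    for (j in longer) {
      s <- sequences[j]
      dels <- unique(vapply(seq_len(L), function(p) {
        paste0(substr(s, 1, p - 1), substr(s, p + 1, L))
      }, character(1)))
      hit <- shorter[match(dels, short_seqs, nomatch = 0)]
      if (length(hit) > 0) {
        indel[[length(indel) + 1]] <-
          cbind(pmin(hit, j), pmax(hit, j))
      }
    }
  }
  out <- rbind(sub_pairs, if (length(indel)) do.call(rbind, indel))
  if (nrow(out) == 0) return(sub_pairs)
  out <- unique(out)
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Build a clonal network from a repertoire
#'
#' Constructs the repertoire similarity network: one vertex per unique CDR3
#' nucleotide sequence (read counts summed across clonotypes sharing the
#' sequence, regardless of V/J call), an edge between every pair of vertices
#' that differ by a single nucleotide, and clusters (clones) as the
#' connected components. Cluster ids are assigned deterministically in
#' decreasing order of aggregate read count, ties broken by the
#' lexicographically smallest member sequence; ids start at 0.
#'
#' @param rep A [repertoire()].
#' @param neighbor_rule `"hamming1"` (default; single substitutions, the
#'   point-mutation reading of "single nucleotide difference") or
#'   `"levenshtein1"` (additionally allows a single insertion/deletion).
#' @param max_length Validation cap on sequence length (default 1000 nt).
#' @return An object of class `ClonalNetwork`: a list with
#'   `vertices` (tibble: `sequence`, `count`, `cluster_id`, `label`),
#'   `edges` (tibble of vertex indices `from`/`to`),
#'   `clusters` (tibble: `cluster_id`, `n_vertices`, `count`),
#'   and `neighbor_rule`.
#' @examples
#' rep <- repertoire(data.frame(cdr3_nt = c("AAA", "AAT", "GGG"),
#'                              read_count = c(5, 2, 7)))
#' net <- build_network(rep)
#' net$clusters
#' @export
build_network <- function(rep, neighbor_rule = c("hamming1", "levenshtein1"),
                          max_length = 1000) {
  neighbor_rule <- match.arg(neighbor_rule)
  if (is_repertoire(rep)) {
    ct <- rep$clonotypes
  } else {
    ct <- as_tibble(rep)
  }
  if (nrow(ct) == 0) {
    return(empty_network(neighbor_rule))
  }
  if (any(nchar(ct$cdr3_nt) > max_length)) {
    stop("sequence longer than the configured cap (", max_length, " nt)",
         call. = FALSE)
  }
  agg <- ct |>
    group_by(sequence = .data$cdr3_nt) |>
    summarise(count = sum(.data$read_count), .groups = "drop") |>
    arrange(.data$sequence)
  pairs <- switch(neighbor_rule,
                  hamming1 = neighbor_pairs(agg$sequence),
                  levenshtein1 = levenshtein1_pairs(agg$sequence))
  comp <- component_ids(nrow(agg), pairs)
  # deterministic cluster ids: count desc, tie -> smallest member sequence
  comp_count <- as.vector(rowsum(agg$count, comp))
  comp_minseq <- vapply(split(agg$sequence, comp), min, character(1))
  comp_levels <- as.integer(names(split(agg$count, comp)))
  ord <- order(-comp_count, comp_minseq)
  new_id <- integer(length(comp_levels))
  new_id[ord] <- seq_along(ord) - 1L
  cluster_id <- new_id[match(comp, comp_levels)]
  vertices <- tibble(sequence = agg$sequence, count = agg$count,
                     cluster_id = cluster_id, label = "normal")
  sizes <- tabulate(cluster_id + 1L, nbins = length(ord))
  clusters <- tibble(cluster_id = seq_along(ord) - 1L,
                     n_vertices = sizes,
                     count = comp_count[ord])
  edges <- tibble(from = as.integer(pairs[, 1]), to = as.integer(pairs[, 2]))
  structure(list(vertices = vertices, edges = edges, clusters = clusters,
                 neighbor_rule = neighbor_rule),
            class = "ClonalNetwork")
}

empty_network <- function(neighbor_rule = "hamming1") {
  structure(list(
    vertices = tibble(sequence = character(), count = numeric(),
                      cluster_id = integer(), label = character()),
    edges = tibble(from = integer(), to = integer()),
    clusters = tibble(cluster_id = integer(), n_vertices = integer(),
                      count = numeric()),
    neighbor_rule = neighbor_rule), class = "ClonalNetwork")
}

component_ids <- function(n, pairs) {
  if (n == 0) return(integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs) > 0) {
    g <- igraph::add_edges(g, as.vector(t(pairs)))
  }
  as.integer(igraph::components(g)$membership)
}

#' @export
print.ClonalNetwork <- function(x, ...) {
  cat("<ClonalNetwork>", nrow(x$vertices), "vertices,", nrow(x$edges),
      "edges,", nrow(x$clusters), "clusters (rule:", x$neighbor_rule, ")\n")
  invisible(x)
}

#' Aggregate read counts per cluster
#'
#' @param network A [build_network()] result.
#' @return Numeric vector of aggregate read counts, ordered by `cluster_id`;
#'   its sum equals the total vertex count mass.
#' @export
cluster_abundances <- function(network) {
  stopifnot(inherits(network, "ClonalNetwork"))
  network$clusters$count
}

#' Convert a clonal network to an igraph object
#'
#' @param network A [build_network()] result.
#' @param layout Optional coordinate matrix from [layout_fr()], stored as
#'   vertex attributes `x`/`y`.
#' @return An `igraph` graph with vertex attributes `name` (sequence),
#'   `count`, `cluster_id` and `label`.
#' @export
as_igraph <- function(network, layout = NULL) {
  stopifnot(inherits(network, "ClonalNetwork"))
  g <- igraph::make_empty_graph(n = nrow(network$vertices), directed = FALSE)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(network$edges))))
  }
  igraph::V(g)$name <- network$vertices$sequence
  igraph::V(g)$count <- network$vertices$count
  igraph::V(g)$cluster_id <- network$vertices$cluster_id
  igraph::V(g)$label <- network$vertices$label
  if (!is.null(layout)) {
    igraph::V(g)$x <- layout[, 1]
    igraph::V(g)$y <- layout[, 2]
  }
  g
}

#' Force-directed network layout (Fruchterman-Reingold)
#'
#' Computes deterministic 2-D coordinates for plotting the clonal network
#' with the classic Fruchterman-Reingold force-directed algorithm with
#' cooling. The same seed always yields identical coordinates.
#'
#' @param network A [build_network()] result.
#' @param iterations Number of iterations (default 500).
#' @param seed Integer RNG seed (default 1).
#' @return A numeric matrix with one `(x, y)` row per vertex (0 rows for an
#'   empty network), all values finite.
#' @export
layout_fr <- function(network, iterations = 500, seed = 1) {
  stopifnot(inherits(network, "ClonalNetwork"), iterations >= 1)
  n <- nrow(network$vertices)
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  g <- as_igraph(network)
  coords <- local_seed(seed, igraph::layout_with_fr(g, niter = iterations))
  dimnames(coords) <- list(network$vertices$sequence, c("x", "y"))
  coords
}

# Evaluate `expr` under a temporary RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Export a clonal network as GraphML
#'
#' @param network A [build_network()] result.
#' @param path Output `.graphml` path.
#' @param layout Optional [layout_fr()] coordinates.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path, layout = NULL) {
  g <- as_igraph(network, layout = layout)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a clonal network as vertex + edge TSV tables
#'
#' Writes `<stem>_vertices.tsv` (sequence, count, cluster_id, label, and
#' layout coordinates when supplied) and `<stem>_edges.tsv` (from/to
#' sequences).
#'
#' @param network A [build_network()] result.
#' @param stem Output path stem.
#' @param layout Optional [layout_fr()] coordinates.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_network_tsv <- function(network, stem, layout = NULL) {
  stopifnot(inherits(network, "ClonalNetwork"))
  v <- network$vertices
  if (!is.null(layout)) {
    v$x <- layout[, 1]
    v$y <- layout[, 2]
  }
  vp <- paste0(stem, "_vertices.tsv")
  ep <- paste0(stem, "_edges.tsv")
  readr::write_tsv(v, vp, progress = FALSE)
  readr::write_tsv(tibble(from = v$sequence[network$edges$from],
                          to = v$sequence[network$edges$to]),
                   ep, progress = FALSE)
  invisible(c(vp, ep))
}
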