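#' Levenshtein (edit) distance between nucleotide sequences
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion),
#' the metric used to match primary tumor CDR3 sequences against a
#' patient's peripheral repertoire. Vectorized over both arguments with the
#' usual recycling rules.
#'
#' @param a,b Character vectors over A/C/G/T (empty strings allowed).
#' @return Integer vector of edit distances.
#' @examples
#' levenshtein("ACGT", "AGT") # 1 (one deletion)
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  bad <- c(a, b)[!grepl("^[ACGT]*$", c(a, b))]
  if (length(bad) > 0) {
    stop("sequences must contain only A/C/G/T: ", bad[1], call. = FALSE)
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- as.integer(utils::adist(a[i], b[i])[1, 1])
  }
  out
}

# Full edit-distance matrix (rows = a, cols = b), used for closest-match
# searches.
levenshtein_matrix <- function(a, b) {
  utils::adist(a, b)
}

#' Extract primary tumor clusters from a tumor repertoire
#'
#' Builds the clonal network of the tumor repertoire and flags every
#' cluster whose collective read fraction is at least `threshold` (default
#' 5% of the total tumor BCR population) as a primary tumor cluster. All
#' clusters are retained with their flags.
#'
#' @param tumor A tumor [repertoire()], e.g. from
#'   [read_tumor_signature()].
#' @param threshold Primary-cluster fraction threshold (default `0.05`).
#' @param neighbor_rule Passed to [build_network()].
#' @return An object of class `TumorSignature`: list with `patient_id`,
#'   `clusters` (tibble: `cluster_id`, `fraction`, `primary`, `n_sequences`,
#'   `sequences` list-column), `network`, and `threshold`.
#' @export
extract_primary_clusters <- function(tumor, threshold = 0.05,
                                     neighbor_rule = "hamming1") {
  stopifnot(is_repertoire(tumor))
  if (nrow(tumor$clonotypes) == 0) {
    stop("tumor repertoire is empty", call. = FALSE)
  }
  net <- build_network(tumor, neighbor_rule = neighbor_rule)
  total <- sum(net$vertices$count)
  seqs <- split(net$vertices$sequence, net$vertices$cluster_id)
  cl <- net$clusters |>
    mutate(fraction = .data$count / total,
           primary = .data$fraction >= threshold,
           sequences = unname(seqs[as.character(.data$cluster_id)]),
           n_sequences = lengths(.data$sequences))
  structure(list(patient_id = tumor$subject_id, clusters = cl,
                 network = net, threshold = threshold),
            class = "TumorSignature")
}

#' @export
print.TumorSignature <- function(x, ...) {
  cat("<TumorSignature> patient:", x$patient_id, "-",
      sum(x$clusters$primary), "primary /", nrow(x$clusters),
      "clusters (threshold", x$threshold, ")\n")
  invisible(x)
}

primary_sequences <- function(signature) {
  stopifnot(inherits(signature, "TumorSignature"))
  sort(unique(unlist(signature$clusters$sequences[
    signature$clusters$primary])))
}

#' Match primary tumor clones against a peripheral repertoire
#'
#' For every sequence of the primary tumor clusters, finds the closest
#' peripheral CDR3 by Levenshtein distance (ties broken by the
#' lexicographically smallest matching sequence). A tumor clone is called
#' MRD-positive (minimal residual disease) only on exact identity (LD = 0);
#' clones at `1 <= LD <= related_max` are flagged `related` — evidence of
#' clonal evolution, but not an MRD call.
#'
#' @param signature A [extract_primary_clusters()] result.
#' @param peripheral A peripheral-blood [repertoire()].
#' @param related_max Maximum LD for the `related` flag (default 1).
#' @return An MRD report tibble: `patient_id`, `timepoint`, `tumor_seq`,
#'   `cluster_id`, `closest_match`, `ld`, `mrd_positive`, `related`. With
#'   an empty peripheral repertoire, `ld`/`closest_match` are `NA`.
#' @export
match_tumor_clones <- function(signature, peripheral, related_max = 1) {
  tumor_seqs <- primary_sequences(signature)
  cl_of <- function(s) {
    hits <- which(vapply(signature$clusters$sequences,
                         function(ss) s %in% ss, logical(1)))
    signature$clusters$cluster_id[hits[1]]
  }
  cluster_ids <- vapply(tumor_seqs, cl_of, integer(1))
  per_seqs <- unique(peripheral$clonotypes$cdr3_nt)
  tp <- as.character(peripheral$timepoint)
  if (length(per_seqs) == 0) {
    return(tibble(patient_id = signature$patient_id, timepoint = tp,
                  tumor_seq = tumor_seqs, cluster_id = cluster_ids,
                  closest_match = NA_character_, ld = NA_integer_,
                  mrd_positive = NA, related = NA))
  }
  d <- levenshtein_matrix(tumor_seqs, per_seqs)
  ld <- apply(d, 1, min)
  closest <- vapply(seq_along(tumor_seqs), function(i) {
    min(per_seqs[d[i, ] == ld[i]])
  }, character(1))
  tibble(patient_id = signature$patient_id, timepoint = tp,
         tumor_seq = tumor_seqs, cluster_id = cluster_ids,
         closest_match = closest, ld = as.integer(ld),
         mrd_positive = ld == 0,
         related = ld >= 1 & ld <= related_max)
}

#' Peripheral read fraction carried by the tumor clone
#'
#' Sum of read counts of peripheral clonotypes whose CDR3 exactly equals
#' any primary tumor sequence, divided by the peripheral total reads.
#' Exact matches only — related (LD >= 1) clones do not contribute.
#'
#' @inheritParams match_tumor_clones
#' @return A fraction in `[0, 1]`.
#' @export
tumor_fraction <- function(signature, peripheral) {
  stopifnot(is_repertoire(peripheral))
  tumor_seqs <- primary_sequences(signature)
  ct <- peripheral$clonotypes
  if (nrow(ct) == 0) return(0)
  sum(ct$read_count[ct$cdr3_nt %in% tumor_seqs]) / peripheral$total_reads
}

#' Spike the primary tumor cluster into a peripheral network
#'
#' Builds the clonal network over the union of the peripheral repertoire
#' and the primary tumor sequences, for visualization of residual disease:
#' tumor vertices present in the blood sample are labeled `tumor_mrd`
#' (keeping their peripheral read count), absent tumor vertices are labeled
#' `tumor_absent` with a nominal count of 1, and peripheral-only vertices
#' are labeled `normal`. Edges follow the standard neighbour rule, so
#' single-mutation relatives connect to the tumor vertex.
#'
#' @inheritParams match_tumor_clones
#' @param neighbor_rule Passed to [build_network()].
#' @return A labeled [build_network()] result.
#' @export
spike_in_network <- function(signature, peripheral,
                             neighbor_rule = "hamming1") {
  stopifnot(is_repertoire(peripheral))
  tumor_seqs <- primary_sequences(signature)
  ct <- peripheral$clonotypes[, c("cdr3_nt", "read_count")]
  spiked_only <- setdiff(tumor_seqs, ct$cdr3_nt)
  if (length(spiked_only) > 0) {
    ct <- bind_rows(ct, tibble(cdr3_nt = spiked_only, read_count = 1))
  }
  net <- build_network(repertoire(ct, sample_id = peripheral$sample_id),
                       neighbor_rule = neighbor_rule)
  is_tumor <- net$vertices$sequence %in% tumor_seqs
  in_blood <- net$vertices$sequence %in% peripheral$clonotypes$cdr3_nt
  net$vertices$label <- dplyr::case_when(
    is_tumor & in_blood ~ "tumor_mrd",
    is_tumor ~ "tumor_absent",
    TRUE ~ "normal")
  net
}

#' Track tumor clones across a patient's timepoints
#'
#' Convenience wrapper running [match_tumor_clones()] and
#' [tumor_fraction()] over a list of peripheral repertoires (one per
#' timepoint).
#'
#' @inheritParams match_tumor_clones
#' @param peripherals Named list of [repertoire()]s (names used as
#'   timepoints when the repertoires carry none).
#' @return The combined MRD report tibble with a `tumor_fraction` column
#'   (per timepoint).
#' @export
track_tumor <- function(signature, peripherals, related_max = 1) {
  reports <- lapply(seq_along(peripherals), function(i) {
    p <- peripherals[[i]]
    rep_i <- match_tumor_clones(signature, p, related_max = related_max)
    if (all(is.na(rep_i$timepoint)) && !is.null(names(peripherals))) {
      rep_i$timepoint <- names(peripherals)[i]
    }
    rep_i$tumor_fraction <- tumor_fraction(signature, p)
    rep_i
  })
  bind_rows(reports)
}
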