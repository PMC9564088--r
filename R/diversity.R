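check_counts <- function(counts) {
  if (length(counts) == 0) {
    stop("diversity indices are undefined for an empty abundance vector",
         call. = FALSE)
  }
  if (any(!is.finite(counts) | counts <= 0)) {
    stop("abundances must be finite and positive", call. = FALSE)
  }
  invisible(counts)
}

#' Shannon diversity index (SDI)
#'
#' Plug-in Shannon entropy \eqn{H = -\sum_i p_i \log p_i} of the clone
#' frequency distribution, with \eqn{p_i} the abundance share of clone `i`.
#' Natural logarithm (nats) by default; `H` equals `log(n, base)` exactly
#' for `n` equally abundant clones and 0 for a single clone.
#'
#' @param counts Positive abundances (read counts; any positive weights are
#'   accepted, the index is scale-invariant).
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return The Shannon index, a non-negative scalar.
#' @examples
#' shannon(c(1, 1, 1, 1)) # log(4)
#' shannon(c(50, 25, 25))
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts(counts)
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' Gini-Simpson coefficient
#'
#' \eqn{D = 1 - \sum_i p_i^2}: the probability that two reads drawn at
#' random come from different clones. Equals `1 - 1/n` for `n` equally
#' abundant clones and 0 for a single clone.
#'
#' @inheritParams shannon
#' @return A value in `[0, 1)`.
#' @examples
#' gini_simpson(c(5, 5)) # 0.5
#' @export
gini_simpson <- function(counts) {
  check_counts(counts)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Gini index of clonal expansion
#'
#' Inequality of clone sizes,
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}: 0 when all clones
#' are equally abundant, approaching 1 under extreme monoclonal expansion.
#' Invariant to uniform scaling of the abundances.
#'
#' @inheritParams shannon
#' @return A value in `[0, 1)`.
#' @examples
#' gini(c(4, 4, 4)) # 0
#' gini(c(1, 3))    # 0.25
#' @export
gini <- function(counts) {
  check_counts(counts)
  n <- length(counts)
  x <- sort(counts)
  # O(n log n) form of the pairwise-difference sum
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Clone- and cluster-level diversity profile of a repertoire
#'
#' Computes richness and the three diversity indices either over individual
#' clones (vertices: unique CDR3 sequences with aggregated read counts) or
#' over clusters (connected components of the clonal network, i.e. groups
#' of sequences linked by single point mutations).
#'
#' @param rep A [repertoire()].
#' @param network Optional pre-built [build_network()] result for `rep`
#'   (built on the fly when omitted).
#' @param level `"vertex"` (individual clones) or `"cluster"`.
#' @param base Logarithm base for the Shannon index.
#' @return A one-row tibble: `sample_id`, `subject_id`, `group`,
#'   `timepoint`, `level`, `richness`, `shannon`, `gini_simpson`, `gini`,
#'   `total_reads`.
#' @export
diversity_profile <- function(rep, network = NULL,
                              level = c("vertex", "cluster"),
                              base = exp(1)) {
  level <- match.arg(level)
  stopifnot(is_repertoire(rep))
  if (is.null(network)) network <- build_network(rep)
  if (nrow(network$vertices) == 0) {
    stop("cannot profile an empty network", call. = FALSE)
  }
  counts <- switch(level, vertex = network$vertices$count,
                   cluster = cluster_abundances(network))
  tibble(sample_id = rep$sample_id, subject_id = rep$subject_id,
         group = rep$group, timepoint = as.character(rep$timepoint),
         level = level, richness = length(counts),
         shannon = shannon(counts, base = base),
         gini_simpson = gini_simpson(counts), gini = gini(counts),
         total_reads = sum(counts))
}

DIVERSITY_INDICES <- c("shannon", "gini_simpson", "gini")

#' Normalize diversity profiles to a healthy cohort
#'
#' Divides each diversity index by the arithmetic mean of the corresponding
#' index over the healthy cohort, index-by-index and level-by-level,
#' yielding `normalized_shannon` (the normalized SDI),
#' `normalized_gini_simpson` and `normalized_gini` columns. A healthy
#' cohort normalized against itself has mean 1 for every index.
#'
#' @param profiles Tibble of [diversity_profile()] rows to normalize.
#' @param healthy Tibble of [diversity_profile()] rows for the healthy
#'   volunteers (must cover every `level` present in `profiles`).
#' @return `profiles` with the three `normalized_*` columns added.
#' @export
normalize_to_healthy <- function(profiles, healthy) {
  if (is.null(healthy) || nrow(healthy) == 0) {
    stop("healthy cohort profiles must be non-empty", call. = FALSE)
  }
  missing_lv <- setdiff(unique(profiles$level), unique(healthy$level))
  if (length(missing_lv) > 0) {
    stop("healthy profiles lack level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  means <- healthy |>
    group_by(.data$level) |>
    summarise(dplyr::across(dplyr::all_of(DIVERSITY_INDICES), mean),
              .groups = "drop")
  for (ix in DIVERSITY_INDICES) {
    m <- means[[ix]][match(profiles$level, means$level)]
    if (any(m == 0)) {
      stop("healthy mean of ", ix, " is zero; normalization undefined",
           call. = FALSE)
    }
    profiles[[paste0("normalized_", ix)]] <- profiles[[ix]] / m
  }
  profiles
}

#' Diversity recovery between the transplant nadir and follow-up
#'
#' Computes the per-subject increase of the normalized Shannon index from
#' TP2 (immediately before stem cell transfusion, the diversity nadir) to
#' TP3 (6-8 weeks after transplant): `delta_sdi = SDI(TP3) - SDI(TP2)` on
#' the healthy-normalized scale. Subjects missing either timepoint get
#' `NA`.
#'
#' @param trajectory Tibble with columns `subject_id`, `timepoint`
#'   (`"TP1"`..`"TP4"`) and `normalized_shannon`.
#' @return Tibble with one row per subject: `subject_id`, `delta_sdi`.
#' @export
delta_sdi <- function(trajectory) {
  stopifnot(all(c("subject_id", "timepoint", "normalized_shannon") %in%
                  names(trajectory)))
  trajectory |>
    group_by(.data$subject_id) |>
    summarise(delta_sdi = {
      tp2 <- .data$normalized_shannon[.data$timepoint == "TP2"]
      tp3 <- .data$normalized_shannon[.data$timepoint == "TP3"]
      if (length(tp2) == 1 && length(tp3) == 1) tp3 - tp2 else NA_real_
    }, .groups = "drop")
}

#' Germline V gene usage with abnormality flags
#'
#' Per-V-gene read fractions of a repertoire, flagging genes absent from a
#' reference pool (e.g. the V genes observed across healthy volunteers) as
#' abnormal.
#'
#' @param rep A [repertoire()] with `v_gene` populated.
#' @param reference_pool Character vector of reference V genes.
#' @return Tibble: `v_gene`, `reads`, `fraction`, `abnormal`; the number of
#'   abnormal genes is attached as attribute `n_abnormal`.
#' @export
v_gene_usage <- function(rep, reference_pool) {
  stopifnot(is_repertoire(rep))
  usage <- rep$clonotypes |>
    group_by(.data$v_gene) |>
    summarise(reads = sum(.data$read_count), .groups = "drop") |>
    mutate(fraction = .data$reads / sum(.data$reads),
           abnormal = !(.data$v_gene %in% reference_pool)) |>
    arrange(dplyr::desc(.data$reads))
  attr(usage, "n_abnormal") <- sum(usage$abnormal)
  usage
}

#' Rarefy a repertoire to a common read depth
#'
#' Multinomial downsampling of the read counts to `depth` total reads
#' (clones drawn to zero are dropped). Rarefaction at the repertoire's full
#' depth returns the repertoire unchanged. This is an optional
#' comparability device; no analysis in the package applies it by default.
#'
#' @param rep A [repertoire()].
#' @param depth Target total read count (must not exceed `total_reads`).
#' @param seed Integer RNG seed.
#' @return A rarefied [repertoire()].
#' @export
rarefy_repertoire <- function(rep, depth, seed = 1) {
  stopifnot(is_repertoire(rep))
  if (depth > rep$total_reads) {
    stop("rarefaction depth exceeds total reads", call. = FALSE)
  }
  if (depth == rep$total_reads) return(rep)
  ct <- rep$clonotypes
  draws <- local_seed(seed, {
    as.vector(stats::rmultinom(1, size = depth,
                               prob = ct$read_count / sum(ct$read_count)))
  })
  ct$read_count <- draws
  ct <- ct[draws > 0, ]
  repertoire(ct, sample_id = rep$sample_id, subject_id = rep$subject_id,
             group = rep$group, timepoint = rep$timepoint, chain = rep$chain)
}
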