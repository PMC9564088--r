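#' Welch two-sample comparison
#'
#' Welch's unequal-variance t test (two-sided) between two groups of
#' diversity scores, via [stats::t.test()]. Group variances are not
#' assumed equal; degrees of freedom follow Welch-Satterthwaite.
#'
#' @param a,b Numeric vectors, each of length >= 2 and not jointly
#'   constant.
#' @return A one-row tibble: `mean_a`, `mean_b`, `var_a`, `var_b`, `n_a`,
#'   `n_b`, `t`, `df`, `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
compare_groups <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  ht <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                 error = function(e) {
                   stop("degenerate group variances (",
                        conditionMessage(e),
                        "); report exact equality instead of a t test",
                        call. = FALSE)
                 })
  tibble(mean_a = mean(a), mean_b = mean(b),
         var_a = stats::var(a), var_b = stats::var(b),
         n_a = length(a), n_b = length(b),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Empirical ROC analysis with Youden-optimal cut-off
#'
#' Computes the empirical ROC curve of a score against binary class labels,
#' the area under the curve by the trapezoidal rule (equal to the
#' Mann-Whitney rank statistic \eqn{P(S_{pos} > S_{neg}) +
#' \tfrac12 P(S_{pos} = S_{neg})}), and the dichotomous cut-off maximizing
#' Youden's J (`sensitivity + specificity - 1`). Scores at or above the
#' cut-off are classified as the positive class. Among tied maxima the
#' cut-off with the highest sensitivity, then the lowest threshold, is
#' chosen; the reported cut-off is the midpoint between the two adjacent
#' distinct scores it separates.
#'
#' @param scores Numeric scores.
#' @param labels Class labels, same length as `scores`.
#' @param positive The label of the positive class (default
#'   `"non_relapse"`: diversity-type scores run higher in patients who do
#'   not relapse, so the reported AUC is above 0.5 when that direction
#'   holds).
#' @return An object of class `ROCResult`: list with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `curve` (tibble `fpr`/`tpr`,
#'   from (0,0) to (1,1)), `n_pos`, `n_neg`, `positive`.
#' @examples
#' roc_analysis(c(0.8, 0.9, 0.1, 0.2),
#'              c("non_relapse", "non_relapse", "relapse", "relapse"))$auc
#' @export
roc_analysis <- function(scores, labels, positive = "non_relapse") {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  thr <- sort(unique(scores))
  # thresholds: rule "score >= t -> positive"; t sweeps from below the
  # minimum (all positive) to above the maximum (all negative)
  cuts <- c(-Inf, thr[-1] - diff(thr) / 2, Inf)
  tpr <- vapply(cuts, function(t) sum(scores[is_pos] >= t) / n_pos,
                numeric(1))
  fpr <- vapply(cuts, function(t) sum(scores[!is_pos] >= t) / n_neg,
                numeric(1))
  ord <- order(fpr, tpr)
  curve <- tibble(fpr = fpr[ord], tpr = tpr[ord])
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  youden <- tpr + (1 - fpr) - 1
  # finite candidate cut-offs only (a dichotomous rule must split the data)
  cand <- which(is.finite(cuts))
  if (length(cand) == 0) cand <- seq_along(cuts)
  best <- cand[order(-youden[cand], -tpr[cand], cuts[cand])][1]
  structure(list(auc = auc, cutoff = cuts[best],
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 youden = youden[best], curve = curve,
                 n_pos = n_pos, n_neg = n_neg, positive = positive),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf(
    "<ROCResult> AUC %.3f | cutoff %.4g (sens %.2f, spec %.2f) | %d pos / %d neg\n",
    x$auc, x$cutoff, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Full cohort diversity and relapse-discrimination pipeline
#'
#' For every patient sample: builds the clonal network, computes vertex-
#' and cluster-level diversity profiles, and normalizes them to the healthy
#' cohort means. Produces the per-subject diversity trajectories with the
#' TP2-to-TP3 recovery (`delta_sdi`), and ROC analyses (relapse vs
#' non-relapse) for every normalized index at every timepoint and for
#' `delta_sdi`, at both network levels.
#'
#' @param cohort Cohort tibble from [read_cohort_table()] (needs
#'   `patient_no` and `progression`).
#' @param repertoires Named list of patient [repertoire()]s, keyed
#'   `"<patient_no>_<timepoint>"` (e.g. `"419_TP2"`).
#' @param healthy List of healthy-volunteer [repertoire()]s.
#' @param neighbor_rule Passed to [build_network()].
#' @param base Logarithm base for the Shannon index.
#' @return An object of class `CohortReport`: list with `profiles`
#'   (normalized per-sample diversity table), `healthy_profiles`,
#'   `trajectories` (subject x timepoint normalized SDI with `delta_sdi`
#'   and relapse label), and `roc` (tibble: `measure`, `level`,
#'   `timepoint`, `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `n_pos`, `n_neg`).
#' @export
cohort_pipeline <- function(cohort, repertoires, healthy,
                            neighbor_rule = "hamming1", base = exp(1)) {
  if (length(healthy) == 0) {
    stop("healthy cohort is required for normalization", call. = FALSE)
  }
  profile_both <- function(rep) {
    net <- build_network(rep, neighbor_rule = neighbor_rule)
    bind_rows(diversity_profile(rep, net, "vertex", base = base),
              diversity_profile(rep, net, "cluster", base = base))
  }
  healthy_profiles <- bind_rows(lapply(healthy, profile_both))
  profiles <- bind_rows(lapply(repertoires, profile_both))
  healthy_profiles <- normalize_to_healthy(healthy_profiles,
                                           healthy_profiles)
  profiles <- normalize_to_healthy(profiles, healthy_profiles)

  labels <- tibble(subject_id = as.character(cohort$patient_no),
                   relapse = ifelse(cohort$progression, "relapse",
                                    "non_relapse"))
  long <- profiles |>
    dplyr::select("subject_id", "timepoint", "level",
                  dplyr::starts_with("normalized_")) |>
    left_join(labels, by = "subject_id")

  trajectories <- long |>
    filter(.data$level == "vertex") |>
    dplyr::select("subject_id", "timepoint", "normalized_shannon",
                  "relapse")
  deltas <- lapply(c("vertex", "cluster"), function(lv) {
    long |>
      filter(.data$level == lv) |>
      delta_sdi() |>
      mutate(level = lv)
  })
  deltas <- bind_rows(deltas) |> left_join(labels, by = "subject_id")
  incomplete <- unique(deltas$subject_id[is.na(deltas$delta_sdi)])
  if (length(incomplete) > 0) {
    warning("subject(s) missing TP2/TP3 excluded from delta-SDI ROC: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  }
  trajectories <- trajectories |>
    left_join(deltas |> filter(.data$level == "vertex") |>
                dplyr::select("subject_id", "delta_sdi"),
              by = "subject_id")

  roc_rows <- list()
  add_roc <- function(measure, level, timepoint, scores, labs) {
    ok <- !is.na(scores) & !is.na(labs)
    if (length(unique(labs[ok])) < 2) return()
    r <- roc_analysis(scores[ok], labs[ok])
    roc_rows[[length(roc_rows) + 1]] <<- tibble(
      measure = measure, level = level, timepoint = timepoint,
      auc = r$auc, cutoff = r$cutoff, sensitivity = r$sensitivity,
      specificity = r$specificity, n_pos = r$n_pos, n_neg = r$n_neg)
  }
  for (lv in c("vertex", "cluster")) {
    for (ix in DIVERSITY_INDICES) {
      col <- paste0("normalized_", ix)
      for (tp in sort(unique(long$timepoint))) {
        sub <- long[long$level == lv & long$timepoint == tp, ]
        add_roc(ix, lv, tp, sub[[col]], sub$relapse)
      }
    }
    sub <- deltas[deltas$level == lv, ]
    add_roc("delta_sdi", lv, NA_character_, sub$delta_sdi, sub$relapse)
  }
  structure(list(profiles = profiles, healthy_profiles = healthy_profiles,
                 trajectories = trajectories, deltas = deltas,
                 roc = bind_rows(roc_rows)),
            class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("<CohortReport>", length(unique(x$trajectories$subject_id)),
      "subjects,", nrow(x$profiles), "profiles,", nrow(x$roc), "ROC rows\n")
  d <- x$roc[x$roc$measure == "delta_sdi" & x$roc$level == "vertex", ]
  if (nrow(d) == 1) {
    cat(sprintf("  delta-SDI (vertex) AUC: %.3f\n", d$auc))
  }
  invisible(x)
}
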