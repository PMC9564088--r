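#' Default run configuration
#'
#' Resolved analysis settings embedded in every pipeline output manifest.
#'
#' @param chain Receptor chain analysed (default `"IGK"`).
#' @param dialect Clonotype table dialect (default `"simple"`).
#' @param neighbor_rule Edge rule of the clonal network (default
#'   `"hamming1"`).
#' @param log_base Shannon index logarithm base (default `exp(1)`).
#' @param primary_threshold Primary tumor cluster fraction threshold
#'   (default 0.05).
#' @param related_max Maximum Levenshtein distance for the `related` flag
#'   (default 1).
#' @param rarefaction_depth Optional common read depth (default `NULL`:
#'   no rarefaction).
#' @param seed Integer seed for any stochastic step (default 1).
#' @return A named list.
#' @export
run_config <- function(chain = "IGK", dialect = "simple",
                       neighbor_rule = "hamming1", log_base = exp(1),
                       primary_threshold = 0.05, related_max = 1,
                       rarefaction_depth = NULL, seed = 1) {
  as.list(environment())
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(list(package = "bcrnet",
                     version = as.character(utils::packageVersion("bcrnet")),
                     timestamp = format(Sys.time(), tz = "UTC")),
                config, extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Analyze a single clonotype table
#'
#' Reads one clonotype table, builds the clonal network, computes vertex-
#' and cluster-level diversity profiles, and writes `diversity.tsv`, the
#' network (GraphML + vertex/edge TSVs) and a run manifest into
#' `out_dir`. Outputs are deterministic given the configuration.
#'
#' @param path Clonotype table path.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the `repertoire`, `network` and
#'   `profiles`.
#' @export
run_sample <- function(path, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- read_clonotype_table(path, dialect = config$dialect,
                              chain_filter = config$chain)
  if (!is.null(config$rarefaction_depth)) {
    rep <- rarefy_repertoire(rep, config$rarefaction_depth,
                             seed = config$seed)
  }
  net <- build_network(rep, neighbor_rule = config$neighbor_rule)
  profiles <- bind_rows(
    diversity_profile(rep, net, "vertex", base = config$log_base),
    diversity_profile(rep, net, "cluster", base = config$log_base))
  readr::write_tsv(profiles, file.path(out_dir, "diversity.tsv"),
                   progress = FALSE)
  write_graphml(net, file.path(out_dir, "network.graphml"))
  write_network_tsv(net, file.path(out_dir, "network"))
  write_manifest(out_dir, config, list(
    input = path, n_vertices = nrow(net$vertices),
    n_edges = nrow(net$edges), n_clusters = nrow(net$clusters)))
  message("run_sample: ", nrow(net$vertices), " vertices, ",
          nrow(net$edges), " edges, ", nrow(net$clusters), " clusters")
  invisible(list(repertoire = rep, network = net, profiles = profiles))
}

read_repertoire_dir <- function(dir, config, group) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  reps <- lapply(files, function(f) {
    key <- sub("\\.tsv$", "", basename(f))
    parts <- strsplit(key, "_")[[1]]
    read_clonotype_table(
      f, dialect = config$dialect, chain_filter = config$chain,
      sample_id = key,
      subject_id = if (length(parts) >= 2) {
        paste(parts[-length(parts)], collapse = "_")
      } else key,
      group = group,
      timepoint = if (length(parts) >= 2) parts[length(parts)] else NA)
  })
  names(reps) <- sub("\\.tsv$", "", basename(files))
  reps
}

#' Run the full cohort analysis from on-disk inputs
#'
#' Directory layout (as produced by [write_cohort_inputs()]): a cohort
#' table, a directory of patient repertoire TSVs named
#' `<subject>_<timepoint>.tsv`, a directory of healthy repertoire TSVs,
#' and optionally a directory of tumor signature TSVs named
#' `<subject>.tsv`. Writes `trajectories.tsv`, `roc.tsv`, `profiles.tsv`,
#' `mrd.tsv` (when signatures are given), `summary.json` and a manifest
#' into `out_dir`.
#'
#' @param cohort_path Cohort table (see [read_cohort_table()]).
#' @param repertoire_dir Directory of patient clonotype TSVs.
#' @param healthy_dir Directory of healthy clonotype TSVs.
#' @param out_dir Output directory.
#' @param signature_dir Optional directory of tumor signature TSVs.
#' @param config A [run_config()].
#' @return Invisibly, the [cohort_pipeline()] report (with an `mrd`
#'   element when signatures were supplied).
#' @export
run_cohort <- function(cohort_path, repertoire_dir, healthy_dir, out_dir,
                       signature_dir = NULL, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_cohort_table(cohort_path)
  healthy <- read_repertoire_dir(healthy_dir, config, "healthy")
  if (length(healthy) == 0) {
    stop("healthy directory is empty; normalization impossible",
         call. = FALSE)
  }
  reps <- read_repertoire_dir(repertoire_dir, config, "patient")
  report <- cohort_pipeline(cohort, reps, healthy,
                            neighbor_rule = config$neighbor_rule,
                            base = config$log_base)

  mrd <- NULL
  if (!is.null(signature_dir)) {
    sig_files <- sort(list.files(signature_dir, pattern = "\\.tsv$",
                                 full.names = TRUE))
    mrd <- bind_rows(lapply(sig_files, function(f) {
      pid <- sub("\\.tsv$", "", basename(f))
      sig <- extract_primary_clusters(
        read_tumor_signature(f, patient_id = pid),
        threshold = config$primary_threshold,
        neighbor_rule = config$neighbor_rule)
      mine <- reps[grepl(paste0("^", pid, "_"), names(reps))]
      if (length(mine) == 0) return(NULL)
      track_tumor(sig, mine, related_max = config$related_max)
    }))
    readr::write_tsv(mrd, file.path(out_dir, "mrd.tsv"), progress = FALSE)
  } else {
    message("run_cohort: no tumor signatures supplied; MRD section omitted")
  }

  readr::write_tsv(report$trajectories,
                   file.path(out_dir, "trajectories.tsv"), progress = FALSE)
  readr::write_tsv(report$roc, file.path(out_dir, "roc.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$profiles, file.path(out_dir, "profiles.tsv"),
                   progress = FALSE)
  delta_row <- report$roc[report$roc$measure == "delta_sdi" &
                            report$roc$level == "vertex", ]
  jsonlite::write_json(list(
    n_patients = length(unique(report$trajectories$subject_id)),
    n_healthy = length(healthy),
    n_relapse = sum(cohort$progression),
    delta_sdi_auc = if (nrow(delta_row) == 1) delta_row$auc else NULL,
    n_mrd_positive = if (!is.null(mrd)) {
      length(unique(mrd$patient_id[mrd$mrd_positive]))
    } else NULL),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  write_manifest(out_dir, config, list(
    cohort = cohort_path, repertoire_dir = repertoire_dir,
    healthy_dir = healthy_dir, signature_dir = signature_dir))
  report$mrd <- mrd
  invisible(report)
}
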