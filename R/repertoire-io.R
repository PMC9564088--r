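#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr group_by summarise arrange mutate filter ungroup left_join bind_rows n
NULL

VALID_CHAINS <- c("IGH", "IGK", "IGL")

#' Construct a repertoire
#'
#' A `Repertoire` is one sample's collection of clonotypes: unique
#' (CDR3 nucleotide sequence, V gene, J gene) records with read counts,
#' plus subject/timepoint metadata. It is the atomic input of every
#' downstream analysis (network construction, diversity, tumor tracking).
#'
#' @param clonotypes A data frame with at least `cdr3_nt` (uppercase
#'   A/C/G/T string) and `read_count` (positive); optional `cdr3_aa`,
#'   `chain`, `v_gene`, `j_gene`. Rows with identical
#'   (`cdr3_nt`, `v_gene`, `j_gene`) are merged by summing `read_count`.
#' @param sample_id,subject_id Sample and subject identifiers.
#' @param group One of `"healthy"`, `"patient"`, `"culture"`, or `NA`.
#' @param timepoint Treatment timepoint (`"TP1"`..`"TP4"`), culture day
#'   (integer), or `NA`.
#' @param chain Receptor chain the repertoire was restricted to
#'   (`"IGH"`, `"IGK"`, `"IGL"`), or `NA` if mixed.
#' @return An object of class `Repertoire`: a list with elements
#'   `clonotypes` (tibble), `sample_id`, `subject_id`, `group`,
#'   `timepoint`, `chain`, and `total_reads`.
#' @examples
#' rep <- repertoire(data.frame(cdr3_nt = c("TGTAAA", "TGTAAT"),
#'                              read_count = c(5, 2)),
#'                   sample_id = "s1")
#' rep$total_reads
#' @export
repertoire <- function(clonotypes, sample_id = NA_character_,
                       subject_id = NA_character_, group = NA_character_,
                       timepoint = NA, chain = NA_character_) {
  ct <- as_tibble(clonotypes)
  if (!all(c("cdr3_nt", "read_count") %in% names(ct))) {
    stop("`clonotypes` must contain columns `cdr3_nt` and `read_count`",
         call. = FALSE)
  }
  for (col in c("cdr3_aa", "v_gene", "j_gene")) {
    if (!col %in% names(ct)) ct[[col]] <- NA_character_
  }
  if (!"chain" %in% names(ct)) ct[[
    "chain"]] <- if (is.na(chain)) NA_character_ else chain
  ct$cdr3_nt <- toupper(as.character(ct$cdr3_nt))
  bad <- !grepl("^[ACGT]+$", ct$cdr3_nt) | !is.finite(ct$read_count) |
    ct$read_count < 1
  if (any(bad)) {
    stop(sum(bad), " clonotype row(s) violate the repertoire invariants ",
         "(cdr3_nt must be non-empty A/C/G/T, read_count >= 1); ",
         "use read_clonotype_table() to drop invalid rows", call. = FALSE)
  }
  key <- paste(ct$cdr3_nt, ct$v_gene, ct$j_gene, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    counts <- rowsum(ct$read_count, key)
    merged <- ct[first, ]
    merged$read_count <- unname(counts[match(key[first],
                                             rownames(counts)), 1])
    ct <- merged
  }
  ct <- ct[order(ct$cdr3_nt), c("cdr3_nt", "cdr3_aa", "chain", "v_gene",
                                "j_gene", "read_count")]
  structure(
    list(clonotypes = ct, sample_id = sample_id, subject_id = subject_id,
         group = group, timepoint = timepoint, chain = chain,
         total_reads = sum(ct$read_count)),
    class = "Repertoire")
}

#' @export
print.Repertoire <- function(x, ...) {
  cat("<Repertoire> sample:", x$sample_id,
      if (!is.na(x$subject_id)) paste0("subject: ", x$subject_id), "\n")
  cat("  chain:", x$chain, " group:", x$group, " timepoint:",
      as.character(x$timepoint), "\n")
  cat("  clonotypes:", nrow(x$clonotypes), " total reads:",
      format(x$total_reads, big.mark = ","), "\n")
  invisible(x)
}

#' @export
summary.Repertoire <- function(object, ...) {
  tibble(sample_id = object$sample_id, subject_id = object$subject_id,
         group = object$group, timepoint = as.character(object$timepoint),
         chain = object$chain, n_clonotypes = nrow(object$clonotypes),
         total_reads = object$total_reads)
}

is_repertoire <- function(x) inherits(x, "Repertoire")

# Column maps for the supported clonotype-table dialects. `chain` may be
# derived from the V call when no locus column is present.
dialect_spec <- function(dialect) {
  switch(dialect,
    simple = list(required = c("cdr3_nt", "read_count", "chain"),
                  map = c(cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3_aa",
                          chain = "chain", v_gene = "v_gene",
                          j_gene = "j_gene", read_count = "read_count")),
    airr = list(required = c("junction", "v_call", "j_call",
                             "duplicate_count"),
                map = c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
                        chain = "locus", v_gene = "v_call",
                        j_gene = "j_call", read_count = "duplicate_count")),
    mixcr = list(required = c("nSeqCDR3", "allVHitsWithScore",
                              "allJHitsWithScore", "cloneCount"),
                 map = c(cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3",
                         chain = NA, v_gene = "allVHitsWithScore",
                         j_gene = "allJHitsWithScore",
                         read_count = "cloneCount")),
    stop("unknown dialect: ", dialect, call. = FALSE))
}

# "IGKV1-5*00(1234.5)" -> "IGKV1-5" (first hit, allele/score stripped)
strip_gene_call <- function(x) {
  x <- sub(",.*$", "", as.character(x))
  sub("[*(].*$", "", x)
}

#' Read a clonotype table
#'
#' Reads a tab-delimited clonotype table produced by an upstream clonotype
#' assembler (AIRR Rearrangement TSV, MiXCR export, or the package's own
#' three-column `simple` format), validates rows, merges duplicate
#' (`cdr3_nt`, `v_gene`, `j_gene`) records, and returns a [repertoire()].
#'
#' Rows failing validation (non-A/C/G/T characters in the nucleotide CDR3,
#' read count below one) are dropped with a warning giving the count.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect One of `"simple"` (columns `cdr3_nt`, `read_count`,
#'   `chain`, optional `v_gene`/`j_gene`/`cdr3_aa`), `"airr"`
#'   (`junction`, `junction_aa`, `v_call`, `j_call`, `duplicate_count`,
#'   optional `locus`), or `"mixcr"` (`nSeqCDR3`, `aaSeqCDR3`,
#'   `allVHitsWithScore`, `allJHitsWithScore`, `cloneCount`).
#' @param chain_filter Chain to retain. Defaults to `"IGK"` — all clinical
#'   diversity analyses in this package operate on the kappa light chain;
#'   pass `"IGH"`/`"IGL"` or `NULL` (keep everything) to override.
#' @param sample_id,subject_id,group,timepoint Metadata attached to the
#'   returned repertoire; `sample_id` defaults to the file name.
#' @return A [repertoire()].
#' @export
read_clonotype_table <- function(path, dialect = c("simple", "airr", "mixcr"),
                                 chain_filter = "IGK",
                                 sample_id = NULL, subject_id = NA_character_,
                                 group = NA_character_, timepoint = NA) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- dialect_spec(dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(spec$required, names(raw))
  if (length(missing_cols) > 0) {
    stop("clonotype table ", path, " (dialect '", dialect,
         "') is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get <- function(field) {
    src <- spec$map[[field]]
    if (is.null(src) || is.na(src) || !src %in% names(raw)) {
      rep(NA_character_, nrow(raw))
    } else as.character(raw[[src]])
  }
  ct <- tibble(
    cdr3_nt = toupper(get("cdr3_nt")),
    cdr3_aa = get("cdr3_aa"),
    chain = get("chain"),
    v_gene = get("v_gene"),
    j_gene = get("j_gene"),
    read_count = suppressWarnings(as.numeric(get("read_count"))))
  if (dialect == "mixcr") {
    ct$v_gene <- strip_gene_call(ct$v_gene)
    ct$j_gene <- strip_gene_call(ct$j_gene)
  }
  # chain falls back to the V-call locus prefix (e.g. IGKV1-5 -> IGK)
  no_chain <- is.na(ct$chain) | ct$chain == ""
  from_v <- substr(ct$v_gene, 1, 3)
  ct$chain[no_chain] <- ifelse(from_v[no_chain] %in% VALID_CHAINS,
                               from_v[no_chain], NA_character_)

  valid <- grepl("^[ACGT]+$", ct$cdr3_nt) & is.finite(ct$read_count) &
    ct$read_count >= 1
  n_dropped <- sum(!valid)
  if (n_dropped > 0) {
    warning("dropped ", n_dropped, " invalid clonotype row(s) from ", path,
            call. = FALSE)
    ct <- ct[valid, ]
  }
  if (!is.null(chain_filter)) {
    chain_filter <- match.arg(chain_filter, VALID_CHAINS)
    ct <- ct[!is.na(ct$chain) & ct$chain == chain_filter, ]
  }
  if (nrow(ct) == 0) {
    stop("no valid clonotypes in ", path,
         if (!is.null(chain_filter)) paste0(" after filtering to chain ",
                                            chain_filter), call. = FALSE)
  }
  repertoire(ct,
             sample_id = sample_id %||% basename(path),
             subject_id = subject_id, group = group, timepoint = timepoint,
             chain = if (is.null(chain_filter)) NA_character_ else chain_filter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a repertoire as a simple-dialect TSV
#'
#' Writes the clonotype table in the package's `simple` dialect; reading the
#' file back with [read_clonotype_table()] reproduces the same clonotype
#' multiset.
#'
#' @param rep A [repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(is_repertoire(rep))
  readr::write_tsv(rep$clonotypes, path, progress = FALSE)
  invisible(path)
}

#' Read a transplant-cohort metadata table
#'
#' Loads a patient cohort table (one row per patient undergoing high-dose
#' therapy with autologous stem cell rescue) with demographic, treatment and
#' outcome columns. The package ships an example DLBCL cohort of 17 patients
#' (8 of whom progressed) at
#' `system.file("extdata", "dlbcl_cohort.tsv", package = "bcrnet")`.
#'
#' @param path CSV or TSV file with header columns `patient_no`, `age`,
#'   `sex` (M/F), `subtype` (GCB / non-GCB), `status`
#'   (Salvage / Consolidation), `regimen`, `progression` (Yes/No), and
#'   `pfs_months` (progression-free survival, months, > 0).
#' @return A tibble of cohort records with `progression` parsed to logical.
#' @examples
#' cohort <- read_cohort_table(
#'   system.file("extdata", "dlbcl_cohort.tsv", package = "bcrnet"))
#' table(cohort$progression)
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("patient_no", "age", "sex", "subtype", "status", "regimen",
                "progression", "pfs_months")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(tibble(
    patient_no = character(), age = numeric(), sex = character(),
    subtype = character(), status = character(), regimen = character(),
    progression = logical(), pfs_months = numeric()))
  prog <- tolower(trimws(as.character(raw$progression)))
  prog_parsed <- dplyr::case_when(prog %in% c("yes", "true") ~ TRUE,
                                  prog %in% c("no", "false") ~ FALSE,
                                  TRUE ~ NA)
  pfs <- suppressWarnings(as.numeric(raw$pfs_months))
  bad <- which(is.na(prog_parsed) | !is.finite(pfs) | pfs <= 0)
  if (length(bad) > 0) {
    stop("unparseable progression/PFS value(s) for patient(s): ",
         paste(raw$patient_no[bad], collapse = ", "), call. = FALSE)
  }
  tibble(patient_no = as.character(raw$patient_no),
         age = as.numeric(raw$age),
         sex = as.character(raw$sex),
         subtype = as.character(raw$subtype),
         status = as.character(raw$status),
         regimen = as.character(raw$regimen),
         progression = prog_parsed,
         pfs_months = pfs)
}

#' Read a tumor CDR3 signature table
#'
#' Loads the primary tumor BCR CDR3 sequences of a patient, given either as
#' read counts or as fractions of the total tumor BCR population. Fractions
#' are converted to pseudo-counts (scaled by `1e6`) that preserve their
#' ratios, so the downstream cluster-fraction logic
#' ([extract_primary_clusters()]) is unaffected by the encoding.
#'
#' @param path TSV with a `cdr3_nt` column and either `read_count` or
#'   `fraction` (in `(0, 1]`; values of 0 are dropped with a warning; a sum
#'   above `1 + tol` is a format error).
#' @param patient_id Optional patient identifier (defaults to the file name).
#' @param tol Tolerance on the fraction sum (default `0.01`).
#' @return A tumor [repertoire()] (`group = "tumor"`).
#' @export
read_tumor_signature <- function(path, patient_id = NULL, tol = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"cdr3_nt" %in% names(raw)) {
    stop("tumor signature table is missing required column: cdr3_nt",
         call. = FALSE)
  }
  if ("read_count" %in% names(raw)) {
    counts <- as.numeric(raw$read_count)
  } else if ("fraction" %in% names(raw)) {
    frac <- as.numeric(raw$fraction)
    if (any(is.na(frac) | frac < 0)) {
      stop("tumor signature fractions must be numeric and >= 0",
           call. = FALSE)
    }
    if (sum(frac) > 1 + tol) {
      stop("tumor signature fractions sum to ", round(sum(frac), 4),
           " > 1 + tol", call. = FALSE)
    }
    zero <- frac == 0
    if (any(zero)) {
      warning("dropped ", sum(zero),
              " tumor signature row(s) with fraction 0", call. = FALSE)
      raw <- raw[!zero, , drop = FALSE]
      frac <- frac[!zero]
    }
    counts <- round(frac * 1e6)
  } else {
    stop("tumor signature table needs a `read_count` or `fraction` column",
         call. = FALSE)
  }
  ct <- tibble(cdr3_nt = toupper(as.character(raw$cdr3_nt)),
               read_count = counts)
  if ("v_gene" %in% names(raw)) ct$v_gene <- as.character(raw$v_gene)
  valid <- grepl("^[ACGT]+$", ct$cdr3_nt) & is.finite(ct$read_count) &
    ct$read_count >= 1
  if (any(!valid)) {
    warning("dropped ", sum(!valid), " invalid tumor signature row(s)",
            call. = FALSE)
    ct <- ct[valid, ]
  }
  if (nrow(ct) == 0) stop("tumor signature is empty after validation",
                          call. = FALSE)
  repertoire(ct, sample_id = patient_id %||% basename(path),
             subject_id = patient_id %||% basename(path),
             group = "tumor", chain = "IGK")
}
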