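BASES <- c("A", "C", "G", "T")

# n random CDR3 nucleotide sequences with lengths uniform on len_range.
# Lengths are drawn multiple-of-3 agnostic; uniqueness enforced by redraw.
random_cdr3 <- function(n, len_range = c(27, 45)) {
  if (n == 0) return(character(0))
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  out <- character(n)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- matrix(sample(BASES, length(idx) * L, replace = TRUE),
                nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_cdr3(length(dup), len_range)
  }
  out
}

#' Mutate a sequence at exactly one position
#'
#' Somatic-hypermutation step: substitutes a uniformly chosen position by a
#' uniformly chosen non-identical base, so the result is always at Hamming
#' distance 1 from (and the same length as) the input. Vectorized.
#'
#' @param seq Character vector of A/C/G/T sequences.
#' @param rng Ignored placeholder for explicit RNG streams; mutation draws
#'   come from R's global RNG (seed it with `set.seed()` for
#'   reproducibility).
#' @return Character vector of mutated sequences.
#' @export
mutate_sequence <- function(seq, rng = NULL) {
  n <- length(seq)
  if (n == 0) return(character(0))
  L <- nchar(seq)
  if (any(L == 0)) stop("sequences must be non-empty", call. = FALSE)
  pos <- floor(stats::runif(n) * L) + 1L
  old <- substr(seq, pos, pos)
  # uniform over the three non-identical bases: rotate by 1..3 in base order
  shift <- sample(1:3, n, replace = TRUE)
  new <- BASES[((match(old, BASES) - 1L + shift) %% 4L) + 1L]
  substr(seq, pos, pos) <- new
  seq
}

#' Co-culture simulator configuration
#'
#' Study conditions of the in-vitro germinal center (hiGC) co-culture that
#' the simulator emulates: naive B cells expand on a feeder layer (IL-4
#' only for the first 4 days, then IL-21 driven expansion), diversify by
#' single point mutations (SHM) from day 4, are replated to `1e5` cells at
#' day 8 and every 4 days thereafter, and optionally share the well with a
#' fast-growing, non-mutating tumor compartment that suppresses normal
#' growth and SHM through a saturating function of the tumor fraction.
#'
#' @param n_naive_clones Number of distinct naive CDR3 clones (default
#'   2000).
#' @param naive_mean_reads Mean of the geometric naive clone-size law
#'   (default 3).
#' @param cdr3_len CDR3 nucleotide length range (default 27-45).
#' @param growth Daily growth factors: `early` (days 0-4, IL-4 only;
#'   default 1.2), `expansion` (days 4-14; default 2.0, calibrated so the
#'   cumulative fold-expansion reaches at least 2000 by day 14), `late`
#'   (day 14 on; default 1.1).
#' @param phase_days Days at which the growth phase switches (default
#'   `c(4, 14)`).
#' @param shm_rate Per-cell probability that a newborn cell carries a
#'   single-substitution mutation (default 0.02, active from day 4).
#' @param maturation_days Effective dark-zone days before the SHM-to-CSR
#'   transition shuts mutation off (default 8: with no tumor, mutation
#'   stops at day 12, where diversity peaks; suppression slows the clock,
#'   delaying the peak past day 14).
#' @param n_start_cells Starting naive cells (default `1e5`).
#' @param replate_days Days on which cells are replated (downsampled to
#'   `replate_cells` preserving proportions; default `c(8, 12, 16)`).
#' @param replate_cells Cells retained at replating (default `1e5`).
#' @param tumor_seed Tumor cells seeded per `n_start_cells` naive cells
#'   (0, 1, 10 or 100 in the study design; any non-negative count).
#' @param tumor_growth Tumor daily growth factor (default 2.0, calibrated
#'   to raise the tumor fraction roughly 200-fold by day 14).
#' @param s_max,K Suppression parameters: normal growth increments and SHM
#'   are multiplied by `1 - s_max * f/(f + K)` where `f` is the tumor cell
#'   fraction (defaults 0.5 and `1e-5`, so even a 0.001% seed produces a
#'   substantial effect).
#' @param tumor_emits_bcr If `TRUE` the tumor contributes one monoclonal
#'   CDR3 to sampled repertoires (default `FALSE`: the modeled tumor line
#'   expresses no stable BCR).
#' @param mode `"mean_field"` (deterministic expected-count propagation)
#'   or `"stochastic"` (Poisson division, binomial mutation).
#' @param n_days Days simulated (default 19).
#' @param sample_days Days at which repertoires are sampled (default
#'   `c(0, 8, 10, 12, 14, 19)`).
#' @param sample_depth Reads per sampled repertoire (default 20000).
#' @param seed Integer RNG seed.
#' @return A `coculture_config` list.
#' @export
coculture_config <- function(n_naive_clones = 2000, naive_mean_reads = 3,
                             cdr3_len = c(27, 45),
                             growth = c(early = 1.2, expansion = 2.0,
                                        late = 1.1),
                             phase_days = c(4, 14),
                             shm_rate = 0.02, maturation_days = 8,
                             n_start_cells = 1e5,
                             replate_days = c(8, 12, 16),
                             replate_cells = 1e5,
                             tumor_seed = 0, tumor_growth = 2.0,
                             s_max = 0.5, K = 1e-5,
                             tumor_emits_bcr = FALSE,
                             mode = c("mean_field", "stochastic"),
                             n_days = 19,
                             sample_days = c(0, 8, 10, 12, 14, 19),
                             sample_depth = 20000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_naive_clones >= 1, naive_mean_reads >= 1,
            all(growth > 0), shm_rate >= 0, shm_rate <= 1,
            tumor_seed >= 0, tumor_growth > 0,
            s_max >= 0, s_max <= 1, K > 0, n_days >= 1)
  as.list(environment())
}

growth_factor <- function(day, config) {
  if (day < config$phase_days[1]) config$growth[["early"]]
  else if (day < config$phase_days[2]) config$growth[["expansion"]]
  else config$growth[["late"]]
}

#' Simulate the germinal center co-culture
#'
#' Propagates a clone-resolved B cell population through the culture
#' schedule of [coculture_config()]: phase-dependent exponential growth,
#' SHM spawning new single-mutation daughter clones (so the clonal network
#' grows outward from the naive vertices), periodic replating, and an
#' optional non-mutating tumor compartment growing at its own rate while
#' suppressing normal growth and SHM. Mean-field mode propagates expected
#' counts deterministically; stochastic mode draws Poisson births and
#' binomial mutation counts. Both are bit-reproducible given the seed.
#'
#' @param config A [coculture_config()].
#' @return A list of class `coculture_sim`:
#'   `population` (tibble per day: `day`, `normal_cells`, `tumor_cells`,
#'   `tumor_fraction`, `suppression`, `cumulative_fold`, `richness`,
#'   `sdi` — the Shannon index of the clone fractions),
#'   `repertoires` (named list of sampled [repertoire()]s at
#'   `sample_days`), `clones` (final clone table with `origin`
#'   naive/novel), and `config`.
#' @examples
#' sim <- simulate_coculture(coculture_config(n_naive_clones = 50,
#'                                            n_days = 6, seed = 1))
#' sim$population
#' @export
simulate_coculture <- function(config = coculture_config()) {
  stopifnot(is.list(config))
  local_seed(config$seed, run_coculture(config))
}

run_coculture <- function(config) {
  stochastic <- config$mode == "stochastic"
  seqs <- random_cdr3(config$n_naive_clones, config$cdr3_len)
  w <- 1 + stats::rgeom(config$n_naive_clones,
                        1 / config$naive_mean_reads)
  if (stochastic) {
    count <- as.vector(stats::rmultinom(1, config$n_start_cells,
                                        w / sum(w)))
    keep <- count > 0
    seqs <- seqs[keep]
    count <- count[keep]
  } else {
    count <- w / sum(w) * config$n_start_cells
  }
  origin <- rep("naive", length(seqs))
  macc <- numeric(length(seqs))      # mean-field mutation accumulator
  tumor <- config$tumor_seed
  tumor_seq <- if (config$tumor_emits_bcr) {
    random_cdr3(1, config$cdr3_len)
  } else NA_character_

  cum_fold <- 1
  maturation <- 0
  pop_rows <- list()
  repertoires <- list()

  snapshot <- function(day) {
    N <- sum(count)
    f <- if (tumor + N > 0) tumor / (tumor + N) else 0
    pop_rows[[length(pop_rows) + 1]] <<- tibble(
      day = day, normal_cells = N, tumor_cells = tumor,
      tumor_fraction = f,
      suppression = config$s_max * f / (f + config$K),
      cumulative_fold = cum_fold,
      richness = length(count), sdi = shannon(count))
    if (day %in% config$sample_days) {
      repertoires[[paste0("day", day)]] <<- sample_culture_repertoire(
        seqs, count, origin, tumor, tumor_seq, config, day)
    }
  }
  snapshot(0)

  for (day in 0:(config$n_days - 1)) {
    N <- sum(count)
    f <- if (tumor + N > 0) tumor / (tumor + N) else 0
    s <- config$s_max * f / (f + config$K)
    g <- growth_factor(day, config)
    g_eff <- 1 + (g - 1) * (1 - s)
    shm_on <- day >= config$phase_days[1] && maturation < 1

    if (stochastic) {
      births <- stats::rpois(length(count), count * (g_eff - 1))
    } else {
      births <- count * (g_eff - 1)
    }
    mutants <- integer(length(count))
    if (shm_on && config$shm_rate > 0) {
      mu_eff <- config$shm_rate * (1 - s)
      if (stochastic) {
        mutants <- stats::rbinom(length(count), births, mu_eff)
      } else {
        macc <- macc + births * mu_eff
        mutants <- floor(macc)
        macc <- macc - mutants
      }
    }
    count <- count + births - mutants
    if (any(mutants > 0)) {
      parents <- rep(seqs, mutants)
      mut_seqs <- mutate_sequence(parents)
      agg <- rowsum(rep(1, length(mut_seqs)), mut_seqs)
      new_seqs <- rownames(agg)
      new_counts <- as.vector(agg)
      hit <- match(new_seqs, seqs)
      known <- !is.na(hit)
      if (any(known)) {
        count[hit[known]] <- count[hit[known]] + new_counts[known]
      }
      if (any(!known)) {
        seqs <- c(seqs, new_seqs[!known])
        count <- c(count, new_counts[!known])
        origin <- c(origin, rep("novel", sum(!known)))
        macc <- c(macc, numeric(sum(!known)))
      }
    }
    tumor <- if (stochastic && tumor > 0) {
      stats::rpois(1, tumor * config$tumor_growth)
    } else {
      tumor * config$tumor_growth
    }
    cum_fold <- cum_fold * g_eff
    if (day >= config$phase_days[1]) maturation <- maturation +
        (1 - s) / config$maturation_days

    new_day <- day + 1
    replate_now <- new_day %in% config$replate_days
    # harvest (snapshot + repertoire sampling) before replating
    snapshot(new_day)
    if (replate_now) {
      total <- sum(count) + tumor
      if (total > config$replate_cells) {
        if (stochastic) {
          drawn <- as.vector(stats::rmultinom(
            1, config$replate_cells,
            c(count, tumor) / total))
          tumor <- drawn[length(drawn)]
          count <- drawn[-length(drawn)]
          keep <- count > 0
          seqs <- seqs[keep]
          count <- count[keep]
          origin <- origin[keep]
        } else {
          scale <- config$replate_cells / total
          count <- count * scale
          tumor <- tumor * scale
        }
      }
    }
  }
  structure(list(population = bind_rows(pop_rows),
                 repertoires = repertoires,
                 clones = tibble(cdr3_nt = seqs, cells = count,
                                 origin = origin),
                 config = config),
            class = "coculture_sim")
}

sample_culture_repertoire <- function(seqs, count, origin, tumor,
                                      tumor_seq, config, day) {
  prob <- count
  labels <- seqs
  if (config$tumor_emits_bcr && tumor > 0) {
    prob <- c(prob, tumor)
    labels <- c(labels, tumor_seq)
  }
  draws <- as.vector(stats::rmultinom(1, config$sample_depth,
                                      prob / sum(prob)))
  keep <- draws > 0
  repertoire(tibble(cdr3_nt = labels[keep], read_count = draws[keep]),
             sample_id = paste0("culture_day", day),
             subject_id = "culture", group = "culture", timepoint = day,
             chain = "IGK")
}

#' Earliest day attaining the maximum diversity
#'
#' Returns the first simulated day whose clone-level Shannon index is
#' within `tol` of the maximum over the whole trajectory. The tolerance
#' absorbs floating-point jitter between days whose clone frequencies are
#' analytically identical (e.g. after the SHM-to-CSR transition, when
#' mutation has stopped and growth is uniform across clones).
#'
#' @param sim A [simulate_coculture()] result.
#' @param days Days to consider (default: the configured `sample_days`).
#' @param tol Tie tolerance on the Shannon index (default `1e-9`).
#' @return The day (integer).
#' @export
sdi_peak_day <- function(sim, days = sim$config$sample_days, tol = 1e-9) {
  pop <- sim$population[sim$population$day %in% days, ]
  pop$day[which(pop$sdi >= max(pop$sdi) - tol)[1]]
}

#' Healthy-volunteer cohort configuration
#'
#' @param n_healthy Number of volunteers (default 12).
#' @param n_clones Clone richness per volunteer (default 5000; jittered
#'   +/-10% between volunteers).
#' @param sdlog Log-normal sd of the heavy-tailed clone-size law
#'   (default 1).
#' @param depth Reads sampled per repertoire (default 20000).
#' @param cdr3_len CDR3 length range.
#' @param v_genes Germline V gene pool assigned to clones.
#' @param seed Integer RNG seed.
#' @export
healthy_config <- function(n_healthy = 12, n_clones = 5000, sdlog = 1,
                           depth = 20000, cdr3_len = c(27, 45),
                           v_genes = HEALTHY_V_POOL, seed = 1) {
  stopifnot(n_healthy >= 1, n_clones >= 2, depth >= 1)
  as.list(environment())
}

HEALTHY_V_POOL <- paste0("IGKV", c("1-5", "1-8", "1-9", "1-12", "1-16",
                                   "1-17", "1-27", "1-33", "1-39", "2-28",
                                   "2-30", "3-11", "3-15", "3-20", "4-1"))

#' Simulate a healthy-volunteer cohort
#'
#' Generates peripheral kappa-chain repertoires with high richness and
#' heavy-tailed (log-normal) clone sizes — the reference against which
#' patient diversity indices are normalized.
#'
#' @param config A [healthy_config()].
#' @return Named list of [repertoire()]s (`H01`, `H02`, ...).
#' @export
simulate_healthy_cohort <- function(config = healthy_config()) {
  local_seed(config$seed, {
    out <- lapply(seq_len(config$n_healthy), function(i) {
      n <- round(config$n_clones * stats::runif(1, 0.9, 1.1))
      w <- stats::rlnorm(n, 0, config$sdlog)
      sample_weighted_repertoire(
        w, depth = config$depth, cdr3_len = config$cdr3_len,
        v_genes = config$v_genes,
        sample_id = sprintf("H%02d", i), subject_id = sprintf("H%02d", i),
        group = "healthy", timepoint = NA)
    })
    names(out) <- sprintf("H%02d", seq_len(config$n_healthy))
    out
  })
}

# Multinomial read sample from clone weights; drops unseen clones.
sample_weighted_repertoire <- function(w, depth, cdr3_len, v_genes,
                                       sample_id, subject_id, group,
                                       timepoint) {
  seqs <- random_cdr3(length(w), cdr3_len)
  reads <- as.vector(stats::rmultinom(1, depth, w / sum(w)))
  keep <- reads > 0
  repertoire(tibble(cdr3_nt = seqs[keep],
                    read_count = reads[keep],
                    v_gene = sample(v_genes, sum(keep), replace = TRUE)),
             sample_id = sample_id, subject_id = subject_id, group = group,
             timepoint = timepoint, chain = "IGK")
}

# Shannon index of a rank-frequency law p_i ~ i^-gamma truncated at n.
zipf_entropy <- function(n, gamma) {
  w <- seq_len(n)^(-gamma)
  p <- w / sum(w)
  -sum(p * log(p))
}

# Smallest n whose Zipf(gamma) entropy reaches target_h (binary search;
# entropy is strictly increasing in n for gamma < 1).
zipf_richness_for <- function(target_h, gamma = 0.3, n_max = 200000) {
  if (target_h <= 0) return(1L)
  lo <- 1L
  hi <- 2L
  while (zipf_entropy(hi, gamma) < target_h && hi < n_max) {
    lo <- hi
    hi <- min(hi * 2L, n_max)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (zipf_entropy(mid, gamma) < target_h) lo <- mid else hi <- mid
  }
  hi
}

#' Patient-cohort generator configuration
#'
#' Study conditions of the HDT-ASCR patient timeline the generator
#' emulates: TP1 (pre-conditioning, suppressed by prior treatment), TP2
#' (immediately before stem cell transfusion: near-ablated, tiny read
#' yield), TP3 (6-8 weeks post transplant: recovery whose rate is reduced
#' in patients carrying residual tumor), and TP4 (relapse patients only).
#' Group sizes default to 8 relapse / 9 non-relapse patients and 12
#' healthy volunteers. Per-timepoint targets are normalized Shannon
#' indices (ratios to the healthy cohort mean).
#'
#' @param n_relapse,n_nonrelapse,n_healthy Group sizes (defaults 8, 9, 12).
#' @param tp1_mean,tp1_sd TP1 normalized-SDI law (defaults 0.55, 0.10).
#' @param tp2_mean,tp2_sd TP2 normalized-SDI law (defaults 0.35, 0.05).
#' @param tp3_nonrelapse_mean,tp3_relapse_mean,tp3_sd TP3 normalized-SDI
#'   means for the two outcome groups and their common sd (defaults 1.0,
#'   0.6, 0.15) — the configured effect the relapse discrimination rests
#'   on, realized through reduced novel-clone influx (lower richness).
#' @param tp4_mean,tp4_sd TP4 (relapse only) law (defaults 0.95, 0.15).
#' @param depth_tp1,depth_tp2,depth_tp3,depth_tp4 Read depths per
#'   timepoint (defaults 10000, 200, 10000, 20000 — TP2 mRNA yield is
#'   near the detection floor).
#' @param tumor_fraction_range Planted tumor-clone read fraction for
#'   relapse patients, drawn log-uniformly (default `c(3e-5, 0.014)`),
#'   present from TP1 onward.
#' @param gamma Zipf exponent of the patient clone-size law (default 0.3).
#' @param healthy A [healthy_config()] for the embedded healthy cohort.
#' @param cdr3_len CDR3 length range.
#' @param seed Integer RNG seed.
#' @export
patient_cohort_config <- function(n_relapse = 8, n_nonrelapse = 9,
                                  n_healthy = 12,
                                  tp1_mean = 0.55, tp1_sd = 0.10,
                                  tp2_mean = 0.35, tp2_sd = 0.05,
                                  tp3_nonrelapse_mean = 1.0,
                                  tp3_relapse_mean = 0.6, tp3_sd = 0.15,
                                  tp4_mean = 0.95, tp4_sd = 0.15,
                                  depth_tp1 = 10000, depth_tp2 = 200,
                                  depth_tp3 = 10000, depth_tp4 = 20000,
                                  tumor_fraction_range = c(3e-5, 0.014),
                                  gamma = 0.3,
                                  healthy = NULL,
                                  cdr3_len = c(27, 45), seed = 1) {
  stopifnot(n_relapse >= 2, n_nonrelapse >= 2, n_healthy >= 1,
            all(tumor_fraction_range > 0), all(tumor_fraction_range < 1))
  cfg <- as.list(environment())
  if (is.null(cfg$healthy)) {
    cfg$healthy <- healthy_config(n_healthy = n_healthy, seed = seed + 1)
  }
  cfg
}

TUMOR_V_GENE <- "IGKV1D-42"  # deliberately outside the healthy V pool

#' Simulate an HDT-ASCR patient cohort with relapse labels
#'
#' Generates the full clinical study structure: a cohort table, healthy
#' volunteer repertoires, per-patient peripheral repertoires at TP1-TP3
#' (plus TP4 for relapse patients), and a primary tumor CDR3 signature for
#' every relapse patient. Relapse patients carry a planted monoclonal
#' tumor clone (read fraction log-uniform over the configured range,
#' count floored at one read) at every timepoint, and their TP3 diversity
#' recovery is reduced to the configured group mean; the planted structure
#' is therefore exactly recoverable by the analysis pipeline
#' ([match_tumor_clones()] at LD 0, delta-SDI group separation).
#'
#' Each sample's target normalized SDI is realized by inverting the
#' Shannon index of a Zipf clone-size law for the required richness
#' against the realized mean SDI of the generated healthy cohort, followed
#' by multinomial read sampling.
#'
#' @param config A [patient_cohort_config()].
#' @return A list of class `patient_cohort_sim`: `cohort` (tibble in
#'   [read_cohort_table()] layout), `repertoires` (named list keyed
#'   `"<patient>_<TP>"`), `healthy` (named list), `signatures` (named list
#'   of [extract_primary_clusters()] results for relapse patients),
#'   `truth` (tibble of planted per-sample targets), and `config`.
#' @export
simulate_patient_cohort <- function(config = patient_cohort_config()) {
  local_seed(config$seed, run_patient_cohort(config))
}

run_patient_cohort <- function(config) {
  healthy <- simulate_healthy_cohort(config$healthy)
  healthy_sdi <- mean(vapply(healthy, function(h) {
    shannon(h$clonotypes$read_count)
  }, numeric(1)))

  n_pat <- config$n_relapse + config$n_nonrelapse
  ids <- sprintf("P%02d", seq_len(n_pat))
  relapse <- sample(rep(c(TRUE, FALSE),
                        c(config$n_relapse, config$n_nonrelapse)))

  rtrunc_norm <- function(n, mean, sd, lo = 0.05) {
    pmax(stats::rnorm(n, mean, sd), lo)
  }
  targets <- tibble(
    subject_id = rep(ids, each = 4),
    timepoint = rep(c("TP1", "TP2", "TP3", "TP4"), n_pat),
    relapse = rep(relapse, each = 4))
  targets$target_nsdi <- NA_real_
  for (i in seq_len(n_pat)) {
    r <- relapse[i]
    rows <- which(targets$subject_id == ids[i])
    targets$target_nsdi[rows] <- c(
      rtrunc_norm(1, config$tp1_mean, config$tp1_sd),
      rtrunc_norm(1, config$tp2_mean, config$tp2_sd),
      rtrunc_norm(1, if (r) config$tp3_relapse_mean else
        config$tp3_nonrelapse_mean, config$tp3_sd),
      if (r) rtrunc_norm(1, config$tp4_mean, config$tp4_sd) else NA_real_)
  }
  targets <- targets[!is.na(targets$target_nsdi), ]

  depths <- c(TP1 = config$depth_tp1, TP2 = config$depth_tp2,
              TP3 = config$depth_tp3, TP4 = config$depth_tp4)
  lf <- log(config$tumor_fraction_range)
  tumor_frac <- exp(stats::runif(n_pat, lf[1], lf[2]))
  tumor_seqs <- random_cdr3(n_pat, config$cdr3_len)

  repertoires <- list()
  for (k in seq_len(nrow(targets))) {
    sid <- targets$subject_id[k]
    tp <- targets$timepoint[k]
    i <- match(sid, ids)
    depth <- depths[[tp]]
    n_clones <- zipf_richness_for(targets$target_nsdi[k] * healthy_sdi,
                                  gamma = config$gamma)
    w <- seq_len(n_clones)^(-config$gamma)
    rep_k <- sample_weighted_repertoire(
      w, depth = depth, cdr3_len = config$cdr3_len,
      v_genes = config$healthy$v_genes,
      sample_id = paste0(sid, "_", tp), subject_id = sid,
      group = "patient", timepoint = tp)
    if (relapse[i]) {
      planted <- tibble(cdr3_nt = tumor_seqs[i],
                        read_count = max(1, round(tumor_frac[i] * depth)),
                        v_gene = TUMOR_V_GENE)
      rep_k <- repertoire(bind_rows(rep_k$clonotypes, planted),
                          sample_id = rep_k$sample_id, subject_id = sid,
                          group = "patient", timepoint = tp, chain = "IGK")
    }
    repertoires[[paste0(sid, "_", tp)]] <- rep_k
  }

  signatures <- list()
  for (i in which(relapse)) {
    # primary cluster: the planted clone plus a minor one-substitution
    # variant, mirroring clonal evolution within the tumor
    sig_rep <- repertoire(
      tibble(cdr3_nt = c(tumor_seqs[i], mutate_sequence(tumor_seqs[i])),
             read_count = c(9e5, 1e5), v_gene = TUMOR_V_GENE),
      sample_id = ids[i], subject_id = ids[i], group = "tumor",
      chain = "IGK")
    signatures[[ids[i]]] <- extract_primary_clusters(sig_rep)
  }

  cohort <- tibble(
    patient_no = ids,
    age = round(stats::runif(n_pat, 20, 65)),
    sex = sample(c("M", "F"), n_pat, replace = TRUE, prob = c(0.7, 0.3)),
    subtype = sample(c("GCB", "non-GCB"), n_pat, replace = TRUE,
                     prob = c(0.25, 0.75)),
    status = sample(c("Salvage", "Consolidation"), n_pat, replace = TRUE,
                    prob = c(0.8, 0.2)),
    regimen = sample(c("CBV", "BEAM", "BEAC"), n_pat, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1)),
    progression = relapse,
    pfs_months = round(ifelse(relapse, stats::runif(n_pat, 4, 24),
                              stats::runif(n_pat, 25, 47)), 1))

  structure(list(cohort = cohort, repertoires = repertoires,
                 healthy = healthy, signatures = signatures,
                 truth = targets |>
                   left_join(tibble(subject_id = ids,
                                    tumor_seq = ifelse(relapse, tumor_seqs,
                                                       NA_character_),
                                    tumor_fraction = ifelse(relapse,
                                                            tumor_frac, NA)),
                             by = "subject_id"),
                 config = config),
            class = "patient_cohort_sim")
}

#' Write simulated cohort inputs to a directory
#'
#' Materializes a [simulate_patient_cohort()] result as the on-disk layout
#' consumed by [run_cohort()]: `cohort.tsv`, `repertoires/<subject>_<TP>.tsv`
#' and `healthy/<id>.tsv` in the simple dialect, tumor signatures under
#' `signatures/`, plus a `manifest.json` recording the configuration so
#' the run is replayable.
#'
#' @param sim A [simulate_patient_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "patient_cohort_sim"))
  dir.create(file.path(dir, "repertoires"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "healthy"), showWarnings = FALSE)
  dir.create(file.path(dir, "signatures"), showWarnings = FALSE)
  readr::write_tsv(sim$cohort, file.path(dir, "cohort.tsv"),
                   progress = FALSE)
  for (key in names(sim$repertoires)) {
    write_repertoire(sim$repertoires[[key]],
                     file.path(dir, "repertoires", paste0(key, ".tsv")))
  }
  for (key in names(sim$healthy)) {
    write_repertoire(sim$healthy[[key]],
                     file.path(dir, "healthy", paste0(key, ".tsv")))
  }
  for (key in names(sim$signatures)) {
    sig <- sim$signatures[[key]]
    v <- sig$network$vertices
    readr::write_tsv(tibble(cdr3_nt = v$sequence,
                            fraction = v$count / sum(v$count)),
                     file.path(dir, "signatures", paste0(key, ".tsv")),
                     progress = FALSE)
  }
  cfg <- sim$config
  cfg$healthy$v_genes <- as.character(cfg$healthy$v_genes)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
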