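test_that("mutate_sequence always yields Hamming distance 1 at equal length", {
  set.seed(41)
  seqs <- replicate(200, paste(sample(c("A", "C", "G", "T"),
                                      sample(5:45, 1), TRUE),
                               collapse = ""))
  muts <- mutate_sequence(seqs)
  expect_equal(nchar(muts), nchar(seqs))
  hamming <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, seqs, muts)
  expect_true(all(hamming == 1))
})

test_that("mutation support covers all single-substitution variants", {
  set.seed(42)
  draws <- mutate_sequence(rep("ACG", 12000))
  # 3 positions x 3 alternative bases = 9 possible variants
  expect_equal(length(unique(draws)), 9)
  expect_false("ACG" %in% draws)
})

test_that("co-culture growth schedule reaches 2000-fold by day 14", {
  sim <- simulate_coculture(coculture_config(tumor_seed = 0,
                                             mode = "mean_field",
                                             n_days = 14, seed = 1))
  fold <- sim$population$cumulative_fold[sim$population$day == 14]
  expect_gte(fold, 2000)
  expect_equal(fold, 1.2^4 * 2^10)
})

test_that("tumor seeding fractions follow the cell arithmetic", {
  for (seed_cells in c(1, 10, 100)) {
    sim <- simulate_coculture(coculture_config(
      tumor_seed = seed_cells, mode = "mean_field", n_days = 1, seed = 1))
    expect_equal(sim$population$tumor_fraction[1],
                 seed_cells / (1e5 + seed_cells))
  }
})

test_that("co-culture runs are bit-reproducible under a fixed seed", {
  cfg <- coculture_config(n_naive_clones = 200, n_days = 9,
                          tumor_seed = 10, mode = "stochastic", seed = 5)
  a <- simulate_coculture(cfg)
  b <- simulate_coculture(cfg)
  expect_identical(a$population, b$population)
  expect_identical(a$repertoires$day8$clonotypes,
                   b$repertoires$day8$clonotypes)
})

test_that("mean-field diversity rises to a day-12 peak without tumor and later with", {
  no_tumor <- simulate_coculture(coculture_config(tumor_seed = 0,
                                                  mode = "mean_field",
                                                  seed = 2))
  sdi <- no_tumor$population$sdi
  upto12 <- no_tumor$population$day <= 12
  # nondecreasing up to the day-12 peak (1e-9 absorbs float jitter on
  # days whose clone frequencies are analytically identical)
  expect_true(all(diff(sdi[upto12]) >= -1e-9))
  expect_equal(sdi_peak_day(no_tumor), 12)

  with_tumor <- simulate_coculture(coculture_config(tumor_seed = 100,
                                                    mode = "mean_field",
                                                    seed = 2))
  expect_gte(sdi_peak_day(with_tumor), 14)
})

test_that("sampled culture repertoires carry the configured depth and day labels", {
  sim <- simulate_coculture(coculture_config(n_naive_clones = 300,
                                             n_days = 10,
                                             sample_days = c(0, 8, 10),
                                             sample_depth = 5000, seed = 3))
  expect_named(sim$repertoires, c("day0", "day8", "day10"))
  for (r in sim$repertoires) {
    expect_equal(r$total_reads, 5000)
    expect_equal(r$group, "culture")
  }
  # day 0 holds only naive clones; later days gain novel single-mutation kin
  expect_gt(nrow(sim$repertoires$day10$clonotypes),
            nrow(sim$repertoires$day0$clonotypes))
})

test_that("healthy cohort is sized, rich and reproducible", {
  cfg <- healthy_config(n_healthy = 5, n_clones = 600, depth = 3000,
                        seed = 9)
  healthy <- simulate_healthy_cohort(cfg)
  expect_length(healthy, 5)
  expect_identical(simulate_healthy_cohort(cfg)[[3]]$clonotypes,
                   healthy[[3]]$clonotypes)
  sdis <- vapply(healthy, function(h) shannon(h$clonotypes$read_count),
                 numeric(1))
  expect_true(all(sdis > 4))
})

test_that("every healthy volunteer out-diversifies every near-ablated TP2 sample", {
  for (s in 1:5) {
    sim <- simulate_patient_cohort(patient_cohort_config(
      n_relapse = 2, n_nonrelapse = 2,
      healthy = healthy_config(n_healthy = 3, n_clones = 800,
                               depth = 4000, seed = s + 100),
      depth_tp1 = 2000, depth_tp3 = 2000, seed = s))
    h_sdi <- vapply(sim$healthy,
                    function(h) shannon(h$clonotypes$read_count),
                    numeric(1))
    tp2 <- sim$repertoires[grepl("_TP2$", names(sim$repertoires))]
    tp2_sdi <- vapply(tp2, function(r) shannon(r$clonotypes$read_count),
                      numeric(1))
    expect_true(min(h_sdi) > max(tp2_sdi))
  }
})

test_that("patient cohort has the study composition and planted structure", {
  sim <- simulate_patient_cohort(patient_cohort_config(seed = 4))
  expect_equal(nrow(sim$cohort), 17)
  expect_equal(sum(sim$cohort$progression), 8)
  expect_length(sim$signatures, 8)
  # relapse patients have TP1-TP4, others TP1-TP3
  for (i in seq_len(17)) {
    id <- sim$cohort$patient_no[i]
    tps <- names(sim$repertoires)[grepl(paste0("^", id, "_"),
                                        names(sim$repertoires))]
    expect_length(tps, if (sim$cohort$progression[i]) 4 else 3)
  }
  # planted tumor clone sits inside the configured fraction range at TP1/TP3
  truth <- sim$truth[sim$truth$relapse & sim$truth$timepoint == "TP1", ]
  expect_true(all(truth$tumor_fraction >= 3e-5 &
                    truth$tumor_fraction <= 0.014))
})

test_that("planted tumor clones are recovered at LD 0; non-relapse patients are clean", {
  sim <- simulate_patient_cohort(patient_cohort_config(seed = 6))
  for (pid in names(sim$signatures)) {
    mine <- sim$repertoires[grepl(paste0("^", pid, "_"),
                                  names(sim$repertoires))]
    report <- track_tumor(sim$signatures[[pid]], mine)
    planted <- sim$truth$tumor_seq[sim$truth$subject_id == pid][1]
    planted_rows <- report[report$tumor_seq == planted, ]
    expect_equal(nrow(planted_rows), 4)
    expect_true(all(planted_rows$mrd_positive))
    expect_true(all(planted_rows$tumor_fraction > 0))
  }
  # non-relapse repertoires contain no relapse patient's tumor clone
  clean_ids <- sim$cohort$patient_no[!sim$cohort$progression]
  planted_all <- stats::na.omit(sim$truth$tumor_seq)
  for (pid in clean_ids) {
    mine <- sim$repertoires[grepl(paste0("^", pid, "_"),
                                  names(sim$repertoires))]
    for (r in mine) {
      expect_false(any(planted_all %in% r$clonotypes$cdr3_nt))
    }
  }
})

test_that("TP3 recovery separates outcome groups in the configured direction", {
  seps <- logical(6)
  for (s in seq_along(seps)) {
    sim <- simulate_patient_cohort(patient_cohort_config(
      n_relapse = 4, n_nonrelapse = 4,
      healthy = healthy_config(n_healthy = 4, n_clones = 1000,
                               depth = 5000, seed = 200 + s),
      depth_tp1 = 2500, depth_tp3 = 2500, seed = 50 + s))
    tp3 <- sim$repertoires[grepl("_TP3$", names(sim$repertoires))]
    sdi <- vapply(tp3, function(r) shannon(r$clonotypes$read_count),
                  numeric(1))
    ids <- sub("_TP3$", "", names(sdi))
    rel <- sim$cohort$progression[match(ids, sim$cohort$patient_no)]
    seps[s] <- mean(sdi[!rel]) > mean(sdi[rel])
  }
  expect_gte(sum(seps), 5)
})

test_that("written cohort inputs reload into an equivalent analysis", {
  sim <- simulate_patient_cohort(patient_cohort_config(
    n_relapse = 2, n_nonrelapse = 2,
    healthy = healthy_config(n_healthy = 3, n_clones = 500, depth = 2500,
                             seed = 11),
    depth_tp1 = 1500, depth_tp3 = 1500, seed = 12))
  dir <- tempfile()
  write_cohort_inputs(sim, dir)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  key <- names(sim$repertoires)[1]
  back <- read_clonotype_table(
    file.path(dir, "repertoires", paste0(key, ".tsv")))
  expect_equal(back$clonotypes$cdr3_nt,
               sim$repertoires[[key]]$clonotypes$cdr3_nt)
  expect_equal(back$total_reads, sim$repertoires[[key]]$total_reads)
  expect_length(list.files(file.path(dir, "signatures")), 2)
})
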