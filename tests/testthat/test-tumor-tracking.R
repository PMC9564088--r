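test_that("levenshtein handles the canonical cases", {
  expect_equal(levenshtein("TGTAAA", "TGTAAA"), 0)
  expect_equal(levenshtein("ACGT", "AGT"), 1)
  expect_equal(levenshtein("", "ACG"), 3)
  # the two dominant clones of the shipped patient-419 tumor signature
  # differ by a single substitution
  sig <- readr::read_tsv(fixture_path("tumor_signature_419.tsv"),
                         show_col_types = FALSE)
  expect_equal(levenshtein(sig$cdr3_nt[1], sig$cdr3_nt[2]), 1)
  expect_error(levenshtein("ACGN", "ACG"), "A/C/G/T")
})

test_that("levenshtein agrees with the DP oracle and is a metric", {
  set.seed(21)
  rand_seq <- function() paste(sample(c("A", "C", "G", "T"),
                                      sample(0:60, 1), replace = TRUE),
                               collapse = "")
  for (i in 1:300) {
    a <- rand_seq()
    b <- rand_seq()
    d <- levenshtein(a, b)
    expect_identical(d, as.integer(dp_levenshtein(a, b)))
    expect_identical(d, levenshtein(b, a))  # symmetry
  }
  for (i in 1:100) {  # triangle inequality on random triples
    a <- rand_seq(); b <- rand_seq(); c <- rand_seq()
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("primary clusters follow the 5% collective-fraction rule", {
  mk <- function(fracs, seqs) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("cdr3_nt\tfraction", paste(seqs, fracs, sep = "\t")), f)
    read_tumor_signature(f, patient_id = "t")
  }
  # two unrelated clones at 97.3% / 0.6%: only one primary cluster
  s1 <- extract_primary_clusters(mk(c(0.973, 0.006),
                                    c("TGTCAGCAGATTGATACCTGGCCTCGAACCTTC",
                                      "TGTCTGCAGCATAATAGATACCCGCTCACTTTC")))
  expect_equal(sum(s1$clusters$primary), 1)
  expect_equal(nrow(s1$clusters), 2)

  # 86.2% / 7.9%, unrelated: both clusters primary
  s2 <- extract_primary_clusters(mk(c(0.862, 0.079),
                                    c("TGTAAATTT", "GGGCCCGGG")))
  expect_equal(sum(s2$clusters$primary), 2)

  # single cluster at 100%
  s3 <- extract_primary_clusters(mk(1, "TGTAAATTT"))
  expect_equal(sum(s3$clusters$primary), 1)

  # related clones at Hamming 1 pool into one cluster before thresholding
  s4 <- extract_primary_clusters(mk(c(0.04, 0.04),
                                    c("TGTAAATTT", "TGTAAATTA")))
  expect_equal(nrow(s4$clusters), 1)
  expect_true(s4$clusters$primary)
})

test_that("the shipped patient-419 signature forms one primary cluster of two clones", {
  sig <- extract_primary_clusters(
    read_tumor_signature(fixture_path("tumor_signature_419.tsv"),
                         patient_id = "419"))
  expect_equal(nrow(sig$clusters), 1)   # the two sequences are LD-1 kin
  expect_true(sig$clusters$primary)
  expect_equal(sig$clusters$n_sequences, 2)
})

test_that("tumor matching calls MRD on exact identity only", {
  sig <- extract_primary_clusters(repertoire(
    data.frame(cdr3_nt = "TGTCAGCAAAGTTACAGTATTCCTCGGACGTTC",
               read_count = 100),
    subject_id = "pt"))
  tumor_seq <- "TGTCAGCAAAGTTACAGTATTCCTCGGACGTTC"
  variant <- "TGTCAGCAAAGTTACAGTATTCCTCGGACCTTC"

  present <- repertoire(data.frame(
    cdr3_nt = c(tumor_seq, "AAACCCGGGTTTAAACCCGGGTTTAAACCC"),
    read_count = c(2, 998)), timepoint = "TP1")
  m <- match_tumor_clones(sig, present)
  expect_true(m$mrd_positive)
  expect_equal(m$ld, 0L)
  expect_equal(tumor_fraction(sig, present), 0.002)

  related <- repertoire(data.frame(cdr3_nt = variant, read_count = 10),
                        timepoint = "TP2")
  m2 <- match_tumor_clones(sig, related)
  expect_false(m2$mrd_positive)
  expect_true(m2$related)
  expect_equal(m2$ld, 1L)
  expect_equal(tumor_fraction(sig, related), 0)

  unrelated <- repertoire(data.frame(
    cdr3_nt = "GGGGGGGGGGAAAAAAAAAATTTTTTTTTT", read_count = 5))
  m3 <- match_tumor_clones(sig, unrelated)
  expect_false(m3$mrd_positive)
  expect_false(m3$related)
  expect_gt(m3$ld, 1)

  # exact peripheral == tumor clone
  self_rep <- repertoire(data.frame(cdr3_nt = tumor_seq, read_count = 7))
  expect_equal(tumor_fraction(sig, self_rep), 1.0)
})

test_that("closest-match ties break lexicographically", {
  sig <- extract_primary_clusters(repertoire(
    data.frame(cdr3_nt = "AAAA", read_count = 10), subject_id = "pt"))
  peri <- repertoire(data.frame(cdr3_nt = c("AAAT", "AAAC"),
                                read_count = c(1, 1)))
  m <- match_tumor_clones(sig, peri)
  expect_equal(m$ld, 1L)
  expect_equal(m$closest_match, "AAAC")
})

test_that("minimum LD is zero exactly when the tumor fraction is positive", {
  set.seed(22)
  for (i in 1:10) {
    peri <- random_test_repertoire(n_base = 30, n_mut = 20)
    tum_seq <- if (i %% 2 == 0) {
      peri$clonotypes$cdr3_nt[sample(nrow(peri$clonotypes), 1)]
    } else {
      paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
            collapse = "")
    }
    sig <- extract_primary_clusters(
      repertoire(data.frame(cdr3_nt = tum_seq, read_count = 50)))
    m <- match_tumor_clones(sig, peri)
    expect_equal(min(m$ld) == 0, tumor_fraction(sig, peri) > 0)
  }
})

test_that("spike-in networks label residual vs absent tumor clones", {
  tumor_seq <- "TGTCAGCAAAGTTACAGTATTCCTCGGACGTTC"
  variant <- "TGTCAGCAAAGTTACAGTATTCCTCGGACCTTC"
  sig <- extract_primary_clusters(repertoire(
    data.frame(cdr3_nt = tumor_seq, read_count = 100)))

  # absent, unrelated tumor clone: blue vertex of degree 0
  peri <- repertoire(data.frame(
    cdr3_nt = "GGGGGGGGGGAAAAAAAAAATTTTTTTTTT", read_count = 5))
  net <- spike_in_network(sig, peri)
  tv <- which(net$vertices$sequence == tumor_seq)
  expect_equal(net$vertices$label[tv], "tumor_absent")
  expect_equal(net$vertices$count[tv], 1)
  expect_false(any(unlist(net$edges) == tv))
  expect_equal(nrow(net$vertices), 2)

  # present tumor clone keeps its peripheral count
  peri2 <- repertoire(data.frame(cdr3_nt = c(tumor_seq, "AAAA"),
                                 read_count = c(42, 1)))
  net2 <- spike_in_network(sig, peri2)
  tv2 <- which(net2$vertices$sequence == tumor_seq)
  expect_equal(net2$vertices$label[tv2], "tumor_mrd")
  expect_equal(net2$vertices$count[tv2], 42)

  # a 1-substitution peripheral variant connects to the spiked vertex
  peri3 <- repertoire(data.frame(cdr3_nt = variant, read_count = 10))
  net3 <- spike_in_network(sig, peri3)
  expect_equal(nrow(net3$edges), 1)
  expect_setequal(net3$vertices$sequence[unlist(net3$edges[1, ])],
                  c(tumor_seq, variant))
  expect_equal(net3$vertices$label[net3$vertices$sequence == variant],
               "normal")
})

test_that("spike-in vertex count is |peripheral| + |tumor not in peripheral|", {
  set.seed(23)
  for (i in 1:5) {
    peri <- random_test_repertoire(n_base = 30, n_mut = 30)
    tum <- repertoire(data.frame(
      cdr3_nt = c(peri$clonotypes$cdr3_nt[1],
                  paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                        collapse = "")),
      read_count = c(50, 50)))
    sig <- extract_primary_clusters(tum)
    net <- spike_in_network(sig, peri)
    n_peri <- length(unique(peri$clonotypes$cdr3_nt))
    n_new <- length(setdiff(primary_seqs <- unlist(sig$clusters$sequences),
                            peri$clonotypes$cdr3_nt))
    expect_equal(nrow(net$vertices), n_peri + n_new)
  }
})
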