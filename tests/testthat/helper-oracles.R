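# Independent oracles used across the suite. These deliberately use naive
# brute-force algorithms (or a different library) than the implementation
# under test.

# Hand-written dynamic-programming edit distance (row-vectorized Wagner-
# Fischer), independent of utils::adist and of the network key hashing.
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    sub_cost <- prev[1:m] + (ca[i] != cb)
    for (j in seq_len(m)) {
      cur[j + 1] <- min(cur[j] + 1, prev[j + 1] + 1, sub_cost[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

# Brute-force all-pairs neighbour sets from a full edit-distance matrix
# (utils::adist, C code, no key hashing involved). Equal-length pairs at
# edit distance 1 are exactly the Hamming-1 pairs.
brute_force_pairs <- function(seqs, rule = c("hamming1", "levenshtein1")) {
  rule <- match.arg(rule)
  d <- utils::adist(seqs, seqs)
  hit <- d == 1 & upper.tri(d)
  if (rule == "hamming1") {
    hit <- hit & outer(nchar(seqs), nchar(seqs), "==")
  }
  idx <- which(hit, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  matrix(as.integer(idx), ncol = 2, dimnames = list(NULL, c("i", "j")))
}

# Mann-Whitney rank statistic: P(pos > neg) + 0.5 P(pos == neg) over all
# cross-pairs; the classic AUC identity, computed by explicit enumeration.
rank_auc <- function(scores, labels, positive = "non_relapse") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Random repertoire with realistic local structure: base clones plus
# single-mutation variants (guaranteeing edges exist) and the occasional
# single-base indel variant.
random_test_repertoire <- function(n_base = 60, n_mut = 80, n_indel = 10,
                                   len_range = c(8, 15)) {
  rand_seq <- function(n) {
    vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
           function(L) paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = ""),
           character(1))
  }
  base <- unique(rand_seq(n_base))
  muts <- if (n_mut > 0) {
    mutate_sequence(sample(base, n_mut, replace = TRUE))
  } else character(0)
  indels <- if (n_indel > 0) {
    vapply(sample(base, n_indel, replace = TRUE), function(s) {
      p <- sample(nchar(s), 1)
      if (stats::runif(1) < 0.5 && nchar(s) > 1) {
        paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
      } else {
        paste0(substr(s, 1, p), sample(c("A", "C", "G", "T"), 1),
               substr(s, p + 1, nchar(s)))
      }
    }, character(1))
  } else character(0)
  seqs <- unique(c(base, muts, indels))
  repertoire(data.frame(cdr3_nt = seqs,
                        read_count = sample(1:50, length(seqs),
                                            replace = TRUE)))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "bcrnet")
}

write_tsv_fixture <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}
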