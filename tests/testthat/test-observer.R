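test_that("k-mer extraction enumerates occurrences and repeats", {
  km <- extract_kmers("ACGTA", 3)
  expect_setequal(km$kmer, c("ACG", "CGT", "GTA"))
  expect_false(any(km$repeated))
  km2 <- extract_kmers("AAAA", 3)
  expect_identical(km2$kmer, "AAA")
  expect_identical(km2$n, 2L)
  expect_true(km2$repeated)
  s <- random_sequence(100, seed = 5)
  expect_identical(sum(extract_kmers(s, 5)$n), 96L)
  expect_error(extract_kmers("ACG", 4), class = "indelrates_invalid_argument")
})

test_that("unitigs of a branchless sequence reassemble the sequence", {
  u <- build_unitigs(extract_kmers("AACCGGTT", 3), 3)
  expect_identical(u$unitig, "AACCGGTT")
  expect_identical(build_unitigs("ACGTT", 5)$unitig, "ACGTT")
})

test_that("a branch splits unitigs", {
  u <- build_unitigs(c("AAC", "ACG", "ACT"), 3)
  expect_setequal(u$unitig, c("AAC", "ACG", "ACT"))
})

test_that("unitig construction matches maximal-path enumeration on random inputs", {
  set.seed(41)
  for (case in 1:60) {
    L <- sample(10:60, 1)
    k <- sample(3:6, 1)
    if (k > L) next
    s <- random_sequence(L, c(A = 0.4, C = 0.3, G = 0.2, T = 0.1))
    km <- extract_kmers(s, k)
    got <- sort(build_unitigs(km, k)$unitig)
    want <- oracle_unitigs(km$kmer, k)
    # unitig content must always match; exact spellings match except on
    # isolated cycles, where the cut point is arbitrary
    kmers_of <- function(tigs) {
      sort(unique(unlist(lapply(tigs, function(t) {
        substring(t, seq_len(nchar(t) - k + 1), seq_len(nchar(t) - k + 1) + k - 1)
      }))))
    }
    expect_identical(kmers_of(got), sort(km$kmer),
                     info = sprintf("case %d content", case))
    expect_identical(kmers_of(got), kmers_of(want),
                     info = sprintf("case %d vs oracle", case))
    if (identical(sort(unique(c(substr(km$kmer, 1, k - 1),
                                substr(km$kmer, 2, k)))),
                  character(0))) next
    expect_identical(length(got), length(want),
                     info = sprintf("case %d path count", case))
  }
})

test_that("every distinct k-mer lands in exactly one unitig", {
  set.seed(42)
  for (case in 1:20) {
    s <- random_sequence(sample(50:200, 1))
    k <- sample(4:8, 1)
    km <- extract_kmers(s, k)
    tigs <- build_unitigs(km, k)$unitig
    all_kmers <- unlist(lapply(tigs, function(t) {
      substring(t, seq_len(nchar(t) - k + 1),
                seq_len(nchar(t) - k + 1) + k - 1)
    }))
    expect_identical(sort(all_kmers), sort(km$kmer))
    expect_false(any(duplicated(all_kmers)))
  }
})

test_that("infix alignment finds exact substrings and respects the threshold", {
  a <- infix_align("TTACGTTT", "ACGT")
  expect_identical(a$edit_distance, 0L)
  expect_identical(a$target_span, c(3L, 6L))
  expect_identical(a$ops, "====")

  a2 <- infix_align("ACGTACGT", "ACGACGT")
  expect_identical(a2$edit_distance, 1L)
  expect_identical(sum(strsplit(a2$ops, "")[[1]] == "D"), 1L)

  expect_null(infix_align("AAAA", "GGGG", max_distance = 1))
})

test_that("infix alignment agrees with the quadratic DP oracle", {
  set.seed(43)
  for (case in 1:200) {
    t <- random_sequence(sample(5:40, 1), c(A = .4, C = .3, G = .2, T = .1))
    q <- random_sequence(sample(1:40, 1), c(A = .4, C = .3, G = .2, T = .1))
    a <- infix_align(t, q)
    expect_identical(a$edit_distance, oracle_infix_distance(t, q),
                     info = sprintf("case %d: t=%s q=%s", case, t, q))
    # the edit script must replay to the reported distance and span
    ops <- strsplit(a$ops, "")[[1]]
    expect_identical(sum(ops %in% c("X", "I", "D")), a$edit_distance)
    expect_identical(sum(ops %in% c("=", "X", "D")),
                     a$target_span[2] - a$target_span[1] + 1L)
    expect_identical(sum(ops %in% c("=", "X", "I")), nchar(q))
    # matched columns really match
    tc <- strsplit(t, "")[[1]]
    qc <- strsplit(q, "")[[1]]
    ti <- a$target_span[1] - 1L
    qi <- 0L
    for (o in ops) {
      if (o %in% c("=", "X", "D")) ti <- ti + 1L
      if (o %in% c("=", "X", "I")) qi <- qi + 1L
      if (o == "=") expect_identical(tc[ti], qc[qi])
      if (o == "X") expect_false(identical(tc[ti], qc[qi]))
    }
  }
})

test_that("window counting matches brute-force enumeration of edit scripts", {
  set.seed(44)
  for (case in 1:100) {
    t <- random_sequence(sample(10:60, 1))
    q <- random_sequence(sample(5:60, 1))
    a <- infix_align(t, q)
    k <- sample(2:6, 1)
    got <- count_windows(a, k)
    want <- oracle_count_windows(a$ops, a$target_span[1], k)
    expect_identical(got$n_contrib, want$n_contrib,
                     info = sprintf("case %d N (ops=%s)", case, a$ops))
    expect_identical(got$d_contrib, want$d_contrib,
                     info = sprintf("case %d D (ops=%s)", case, a$ops))
    expect_identical(nrow(got$windows), got$n_contrib + got$d_contrib)
  }
})

test_that("perfect and short alignments hit the window-count edge cases", {
  a <- infix_align(strrep("ACGT", 10), strrep("ACGT", 10))
  cw <- count_windows(a, 5)
  expect_identical(cw$n_contrib, 40L - 5L + 1L)
  expect_identical(cw$d_contrib, 0L)
  # aligned region shorter than k
  a2 <- infix_align("TTTTACGTTTT", "ACG")
  expect_identical(count_windows(a2, 5)$n_contrib, 0L)
  expect_identical(count_windows(a2, 5)$d_contrib, 0L)
})

test_that("a single interior deletion contributes k windows to D", {
  t <- random_sequence(60, seed = 46)
  q <- paste0(substr(t, 1, 29), substr(t, 31, 60))  # delete position 30
  a <- infix_align(t, q)
  expect_identical(a$edit_distance, 1L)
  k <- 7
  cw <- count_windows(a, k)
  covered <- a$target_span[2] - a$target_span[1] + 1L - as.integer(k) + 1L
  expect_identical(cw$d_contrib + cw$n_contrib, covered)
  expect_identical(cw$d_contrib, 7L)
})

test_that("estimate_counts recovers exact counts for identical sequences", {
  s <- random_sequence(3000, seed = 47)
  cnt <- estimate_counts(s, s, 21)
  expect_identical(cnt$N, 3000 - 21 + 1)
  expect_identical(cnt$D, 0)
  expect_identical(cnt$provenance, "alignment-estimated")
})

test_that("estimate_counts returns zero counts for unrelated sequences", {
  s1 <- strrep("AC", 200)
  s2 <- strrep("GT", 200)
  cnt <- suppressWarnings(estimate_counts(s1, s2, 11))
  expect_identical(cnt$N, 0)
  expect_identical(cnt$D, 0)
})

test_that("observer count error grows with the mutation rate", {
  L <- 3e4; k <- 21
  S <- random_sequence(L, composition_fracA(0.30), seed = 301)
  rates <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  rel_err <- vapply(rates, function(r) {
    rec <- mutate_sequence(S, mutation_params(r, r, r),
                           seed = 300 + round(100 * r))
    gt <- ground_truth_counts(rec, k)
    obs <- estimate_counts(S, rec$mutated, k)
    mean(c(abs(obs$N - gt$N) / gt$N, abs(obs$D - gt$D) / max(gt$D, 1)))
  }, numeric(1))
  expect_lt(rel_err[1], rel_err[5])
  expect_gt(stats::cor(rates, rel_err, method = "spearman"), 0)
})

test_that("alignment-estimated counts calibrate against ground truth", {
  L <- 3e4; k <- 21
  S <- random_sequence(L, composition_fracA(0.30), seed = 48)
  rec <- mutate_sequence(S, mutation_params(0.01, 0.01, 0.01), seed = 49)
  gt <- ground_truth_counts(rec, k)
  obs <- estimate_counts(S, rec$mutated, k)
  expect_lt(abs(obs$N - gt$N) / gt$N, 0.05)
  expect_lt(abs(obs$D - gt$D) / gt$D, 0.05)
})
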