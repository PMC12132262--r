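test_that("FASTA round trip preserves residues and headers", {
  s <- random_sequence(1000, seed = 61)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(path, s, header = "synthetic test sequence")
  back <- read_fasta(path)
  expect_identical(unname(back), s)
  expect_identical(names(back), "synthetic test sequence")
  # wrapped at 80 columns
  lines <- readLines(path)
  expect_true(all(nchar(lines[-1]) <= 80))
})

test_that("FASTA reader enforces the alphabet policy", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTNNACGT"), path)
  expect_error(read_fasta(path), "position 5",
               class = "indelrates_invalid_character")
  s <- suppressMessages(read_fasta(path, replace_ambiguous = TRUE, seed = 3))
  expect_identical(nchar(unname(s)), 10L)
  expect_false(grepl("[^ACGT]", s))
  # untouched residues preserved
  expect_identical(unname(substr(s, 1, 4)), "ACGT")
})

test_that("multi-record FASTA follows the documented dialect", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGT", ">r2", "GGCC"), path)
  expect_warning(one <- read_fasta(path), "2 records")
  expect_identical(unname(one), "ACGT")
  all_recs <- read_fasta(path, all_records = TRUE)
  expect_identical(unname(all_recs), c("ACGT", "GGCC"))
  expect_error(read_fasta(withr::local_tempfile(fileext = ".fa")),
               class = "indelrates_missing_file")
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), class = "indelrates_malformed_fasta")
})

test_that("run_experiment is byte-identical under a fixed master seed", {
  cfg <- experiment_config(mode = "rate_grid", L = 2000, k = 11,
                           ps = c(0.01, 0.05), pd = 0.02, g = 0.02,
                           replicates = 3, seed = 7)
  t1 <- run_experiment(cfg)
  t2 <- run_experiment(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_result_tsv(t1, p1); write_result_tsv(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(nrow(t1), 2L * 3L * 3L)  # settings x replicates x params
})

test_that("failed settings are recorded, not fatal", {
  cfg <- experiment_config(mode = "composition_sweep", L = 400, k = 5,
                           frac_A = c(0.25, 0.30), ps = 0.01, pd = 0.01,
                           g = 0.01, replicates = 1, seed = 2)
  tab <- run_experiment(cfg)
  bad <- dplyr::filter(tab, frac_A == 0.25)
  # exact-quarter composition can fail (4cA == L); if it did, the note says so
  if (any(is.na(bad$estimate))) {
    expect_true(any(grepl("25%", bad$note)))
  }
  good <- dplyr::filter(tab, frac_A == 0.30)
  expect_true(all(!is.na(good$estimate)))
})

test_that("summaries compute bias, RMSE and flags per the conventions", {
  tab <- tibble::tibble(
    mode = "rate_grid", setting = 1L, L = 100, frac_A = 0.3, k = 5L,
    ps = 0.05, pd = 0.05, g = 0.05, replicate = 1:2, seed = 1:2,
    estimator = "pd", truth = 0.05, estimate = c(0.04, 0.06),
    note = NA_character_
  )
  sm <- summarize_experiment(tab)
  expect_equal(sm$bias, 0)
  expect_equal(sm$rmse, 0.01)
  expect_equal(sm$n, 2L)

  exact <- dplyr::mutate(tab, estimate = truth)
  sm2 <- summarize_experiment(exact)
  expect_equal(sm2$bias, 0)
  expect_equal(sm2$rmse, 0)

  single <- tab[1, ]
  sm3 <- summarize_experiment(single)
  expect_identical(sm3$sd, 0)
  expect_true(sm3$single_replicate)
  expect_error(summarize_experiment(tab[0, ]),
               class = "indelrates_invalid_argument")
})

test_that("k sweep dispersion grows with k and length sweep shrinks with L", {
  cfg_k <- experiment_config(mode = "k_sweep", L = 1e5, k = c(11, 31),
                             ps = 0.05, pd = 0.05, g = 0.05,
                             replicates = 12, seed = 5)
  sm_k <- summarize_experiment(run_experiment(cfg_k))
  # the k effect is assessed for pd and g; the variability of the
  # substitution estimator is known to be nearly flat across moderate k
  for (p in c("pd", "g")) {
    sds <- sm_k$sd[sm_k$estimator == p][order(sm_k$k[sm_k$estimator == p])]
    expect_lte(sds[1], sds[2])
  }

  cfg_L <- experiment_config(mode = "length_sweep", L = c(1e4, 1e5), k = 21,
                             ps = 0.05, pd = 0.05, g = 0.05,
                             replicates = 8, seed = 6)
  sm_L <- summarize_experiment(run_experiment(cfg_L))
  for (p in c("ps", "pd", "g")) {
    sds <- sm_L$sd[sm_L$estimator == p][order(sm_L$L[sm_L$estimator == p])]
    expect_gte(sds[1], sds[2])
  }
})

test_that("smm_compare mode adds an overestimating baseline column", {
  cfg <- experiment_config(mode = "smm_compare", L = 5e4, k = 21,
                           ps = 0.01, pd = 0.05, g = 0.05,
                           replicates = 5, seed = 8)
  tab <- run_experiment(cfg)
  expect_true("ps_smm" %in% tab$estimator)
  mean_smm <- mean(tab$estimate[tab$estimator == "ps_smm"])
  mean_ps <- mean(tab$estimate[tab$estimator == "ps"])
  expect_gt(mean_smm, mean_ps)
  expect_gt(mean_smm, 0.01)
})

test_that("experiment plots build without error", {
  cfg <- experiment_config(mode = "k_sweep", L = 2000, k = c(7, 11),
                           ps = 0.02, pd = 0.02, g = 0.02,
                           replicates = 3, seed = 9)
  tab <- run_experiment(cfg)
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})

test_that("derived per-run seeds are reproducible and spread out", {
  s1 <- derive_seed(1, 1, 1)
  expect_identical(s1, derive_seed(1, 1, 1))
  grid <- expand.grid(setting = 1:20, rep = 1:20)
  seeds <- mapply(derive_seed, 1, grid$setting, grid$rep)
  expect_identical(anyDuplicated(seeds), 0L)
})

test_that("the CLI script parses cleanly", {
  path <- system.file("cli", "indelrates.R", package = "indelrates")
  expect_true(nzchar(path))
  expect_no_error(parse(path))
})
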