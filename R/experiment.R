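#' Configuration of a parameter-recovery experiment
#'
#' Describes one of the standard simulation sweeps: vary the k-mer size
#' (`k_sweep`), the sequence length (`length_sweep`), the base composition
#' (`composition_sweep`), the true mutation rates (`rate_grid`), or compare
#' the indel-aware substitution estimate with the substitution-only baseline
#' (`smm_compare`). Vector-valued fields are expanded into a full settings
#' grid; every setting is replicated `replicates` times with per-run seeds
#' derived deterministically from `seed` (see [derive_seed()]).
#'
#' @param mode One of `"k_sweep"`, `"length_sweep"`, `"composition_sweep"`,
#'   `"rate_grid"`, `"smm_compare"`.
#' @param L Sequence length(s).
#' @param frac_A Fraction(s) of 'A' in the reference composition (the rest is
#'   split equally over C, G, T).
#' @param k k-mer size(s).
#' @param ps,pd,g True mutation-rate value(s); vectors are crossed.
#' @param replicates Replicates per setting (>= 1).
#' @param seed Master seed.
#' @param counts_source `"ground_truth"` (count k-spans from the mutation
#'   record) or `"alignment"` (estimate them with [estimate_counts()]).
#' @param max_dist_frac Alignment rejection threshold for the alignment
#'   observer.
#' @param reference Optional FASTA path or DNA string to use as the reference
#'   sequence instead of generating one (real-genome mode); `L` and `frac_A`
#'   are then ignored.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(mode = c("rate_grid", "k_sweep", "length_sweep",
                                       "composition_sweep", "smm_compare"),
                              L = 1e5, frac_A = 0.30, k = 21,
                              ps = 0.05, pd = 0.05, g = 0.05,
                              replicates = 10, seed = 1,
                              counts_source = c("ground_truth", "alignment"),
                              max_dist_frac = 0.35,
                              reference = NULL) {
  mode <- match.arg(mode)
  counts_source <- match.arg(counts_source)
  if (replicates < 1) {
    abort("`replicates` must be >= 1.", class = "indelrates_invalid_argument")
  }
  for (v in list(ps = ps, pd = pd, g = g)) {
    if (any(v < 0)) abort("Rates must be non-negative.",
                          class = "indelrates_invalid_argument")
  }
  if (any(ps + pd >= 1) || any(ps >= 1) || any(pd >= 1)) {
    abort("Need ps < 1, pd < 1 and ps + pd < 1 for all grid values.",
          class = "indelrates_invalid_argument")
  }
  if (any(frac_A < 0 | frac_A > 1)) {
    abort("`frac_A` must lie in [0, 1].",
          class = "indelrates_invalid_argument")
  }
  structure(
    list(mode = mode, L = L, frac_A = frac_A, k = k, ps = ps, pd = pd, g = g,
         replicates = as.integer(replicates), seed = as.integer(seed),
         counts_source = counts_source, max_dist_frac = max_dist_frac,
         reference = reference),
    class = "experiment_config"
  )
}

#' Deterministic per-run seed derivation
#'
#' Derives the seed of an individual simulation run from the master seed, the
#' setting index and the replicate index via two steps of a Lehmer-style
#' congruential mix (`x <- (x * 48271 + key) mod (2^31 - 1)`). Every run is
#' therefore independently reproducible from `(master, setting, replicate)`.
#'
#' @param master Master seed (integer).
#' @param setting Setting index (integer >= 1).
#' @param replicate Replicate index (integer >= 1).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, setting, replicate) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 48271 + as.numeric(setting)) %% m
  x <- (x * 48271 + as.numeric(replicate)) %% m
  as.integer(x + 1)
}

settings_grid <- function(config) {
  grid <- tidyr::expand_grid(
    L = config$L, frac_A = config$frac_A, k = config$k,
    ps = config$ps, pd = config$pd, g = config$g
  )
  dplyr::mutate(grid, setting = dplyr::row_number(), .before = 1)
}

#' Run a parameter-recovery experiment
#'
#' For every setting of the configuration grid and every replicate: generate
#' a reference sequence (or reuse the configured one), push it through the
#' mutation channel, obtain the k-span counts from the requested source,
#' apply the closed-form estimators (and the substitution-only baseline in
#' `smm_compare` mode), and append one row per estimated parameter. The run
#' is fully deterministic given the master seed. A failing setting/replicate
#' (e.g. degenerate 25% 'A' composition) is recorded with `NA` estimates and
#' the error message in `note` rather than aborting the sweep.
#'
#' @param config An [experiment_config()].
#' @return A `rates_experiment` tibble with columns `mode`, `setting`, `L`,
#'   `frac_A`, `k`, `ps`, `pd`, `g`, `replicate`, `seed`, `estimator`
#'   (`"ps"`, `"pd"`, `"g"`, or `"ps_smm"`), `truth`, `estimate`, `note`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- settings_grid(config)
  ref_seq <- NULL
  if (!is.null(config$reference)) {
    ref_seq <- if (file.exists(config$reference)) {
      unname(read_fasta(config$reference))
    } else {
      validate_sequence(config$reference, "reference")
      config$reference
    }
  }

  rows <- purrr::pmap(grid, function(setting, L, frac_A, k, ps, pd, g) {
    purrr::map(seq_len(config$replicates), function(rep) {
      run_seed <- derive_seed(config$seed, setting, rep)
      base <- tibble(
        mode = config$mode, setting = setting, L = L, frac_A = frac_A,
        k = k, ps = ps, pd = pd, g = g, replicate = rep, seed = run_seed
      )
      res <- tryCatch({
        S <- ref_seq %||%
          random_sequence(L, composition_fracA(frac_A), seed = run_seed)
        rec <- mutate_sequence(S, mutation_params(ps, pd, g),
                               seed = derive_seed(run_seed, setting, rep))
        counts <- if (config$counts_source == "ground_truth") {
          ground_truth_counts(rec, k)
        } else {
          estimate_counts(S, rec$mutated, k,
                          max_dist_frac = config$max_dist_frac)
        }
        est <- estimate_rates(counts)
        out <- tibble(
          estimator = c("ps", "pd", "g"),
          truth = c(ps, pd, g),
          estimate = c(est$ps_hat, est$pd_hat, est$g_hat),
          note = NA_character_
        )
        if (config$mode == "smm_compare") {
          L0 <- nchar(S) - k + 1
          out <- dplyr::bind_rows(out, tibble(
            estimator = "ps_smm", truth = ps,
            estimate = smm_substitution_rate(counts$N, L0, k),
            note = NA_character_
          ))
        }
        out
      }, error = function(e) {
        tibble(estimator = c("ps", "pd", "g"),
               truth = c(ps, pd, g), estimate = NA_real_,
               note = conditionMessage(e))
      })
      dplyr::bind_cols(base[rep(1, nrow(res)), ], res)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rates_experiment", class(out))
  out
}

#' Summarize an experiment table
#'
#' Per-setting, per-estimator summary: replicate count, mean and standard
#' deviation of the estimates, bias (`mean - truth`) and RMSE. A setting with
#' a single replicate reports `sd = 0` and is flagged in `single_replicate`.
#' Failed replicates (NA estimates) are dropped from the statistics; their
#' count is reported in `n_failed`.
#'
#' @param table A `rates_experiment` tibble from [run_experiment()].
#' @return A tibble with one row per (setting, estimator).
#' @export
summarize_experiment <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("`table` must be a non-empty experiment table.",
          class = "indelrates_invalid_argument")
  }
  grp <- intersect(
    c("mode", "setting", "L", "frac_A", "k", "ps", "pd", "g", "estimator",
      "truth"),
    names(table)
  )
  out <- dplyr::summarise(
    dplyr::group_by(table, dplyr::across(dplyr::all_of(grp))),
    n = sum(!is.na(.data$estimate)),
    n_failed = sum(is.na(.data$estimate)),
    mean = mean(.data$estimate, na.rm = TRUE),
    sd = ifelse(sum(!is.na(.data$estimate)) > 1,
                sd(.data$estimate, na.rm = TRUE), 0),
    bias = mean(.data$estimate, na.rm = TRUE) - .data$truth[1],
    rmse = sqrt(mean((.data$estimate - .data$truth)^2, na.rm = TRUE)),
    single_replicate = sum(!is.na(.data$estimate)) == 1,
    .groups = "drop"
  )
  out
}

#' Write an experiment table as TSV
#'
#' Fixed-header TSV serialization; byte-identical for identical tables.
#'
#' @param table A tibble (experiment or summary).
#' @param path Output path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}
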