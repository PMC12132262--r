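#' Expected values of the observable statistics under the indel channel
#'
#' Closed-form expectations of the five observables of the mutation channel
#' for a reference of length `L` with `cA` 'A' characters, mutated with
#' parameters `(ps, pd, g)`, at span length `k` (`L0 = L - k + 1`):
#' \deqn{E[L'] = L (1 + g - pd)}
#' \deqn{E[N] = L0 (1 - ps - pd)^k / (g+1)^{k-1}}
#' \deqn{E[D] = L0 \, k (1 - ps - pd)^{k-1} pd / (g+1)^{k-1}}
#' \deqn{E[cA'] = cA (1 - ps - pd) + ps (L - cA)/3 + g L / 4}
#' \deqn{E[P] = (L - 4 cA) (1 - \tfrac{4}{3} ps - pd)}
#' Powers of `1 - ps - pd` are evaluated via `exp(k * log1p(-(ps+pd)))` for
#' stability at large `k`. Arguments are vectorized and recycled.
#'
#' @param L Reference length(s).
#' @param cA Count(s) of 'A' in the reference.
#' @param params A [mutation_params()] object, or a data frame with columns
#'   `ps`, `pd`, `g` (one row per setting).
#' @param k Span length(s), `k <= L`.
#' @return A tibble with the context columns `L`, `cA`, `k`, `ps`, `pd`, `g`
#'   and the expectation columns `E_Lprime`, `E_N`, `E_D`, `E_cAprime`, `E_P`.
#' @examples
#' expected_stats(1e6, 3e5, mutation_params(0.05, 0.05, 0.05), k = 21)
#' @export
expected_stats <- function(L, cA, params, k) {
  if (is.data.frame(params)) {
    need <- c("ps", "pd", "g")
    if (!all(need %in% names(params))) {
      abort("`params` data frame needs columns ps, pd, g.",
            class = "indelrates_invalid_argument")
    }
    ps <- params$ps; pd <- params$pd; g <- params$g
    ok <- ps >= 0 & ps < 1 & pd >= 0 & pd < 1 & ps + pd < 1 & g >= 0
    if (!all(ok)) {
      abort("Invalid mutation parameters in `params`.",
            class = "indelrates_invalid_argument")
    }
  } else {
    params <- as_mutation_params(params)
    ps <- params$ps; pd <- params$pd; g <- params$g
  }
  if (any(k > L) || any(k < 1)) {
    abort("Need 1 <= k <= L.", class = "indelrates_invalid_argument")
  }
  ctx <- tibble(L = L, cA = cA, k = k, ps = ps, pd = pd, g = g)
  L <- ctx$L; cA <- ctx$cA; k <- ctx$k
  ps <- ctx$ps; pd <- ctx$pd; g <- ctx$g

  L0 <- L - k + 1
  stay_k <- exp(k * log1p(-(ps + pd)))          # (1-ps-pd)^k
  stay_km1 <- exp((k - 1) * log1p(-(ps + pd)))  # (1-ps-pd)^(k-1)
  gpow <- exp((k - 1) * log1p(g))               # (g+1)^(k-1)

  dplyr::mutate(
    ctx,
    E_Lprime = L * (1 + g - pd),
    E_N = L0 * stay_k / gpow,
    E_D = L0 * k * stay_km1 * pd / gpow,
    E_cAprime = cA * (1 - ps - pd) + ps * (L - cA) / 3 + g * L / 4,
    E_P = (L - 4 * cA) * (1 - 4 / 3 * ps - pd)
  )
}

#' Expectations as a span-count table
#'
#' Convenience wrapper that reshapes [expected_stats()] into the column
#' layout of [ground_truth_counts()], so the expected values can be fed
#' straight into [estimate_rates()] (the algebraic round-trip recovers the
#' generating parameters exactly).
#'
#' @inheritParams expected_stats
#' @return A `span_counts` tibble with `provenance = "expectation"`.
#' @export
expected_counts <- function(L, cA, params, k) {
  ex <- expected_stats(L, cA, params, k)
  new_span_counts(
    N = ex$E_N, D = ex$E_D, L_prime = ex$E_Lprime, cA_prime = ex$E_cAprime,
    k = ex$k, L = ex$L, cA = ex$cA, provenance = "expectation"
  )
}

#' Closed-form estimators of the mutation parameters
#'
#' Moment estimators for the substitution rate, deletion rate and mean
#' insertion length, obtained by substituting the observed statistics
#' `(N, D, L', cA')` for their expectations in the linear system implied by
#' the channel's moment equations:
#' \deqn{\hat p_s = \frac{3[kN(L'-L+4cA-4cA') + D(L'-4cA')]}{(4cA-L)(D+4kN)}}
#' \deqn{\hat p_d = \frac{D[3(L'-4cA') + L-4cA]}{(L-4cA)(D+4kN)}}
#' \deqn{\hat g = L'/L - 1 + \hat p_d}
#' Estimates are deliberately *not* clamped to their natural ranges:
#' out-of-range (e.g. negative) values are informative about ill-conditioned
#' inputs such as near-25% 'A' composition. Set `clamp = TRUE` to truncate
#' `ps_hat` and `pd_hat` to `[0, 1)` and `g_hat` to `[0, Inf)` for downstream
#' use.
#'
#' The estimators are undefined when `4 cA = L` (the composition statistic
#' `P` has expectation zero) and when `D + 4kN = 0` (no surviving signal);
#' both raise classed errors (`indelrates_degenerate_composition`,
#' `indelrates_insufficient_signal`).
#'
#' @param counts A data frame with columns `N`, `D`, `L_prime`, `cA_prime`,
#'   `k`, `L`, `cA` — one row per pair, e.g. from [ground_truth_counts()],
#'   [estimate_counts()] or [expected_counts()]. Extra columns are carried
#'   through.
#' @param clamp Clamp estimates to their natural ranges (default `FALSE`).
#' @return A `rate_estimates` tibble: the input columns plus `P`, `Q`, `R`,
#'   `T` diagnostics and the estimates `ps_hat`, `pd_hat`, `g_hat`.
#' @examples
#' counts <- expected_counts(1e6, 3e5, mutation_params(0.05, 0.05, 0.05), 21)
#' estimate_rates(counts)
#' @export
estimate_rates <- function(counts, clamp = FALSE) {
  counts <- derive_pqrt(counts)
  check_estimable(counts)
  N <- counts$N; D <- counts$D; k <- counts$k
  L <- counts$L; cA <- counts$cA
  Lp <- counts$L_prime; cAp <- counts$cA_prime

  ps_hat <- 3 * (k * N * (Lp - L + 4 * cA - 4 * cAp) + D * (Lp - 4 * cAp)) /
    ((4 * cA - L) * (D + 4 * k * N))
  pd_hat <- D * (3 * (Lp - 4 * cAp) + L - 4 * cA) /
    ((L - 4 * cA) * (D + 4 * k * N))
  g_hat <- Lp / L - 1 + pd_hat

  finish_estimates(counts, ps_hat, pd_hat, g_hat, clamp)
}

#' Alternate formulation of the estimators via P, Q, R, T
#'
#' Algebraically identical reformulation of [estimate_rates()] in terms of
#' the derived statistics `P = L'-4cA'`, `Q = kN+D`, `R = k(L-4cA)N`,
#' `T = 4kN+D`:
#' \deqn{\hat p_s = \frac{-3 (PQ - R)}{(L-4cA)\,T}, \quad
#'       \hat p_d = \frac{D (3P + L-4cA)}{(L-4cA)\,T}, \quad
#'       \hat g = L'/L - 1 + \hat p_d}
#' Kept as an independent code path; the two formulations agree to floating
#' round-off and are cross-checked in the test suite.
#'
#' @inheritParams estimate_rates
#' @return A `rate_estimates` tibble, as [estimate_rates()].
#' @export
estimate_rates_alt <- function(counts, clamp = FALSE) {
  counts <- derive_pqrt(counts)
  check_estimable(counts)
  L <- counts$L; cA <- counts$cA
  P <- counts$P; Q <- counts$Q; R <- counts$R; T <- counts$T

  ps_hat <- -3 * (P * Q - R) / ((L - 4 * cA) * T)
  pd_hat <- counts$D * (3 * P + L - 4 * cA) / ((L - 4 * cA) * T)
  g_hat <- counts$L_prime / counts$L - 1 + pd_hat

  finish_estimates(counts, ps_hat, pd_hat, g_hat, clamp)
}

check_estimable <- function(counts) {
  if (any(4 * counts$cA == counts$L)) {
    abort(paste0(
      "Estimators are undefined at 4*cA == L (exactly 25% 'A' in the ",
      "reference): the composition statistic P has expectation 0."),
      class = c("indelrates_degenerate_composition",
                "indelrates_invalid_argument"))
  }
  if (any(counts$D + 4 * counts$k * counts$N <= 0)) {
    abort("No signal: D + 4kN must be positive.",
          class = c("indelrates_insufficient_signal",
                    "indelrates_invalid_argument"))
  }
  invisible(counts)
}

finish_estimates <- function(counts, ps_hat, pd_hat, g_hat, clamp) {
  if (clamp) {
    ps_hat <- pmin(pmax(ps_hat, 0), 1 - 1e-12)
    pd_hat <- pmin(pmax(pd_hat, 0), 1 - 1e-12)
    g_hat <- pmax(g_hat, 0)
  }
  out <- dplyr::mutate(counts, ps_hat = ps_hat, pd_hat = pd_hat,
                       g_hat = g_hat)
  class(out) <- c("rate_estimates", setdiff(class(out), "rate_estimates"))
  out
}

#' @export
tidy.rate_estimates <- function(x, ...) {
  keep <- intersect(c("provenance", "replicate"), names(x))
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(x), dplyr::all_of(keep), dplyr::all_of(
      c("ps_hat", "pd_hat", "g_hat"))),
    cols = dplyr::all_of(c("ps_hat", "pd_hat", "g_hat")),
    names_to = "parameter", values_to = "estimate"
  )
  long$parameter <- sub("_hat$", "", long$parameter)
  long
}

#' @export
glance.rate_estimates <- function(x, ...) {
  as_tibble(x)[, intersect(
    c("L", "L_prime", "k", "N", "D", "P", "ps_hat", "pd_hat", "g_hat",
      "provenance"),
    names(x)
  )]
}

#' Substitution-only baseline estimator (simple mutation model)
#'
#' The substitution-rate estimator of the substitution-only k-mer mutation
#' model, `1 - (N / L0)^(1/k)`, used as the comparison baseline. Because this
#' model has no notion of indels, disruption of k-mer content by insertions
#' and deletions is attributed to substitutions, so it systematically
#' overestimates `ps` when indels are present.
#'
#' @param N Number of unmutated k-spans (or containment times `L0`).
#'   Vectorized.
#' @param L0 Number of k-spans, `L - k + 1`.
#' @param k Span length.
#' @return Numeric vector of baseline substitution-rate estimates.
#' @export
smm_substitution_rate <- function(N, L0, k) {
  if (any(N < 0) || any(N > L0)) {
    abort("Need 0 <= N <= L0.", class = "indelrates_invalid_argument")
  }
  1 - (N / L0)^(1 / k)
}
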