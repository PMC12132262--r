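#' Concentration-bound calculator for the rate estimators
#'
#' Evaluates the theoretical tail bounds on the deviation of the three
#' estimators from the true parameters. With `theta1 = min(g^2 / (2 (g+1)^2),
#' pd / 3)` and `theta2 = max(g + 1, 8)`, and expectations from
#' [expected_stats()], the bounds are sums of terms of the form
#' `a k exp(-delta^2 E[D] / (3k))`, `b k exp(-delta^2 E[N] / (3k))`, a
#' sub-exponential term `c exp(-delta^2 E[P]^2 / (72 L e^(24 theta2 + 1)))`,
#' and (for the insertion-length estimator only) `4 exp(-theta1 L delta^2)`:
#' * `P(|pd_hat - pd| >= 4 delta)  <= 6k D-term + 3k N-term + 6 P-term`
#' * `P(|ps_hat - ps| >= 12 delta) <= 9k N-term + 6k D-term + 6 P-term`
#' * `P(|g_hat - g| >= (5+g) delta) <= 6k D-term + 3k N-term + 6 P-term
#'    + 4 exp(-theta1 L delta^2)`
#'
#' The constants of the sub-exponential P-term are typographically fragile in
#' print and are therefore exposed via `p_constants`; the default reading is
#' `denominator = p_constants[1] * L * exp(p_constants[2] * theta2 +
#' p_constants[3])`. Because `theta2 >= 8`, the P-term is near its prefactor
#' at any practical scale, so the capped bounds are often vacuous (1); the
#' uncapped values (`raw_*` columns) remain informative, e.g. they decrease
#' monotonically in `L`.
#'
#' The theorem behind the bounds is stated for `4 cA < L`, but only `E[P]^2`
#' enters the expressions, so the calculator accepts any composition with
#' `4 cA != L`: the `4 cA > L` case (e.g. 30% 'A') is covered by the same
#' formulas after relabeling the distinguished character.
#'
#' @param params A [mutation_params()] object.
#' @param L,cA Reference length and 'A'-count; requires `4 cA != L`.
#' @param k Span length.
#' @param delta Deviation scale, in `(0, 1/5)`.
#' @param p_constants Numeric triple `(denom_coef, exp_coef, exp_offset)` of
#'   the sub-exponential term; default `c(72, 24, 1)`.
#' @return A one-row tibble with the capped probabilities `bound_ps`,
#'   `bound_pd`, `bound_g` (each `min(raw, 1)`), their uncapped versions
#'   `raw_ps`, `raw_pd`, `raw_g`, and the context columns `theta1`, `theta2`,
#'   `delta`.
#' @examples
#' concentration_bounds(mutation_params(0.05, 0.05, 0.05),
#'                      L = 1e6, cA = 3e5, k = 21, delta = 0.1)
#' @export
concentration_bounds <- function(params, L, cA, k, delta,
                                 p_constants = c(72, 24, 1)) {
  params <- as_mutation_params(params)
  if (4 * cA == L) {
    abort("Precondition violated: need 4*cA != L (E[P] would be 0).",
          class = "indelrates_invalid_argument")
  }
  if (!(4 / 3 * params$ps + params$pd < 1)) {
    abort("Precondition violated: need (4/3)*ps + pd < 1.",
          class = "indelrates_invalid_argument")
  }
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta <= 0 || delta >= 1 / 5) {
    abort("Precondition violated: need delta in (0, 1/5).",
          class = "indelrates_invalid_argument")
  }
  if (!is.numeric(p_constants) || length(p_constants) != 3) {
    abort("`p_constants` must be a numeric triple.",
          class = "indelrates_invalid_argument")
  }

  g <- params$g; pd <- params$pd
  theta1 <- min(g^2 / (2 * (g + 1)^2), pd / 3)
  theta2 <- max(g + 1, 8)

  ex <- expected_stats(L, cA, params, k)

  d_term <- exp(-delta^2 * ex$E_D / (3 * k))
  n_term <- exp(-delta^2 * ex$E_N / (3 * k))
  # sub-exponential Bernstein term for P; exponent computed in log space
  log_denom <- log(p_constants[1]) + log(L) +
    p_constants[2] * theta2 + p_constants[3]
  p_term <- exp(-delta^2 * ex$E_P^2 * exp(-log_denom))
  lp_term <- 4 * exp(-theta1 * L * delta^2)

  raw_pd <- 6 * k * d_term + 3 * k * n_term + 6 * p_term
  raw_ps <- 9 * k * n_term + 6 * k * d_term + 6 * p_term
  raw_g <- raw_pd + lp_term

  tibble(
    bound_ps = pmin(raw_ps, 1), bound_pd = pmin(raw_pd, 1),
    bound_g = pmin(raw_g, 1),
    raw_ps = raw_ps, raw_pd = raw_pd, raw_g = raw_g,
    theta1 = theta1, theta2 = theta2, delta = delta,
    L = L, cA = cA, k = as.integer(k)
  )
}
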