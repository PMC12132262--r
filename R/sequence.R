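#' Generate a random DNA sequence
#'
#' Draws a sequence of i.i.d. bases from a fixed base composition. This is the
#' reference-sequence generator used throughout the simulation experiments;
#' the composition default reproduces the synthetic-genome setting used in the
#' parameter-recovery studies (30% 'A', the rest split equally).
#'
#' @param length Sequence length (positive integer).
#' @param base_freqs Named numeric vector of frequencies for A, C, G, T.
#'   Must be non-negative and sum to 1 (tolerance 1e-9).
#' @param seed Optional integer seed. When supplied the draw is made in a
#'   local RNG scope (the global RNG state is untouched) and the result is
#'   reproducible; when `NULL` the current RNG stream is used.
#' @return A single character string over `{A,C,G,T}`.
#' @examples
#' random_sequence(30, seed = 1)
#' @export
random_sequence <- function(length,
                            base_freqs = c(A = 0.30, C = 0.70 / 3,
                                           G = 0.70 / 3, T = 0.70 / 3),
                            seed = NULL) {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) ||
      length < 1 || length != floor(length)) {
    abort("`length` must be a positive integer.",
          class = "indelrates_invalid_argument")
  }
  base_freqs <- check_base_freqs(base_freqs)
  draw <- function() {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = base_freqs),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_base_freqs <- function(base_freqs) {
  if (!is.numeric(base_freqs) || length(base_freqs) != 4 ||
      anyNA(base_freqs) || any(base_freqs < 0)) {
    abort("`base_freqs` must be four non-negative frequencies for A, C, G, T.",
          class = "indelrates_invalid_argument")
  }
  if (abs(sum(base_freqs) - 1) > 1e-9) {
    abort(sprintf("`base_freqs` must sum to 1 (got %.12g).", sum(base_freqs)),
          class = "indelrates_invalid_argument")
  }
  if (!is.null(names(base_freqs))) {
    if (!setequal(names(base_freqs), DNA_BASES)) {
      abort("`base_freqs` names must be A, C, G, T.",
            class = "indelrates_invalid_argument")
    }
    base_freqs <- base_freqs[DNA_BASES]
  }
  unname(base_freqs)
}

#' Base-composition helper for a target fraction of 'A'
#'
#' Returns the composition with the given fraction of 'A' and the remaining
#' mass split equally among C, G and T, the design used in the composition
#' sensitivity experiments.
#'
#' @param frac_A Fraction of 'A' in `[0, 1]`.
#' @return Named numeric vector of length 4.
#' @export
composition_fracA <- function(frac_A) {
  if (!is.numeric(frac_A) || length(frac_A) != 1 || is.na(frac_A) ||
      frac_A < 0 || frac_A > 1) {
    abort("`frac_A` must be a single value in [0, 1].",
          class = "indelrates_invalid_argument")
  }
  c(A = frac_A, C = (1 - frac_A) / 3, G = (1 - frac_A) / 3,
    T = (1 - frac_A) / 3)
}

validate_sequence <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    abort(sprintf("`%s` must be a single character string.", arg),
          class = "indelrates_invalid_argument")
  }
  bad <- gsub("[ACGT]", "", seq)
  if (nchar(bad) > 0) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T}: '%s' ...",
                  arg, substr(bad, 1, 10)),
          class = "indelrates_invalid_character")
  }
  invisible(seq)
}

count_base <- function(seq, base) {
  nchar(seq) - nchar(gsub(base, "", seq, fixed = TRUE))
}

#' Directly observable statistics of a (mutated) sequence
#'
#' Reads off the sequence length `L'`, the count of 'A' characters `cA'`, and
#' the derived composition statistic `P = L' - 4 cA'` used by the estimators.
#' `P` is zero for a sequence with exactly 25% 'A' and may be negative.
#'
#' @param seq A DNA string.
#' @return A one-row tibble with columns `L_prime`, `cA_prime`, `P`.
#' @examples
#' observed_stats("ACGT")
#' @export
observed_stats <- function(seq) {
  validate_sequence(seq)
  Lp <- nchar(seq)
  cAp <- count_base(seq, "A")
  tibble(L_prime = Lp, cA_prime = cAp, P = Lp - 4L * cAp)
}
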