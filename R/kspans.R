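#' Classify every k-span of a mutation record
#'
#' A k-span is the interval `[i, i+k-1]` of positions in the *original*
#' sequence; there are `L0 = L - k + 1` of them. A span is `NoMutation` when
#' every position in it received `Stay` and no insertion is attached to an
#' interior position (`j` in `i+1 .. i+k-1`; the insert string for position
#' `j` sits between residues `j-1` and `j`, so inserts attached to `i` or to
#' `i+k` fall outside the span). A span is `SingleDeletion` when exactly one
#' position was deleted, all others received `Stay`, and again no interior
#' insertion. Everything else is `Other`.
#'
#' @param record A `mutation_record` from [mutate_sequence()].
#' @param k Span length (positive integer, `k <= L`).
#' @return Character vector of length `L0` over
#'   `{"NoMutation","SingleDeletion","Other"}`.
#' @export
classify_kspans <- function(record, k) {
  stopifnot(inherits(record, "mutation_record"))
  L <- length(record$ops)
  check_k(k, L)
  k <- as.integer(k)
  L0 <- L - k + 1L

  is_sub <- record$ops == "Sub"
  is_del <- record$ops == "Del"
  has_ins <- record$insert_lengths > 0L

  cs_sub <- c(0L, cumsum(is_sub))
  cs_del <- c(0L, cumsum(is_del))
  cs_ins <- c(0L, cumsum(has_ins))

  i <- seq_len(L0)
  n_sub <- cs_sub[i + k] - cs_sub[i]            # Sub ops in [i, i+k-1]
  n_del <- cs_del[i + k] - cs_del[i]            # Del ops in [i, i+k-1]
  n_ins <- cs_ins[i + k] - cs_ins[i + 1L]       # insertions at [i+1, i+k-1]

  out <- rep("Other", L0)
  clean <- n_sub == 0L & n_ins == 0L
  out[clean & n_del == 0L] <- "NoMutation"
  out[clean & n_del == 1L] <- "SingleDeletion"
  out
}

check_k <- function(k, L) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 ||
      k != floor(k)) {
    abort("`k` must be a positive integer.",
          class = "indelrates_invalid_argument")
  }
  if (k > L) {
    abort(sprintf("`k` (%d) must not exceed the sequence length (%d).",
                  as.integer(k), L),
          class = "indelrates_invalid_argument")
  }
  invisible(k)
}

new_span_counts <- function(N, D, L_prime, cA_prime, k, L, cA,
                            provenance = "ground_truth") {
  out <- tibble(
    N = as.numeric(N), D = as.numeric(D),
    L_prime = as.numeric(L_prime), cA_prime = as.numeric(cA_prime),
    k = as.integer(k), L = as.numeric(L), cA = as.numeric(cA),
    provenance = provenance
  )
  class(out) <- c("span_counts", class(out))
  out
}

#' Exact k-span counts from the known mutation record
#'
#' Counts `N` (k-spans with no mutation) and `D` (k-spans whose only mutation
#' is exactly one deletion) directly from the ground-truth record of the
#' mutation channel, and reads `L'` and `cA'` off the mutated sequence. These
#' are the observables the closed-form rate estimators consume.
#'
#' @inheritParams classify_kspans
#' @return A one-row `span_counts` tibble with columns `N`, `D`, `L_prime`,
#'   `cA_prime`, `k`, `L`, `cA`, `provenance` (`"ground_truth"`).
#' @seealso [estimate_rates()], [estimate_counts()] for the alignment-based
#'   counterpart.
#' @export
ground_truth_counts <- function(record, k) {
  labels <- classify_kspans(record, k)
  new_span_counts(
    N = sum(labels == "NoMutation"),
    D = sum(labels == "SingleDeletion"),
    L_prime = nchar(record$mutated),
    cA_prime = count_base(record$mutated, "A"),
    k = k,
    L = nchar(record$original),
    cA = count_base(record$original, "A"),
    provenance = "ground_truth"
  )
}

#' Derived statistics P, Q, R, T of a span-count table
#'
#' Adds the derived columns `P = L' - 4 cA'`, `Q = kN + D`,
#' `R = k (L - 4 cA) N` and `T = 4kN + D` used by the alternate estimator
#' formulation and the concentration analysis.
#'
#' @param counts A data frame with columns `N`, `D`, `L_prime`, `cA_prime`,
#'   `k`, `L`, `cA` (e.g. from [ground_truth_counts()]).
#' @return The input with columns `P`, `Q`, `R`, `T` appended.
#' @export
derive_pqrt <- function(counts) {
  counts <- check_counts_df(counts)
  dplyr::mutate(
    counts,
    P = .data$L_prime - 4 * .data$cA_prime,
    Q = .data$k * .data$N + .data$D,
    R = .data$k * (.data$L - 4 * .data$cA) * .data$N,
    T = 4 * .data$k * .data$N + .data$D
  )
}

check_counts_df <- function(counts) {
  need <- c("N", "D", "L_prime", "cA_prime", "k", "L", "cA")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    abort(paste0("`counts` must be a data frame with columns ",
                 paste(need, collapse = ", "), "."),
          class = "indelrates_invalid_argument")
  }
  if (nrow(counts) == 0) {
    abort("`counts` has no rows.", class = "indelrates_invalid_argument")
  }
  counts
}
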