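#' Apply the indel mutation channel to a sequence
#'
#' Runs the generative mutation process on a reference sequence `S` and
#' returns the mutated sequence `S'` together with the complete ground truth
#' of the channel invocation, so that k-span statistics can later be counted
#' exactly from the known mutation record rather than re-inferred.
#'
#' The channel proceeds position by position over `S`:
#' 1. each position independently receives an operation from
#'    `{Sub, Del, Stay}` with probabilities `ps`, `pd`, `1 - ps - pd`;
#' 2. each `Sub` position is replaced by a base drawn uniformly from the
#'    three bases different from the original;
#' 3. each position `i` draws an insertion length `I[i]` from a geometric
#'    distribution on `{0, 1, 2, ...}` with mean `g`, and an insert string of
#'    that length with bases i.i.d. uniform over `{A,C,G,T}`;
#' 4. the insert string for position `i` is placed immediately before
#'    position `i` (prepended for `i = 1`), and deletions are applied last.
#'
#' Random draws are consumed in a fixed, documented order (operations, then
#' substitution choices, then insertion lengths, then insert bases) so a
#' record is fully reproducible from `(S, params, seed)`.
#'
#' @param seq Reference DNA string (non-empty).
#' @param params A [mutation_params()] object (or coercible list/vector).
#' @param seed Optional integer seed; when supplied the channel runs in a
#'   local RNG scope and is deterministic.
#' @return An object of class `mutation_record`: a list with elements
#'   `original`, `mutated` (the two strings), `ops` (character vector of
#'   length `L` over `{"Sub","Del","Stay"}`), `insert_lengths` (integer
#'   vector `I`, length `L`), `insert_chars` (the flat string of inserted
#'   bases, in position order), `track` (integer vector, `track[i]` = 1-based
#'   position of surviving original position `i` in the mutated string, `NA`
#'   for deleted positions), and `params`.
#' @seealso [insertion_strings()], [classify_kspans()], [ground_truth_counts()]
#' @examples
#' rec <- mutate_sequence(random_sequence(50, seed = 1),
#'                        mutation_params(0.1, 0.1, 0.1), seed = 2)
#' rec$mutated
#' @export
mutate_sequence <- function(seq, params, seed = NULL) {
  validate_sequence(seq)
  params <- as_mutation_params(params)
  L <- nchar(seq)
  if (L < 1) {
    abort("`seq` must be non-empty.", class = "indelrates_invalid_argument")
  }
  run <- function() mutate_impl(seq, L, params)
  rec <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  rec
}

mutate_impl <- function(seq, L, params) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  # 1) operation draws
  ops <- sample(c("Sub", "Del", "Stay"), L, replace = TRUE,
                prob = c(params$ps, params$pd, 1 - params$ps - params$pd))

  # 2) substitution draws: uniform over the 3 bases != original
  out_chars <- chars
  sub_idx <- which(ops == "Sub")
  if (length(sub_idx) > 0) {
    r <- sample.int(3L, length(sub_idx), replace = TRUE)
    out_chars[sub_idx] <-
      SUB_ALTERNATIVES[cbind(r, match(chars[sub_idx], DNA_BASES))]
  }

  # 3) insertion lengths, geometric on {0,1,...} with mean g
  I <- if (params$g > 0) {
    rgeom(L, prob = 1 / (1 + params$g))
  } else {
    integer(L)
  }

  # 4) insert bases, uniform, flat in position order
  total_ins <- sum(I)
  ins_chars <- if (total_ins > 0) {
    sample(DNA_BASES, total_ins, replace = TRUE)
  } else {
    character(0)
  }

  keep <- ops != "Del"
  # interleave: insert string for position i goes immediately before the
  # (possibly substituted) residue at i; deleted residues drop out
  all_chars <- c(ins_chars, out_chars[keep])
  key <- c(rep.int(seq_len(L), I) * 2 - 1, which(keep) * 2)
  mutated <- paste(all_chars[order(key)], collapse = "")

  track <- cumsum(I) + cumsum(keep)
  track[!keep] <- NA_integer_

  structure(
    list(
      original = seq,
      mutated = mutated,
      ops = ops,
      insert_lengths = as.integer(I),
      insert_chars = paste(ins_chars, collapse = ""),
      track = as.integer(track),
      params = params
    ),
    class = "mutation_record"
  )
}

#' Per-position insert strings of a mutation record
#'
#' Expands the flat inserted-base string of a [mutate_sequence()] record into
#' one string per original position (empty where `I[i] = 0`).
#'
#' @param record A `mutation_record`.
#' @return Character vector of length `L`.
#' @export
insertion_strings <- function(record) {
  stopifnot(inherits(record, "mutation_record"))
  I <- record$insert_lengths
  ends <- cumsum(I)
  starts <- ends - I + 1L
  out <- character(length(I))
  nz <- I > 0L
  out[nz] <- substring(record$insert_chars, starts[nz], ends[nz])
  out[!nz] <- ""
  out
}

#' @export
print.mutation_record <- function(x, ...) {
  L <- nchar(x$original)
  cat(sprintf(
    "<mutation_record> L = %d -> L' = %d | Sub %d, Del %d, inserted %d\n",
    L, nchar(x$mutated), sum(x$ops == "Sub"), sum(x$ops == "Del"),
    nchar(x$insert_chars)
  ))
  invisible(x)
}

#' Tidy view of a mutation record
#'
#' One row per original position: the operation, the insertion length, and
#' the tracked position in the mutated string (`NA` for deleted positions).
#' This is also the sidecar ground-truth table written by the CLI.
#'
#' @param x A `mutation_record`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `op`, `insert_length`,
#'   `inserted_string`, `track`.
#' @export
tidy.mutation_record <- function(x, ...) {
  tibble(
    position = seq_along(x$ops),
    op = x$ops,
    insert_length = x$insert_lengths,
    inserted_string = insertion_strings(x),
    track = x$track
  )
}

#' One-row summary of a mutation record
#'
#' @param x A `mutation_record`.
#' @param ... Unused.
#' @return A one-row tibble with `L`, `L_prime`, `n_sub`, `n_del`,
#'   `n_inserted`, `cA`, `cA_prime`.
#' @export
glance.mutation_record <- function(x, ...) {
  tibble(
    L = nchar(x$original),
    L_prime = nchar(x$mutated),
    n_sub = sum(x$ops == "Sub"),
    n_del = sum(x$ops == "Del"),
    n_inserted = nchar(x$insert_chars),
    cA = count_base(x$original, "A"),
    cA_prime = count_base(x$mutated, "A")
  )
}
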