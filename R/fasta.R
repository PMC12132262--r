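#' Read a DNA sequence from a FASTA file
#'
#' Reads single- or multi-record FASTA. The mutation model is defined on
#' `{A,C,G,T}` only, so other characters (e.g. `N`) are rejected by default;
#' `replace_ambiguous = TRUE` substitutes them with uniform random bases (the
#' number of replacements is reported). Lowercase residues are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param all_records Return all records (named character vector) instead of
#'   the first record only (with a warning when more exist).
#' @param replace_ambiguous Replace non-ACGT characters with random bases.
#' @param seed Optional seed for the replacement draws.
#' @return A character string named by its FASTA header (or a named vector
#'   when `all_records = TRUE`).
#' @export
read_fasta <- function(path, all_records = FALSE, replace_ambiguous = FALSE,
                       seed = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path),
          class = "indelrates_missing_file")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("Malformed FASTA file %s: %s", path, conditionMessage(e)),
            class = "indelrates_malformed_fasta")
    }
  )
  if (length(set) == 0) {
    abort(sprintf("FASTA file %s contains no records.", path),
          class = "indelrates_malformed_fasta")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- names(set)
  if (!all_records && length(seqs) > 1) {
    warn(sprintf("%s has %d records; using the first ('%s').",
                 path, length(seqs), names(seqs)[1]))
    seqs <- seqs[1]
  }
  seqs <- vapply(seqs, sanitize_residues, character(1),
                 replace_ambiguous = replace_ambiguous, seed = seed)
  if (!all_records) return(seqs[1])
  seqs
}

sanitize_residues <- function(seq, replace_ambiguous, seed = NULL) {
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] == -1) return(seq)
  if (!replace_ambiguous) {
    abort(sprintf(
      "Sequence contains %d non-ACGT character(s); first at position %d ('%s'). Use replace_ambiguous = TRUE to randomize them.",
      length(bad), bad[1], substr(seq, bad[1], bad[1])),
      class = "indelrates_invalid_character")
  }
  draw <- function() sample(DNA_BASES, length(bad), replace = TRUE)
  repl <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[bad] <- repl
  inform(sprintf("Replaced %d non-ACGT character(s) with random bases.",
                 length(bad)))
  paste(chars, collapse = "")
}

#' Write a DNA sequence to a FASTA file
#'
#' @param path Output path.
#' @param seq DNA string.
#' @param header Record header (without the `>`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(path, seq, header = "sequence") {
  validate_sequence(seq)
  set <- Biostrings::BStringSet(setNames(seq, header))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}
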