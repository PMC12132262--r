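#' Mutation-channel parameters
#'
#' Bundles and validates the three parameters of the indel mutation channel:
#' the per-position substitution probability `ps`, the per-position deletion
#' probability `pd`, and the mean insertion length `g` (insertions at each
#' position are geometric on `{0, 1, 2, ...}` with mean `g`, i.e. success
#' probability `1/(1+g)`).
#'
#' @param ps Substitution probability, `0 <= ps < 1`.
#' @param pd Deletion probability, `0 <= pd < 1`, with `ps + pd < 1`.
#' @param g Mean insertion length, `g >= 0`.
#' @return An object of class `mutation_params` (a named list).
#' @examples
#' mutation_params(0.05, 0.05, 0.05)
#' @export
mutation_params <- function(ps, pd, g) {
  for (nm in c("ps", "pd", "g")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("`%s` must be a single numeric value.", nm),
            class = "indelrates_invalid_argument")
    }
  }
  if (ps < 0 || ps >= 1 || pd < 0 || pd >= 1 || ps + pd >= 1 || g < 0) {
    abort("Need 0 <= ps < 1, 0 <= pd < 1, ps + pd < 1 and g >= 0.",
          class = "indelrates_invalid_argument")
  }
  structure(list(ps = ps, pd = pd, g = g), class = "mutation_params")
}

as_mutation_params <- function(x) {
  if (inherits(x, "mutation_params")) return(x)
  if (is.list(x) && all(c("ps", "pd", "g") %in% names(x))) {
    return(mutation_params(x$ps, x$pd, x$g))
  }
  if (is.numeric(x) && length(x) == 3) {
    if (!is.null(names(x)) && all(c("ps", "pd", "g") %in% names(x))) {
      return(mutation_params(x[["ps"]], x[["pd"]], x[["g"]]))
    }
    return(mutation_params(x[[1]], x[[2]], x[[3]]))
  }
  abort("Cannot interpret `params`; use mutation_params(ps, pd, g).",
        class = "indelrates_invalid_argument")
}

#' @export
print.mutation_params <- function(x, ...) {
  cat(sprintf("<mutation_params> ps = %g, pd = %g, g = %g\n", x$ps, x$pd, x$g))
  invisible(x)
}
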