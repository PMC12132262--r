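#' Enumerate the k-mers of a sequence
#'
#' Forward-strand k-mer content: all `L - k + 1` occurrences, reported as the
#' distinct k-mer set with a multiplicity flag.
#'
#' @param seq DNA string of length `>= k`.
#' @param k k-mer size.
#' @return A tibble with columns `kmer` (distinct, in order of first
#'   occurrence), `n` (occurrence count) and `repeated` (`n > 1`).
#' @export
extract_kmers <- function(seq, k) {
  validate_sequence(seq)
  L <- nchar(seq)
  check_k(k, L)
  occ <- substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  cnt <- table(factor(occ, levels = unique(occ)))
  tibble(kmer = names(cnt), n = as.integer(cnt),
         repeated = as.integer(cnt) > 1L)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Build unitigs of the node-centric de Bruijn graph of a k-mer set
#'
#' Nodes are the distinct k-mers; there is an edge `u -> v` whenever the
#' `(k-1)`-suffix of `u` equals the `(k-1)`-prefix of `v`. Unitigs are the
#' maximal non-branching paths: `u` is extended to `v` only when `u` has a
#' unique out-neighbor `v` and `v` has a unique in-neighbor. Isolated cycles
#' are broken at an arbitrary node. Every distinct k-mer ends up in exactly
#' one unitig.
#'
#' @param kmers Character vector of k-mers (duplicates collapsed), or the
#'   tibble returned by [extract_kmers()].
#' @param k k-mer size; all k-mers must have `nchar == k`.
#' @param canonical When `TRUE`, the reverse complement of every k-mer is
#'   added to the node set before construction, making the graph
#'   strand-symmetric (for real-data use; the mutation channel itself is
#'   strand-oblivious and the default is `FALSE`).
#' @return A `unitig_set` tibble with column `unitig`; attribute `k`.
#' @export
build_unitigs <- function(kmers, k, canonical = FALSE) {
  if (is.data.frame(kmers)) kmers <- kmers$kmer
  if (length(kmers) == 0) {
    abort("`kmers` must be non-empty.", class = "indelrates_invalid_argument")
  }
  kmers <- unique(kmers)
  if (any(nchar(kmers) != k)) {
    abort("All k-mers must have length `k`.",
          class = "indelrates_invalid_argument")
  }
  if (canonical) kmers <- unique(c(kmers, revcomp(kmers)))

  n <- length(kmers)
  pref <- substr(kmers, 1L, k - 1L)
  suff <- substr(kmers, 2L, k)
  km1 <- unique(c(pref, suff))
  pid <- match(pref, km1)
  sid <- match(suff, km1)
  nb <- length(km1)
  n_with_pref <- tabulate(pid, nbins = nb)  # k-mers whose prefix is x
  n_with_suff <- tabulate(sid, nbins = nb)  # k-mers whose suffix is x

  outdeg <- n_with_pref[sid]  # out-neighbors of each node
  indeg <- n_with_suff[pid]   # in-neighbors of each node

  # successor where the out-neighbor is unique; match() finds it because a
  # unique out-neighbor means exactly one k-mer carries that prefix
  succ <- rep(NA_integer_, n)
  uniq_out <- which(outdeg == 1L)
  succ[uniq_out] <- match(suff[uniq_out], pref)
  # link u -> succ[u] only when succ's in-neighbor is unique; drop self-loops
  linked <- !is.na(succ) & indeg[ifelse(is.na(succ), 1L, succ)] == 1L &
    succ != seq_len(n)
  succ[!linked] <- NA_integer_

  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE

  visited <- rep(FALSE, n)
  unitigs <- character(0)
  walk <- function(start) {
    path <- integer(0)
    node <- start
    repeat {
      path <- c(path, node)
      visited[node] <<- TRUE
      nxt <- succ[node]
      if (is.na(nxt) || visited[nxt]) break
      node <- nxt
    }
    paste0(kmers[path[1]],
           paste(substr(kmers[path[-1]], k, k), collapse = ""))
  }
  for (s in which(!has_pred)) {
    if (!visited[s]) unitigs <- c(unitigs, walk(s))
  }
  for (s in seq_len(n)) {  # remaining nodes lie on isolated cycles
    if (!visited[s]) unitigs <- c(unitigs, walk(s))
  }

  out <- tibble(unitig = unitigs)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("unitig_set", class(out))
  out
}

#' Semi-global (infix) alignment of a query inside a target
#'
#' Minimal-edit-distance alignment of the whole query against a substring of
#' the target: leading and trailing target characters are free, every query
#' character is aligned. Edit operations are unit-cost substitutions,
#' insertions (in the query) and deletions (from the target). The distance is
#' computed by full dynamic programming; the edit script is recovered with a
#' banded traceback whose band is provably wide enough (radius = distance+1).
#'
#' @param target,query Non-empty DNA strings; the query is matched inside the
#'   target.
#' @param max_distance Reject alignments with edit distance above this value
#'   (returns a no-hit). `NULL` (default) disables the threshold.
#' @param traceback Set `FALSE` to skip the edit script (distance and end
#'   position only).
#' @return For a hit, a `pair_alignment` list with `edit_distance`,
#'   `target_span` (1-based closed interval, `c(1, 0)` when the query aligns
#'   to an empty span) and `ops`, a single string over `=` (match), `X`
#'   (mismatch), `I` (insertion in query), `D` (deletion from target).
#'   For a rejected alignment, `NULL` (with the distance in
#'   `attr(, "edit_distance")` omitted; use `max_distance = NULL` to force a
#'   hit).
#' @examples
#' infix_align("TTACGTTT", "ACGT")
#' @export
infix_align <- function(target, query, max_distance = NULL,
                        traceback = TRUE) {
  validate_sequence(target, "target")
  validate_sequence(query, "query")
  res <- cpp_infix_align(target, query,
                         if (is.null(max_distance)) -1 else max_distance,
                         traceback)
  if (!res$hit) return(NULL)
  out <- list(
    edit_distance = res$edit_distance,
    target_span = if (traceback) c(res$target_start, res$target_end)
                  else c(NA_integer_, res$target_end),
    ops = if (traceback) res$ops else NA_character_
  )
  class(out) <- "pair_alignment"
  out
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> distance %d, target span [%s, %s]\n",
              x$edit_distance, x$target_span[1], x$target_span[2]))
  invisible(x)
}

#' Count N- and D-contributing k-windows of one alignment
#'
#' Slides over every window of `k` consecutive *target* characters that is
#' fully covered by the aligned region. A window contributes to `N` when all
#' `k` characters are matches and no query-insertion falls strictly inside
#' the window (between two of its characters); it contributes to `D` when
#' exactly one character is deleted from the target, all others are matches,
#' and again no interior insertion. Insertions immediately before the first
#' or after the last character of a window are exterior and do not disqualify
#' it, mirroring the k-span convention of the mutation channel.
#'
#' @param alignment A `pair_alignment` from [infix_align()] (with traceback).
#' @param k Window length.
#' @return A list with `n_contrib`, `d_contrib`, and `windows`, a tibble of
#'   contributing windows (`start` = 1-based target coordinate of the first
#'   window character, `class` = `"N"` or `"D"`).
#' @export
count_windows <- function(alignment, k) {
  stopifnot(inherits(alignment, "pair_alignment"))
  if (is.na(alignment$ops)) {
    abort("Alignment was computed without traceback.",
          class = "indelrates_invalid_argument")
  }
  ops <- strsplit(alignment$ops, "", fixed = TRUE)[[1]]
  consumes_target <- ops %in% c("=", "X", "D")
  nt <- sum(consumes_target)
  empty <- list(n_contrib = 0L, d_contrib = 0L,
                windows = tibble(start = integer(0), class = character(0)))
  if (nt < k) return(empty)

  # per target position: its op, and the number of I columns in the gap
  # immediately before it (within the aligned region)
  tpos_op <- ops[consumes_target]
  col_of_t <- which(consumes_target)
  ins_before <- diff(c(0L, cumsum(ops == "I"))[c(1L, col_of_t)])
  # ins_before[p] = I-columns between target position p-1 and p (p = 1 is
  # the region edge and never interior to a window)

  is_match <- tpos_op == "="
  is_del <- tpos_op == "D"
  is_mm <- tpos_op == "X"

  cs_m <- c(0L, cumsum(is_match))
  cs_d <- c(0L, cumsum(is_del))
  cs_x <- c(0L, cumsum(is_mm))
  cs_i <- c(0L, cumsum(ins_before))

  i <- seq_len(nt - k + 1L)
  n_m <- cs_m[i + k] - cs_m[i]
  n_d <- cs_d[i + k] - cs_d[i]
  n_x <- cs_x[i + k] - cs_x[i]
  n_ins <- cs_i[i + k] - cs_i[i + 1L]  # interior gaps only

  is_N <- n_m == k & n_ins == 0L
  is_D <- n_d == 1L & n_x == 0L & n_m == k - 1L & n_ins == 0L

  start0 <- alignment$target_span[1]
  windows <- tibble(
    start = start0 + c(which(is_N), which(is_D)) - 1L,
    class = rep(c("N", "D"), c(sum(is_N), sum(is_D)))
  )
  list(n_contrib = sum(is_N), d_contrib = sum(is_D), windows = windows)
}

#' Estimate the k-span counts from two raw sequences
#'
#' Alignment-based observer for the unobservable counts `N` and `D`: builds
#' the unitig sets of the de Bruijn graphs of both sequences, aligns every
#' mutated-side unitig inside every reference-side unitig (infix alignment),
#' classifies all fully covered k-windows, and accumulates the contributions
#' into global counts. Each target-window coordinate (per reference unitig)
#' is counted at most once across all query unitigs, keeping the
#' classification from the lowest-edit-distance alignment (ties resolved
#' toward `N`, then `D`). `L'`, `cA'`, `L` and `cA` are read directly off the
#' sequences.
#'
#' Unitig construction collapses repeated k-mers, so the estimate can
#' undercount on repetitive sequences; a warning reports the repeat fraction
#' when it is non-zero.
#'
#' @param seq Reference sequence `S`.
#' @param seq_prime Mutated sequence `S'`.
#' @param k Span length.
#' @param max_dist_frac Alignments with edit distance above
#'   `ceiling(max_dist_frac * nchar(query))` are discarded as spurious
#'   (default 0.35).
#' @param canonical Passed to [build_unitigs()].
#' @return A one-row `span_counts` tibble with
#'   `provenance = "alignment-estimated"`, directly consumable by
#'   [estimate_rates()].
#' @export
estimate_counts <- function(seq, seq_prime, k, max_dist_frac = 0.35,
                            canonical = FALSE) {
  validate_sequence(seq, "seq")
  validate_sequence(seq_prime, "seq_prime")
  check_k(k, nchar(seq))
  check_k(k, nchar(seq_prime))

  km <- extract_kmers(seq, k)
  rep_frac <- sum(km$n[km$repeated]) / sum(km$n)
  if (rep_frac > 0) {
    warn(sprintf(
      "%.2f%% of reference k-mer occurrences are repeats; unitig collapse may undercount N.",
      100 * rep_frac))
  }
  U <- build_unitigs(km, k, canonical = canonical)$unitig
  Up <- build_unitigs(extract_kmers(seq_prime, k), k,
                      canonical = canonical)$unitig

  N_hat <- 0L
  D_hat <- 0L
  for (u in U) {
    if (nchar(u) < k) next
    # per-window best (distance, class-rank); rank 1 = N, 2 = D
    best <- NULL
    for (up in Up) {
      aln <- infix_align(u, up,
                         max_distance = ceiling(max_dist_frac * nchar(up)))
      if (is.null(aln)) next
      cw <- count_windows(aln, k)
      if (nrow(cw$windows) == 0) next
      cand <- dplyr::mutate(cw$windows,
                            dist = aln$edit_distance,
                            rank = ifelse(.data$class == "N", 1L, 2L))
      best <- if (is.null(best)) cand else dplyr::bind_rows(best, cand)
    }
    if (!is.null(best)) {
      best <- dplyr::arrange(best, .data$start, .data$dist, .data$rank)
      best <- best[!duplicated(best$start), ]
      N_hat <- N_hat + sum(best$class == "N")
      D_hat <- D_hat + sum(best$class == "D")
    }
  }

  new_span_counts(
    N = N_hat, D = D_hat,
    L_prime = nchar(seq_prime), cA_prime = count_base(seq_prime, "A"),
    k = k, L = nchar(seq), cA = count_base(seq, "A"),
    provenance = "alignment-estimated"
  )
}
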