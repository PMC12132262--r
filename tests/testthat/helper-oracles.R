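# Brute-force oracles, deliberately naive and independent of the package's
# vectorized/C++ code paths.

# re-scan every k-span of a mutation record position by position
oracle_classify <- function(ops, I, k) {
  L <- length(ops)
  vapply(seq_len(L - k + 1), function(i) {
    span_ops <- ops[i:(i + k - 1)]
    interior <- if (k >= 2) I[(i + 1):(i + k - 1)] else integer(0)
    if (all(span_ops == "Stay") && all(interior == 0)) {
      "NoMutation"
    } else if (sum(span_ops == "Del") == 1 &&
               all(span_ops[span_ops != "Del"] == "Stay") &&
               all(interior == 0)) {
      "SingleDeletion"
    } else {
      "Other"
    }
  }, character(1))
}

# full quadratic DP for semi-global (infix) edit distance: query fully
# aligned, leading/trailing target characters free
oracle_infix_distance <- function(target, query) {
  tn <- strsplit(target, "")[[1]]
  qn <- strsplit(query, "")[[1]]
  n <- length(tn); m <- length(qn)
  C <- matrix(0L, m + 1, n + 1)
  C[, 1] <- 0:m
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      C[i + 1, j + 1] <- min(
        C[i, j] + as.integer(qn[i] != tn[j]),
        C[i, j + 1] + 1L,   # deletion from target
        C[i + 1, j] + 1L    # insertion in query
      )
    }
  }
  min(C[m + 1, ])
}

# maximal non-branching path enumeration on the node-centric de Bruijn graph,
# via explicit adjacency lists and chain extension
oracle_unitigs <- function(kmers, k) {
  kmers <- unique(kmers)
  n <- length(kmers)
  pref <- substr(kmers, 1, k - 1)
  suff <- substr(kmers, 2, k)
  out_nb <- lapply(seq_len(n), function(u) which(pref == suff[u]))
  in_nb <- lapply(seq_len(n), function(v) which(suff == pref[v]))
  chainable <- function(u, v) {
    length(out_nb[[u]]) == 1 && out_nb[[u]] == v &&
      length(in_nb[[v]]) == 1 && u != v
  }
  spell <- function(path) {
    paste0(kmers[path[1]],
           paste(substr(kmers[path[-1]], k, k), collapse = ""))
  }
  done <- rep(FALSE, n)
  tigs <- character(0)
  for (u in seq_len(n)) {
    if (done[u]) next
    path <- u
    repeat {  # extend forward
      nxt <- Filter(function(v) chainable(path[length(path)], v) &&
                      !(v %in% path), seq_len(n))
      if (length(nxt) != 1) break
      path <- c(path, nxt[[1]])
    }
    repeat {  # extend backward
      prv <- Filter(function(v) chainable(v, path[1]) && !(v %in% path),
                    seq_len(n))
      if (length(prv) != 1) break
      path <- c(prv[[1]], path)
    }
    done[path] <- TRUE
    tigs <- c(tigs, spell(path))
  }
  sort(tigs)
}

# window classification straight off a per-column edit script
oracle_count_windows <- function(ops_string, target_start, k) {
  cols <- strsplit(ops_string, "")[[1]]
  tpos <- which(cols %in% c("=", "X", "D"))
  nt <- length(tpos)
  n_c <- 0L; d_c <- 0L
  if (nt >= k) {
    for (i in seq_len(nt - k + 1)) {
      window_cols <- cols[tpos[i]:tpos[i + k - 1]]
      chars <- window_cols[window_cols != "I"]
      # interior insertions: I columns strictly between the first and last
      # target-consuming column of the window
      has_ins <- any(window_cols == "I")
      if (!has_ins && all(chars == "=")) {
        n_c <- n_c + 1L
      } else if (!has_ins && sum(chars == "D") == 1 &&
                 all(chars[chars != "D"] == "=")) {
        d_c <- d_c + 1L
      }
    }
  }
  list(n_contrib = n_c, d_contrib = d_c)
}

# simulate n replicate mutation records and return the stacked ground-truth
# count table
sim_ground_truth <- function(S, params, k, n, seed0) {
  dplyr::bind_rows(lapply(seq_len(n), function(r) {
    rec <- mutate_sequence(S, params, seed = seed0 + r)
    ground_truth_counts(rec, k)
  }))
}

# random valid fuzz setting for the estimator round-trip tests
fuzz_setting <- function() {
  repeat {
    ps <- runif(1, 0, 0.3)
    pd <- runif(1, 0, 0.3)
    g <- runif(1, 0, 0.5)
    if (ps + pd < 1 && 4 / 3 * ps + pd < 1) break
  }
  L <- sample(1000:2000000, 1)
  k <- sample(5:41, 1)
  frac <- runif(1, 0.05, 0.45)
  cA <- round(frac * L)
  if (4 * cA == L) cA <- cA + 1
  list(L = L, cA = cA, k = k, params = mutation_params(ps, pd, g))
}
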