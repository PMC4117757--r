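## Independent oracle for reversal distances: breadth-first search from the
## identity over the whole space of signed permutations of size m (feasible
## for m <= 7).  Entirely independent of the package's sorting machinery:
## states are expanded by raw vector reversals, ranked by a Lehmer code.

bfs_reversal_oracle <- function(m) {
  stopifnot(m >= 1, m <= 7)
  total <- factorial(m) * 2^m
  pow2 <- 2^(0:(m - 1))
  rank_rows <- function(P) {
    A <- abs(P)
    r <- numeric(nrow(P))
    for (k in seq_len(m)) {
      smaller <- numeric(nrow(P))
      if (k < m) for (j in (k + 1):m) smaller <- smaller + (A[, j] < A[, k])
      r <- r * (m - k + 1) + smaller
    }
    as.numeric(r * 2^m + (P < 0) %*% pow2)
  }
  dist <- rep(NA_integer_, total)
  frontier <- matrix(seq_len(m), nrow = 1)
  dist[rank_rows(frontier) + 1] <- 0L
  ivs <- which(upper.tri(matrix(TRUE, m, m), diag = TRUE), arr.ind = TRUE)
  lev <- 0L
  while (nrow(frontier)) {
    cand <- vector("list", nrow(ivs))
    for (r in seq_len(nrow(ivs))) {
      i <- ivs[r, 1]; j <- ivs[r, 2]
      Q <- frontier
      Q[, i:j] <- -Q[, j:i, drop = FALSE]
      cand[[r]] <- Q
    }
    cand <- do.call(rbind, cand)
    rk <- rank_rows(cand) + 1
    new <- is.na(dist[rk]) & !duplicated(rk)
    lev <- lev + 1L
    dist[rk[new]] <- lev
    frontier <- cand[new, , drop = FALSE]
  }
  list(
    dist = dist,
    lookup = function(p) dist[rank_rows(matrix(as.integer(p), nrow = 1)) + 1]
  )
}

## all signed permutations of size m as a matrix (rows)
all_signed_perms <- function(m) {
  base <- as.matrix(expand.grid(rep(list(seq_len(m)), m)))
  base <- base[apply(base, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), m)))
  out <- matrix(0L, nrow(base) * nrow(signs), m)
  row <- 0L
  for (b in seq_len(nrow(base))) for (s in seq_len(nrow(signs))) {
    row <- row + 1L
    out[row, ] <- base[b, ] * signs[s, ]
  }
  out
}

## apply a reversal_sort plan to the identity, independently of the package
replay_inversions <- function(events, m) {
  p <- seq_len(m)
  for (ev in events) p[ev$from:ev$to] <- -rev(p[ev$from:ev$to])
  p
}
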