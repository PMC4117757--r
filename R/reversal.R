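## Sorting signed permutations by reversals (inversions), with exact
## Hannenhalli-Pevzner distances.
##
## The distance of a signed permutation pi over 1..m from the identity is
##     d(pi) = (m + 1) - c(pi) + h(pi) + f(pi)
## where c counts the cycles of the breakpoint graph of the doubled
## (unsigned) representation, h counts hurdles (unoriented components that
## are minimal in circular containment order, i.e. minimal on the line or
## containing every other unoriented component), and f is 1 for a fortress
## (an odd number of hurdles, all "super").  The sorter applies Bergeron's
## maximal-score oriented reversals while any oriented pair exists, and
## explicit hurdle cut/merge reversals otherwise; every chosen reversal is
## checked to reduce the exact distance by one, with a brute-force scan of
## all reversals as a safety net, so the emitted sequence always has length
## exactly d(pi).

## framed permutation: c(0, pi, m + 1)
frame_perm <- function(perm) c(0L, as.integer(perm), length(perm) + 1L)

## doubled unsigned representation of a framed permutation; s[1] = 0,
## element k occupies s[2k], s[2k+1], s[2m+2] = 2m+1
double_perm <- function(perm) {
  m <- length(perm)
  ends <- vapply(perm, function(x) {
    if (x > 0) c(2L * x - 1L, 2L * x) else c(-2L * x, -2L * x - 1L)
  }, integer(2))
  c(0L, as.integer(ends), 2L * m + 1L)
}

## full structural analysis of a signed permutation (unframed input)
analyze_perm <- function(perm) {
  m <- length(perm)
  s <- double_perm(perm)
  nv <- 2L * m + 2L
  pos <- integer(nv); pos[s + 1L] <- seq_len(nv)

  ## black edge j joins s[2j - 1] and s[2j]; gray partner of value v is
  ## bitwXor(v, 1)
  black_partner <- integer(nv)
  black_partner[s[seq(1L, nv, by = 2L)] + 1L] <- s[seq(2L, nv, by = 2L)]
  black_partner[s[seq(2L, nv, by = 2L)] + 1L] <- s[seq(1L, nv, by = 2L)]

  cycle_id <- integer(nv)          # per value 0..nv-1 (index v + 1)
  n_cycles <- 0L
  cycle_size <- integer()
  for (v0 in 0:(nv - 1L)) {
    if (cycle_id[v0 + 1L] > 0L) next
    n_cycles <- n_cycles + 1L
    sz <- 0L
    v <- v0
    repeat {
      cycle_id[v + 1L] <- n_cycles
      u <- black_partner[v + 1L]                  # black edge
      cycle_id[u + 1L] <- n_cycles
      sz <- sz + 2L
      v <- bitwXor(u, 1L)                         # then gray edge
      if (v == v0) break
    }
    cycle_size[n_cycles] <- sz
  }

  ## gray edges (one per value pair 2i, 2i+1)
  gi <- 0:m
  ga <- pmin(pos[2L * gi + 1L], pos[2L * gi + 2L])
  gb <- pmax(pos[2L * gi + 1L], pos[2L * gi + 2L])
  gcyc <- cycle_id[2L * gi + 1L]
  goriented <- (ga + gb) %% 2L == 0L
  nontrivial <- cycle_size[gcyc] > 2L

  comp_of_cycle <- seq_len(n_cycles)
  find <- function(x) { while (comp_of_cycle[x] != x) x <- comp_of_cycle[x]; x }
  if (any(nontrivial)) {
    idx <- which(nontrivial)
    a <- ga[idx]; b <- gb[idx]; cy <- gcyc[idx]
    if (length(idx) > 1L) {
      ## edges i, j cross iff a_i < a_j < b_i < b_j (either order)
      cross <- (outer(a, a, "<") & outer(b, a, ">") & outer(b, b, "<"))
      cross <- cross | t(cross)
      for (i in seq_along(idx)) {
        js <- which(cross[i, ])
        for (j in js) {
          ri <- find(cy[i]); rj <- find(cy[j])
          if (ri != rj) comp_of_cycle[ri] <- rj
        }
      }
    }
  }

  ## unoriented components (only nontrivial cycles can form them)
  comp_info <- NULL
  if (any(nontrivial)) {
    idx <- which(nontrivial)
    comp_key <- vapply(gcyc[idx], find, integer(1))
    sp <- split(idx, comp_key)
    comp_info <- data.frame(
      lo = vapply(sp, function(ii) min(ga[ii]), integer(1)),
      hi = vapply(sp, function(ii) max(gb[ii]), integer(1)),
      oriented = vapply(sp, function(ii) any(goriented[ii]), logical(1))
    )
  }

  un <- if (is.null(comp_info))
    data.frame(lo = integer(), hi = integer(), oriented = logical()) else
    comp_info[!comp_info$oriented, , drop = FALSE]
  hres <- hurdle_analysis(un)

  b <- sum(s[seq(2L, nv, by = 2L)] != s[seq(1L, nv, by = 2L)] + 1L)
  list(
    m = m, b = b, c = n_cycles, h = hres$h, f = hres$f,
    d = (m + 1L) - n_cycles + hres$h + hres$f,
    lower_bound = (m + 1L) - n_cycles,
    unoriented = un, components = comp_info
  )
}

## hurdles among the unoriented components: minimal in span containment,
## plus the greatest component when it contains all other unoriented ones
hurdle_set <- function(un) {
  k <- nrow(un)
  if (k == 0L) return(integer())
  if (k == 1L) return(1L)
  contains <- outer(un$lo, un$lo, "<") & outer(un$hi, un$hi, ">")
  minimal <- which(!apply(contains, 1, any))      # contains nothing
  greatest <- which(vapply(seq_len(k), function(i)
    all(contains[i, -i]), logical(1)))
  sort(unique(c(minimal, greatest)))
}

hurdle_analysis <- function(un) {
  if (is.null(un) || nrow(un) == 0L) return(list(h = 0L, f = 0L))
  hs <- hurdle_set(un)
  h <- length(hs)
  f <- 0L
  if (h %% 2L == 1L && h >= 3L) {
    super <- vapply(hs, function(u) {
      rest <- un[-u, , drop = FALSE]
      hs2 <- hurdle_set(rest)
      ## indices of `rest` mapped back to original rows
      orig <- seq_len(nrow(un))[-u][hs2]
      length(setdiff(orig, hs)) > 0L
    }, logical(1))
    if (all(super)) f <- 1L
  }
  list(h = h, f = f)
}

#' Reversal (inversion) distance of a signed permutation
#'
#' Exact minimal number of reversals transforming the identity into
#' `perm` (equivalently `perm` into the identity), by the
#' Hannenhalli-Pevzner formula, together with its ingredients.
#'
#' @param perm Signed permutation: each of `1..m` exactly once, signed.
#' @return List with `d` (the distance), `b` (breakpoints), `c` (cycles of
#'   the doubled breakpoint graph), `h` (hurdles), `f` (fortress indicator)
#'   and `lower_bound` (the cycle bound `d >= b - c`).
#' @examples
#' reversal_distance(c(2, 1))$d    # 3
#' @export
reversal_distance <- function(perm) {
  validate_signed_perm(perm)
  a <- analyze_perm(as.integer(perm))
  a[c("d", "b", "c", "h", "f", "lower_bound")]
}

validate_signed_perm <- function(perm) {
  perm <- as.integer(perm)
  m <- length(perm)
  if (m && !identical(sort(abs(perm)), seq_len(m)))
    stop("`perm` must contain each id 1..m exactly once (signed)")
  invisible(perm)
}

## oriented pairs of a framed permutation fp: values k such that the
## elements with absolute values k and k+1 have opposite signs.  Returns the
## induced interior reversals as a 2-column matrix of fp positions.
oriented_reversals <- function(fp) {
  mp2 <- length(fp)
  posv <- integer(mp2); posv[abs(fp) + 1L] <- seq_len(mp2)
  sgn <- sign(fp); sgn[1] <- 1L
  k <- 0:(mp2 - 2L)
  op <- which(sgn[posv[k + 1L]] != sgn[posv[k + 2L]]) - 1L
  if (!length(op)) return(matrix(integer(), ncol = 2L))
  i <- pmin(posv[op + 1L], posv[op + 2L])
  j <- pmax(posv[op + 1L], posv[op + 2L])
  ssum <- fp[posv[op + 1L]] + fp[posv[op + 2L]]
  from <- ifelse(ssum == 1L, i, i + 1L)
  to <- ifelse(ssum == 1L, j - 1L, j)
  cbind(from, to)
}

count_oriented_pairs <- function(fp) {
  mp2 <- length(fp)
  posv <- integer(mp2); posv[abs(fp) + 1L] <- seq_len(mp2)
  sgn <- sign(fp); sgn[1] <- 1L
  k <- 0:(mp2 - 2L)
  sum(sgn[posv[k + 1L]] != sgn[posv[k + 2L]])
}

rev_fp <- function(fp, from, to) {
  fp[from:to] <- -rev(fp[from:to])
  fp
}

## candidate hurdle-resolving reversals (fp coordinates), to be verified
hurdle_candidates <- function(fp, un) {
  m <- length(fp) - 2L
  ## gray-edge positions (in the doubled sequence) -> framed element index
  lo <- ceiling(un$lo / 2)
  hi <- ceiling(un$hi / 2)
  hs <- hurdle_set(un)
  clip <- function(x) pmin(pmax(x, 2L), m + 1L)
  cands <- list()
  for (u in hs) {
    a <- clip(lo[u]); b <- clip(hi[u])
    cands <- c(cands, list(c(a, b), c(a + 1L, b), c(a, b - 1L),
                           c(a + 1L, b - 1L)))
  }
  if (length(hs) >= 2L) {
    for (i in seq_along(hs)) for (j in seq_along(hs)) {
      if (i >= j) next
      u <- hs[i]; v <- hs[j]
      aa <- clip(c(lo[u], lo[u] + 1L, hi[u], hi[u] - 1L))
      bb <- clip(c(lo[v], lo[v] + 1L, hi[v], hi[v] - 1L))
      for (x in aa) for (y in bb) if (x <= y)
        cands <- c(cands, list(c(x, y)))
    }
  }
  cands <- unique(cands)
  cands[vapply(cands, function(p) p[1] <= p[2], logical(1))]
}

#' Sort the identity into a signed permutation by reversals
#'
#' Emits a minimal-length sequence of inversions that transforms the intact
#' order `+1, +2, ..., +m` into `target` (Hannenhalli-Pevzner distance,
#' including hurdle and fortress corrections).  The cycle lower bound
#' `b - c` is attached for reference alongside the achieved length.
#'
#' @param target Signed permutation over `1..m`, each id exactly once.
#' @return List of [rearrangement_event()] inversions, in application order
#'   starting from the identity, with attributes `distance` (sequence
#'   length, equal to the reversal distance) and `lower_bound`.
#' @examples
#' reversal_sort(c(-3, -2, -1))    # one whole-chromosome flip
#' length(reversal_sort(c(2, 1)))  # 3
#' @export
reversal_sort <- function(target) {
  target <- validate_signed_perm(target)
  m <- length(target)
  info <- analyze_perm(target)
  if (m == 0L)
    return(structure(list(), distance = 0L, lower_bound = 0L))
  fp <- frame_perm(target)
  d_cur <- info$d
  sorting <- vector("list", d_cur)
  step <- 0L
  while (d_cur > 0L) {
    chosen <- NULL
    ors <- oriented_reversals(fp)
    if (nrow(ors)) {
      scores <- vapply(seq_len(nrow(ors)), function(i)
        count_oriented_pairs(rev_fp(fp, ors[i, 1], ors[i, 2])), integer(1))
      for (i in order(scores, decreasing = TRUE)) {
        cand <- rev_fp(fp, ors[i, 1], ors[i, 2])
        if (analyze_perm(cand[-c(1L, length(cand))])$d == d_cur - 1L) {
          chosen <- ors[i, ]; fp <- cand; break
        }
      }
    }
    if (is.null(chosen)) {
      a <- analyze_perm(fp[-c(1L, length(fp))])
      cands <- if (!is.null(a$unoriented) && nrow(a$unoriented))
        hurdle_candidates(fp, a$unoriented) else list()
      ## safety net: all interior reversals
      cands <- c(cands, {
        all_iv <- list()
        for (i in 2:(m + 1L)) for (j in i:(m + 1L))
          all_iv[[length(all_iv) + 1L]] <- c(i, j)
        all_iv
      })
      for (p in cands) {
        cand <- rev_fp(fp, p[1], p[2])
        if (analyze_perm(cand[-c(1L, length(cand))])$d == d_cur - 1L) {
          chosen <- p; fp <- cand; break
        }
      }
      if (is.null(chosen))
        stop("internal error: no distance-reducing reversal found")
    }
    step <- step + 1L
    sorting[[step]] <- chosen
    d_cur <- d_cur - 1L
  }
  ## `sorting` transforms target -> identity; reversals are involutions, so
  ## the reversed list transforms identity -> target
  events <- lapply(rev(sorting[seq_len(step)]), function(p)
    rearrangement_event("inversion", p[1] - 1L, p[2] - 1L))
  structure(events, distance = info$d, lower_bound = info$lower_bound)
}

## apply a reversal_sort plan to the identity (unframed), for verification
replay_reversals <- function(events, m) {
  perm <- seq_len(m)
  for (ev in events)
    perm <- apply_event_copies(perm, "inversion", ev$from, ev$to)
  perm
}
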