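#' Enumerate events that realize an observed breakpoint
#'
#' Finds every inversion, deletion or tandem duplication whose application to
#' `arr` creates at least one new junction equal to the observed breakpoint
#' `bp`.  A deletion realizes the breakpoint by joining the flanks of the
#' removed span; a tandem duplication joins the end of the span back to its
#' start; an inversion realizes it at either the left or the right edge of
#' the inverted span (and always creates a second, by-product junction at
#' the other edge when one exists).
#'
#' An empty result means the breakpoint is not currently realizable on this
#' arrangement.
#'
#' @param arr An `sv_arrangement`.
#' @param bp A one-row [breakpoints()] table.
#' @return List of [rearrangement_event()] objects (possibly empty).
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' find_realizations(intact_chromosome(part), breakpoints(60, "head", 80, "tail"))
#' @export
find_realizations <- function(arr, bp) {
  stopifnot(inherits(arr, "sv_arrangement"), inherits(bp, "sv_breakpoints"),
            nrow(bp) == 1L)
  cd <- breakpoint_codes(bp, arr$partition)
  m <- find_realizations_codes(arr$copies, cd[1, 1], cd[1, 2])
  kinds <- c("inversion", "deletion", "tandem_duplication")
  lapply(seq_len(nrow(m)), function(k)
    rearrangement_event(kinds[m[k, 1]], m[k, 2], m[k, 3]))
}

## hot path: returns a matrix with columns (kind 1=inv 2=del 3=dup, from, to)
find_realizations_codes <- function(copies, code_a, code_b) {
  len <- length(copies)
  out <- matrix(integer(), ncol = 3L)
  if (len == 0L) return(out)
  lc <- copy_left_codes(copies)
  rc <- copy_right_codes(copies)
  la <- which(lc == code_a); lb <- which(lc == code_b)
  ra <- which(rc == code_a); rb <- which(rc == code_b)
  same <- code_a == code_b

  pairs <- function(i, j) {
    if (length(i) == 0L || length(j) == 0L) return(NULL)
    cbind(rep(i, times = length(j)), rep(j, each = length(i)))
  }
  acc <- vector("list", 8L); nacc <- 0L
  add <- function(kind, from, to) {
    if (length(from) == 0L) return(invisible())
    nacc <<- nacc + 1L
    acc[[nacc]] <<- cbind(kind, from, to)
    invisible()
  }

  ## tandem duplication of [i, j]: joins right end of j to left end of i
  p <- rbind(pairs(la, rb), if (!same) pairs(lb, ra))
  if (!is.null(p)) {
    ok <- p[, 2] >= p[, 1]
    add(3L, p[ok, 1], p[ok, 2])
  }

  ## deletion of [u+1, v-1]: joins right end of u to left end of v
  p <- rbind(pairs(ra, lb), if (!same) pairs(rb, la))
  if (!is.null(p)) {
    ok <- p[, 2] >= p[, 1] + 2L
    add(2L, p[ok, 1] + 1L, p[ok, 2] - 1L)
  }

  ## inversion of [u+1, j]: joins right end of u to (old) right end of j
  p <- if (same) {
    q <- pairs(ra, ra); if (!is.null(q)) q[q[, 1] < q[, 2], , drop = FALSE]
  } else {
    rbind(pairs(ra, rb), pairs(rb, ra))
  }
  if (!is.null(p) && nrow(p)) {
    ok <- p[, 2] >= p[, 1] + 1L
    add(1L, p[ok, 1] + 1L, p[ok, 2])
  }

  ## inversion of [i, w-1]: joins (old) left end of i to left end of w
  p <- if (same) {
    q <- pairs(la, la); if (!is.null(q)) q[q[, 1] < q[, 2], , drop = FALSE]
  } else {
    rbind(pairs(la, lb), pairs(lb, la))
  }
  if (!is.null(p) && nrow(p)) {
    ok <- p[, 2] >= p[, 1] + 1L
    add(1L, p[ok, 1], p[ok, 2] - 1L)
  }

  if (nacc == 0L) return(out)
  m <- do.call(rbind, acc[seq_len(nacc)])
  m <- m[!duplicated(m), , drop = FALSE]
  ## stable deterministic order: by kind, then span start, then span end
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}
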