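#' Segment partition of a chromosome
#'
#' A chromosome of length `L` bases is partitioned into `n` segments by the
#' interior boundary positions `boundaries` (strictly increasing, strictly
#' inside `(1, L)`).  Segment `i` spans the interval `(p[i-1], p[i]]` with
#' `p[0] = 1` and `p[n] = L`, so segment ends carry the positions a breakpoint
#' table reports: the *head* (5' end in reference orientation) of segment `i`
#' is labelled with position `p[i-1]` (position 1 for segment 1) and its
#' *tail* (3' end) with `p[i]` (position `L` for segment `n`).
#'
#' @param L Chromosome length in bases (`L >= 2`).
#' @param boundaries Integer vector of interior boundary positions, strictly
#'   increasing, each in `(1, L)`.  May be empty, giving a single segment.
#' @return An object of class `sv_partition` with elements `L`, `boundaries`,
#'   `n` (number of segments) and `pos` (the `n + 1` end-label positions,
#'   starting at 1 and ending at `L`).
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' part$n
#' segment_lengths(part)
#' @export
segment_partition <- function(L, boundaries = integer()) {
  L <- as.numeric(L)
  boundaries <- as.numeric(boundaries)
  if (length(L) != 1L || is.na(L) || L < 2)
    stop("`L` must be a single length >= 2")
  if (any(is.na(boundaries)))
    stop("`boundaries` must not contain NA")
  if (length(boundaries) > 0) {
    if (any(boundaries <= 1 | boundaries >= L))
      stop("all boundaries must lie strictly inside (1, L)")
    if (any(diff(boundaries) <= 0))
      stop("boundaries must be strictly increasing")
  }
  structure(
    list(
      L = L,
      boundaries = boundaries,
      n = length(boundaries) + 1L,
      pos = c(1, boundaries, L)
    ),
    class = "sv_partition"
  )
}

#' @export
print.sv_partition <- function(x, ...) {
  cat(sprintf("<sv_partition> %d segment%s over a %s-base chromosome\n",
              x$n, if (x$n == 1L) "" else "s", format(x$L, big.mark = ",")))
  invisible(x)
}

#' Segment lengths of a partition
#'
#' @param partition An [segment_partition()] object.
#' @return Numeric vector of the `n` segment lengths, summing to `L`:
#'   segment 1 spans `[1, p[1]]` (length `p[1]`), segment `i > 1` spans
#'   `(p[i-1], p[i]]` (length `p[i] - p[i-1]`).
#' @export
segment_lengths <- function(partition) {
  stopifnot(inherits(partition, "sv_partition"))
  len <- diff(partition$pos)
  len[1] <- len[1] + 1
  len
}

## ---- internal end-label code scheme -------------------------------------
##
## Every segment end gets a 0-based integer code: head of segment i -> 2i - 2,
## tail of segment i -> 2i - 1.  The segment edge of the breakpoint graph then
## joins code c to bitwXor(c, 1), and (position, terminus) labels map
## bijectively onto codes, which keeps all hot loops on integer vectors.

head_code <- function(i) 2L * as.integer(i) - 2L
tail_code <- function(i) 2L * as.integer(i) - 1L

code_segment <- function(code) code %/% 2L + 1L
code_is_tail <- function(code) code %% 2L == 1L

## position label carried by a code
code_position <- function(code, partition) {
  seg <- code_segment(code)
  ifelse(code_is_tail(code), partition$pos[seg + 1L], partition$pos[seg])
}

code_terminus <- function(code) ifelse(code_is_tail(code), "tail", "head")

## (position, terminus) -> code; terminus is "head"/"tail".  Errors on labels
## that do not coincide with a partition end label.
label_code <- function(pos, terminus, partition) {
  n <- partition$n
  out <- integer(length(pos))
  is_tail <- terminus == "tail"
  if (any(!terminus %in% c("head", "tail")))
    stop("terminus must be \"head\" or \"tail\"")
  ih <- match(pos[!is_tail], partition$pos[seq_len(n)])
  it <- match(pos[is_tail], partition$pos[seq_len(n) + 1L])
  if (anyNA(ih) || anyNA(it)) {
    bad <- c(pos[!is_tail][is.na(ih)], pos[is_tail][is.na(it)])
    stop(sprintf("position(s) %s do not match any segment end label",
                 paste(unique(bad), collapse = ", ")))
  }
  out[!is_tail] <- head_code(ih)
  out[is_tail] <- tail_code(it)
  out
}
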