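#' Segment arrangements (derivative chromosomes)
#'
#' An arrangement is the ordered sequence of signed reference-segment copies
#' making up a (possibly rearranged) chromosome: `+i` is a copy of segment
#' `i` in reference orientation, `-i` an inverted copy.  The intact
#' chromosome is `+1, +2, ..., +n`.  An arrangement may be empty (fully
#' deleted chromosome).
#'
#' @param copies Integer vector of signed segment ids (no zeros), or a string
#'   accepted by [parse_arrangement()].
#' @param partition The [segment_partition()] the ids refer to.
#' @return An object of class `sv_arrangement` with elements `copies` and
#'   `partition`.
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' arrangement("a e -c -g -h j", part)
#' @export
arrangement <- function(copies, partition) {
  stopifnot(inherits(partition, "sv_partition"))
  if (is.character(copies)) copies <- parse_arrangement(copies)
  copies <- as.integer(copies)
  if (any(is.na(copies) | copies == 0L))
    stop("copies must be nonzero signed segment ids")
  if (any(abs(copies) > partition$n))
    stop("segment id outside 1..n for this partition")
  structure(list(copies = copies, partition = partition),
            class = "sv_arrangement")
}

#' The intact (unrearranged) chromosome of a partition
#'
#' @inheritParams arrangement
#' @return An `sv_arrangement` equal to `+1, +2, ..., +n`.
#' @export
intact_chromosome <- function(partition) {
  arrangement(seq_len(partition$n), partition)
}

#' Parse an arrangement from text
#'
#' Accepts whitespace-separated signed integers (`"1 5 -3 -7 -8 10"`),
#' whitespace-separated letters with optional leading minus (`"a e -c"`,
#' `a = 1`), or the compact letter notation used for small examples,
#' `"ae(-c)(-g)(-h)j"`.
#'
#' @param text A single string.
#' @return Integer vector of signed segment ids.
#' @export
parse_arrangement <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (text == "") return(integer())
  if (!grepl("\\s", text) && grepl("^([a-z]|\\(-[a-z]\\))+$", text)) {
    toks <- regmatches(text, gregexpr("\\(-[a-z]\\)|[a-z]", text))[[1]]
  } else {
    toks <- strsplit(text, "\\s+")[[1]]
  }
  out <- vapply(toks, function(tok) {
    tok <- gsub("[()]", "", tok)
    neg <- startsWith(tok, "-")
    if (neg) tok <- substring(tok, 2)
    v <- if (grepl("^[a-z]$", tok)) {
      match(tok, letters)
    } else if (grepl("^[0-9]+$", tok)) {
      as.integer(tok)
    } else {
      stop(sprintf("cannot parse arrangement token %s", dQuote(tok)))
    }
    if (neg) -v else v
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Format an arrangement as text
#'
#' @param arr An `sv_arrangement`.
#' @param letters_ok Use `a..z` letters when all ids are at most 26.
#' @return A single string.
#' @export
format_arrangement <- function(arr, letters_ok = TRUE) {
  stopifnot(inherits(arr, "sv_arrangement"))
  x <- arr$copies
  if (length(x) == 0L) return("")
  if (letters_ok && max(abs(x)) <= 26L) {
    lab <- letters[abs(x)]
    paste(ifelse(x < 0, paste0("-", lab), lab), collapse = " ")
  } else {
    paste(x, collapse = " ")
  }
}

#' @export
print.sv_arrangement <- function(x, ...) {
  cat(sprintf("<sv_arrangement> %d cop%s of %d reference segment%s\n",
              length(x$copies), if (length(x$copies) == 1L) "y" else "ies",
              x$partition$n, if (x$partition$n == 1L) "" else "s"))
  if (length(x$copies)) cat(" ", format_arrangement(x), "\n")
  invisible(x)
}

## vectorized junction end codes of each copy: the code of the end facing
## left and the end facing right, given the copy's orientation (branch-free:
## +s -> head 2s-2 / tail 2s-1, -s -> tail 2s-1 / head 2s-2)
copy_left_codes <- function(copies) {
  2L * abs(copies) - 2L + (copies < 0L)
}
copy_right_codes <- function(copies) {
  2L * abs(copies) - 1L - (copies < 0L)
}

## a junction (rc, lc) is normal iff it is a reference boundary pair
## {tail i, head i+1} = {2i-1, 2i}: codes differing by 1 with the smaller odd
junction_is_normal <- function(rc, lc) {
  abs(lc - rc) == 1L & pmin(lc, rc) %% 2L == 1L
}

#' Rearrangement events
#'
#' An event is one of the three operators acting on a span of *copy indices*
#' `[from, to]` (1-based, inclusive) of the arrangement at the time it is
#' applied: `inversion` reverses the span and flips orientations, `deletion`
#' removes it, `tandem_duplication` inserts a verbatim copy of the span
#' immediately after it.
#'
#' @param kind `"inversion"`, `"deletion"` or `"tandem_duplication"`.
#' @param from,to Copy-index span, `1 <= from <= to`.
#' @return An object of class `sv_event`.
#' @export
rearrangement_event <- function(kind, from, to = from) {
  kind <- match.arg(kind, c("inversion", "deletion", "tandem_duplication"))
  from <- as.integer(from); to <- as.integer(to)
  if (is.na(from) || is.na(to) || from < 1L || to < from)
    stop("event span must satisfy 1 <= from <= to")
  structure(list(kind = kind, from = from, to = to), class = "sv_event")
}

#' @export
print.sv_event <- function(x, ...) {
  cat(sprintf("<sv_event> %s of copies [%d, %d]\n", x$kind, x$from, x$to))
  invisible(x)
}

#' Apply a rearrangement event to an arrangement
#'
#' Inversion reverses the span and flips orientations, so it never changes
#' the copy-number profile; deletion removes the span; tandem duplication
#' inserts a verbatim copy of the span immediately after it.
#'
#' @param arr An `sv_arrangement`.
#' @param event An [rearrangement_event()], with a span valid for `arr`.
#' @return The rearranged `sv_arrangement`.
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' dup <- rearrangement_event("tandem_duplication", 7, 8)
#' format_arrangement(apply_event(intact_chromosome(part), dup))
#' @export
apply_event <- function(arr, event) {
  stopifnot(inherits(arr, "sv_arrangement"), inherits(event, "sv_event"))
  arr$copies <- apply_event_copies(arr$copies, event$kind, event$from, event$to)
  arr
}

## hot-path version on the raw copies vector
apply_event_copies <- function(copies, kind, from, to) {
  len <- length(copies)
  if (len == 0L || from < 1L || to > len)
    stop(sprintf("event span [%d, %d] out of bounds for arrangement of length %d",
                 from, to, len))
  switch(kind,
    inversion = {
      copies[from:to] <- -rev(copies[from:to])
      copies
    },
    deletion = copies[-(from:to)],
    tandem_duplication = append(copies, copies[from:to], after = to),
    stop("unknown event kind")
  )
}

#' Copy-number profile of an arrangement
#'
#' Counts, for each reference segment, how many copies (of either
#' orientation) the arrangement carries.
#'
#' @param arr An `sv_arrangement`.
#' @return An object of class `sv_profile`: list with `counts` (integer per
#'   reference segment) and `partition`.
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' arr <- arrangement("a e -c -g -h -g -f d e f g h g -i -h j", part)
#' copy_number_profile(arr)$counts
#' @export
copy_number_profile <- function(arr) {
  stopifnot(inherits(arr, "sv_arrangement"))
  structure(
    list(counts = tabulate(abs(arr$copies), nbins = arr$partition$n),
         partition = arr$partition),
    class = "sv_profile"
  )
}

#' @export
print.sv_profile <- function(x, ...) {
  cat("<sv_profile> per-segment copy number\n")
  cat(" ", paste(x$counts, collapse = " "), "\n")
  coll <- collapse_profile(x)
  cat("  collapsed:", paste(coll$value, collapse = ","), "\n")
  invisible(x)
}

#' Collapse a copy-number profile into constant blocks
#'
#' Merges runs of consecutive reference segments with equal copy number, the
#' view a segmentation of array or read-depth data would give.
#'
#' @param profile An `sv_profile`.
#' @return Data frame with columns `start`, `end` (reference coordinates of
#'   each block, `(start, end]`), `value` (copy number) and `width`.
#' @export
collapse_profile <- function(profile) {
  stopifnot(inherits(profile, "sv_profile"))
  counts <- profile$counts
  pos <- profile$partition$pos
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)]) + 1L
  data.frame(
    start = pos[starts],
    end = pos[ends + 1L],
    value = r$values,
    width = pos[ends + 1L] - pos[starts]
  )
}

#' Abnormal adjacencies of an arrangement
#'
#' Walks the arrangement left to right and reports every junction between
#' consecutive copies that is not a reference adjacency (a junction is normal
#' only for `+i, +(i+1)` or `-i, -(i-1)`).  Chromosome ends are never
#' junctions, and repeated junctions are reported with multiplicity.
#'
#' @param arr An `sv_arrangement`.
#' @return An [breakpoints()] table, one row per abnormal junction in
#'   left-to-right order.
#' @export
extract_adjacencies <- function(arr) {
  stopifnot(inherits(arr, "sv_arrangement"))
  copies <- arr$copies
  if (length(copies) < 2L) {
    return(breakpoints(numeric(), character(), numeric(), character()))
  }
  rc <- copy_right_codes(copies[-length(copies)])
  lc <- copy_left_codes(copies[-1L])
  keep <- !junction_is_normal(rc, lc)
  codes_to_breakpoints(rc[keep], lc[keep], arr$partition)
}

#' Breakpoint implied by a single junction
#'
#' @param left_copy,right_copy Signed segment ids of two consecutive copies.
#' @param partition Their [segment_partition()].
#' @return A one-row [breakpoints()] table.  Errors if the junction is a
#'   normal reference adjacency.
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' junction_to_breakpoint(1, 5, part)   # Table-style (10, tail) -- (40, head)
#' @export
junction_to_breakpoint <- function(left_copy, right_copy, partition) {
  rc <- copy_right_codes(as.integer(left_copy))
  lc <- copy_left_codes(as.integer(right_copy))
  if (junction_is_normal(rc, lc))
    stop("junction is a normal reference adjacency, not a breakpoint")
  codes_to_breakpoints(rc, lc, partition)
}

#' Count breakpoints of an arrangement
#'
#' Three conventions are supported. `"adjacency"` counts every abnormal
#' junction, with multiplicity -- the count an exhaustive walk of the
#' derivative chromosome gives.  `"pes"` counts distinct junctions, the view
#' of a paired-end sequencing experiment in which a duplicated junction is
#' reported once.  `"microarray"` counts the positions at which the
#' copy-number profile changes value, the view of array or depth-of-coverage
#' data.
#'
#' @param arr An `sv_arrangement`.
#' @param mode `"adjacency"`, `"pes"` or `"microarray"`.
#' @return Integer count.
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' arr <- arrangement("a e -c -g -h -g -f d e f g h g -i -h j", part)
#' sapply(c("adjacency", "pes", "microarray"), count_breakpoints, arr = arr)
#' @export
count_breakpoints <- function(arr, mode = c("adjacency", "pes", "microarray")) {
  mode <- match.arg(mode)
  stopifnot(inherits(arr, "sv_arrangement"))
  count_breakpoints_copies(arr$copies, mode, arr$partition$n)
}

## hot-path version on the raw copies vector
count_breakpoints_copies <- function(copies, mode, n_segments) {
  if (mode == "microarray") {
    counts <- tabulate(abs(copies), nbins = n_segments)
    return(sum(diff(counts) != 0L))
  }
  if (length(copies) < 2L) return(0L)
  rc <- copy_right_codes(copies[-length(copies)])
  lc <- copy_left_codes(copies[-1L])
  abn <- !junction_is_normal(rc, lc)
  if (mode == "adjacency") return(sum(abn))
  ## pes: distinct unordered code pairs (integer-encoded)
  a <- rc[abn]; b <- lc[abn]
  length(unique(pmin(a, b) * (2 * n_segments) + pmax(a, b)))
}

#' Count copy-number states
#'
#' `"strict"` counts the distinct copy-number values observed across the
#' chromosome, regardless of how little of it each value covers.
#' `"relaxed"` counts the minimal number of states whose combined reference
#' coverage reaches at least `fraction` of the chromosome; zero-copy regions
#' contribute their reference length, since absence of coverage is itself a
#' state of the reference coordinate system.
#'
#' @param profile An `sv_profile`.
#' @param mode `"strict"` or `"relaxed"`.
#' @param fraction Required coverage fraction in `(0, 1]` for relaxed
#'   counting; `relaxed` with `fraction = 1` equals `strict`.
#' @return Integer count of states.
#' @examples
#' part <- segment_partition(100, seq(10, 90, by = 10))
#' arr <- arrangement("a e -c -g -h -g -f d e f g h g -i -h j", part)
#' prof <- copy_number_profile(arr)
#' count_copy_states(prof, "strict")
#' count_copy_states(prof, "relaxed", fraction = 0.90)
#' @export
count_copy_states <- function(profile, mode = c("strict", "relaxed"),
                              fraction = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "sv_profile"))
  count_copy_states_counts(profile$counts, segment_lengths(profile$partition),
                           mode, fraction)
}

## hot-path version on raw vectors
count_copy_states_counts <- function(counts, seg_len, mode, fraction = 0.95) {
  if (mode == "strict") return(length(unique(counts)))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be a single value in (0, 1]")
  cover <- rowsum(seg_len, group = counts)[, 1]
  cover <- sort(cover, decreasing = TRUE)
  needed <- fraction * sum(seg_len)
  sum(cumsum(cover) < needed) + 1L
}
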