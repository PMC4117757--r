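#' Breakpoint tables
#'
#' A breakpoint is an abnormal junction between two reference loci, each
#' described by a (position, terminus) pair where the terminus says which
#' segment end faces the junction: `"head"` is the lower-coordinate (5') end
#' of a segment, `"tail"` the higher-coordinate (3') end.  Breakpoints are
#' stored canonically with the lower position first; ties at equal position
#' are broken head-before-tail.
#'
#' @param pos_low,pos_high Reference positions of the two junction ends.
#' @param terminus_low,terminus_high `"head"` or `"tail"` for each end.
#' @return A data frame of class `sv_breakpoints` with columns `pos_low`,
#'   `terminus_low`, `pos_high`, `terminus_high`, rows canonicalized.
#' @examples
#' breakpoints(c(10, 50), c("tail", "tail"), c(40, 30), c("head", "tail"))
#' @export
breakpoints <- function(pos_low, terminus_low, pos_high, terminus_high) {
  if (!all(c(terminus_low, terminus_high) %in% c("head", "tail")))
    stop("termini must be \"head\" or \"tail\"")
  df <- data.frame(
    pos_low = as.numeric(pos_low),
    terminus_low = as.character(terminus_low),
    pos_high = as.numeric(pos_high),
    terminus_high = as.character(terminus_high),
    stringsAsFactors = FALSE
  )
  canonicalize_breakpoints(df)
}

## order each row's two ends by (position, head-before-tail)
canonicalize_breakpoints <- function(df) {
  tl <- df$terminus_low == "tail"
  th <- df$terminus_high == "tail"
  swap <- df$pos_low > df$pos_high |
    (df$pos_low == df$pos_high & tl & !th)
  if (any(swap)) {
    tmp_p <- df$pos_low[swap]
    tmp_t <- df$terminus_low[swap]
    df$pos_low[swap] <- df$pos_high[swap]
    df$terminus_low[swap] <- df$terminus_high[swap]
    df$pos_high[swap] <- tmp_p
    df$terminus_high[swap] <- tmp_t
  }
  rownames(df) <- NULL
  class(df) <- c("sv_breakpoints", "data.frame")
  df
}

#' @export
print.sv_breakpoints <- function(x, ...) {
  cat(sprintf("<sv_breakpoints> %d junction%s\n", nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  print.data.frame(x, ...)
  invisible(x)
}

## canonical string key, used for set operations on breakpoints
breakpoint_keys <- function(bp) {
  if (nrow(bp) == 0L) return(character())
  paste0(bp$pos_low, substr(bp$terminus_low, 1, 1), "|",
         bp$pos_high, substr(bp$terminus_high, 1, 1))
}

## unique canonical breakpoints (PES view of a junction list)
unique_breakpoints <- function(bp) {
  bp[!duplicated(breakpoint_keys(bp)), , drop = FALSE]
}

#' Operation class implied by a breakpoint's end orientations
#'
#' On an intact chromosome each terminus combination can only be produced by
#' one rearrangement type: a tail-to-head junction arises from a deletion of
#' the intervening material, a head-to-tail junction from a tandem
#' duplication, and head-to-head or tail-to-tail junctions from an inversion
#' (which also leaves a second, mirror-oriented junction).
#'
#' @param bp An [breakpoints()] table.
#' @return Character vector, one of `"deletion"`, `"tandem_duplication"`,
#'   `"inversion"` per row.
#' @examples
#' classify_operation(breakpoints(10, "tail", 40, "head"))   # deletion
#' classify_operation(breakpoints(60, "head", 80, "tail"))   # tandem dup
#' @export
classify_operation <- function(bp) {
  stopifnot(inherits(bp, "sv_breakpoints"))
  ifelse(bp$terminus_low == "tail" & bp$terminus_high == "head", "deletion",
  ifelse(bp$terminus_low == "head" & bp$terminus_high == "tail",
         "tandem_duplication", "inversion"))
}

## breakpoints -> 2-column matrix of end codes under a partition
breakpoint_codes <- function(bp, partition) {
  cbind(label_code(bp$pos_low, bp$terminus_low, partition),
        label_code(bp$pos_high, bp$terminus_high, partition))
}

## codes -> canonical breakpoint table under a partition
codes_to_breakpoints <- function(code_a, code_b, partition) {
  breakpoints(code_position(code_a, partition), code_terminus(code_a),
              code_position(code_b, partition), code_terminus(code_b))
}
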