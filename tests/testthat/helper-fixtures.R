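## Shared fixtures: the didactic 100-base, 10-segment chromosome, its
## five-breakpoint rearrangement (a e -c -g -h j) and the derived
## progressive end state, all built in code.

didactic_partition <- function() segment_partition(100, seq(10, 90, by = 10))

## the five breakpoints of the shattered didactic chromosome
table1_breakpoints <- function() {
  bp <- breakpoints(
    pos_low = c(10, 30, 20, 60, 70),
    terminus_low = c("tail", "tail", "head", "head", "head"),
    pos_high = c(40, 50, 70, 80, 90),
    terminus_high = c("head", "tail", "tail", "tail", "head"))
  attr(bp, "L") <- 100
  bp
}

## the rearranged chromosome carrying exactly the table's breakpoints
table1_arrangement <- function() {
  arrangement("a e -c -g -h j", didactic_partition())
}

## the end state after progressively realizing all five breakpoints
figure2_arrangement <- function() {
  arrangement("a e -c -g -h -g -f d e f g h g -i -h j", didactic_partition())
}

## random free-simulation arrangement for property tests
random_arrangement <- function(seed, n_segments = 30, n_events = 12) {
  part <- segment_partition(n_segments * 10,
                            seq(10, (n_segments - 1) * 10, by = 10))
  simulate_free(n_events, c(1, 1, 1), part, seed = seed)$final
}

## plain data-frame view of a breakpoint table for equality checks
bp_df <- function(bp) {
  d <- as.data.frame(bp)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}
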