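#' Specification for a synthetic rearrangement history
#'
#' Describes how to generate a ground-truth progressive history: a lattice
#' chromosome of `n_segments` segments of `unit` bases each, `n_events`
#' events drawn from `type_mix`, with event spans of `span_range` copies.
#' Positions on a lattice avoid adjacent-boundary degeneracies, mirroring
#' the equal-block didactic chromosome model.
#'
#' @param n_segments Number of reference segments.
#' @param n_events Number of history events.
#' @param type_mix Proportions (or weights) for `inversion`, `deletion`,
#'   `tandem_duplication`.
#' @param span_range Two integers: min and max event span, in copies.
#' @param unit Segment length in bases.
#' @param seed Integer seed.
#' @return A list of class `sv_history_spec`.
#' @export
history_spec <- function(n_segments = 20, n_events = 6,
                         type_mix = c(inversion = 1, deletion = 1,
                                      tandem_duplication = 1),
                         span_range = c(1, 5), unit = 10, seed = NULL) {
  stopifnot(n_segments >= 1, n_events >= 0, length(type_mix) == 3L,
            all(type_mix >= 0), !all(type_mix == 0),
            length(span_range) == 2L, span_range[1] >= 1,
            span_range[2] >= span_range[1], unit >= 2)
  names(type_mix) <- c("inversion", "deletion", "tandem_duplication")
  structure(list(n_segments = as.integer(n_segments),
                 n_events = as.integer(n_events),
                 type_mix = type_mix / sum(type_mix),
                 span_range = as.integer(span_range),
                 unit = unit, seed = seed),
            class = "sv_history_spec")
}

#' Generate a ground-truth rearrangement history
#'
#' Samples `n_events` events per the spec, replays them from the intact
#' chromosome, and emits the final arrangement together with its distinct
#' (PES) breakpoint set and the generating scenario.  Histories whose final
#' breakpoint set is not graph-valid -- a junction end label shared by two
#' distinct junctions, or a fold-back junction pairing a label with itself,
#' neither of which the single-path breakpoint-graph model represents -- are
#' resampled (bounded retries).  Deletions that would empty the chromosome
#' are likewise resampled.  Deterministic per seed.
#'
#' @param spec An [history_spec()].
#' @return List with `scenario` (ground-truth `sv_scenario`), `arrangement`
#'   (final `sv_arrangement`) and `breakpoints` (canonical
#'   [breakpoints()] with attribute `"L"`).
#' @examples
#' h <- generate_history(history_spec(n_segments = 12, n_events = 4, seed = 1))
#' h$breakpoints
#' @export
generate_history <- function(spec) {
  stopifnot(inherits(spec, "sv_history_spec"))
  n <- spec$n_segments
  partition <- segment_partition(spec$unit * n,
                                 spec$unit * seq_len(n - 1))
  kinds <- c("inversion", "deletion", "tandem_duplication")
  with_seed(spec$seed, {
    for (attempt in seq_len(100L)) {
      copies <- seq_len(n)
      events <- vector("list", spec$n_events)
      ok <- TRUE
      for (e in seq_len(spec$n_events)) {
        placed <- FALSE
        for (try in seq_len(100L)) {
          kind <- kinds[sample.int(3L, 1L, prob = spec$type_mix)]
          len <- length(copies)
          w <- sample.int(spec$span_range[2] - spec$span_range[1] + 1L, 1L) +
            spec$span_range[1] - 1L
          w <- min(w, len)
          if (kind == "deletion" && w >= len) next
          from <- sample.int(len - w + 1L, 1L)
          copies <- apply_event_copies(copies, kind, from, from + w - 1L)
          ev <- rearrangement_event(kind, from, from + w - 1L)
          ev$phase <- "history"
          events[[e]] <- ev
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      arr <- arrangement(copies, partition)
      bp <- unique_breakpoints(extract_adjacencies(arr))
      if (breakpoints_graph_valid(bp, partition)) {
        attr(bp, "L") <- partition$L
        scenario <- structure(
          list(events = events[lengths(events) > 0],
               partition = partition, observed = bp,
               deleted_segments = integer(), chain = NULL,
               inversion_lower_bound = NA_integer_),
          class = "sv_scenario")
        return(list(scenario = scenario, arrangement = arr,
                    breakpoints = bp))
      }
    }
    stop("could not generate a graph-valid history for this spec")
  })
}

## every end label used by at most one distinct junction, no fold-backs, and
## both reference telomeres retained (no junction at the labels (1,h) or
## (L,t)) -- the single-path breakpoint-graph model assumes the derivative
## still runs from chromosome start to chromosome end
breakpoints_graph_valid <- function(bp, partition) {
  if (nrow(bp) == 0L) return(TRUE)
  if (any(c(bp$pos_low, bp$pos_high) %in% c(1, partition$L))) return(FALSE)
  cd <- breakpoint_codes(bp, partition)
  if (any(cd[, 1] == cd[, 2])) return(FALSE)
  !any(duplicated(c(cd[, 1], cd[, 2])))
}

#' Synthetic breakpoint set at the scale of a heavily rearranged chromosome
#'
#' Builds a canonical, node-disjoint breakpoint set of `n_breakpoints`
#' junctions (default 239, the size of the classic paired-end-sequencing
#' exemplar) over a chromosome-scale lattice partition, with a configurable
#' mix of the four terminus-orientation classes (default near-balanced).
#' Junction partner positions are drawn with bounded gaps (`1..max_gap`
#' lattice units), so events act on sizeable but not chromosome-spanning
#' intervals; all positions are distinct, so the set always builds a valid
#' breakpoint graph.
#'
#' @param seed Integer seed.
#' @param n_breakpoints Number of junctions.
#' @param class_counts Named counts for classes `hh`, `tt`, `ht`, `th`
#'   (head-head, tail-tail, head-tail i.e. tandem-duplication-like, and
#'   tail-head i.e. deletion-like); must sum to `n_breakpoints`.  Default
#'   splits as evenly as possible.
#' @param L Chromosome length in bases.
#' @param unit Lattice unit in bases.
#' @param max_gap Maximum junction span in lattice units (default 1000,
#'   i.e. up to 10% of the default chromosome per junction: partners are
#'   broadly distributed but bounded, the regime in which progressive
#'   simulations neither stall nor blow up).
#' @return An [breakpoints()] table with attribute `"L"`, ready for
#'   [simulate_progressive()].
#' @examples
#' bp <- snu_c1_like(seed = 1)
#' nrow(bp)
#' table(classify_operation(bp))
#' @export
snu_c1_like <- function(seed = NULL, n_breakpoints = 239,
                        class_counts = NULL, L = 1e8, unit = 1e4,
                        max_gap = 1000) {
  if (is.null(class_counts)) {
    base <- n_breakpoints %/% 4L
    extra <- n_breakpoints %% 4L
    class_counts <- c(hh = base + (extra >= 1L), tt = base + (extra >= 2L),
                      ht = base + (extra >= 3L), th = base)
  }
  stopifnot(sum(class_counts) == n_breakpoints,
            all(names(class_counts) %in% c("hh", "tt", "ht", "th")))
  n_sites <- floor(L / unit) - 1L
  stopifnot(n_sites > 4L * n_breakpoints)
  with_seed(seed, {
    used <- integer()
    lows <- integer(n_breakpoints)
    highs <- integer(n_breakpoints)
    for (i in seq_len(n_breakpoints)) {
      repeat {
        lo <- sample.int(n_sites - max_gap, 1L)
        gap <- sample.int(max_gap, 1L)
        hi <- lo + gap
        if (!lo %in% used && !hi %in% used) break
      }
      used <- c(used, lo, hi)
      lows[i] <- lo; highs[i] <- hi
    }
    cls <- rep(names(class_counts), times = class_counts)
    cls <- cls[sample.int(length(cls))]
    t_low <- c(hh = "head", tt = "tail", ht = "head", th = "tail")[cls]
    t_high <- c(hh = "head", tt = "tail", ht = "tail", th = "head")[cls]
    bp <- breakpoints(lows * unit, t_low, highs * unit, t_high)
    attr(bp, "L") <- L
    bp
  })
}
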