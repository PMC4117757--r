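#' Simulation configuration
#'
#' Collects the knobs of the progressive-rearrangement simulation: which
#' breakpoint-counting convention and copy-state convention to record, the
#' relative sampling weights of the three operation classes, how to choose
#' among candidate realizations of a drawn breakpoint, optional breakpoint
#' checkpoints, a seed, and an event cap.
#'
#' @param counting_mode Breakpoint counting convention for trajectory
#'   snapshots: `"adjacency"`, `"pes"` or `"microarray"`.
#' @param state_mode Copy-state convention: `"strict"` or `"relaxed"`.
#' @param relaxed_fraction Coverage fraction for relaxed state counting
#'   (default 0.95; 0.90 is the value used in small worked examples).
#' @param type_weights Positive sampling weights for the classes
#'   `inversion`, `deletion`, `tandem_duplication`; a drawn breakpoint's
#'   probability is proportional to the weight of its operation class.
#'   `c(2, 1, 1)` makes inversions twice as likely as either other class.
#' @param realization_strategy How to pick among candidate events realizing
#'   a drawn breakpoint: `"random"` (uniform), `"nearest"` (smallest span) or
#'   `"furthest"` (largest span).
#' @param checkpoints Optional increasing breakpoint counts at which
#'   snapshots are flagged; the simulation stops once the running breakpoint
#'   count reaches the largest checkpoint.
#' @param seed Integer seed; identical seed, config and input give an
#'   identical trajectory.
#' @param max_events Cap on the number of applied events.
#' @return A list of class `sv_sim_config`.
#' @export
sim_config <- function(counting_mode = c("adjacency", "pes", "microarray"),
                       state_mode = c("strict", "relaxed"),
                       relaxed_fraction = 0.95,
                       type_weights = c(inversion = 1, deletion = 1,
                                        tandem_duplication = 1),
                       realization_strategy = c("random", "nearest", "furthest"),
                       checkpoints = NULL,
                       seed = NULL,
                       max_events = Inf) {
  counting_mode <- match.arg(counting_mode)
  state_mode <- match.arg(state_mode)
  realization_strategy <- match.arg(realization_strategy)
  if (length(type_weights) != 3L || any(type_weights < 0) ||
      all(type_weights == 0))
    stop("`type_weights` must be three non-negative weights, not all zero")
  names(type_weights) <- c("inversion", "deletion", "tandem_duplication")
  if (relaxed_fraction <= 0 || relaxed_fraction > 1)
    stop("`relaxed_fraction` must be in (0, 1]")
  structure(
    list(counting_mode = counting_mode, state_mode = state_mode,
         relaxed_fraction = relaxed_fraction, type_weights = type_weights,
         realization_strategy = realization_strategy,
         checkpoints = checkpoints, seed = seed, max_events = max_events),
    class = "sv_sim_config"
  )
}

#' Partition implied by a breakpoint set
#'
#' The simulation and the breakpoint graph both segment the chromosome at
#' the observed breakpoint coordinates: boundaries are the sorted unique
#' positions of the set.
#'
#' @param bp An [breakpoints()] table.
#' @param L Chromosome length; must exceed every breakpoint position.
#' @return An [segment_partition()].
#' @export
partition_from_breakpoints <- function(bp, L = attr(bp, "L")) {
  stopifnot(inherits(bp, "sv_breakpoints"))
  if (is.null(L))
    stop("supply `L` (chromosome length) or a breakpoint set carrying attr \"L\"")
  pos <- sort(unique(c(bp$pos_low, bp$pos_high)))
  if (length(pos) && (min(pos) < 1 || max(pos) > L))
    stop("breakpoint positions must lie inside [1, L]")
  ## 1 and L are the labels of the chromosome ends, not interior boundaries
  segment_partition(L, setdiff(pos, c(1, L)))
}

new_trajectory <- function(snapshots, final, realized, discarded, destroyed,
                           config) {
  structure(
    list(snapshots = snapshots, final = final, realized = realized,
         discarded = discarded, destroyed = destroyed, config = config),
    class = "sv_trajectory"
  )
}

#' @export
print.sv_trajectory <- function(x, ...) {
  ns <- nrow(x$snapshots)
  cat(sprintf("<sv_trajectory> %d event%s applied\n", ns,
              if (ns == 1L) "" else "s"))
  if (ns) {
    last <- x$snapshots[ns, ]
    cat(sprintf("  final: %d breakpoints (%s), %d copy states (%s)\n",
                last$n_breakpoints, x$config$counting_mode, last$n_states,
                x$config$state_mode))
  }
  if (length(x$discarded))
    cat(sprintf("  %d observed breakpoint(s) were unrealizable and discarded\n",
                length(x$discarded)))
  if (length(x$destroyed))
    cat(sprintf("  %d realized breakpoint(s) later destroyed\n",
                length(x$destroyed)))
  invisible(x)
}

empty_snapshots <- function() {
  data.frame(event_index = integer(), bp_index = integer(),
             bp_class = character(), event_kind = character(),
             n_breakpoints = integer(), n_states = integer(),
             arrangement_length = integer(), at_checkpoint = logical())
}

#' Progressively realize an observed breakpoint set
#'
#' The Stephens-style simulation: starting from the intact chromosome, draw
#' observed breakpoints one at a time without replacement (with probability
#' proportional to the weight of each breakpoint's operation class), find
#' the rearrangement events that would realize the drawn breakpoint on the
#' current arrangement, apply one of them, and record the running breakpoint
#' and copy-state counts.  Drawn breakpoints with no realization on the
#' current arrangement are discarded (and reported).  Later events may
#' destroy earlier junctions; counts are always recomputed from the current
#' arrangement, and realized-then-destroyed breakpoints are reported.
#'
#' @param observed An [breakpoints()] table (canonical, one shared
#'   chromosome).
#' @param config An [sim_config()].
#' @param partition Optional [segment_partition()]; defaults to
#'   [partition_from_breakpoints()] of `observed` (which then must carry an
#'   `"L"` attribute or `L` must be given).
#' @param L Chromosome length used when `partition` is `NULL`.
#' @return An `sv_trajectory`: per-event `snapshots` (data frame), the
#'   `final` arrangement, the `realized` and `discarded` observed breakpoint
#'   indices, and the keys of realized breakpoints later `destroyed`.
#' @examples
#' tbl1 <- breakpoints(c(10, 30, 20, 60, 70), c("tail", "tail", "head", "head", "head"),
#'                     c(40, 50, 70, 80, 90), c("head", "tail", "tail", "tail", "head"))
#' traj <- simulate_progressive(tbl1, sim_config(seed = 1), L = 100)
#' traj$snapshots
#' @export
simulate_progressive <- function(observed, config = sim_config(),
                                 partition = NULL, L = attr(observed, "L")) {
  stopifnot(inherits(observed, "sv_breakpoints"),
            inherits(config, "sv_sim_config"))
  if (is.null(partition)) {
    if (nrow(observed) == 0L) {
      part <- segment_partition(if (is.null(L)) 2 else L)
      return(new_trajectory(empty_snapshots(), intact_chromosome(part),
                            integer(), integer(), character(), config))
    }
    partition <- partition_from_breakpoints(observed, L)
  }
  stopifnot(inherits(partition, "sv_partition"))
  cd <- breakpoint_codes(observed, partition)
  classes <- classify_operation(observed)
  w <- unname(config$type_weights[classes])
  if (nrow(observed) > 0L && all(w == 0))
    stop("all observed breakpoints have zero sampling weight")
  n <- partition$n
  seg_len <- segment_lengths(partition)
  stop_at <- if (length(config$checkpoints)) max(config$checkpoints) else Inf
  cps <- sort(unique(config$checkpoints))

  kinds <- c("inversion", "deletion", "tandem_duplication")
  class_id <- match(classes, kinds)
  with_seed(config$seed, {
    res <- cpp_simulate_progressive(
      cd, class_id, unname(config$type_weights), n, seg_len,
      match(config$counting_mode, c("adjacency", "pes", "microarray")),
      match(config$state_mode, c("strict", "relaxed")),
      config$relaxed_fraction,
      match(config$realization_strategy, c("random", "nearest", "furthest")),
      as.double(config$max_events), as.double(stop_at))
    ev <- length(res$bp_index)
    final <- arrangement(res$final, partition)
    applied <- res$applied
    realized_bp <- observed[applied, , drop = FALSE]
    final_keys <- breakpoint_keys(extract_adjacencies(final))
    destroyed <- setdiff(breakpoint_keys(realized_bp), final_keys)
    snapshots <- if (ev > 0L) {
      at_cp <- rep(FALSE, ev)
      if (length(cps)) {
        ## flag the first snapshot reaching each checkpoint count
        for (cp in cps) {
          hit <- which(res$n_breakpoints >= cp)[1]
          if (!is.na(hit)) at_cp[hit] <- TRUE
        }
      }
      data.frame(event_index = seq_len(ev), bp_index = res$bp_index,
                 bp_class = classes[res$bp_index],
                 event_kind = kinds[res$kind],
                 n_breakpoints = res$n_breakpoints,
                 n_states = res$n_states,
                 arrangement_length = res$arrangement_length,
                 at_checkpoint = at_cp)
    } else empty_snapshots()
    new_trajectory(snapshots, final, applied, res$discarded, destroyed,
                   config)
  })
}

#' Free (unconstrained) progressive simulation
#'
#' Applies `n_events` rearrangements with uniformly random valid spans,
#' drawing each event's type from `type_weights`.  Unlike
#' [simulate_progressive()] there is no observed breakpoint set: this is the
#' regime used to show that inversions and deletions alone can produce
#' hundreds of breakpoints while the chromosome never leaves copy states 0
#' and 1.
#'
#' @param n_events Number of events to apply.
#' @param type_weights Weights for `inversion`, `deletion`,
#'   `tandem_duplication`; must not all be zero.
#' @param partition The chromosome [segment_partition()].
#' @param seed Integer seed.
#' @param counting_mode,state_mode,relaxed_fraction Snapshot conventions, as
#'   in [sim_config()].
#' @return An `sv_trajectory`.
#' @examples
#' part <- segment_partition(1001, seq(11, 991, by = 10))
#' traj <- simulate_free(50, c(1, 1, 0), part, seed = 1)
#' range(copy_number_profile(traj$final)$counts)
#' @export
simulate_free <- function(n_events, type_weights, partition, seed = NULL,
                          counting_mode = "adjacency", state_mode = "strict",
                          relaxed_fraction = 0.95) {
  stopifnot(inherits(partition, "sv_partition"), n_events >= 0)
  if (length(type_weights) != 3L || any(type_weights < 0) ||
      all(type_weights == 0))
    stop("`type_weights` must be three non-negative weights, not all zero")
  config <- sim_config(counting_mode = counting_mode, state_mode = state_mode,
                       relaxed_fraction = relaxed_fraction,
                       type_weights = type_weights, seed = seed)
  n <- partition$n
  seg_len <- segment_lengths(partition)
  kinds <- c("inversion", "deletion", "tandem_duplication")
  with_seed(seed, {
    copies <- seq_len(n)
    snaps <- vector("list", n_events)
    ev <- 0L
    while (ev < n_events) {
      kind <- kinds[sample.int(3L, 1L, prob = type_weights)]
      len <- length(copies)
      retries <- 0L
      repeat {
        from <- sample.int(len, 1L, prob = len:1)
        to <- from + sample.int(len - from + 1L, 1L) - 1L
        if (!(kind == "deletion" && to - from + 1L == len)) break
        retries <- retries + 1L
        if (retries > 100L) break
      }
      if (kind == "deletion" && to - from + 1L == len) {
        ## cannot delete without emptying the chromosome; skip this event
        ev <- ev + 1L
        next
      }
      copies <- apply_event_copies(copies, kind, from, to)
      ev <- ev + 1L
      nbp <- count_breakpoints_copies(copies, counting_mode, n)
      nst <- count_copy_states_counts(tabulate(abs(copies), nbins = n),
                                      seg_len, state_mode, relaxed_fraction)
      snaps[[ev]] <- data.frame(
        event_index = ev, bp_index = NA_integer_, bp_class = NA_character_,
        event_kind = kind, n_breakpoints = nbp, n_states = nst,
        arrangement_length = length(copies), at_checkpoint = FALSE)
    }
    snapshots <- if (n_events > 0L)
      do.call(rbind, snaps[!vapply(snaps, is.null, logical(1))]) else
      empty_snapshots()
    if (nrow(snapshots)) snapshots$event_index <- seq_len(nrow(snapshots))
    new_trajectory(snapshots, arrangement(copies, partition),
                   integer(), integer(), character(), config)
  })
}

#' Replicate progressive simulations and aggregate trajectories
#'
#' Runs [simulate_progressive()] `n_replicates` times with independent
#' derived seeds, pools the per-event snapshots, and summarizes copy-state
#' counts per breakpoint-count bin (median and the central interval holding
#' 99% of observations).  By default every running snapshot contributes, so
#' one replicate populates many bins; `endpoints_only` restricts the
#' aggregation to each replicate's final state.
#'
#' @inheritParams simulate_progressive
#' @param n_replicates Number of replicates (`>= 1`).
#' @param endpoints_only Aggregate only each replicate's last snapshot.
#' @return An `sv_sweep`: `snapshots` (with a `replicate` column) and `bins`
#'   (data frame `n_breakpoints`, `n_obs`, `median_states`, `lo99`, `hi99`).
#' @export
sweep_replicates <- function(observed, config = sim_config(), n_replicates,
                             partition = NULL, L = attr(observed, "L"),
                             endpoints_only = FALSE) {
  stopifnot(n_replicates >= 1)
  if (is.null(partition)) partition <- partition_from_breakpoints(observed, L)
  seeds <- derive_seeds(config$seed, n_replicates)
  all_snaps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    tr <- simulate_progressive(observed, cfg, partition = partition)
    s <- tr$snapshots
    if (endpoints_only && nrow(s) > 0L) s <- s[nrow(s), , drop = FALSE]
    if (nrow(s) > 0L) s$replicate <- r
    all_snaps[[r]] <- s
  }
  snapshots <- do.call(rbind, all_snaps[vapply(all_snaps, nrow, 0L) > 0])
  if (is.null(snapshots)) snapshots <- cbind(empty_snapshots(),
                                             replicate = integer())
  bins <- aggregate_sweep_bins(snapshots)
  structure(list(snapshots = snapshots, bins = bins, config = config,
                 n_replicates = n_replicates),
            class = "sv_sweep")
}

aggregate_sweep_bins <- function(snapshots) {
  if (nrow(snapshots) == 0L)
    return(data.frame(n_breakpoints = integer(), n_obs = integer(),
                      median_states = numeric(), lo99 = numeric(),
                      hi99 = numeric()))
  sp <- split(snapshots$n_states, snapshots$n_breakpoints)
  data.frame(
    n_breakpoints = as.integer(names(sp)),
    n_obs = lengths(sp),
    median_states = vapply(sp, stats::median, numeric(1)),
    lo99 = vapply(sp, stats::quantile, numeric(1), probs = 0.005, names = FALSE),
    hi99 = vapply(sp, stats::quantile, numeric(1), probs = 0.995, names = FALSE),
    row.names = NULL
  )
}

#' @export
print.sv_sweep <- function(x, ...) {
  cat(sprintf("<sv_sweep> %d replicates, %d snapshots, %d breakpoint bins\n",
              x$n_replicates, nrow(x$snapshots), nrow(x$bins)))
  invisible(x)
}

#' Footprint criteria for chromothripsis screening
#'
#' The operational footprint: at least `min_breakpoints` breakpoints on a
#' chromosome dominated by at most `max_states` copy-number states.
#'
#' @param min_breakpoints Minimum breakpoint count (default 50).
#' @param max_states Maximum copy-state count (default 3).
#' @param state_mode,relaxed_fraction State-counting convention the counts
#'   are expected to come from (recorded for provenance).
#' @return A list of class `sv_footprint_criteria`.
#' @export
footprint_criteria <- function(min_breakpoints = 50, max_states = 3,
                               state_mode = "relaxed",
                               relaxed_fraction = 0.95) {
  stopifnot(min_breakpoints >= 1, max_states >= 1)
  structure(list(min_breakpoints = min_breakpoints, max_states = max_states,
                 state_mode = state_mode, relaxed_fraction = relaxed_fraction),
            class = "sv_footprint_criteria")
}

#' Does a chromosome bear the footprint of chromothripsis?
#'
#' @param breakpoint_count,state_count Non-negative counts (vectorized).
#' @param criteria An [footprint_criteria()].
#' @return Logical: `TRUE` iff `breakpoint_count >= min_breakpoints` and
#'   `state_count <= max_states`.
#' @examples
#' classify_footprint(67, 3)    # TRUE
#' classify_footprint(49, 2)    # FALSE
#' @export
classify_footprint <- function(breakpoint_count, state_count,
                               criteria = footprint_criteria()) {
  stopifnot(inherits(criteria, "sv_footprint_criteria"),
            all(breakpoint_count >= 0), all(state_count >= 0))
  breakpoint_count >= criteria$min_breakpoints &
    state_count <= criteria$max_states
}
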