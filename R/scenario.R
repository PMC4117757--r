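#' Build an explicit progressive-rearrangement scenario
#'
#' Turns a chained breakpoint graph into an ordered series of inversions,
#' deletions and tandem duplications that replays from the intact chromosome
#' and reproduces the observed breakpoints.  Inversions come from sorting
#' the chained path's signed permutation (computed over retained segments
#' only); deletion events for isolated components are placed at
#' seeded-random positions among the inversions, with spans resolved against
#' the arrangement at insertion time; duplications -- cycle components and
#' any remaining duplication-type junctions -- are realized last, so copy
#' numbers stay low for as long as possible.  A final repair pass realizes
#' any observed junction still missing, accepting only events that enlarge
#' the set of observed junctions present.
#'
#' @param x An [chain_paths()] result, an [build_graph()] object, or an
#'   [breakpoints()] table (the latter two are chained internally).
#' @param seed Integer seed for deletion placement, chaining and repair
#'   order.
#' @param L Chromosome length, required when `x` is a breakpoint table
#'   without an `"L"` attribute.
#' @return An object of class `sv_scenario`: `events` (list of
#'   [rearrangement_event()]s, each annotated with its construction `phase`,
#'   the observed junctions it `creates` and its `byproducts`), the graph
#'   `partition`, and the observed breakpoint table.
#' @examples
#' tbl1 <- breakpoints(c(10, 30, 20, 60, 70), c("tail", "tail", "head", "head", "head"),
#'                     c(40, 50, 70, 80, 90), c("head", "tail", "tail", "tail", "head"))
#' sc <- build_scenario(tbl1, seed = 1, L = 100)
#' verify_scenario(sc, tbl1)
#' @export
build_scenario <- function(x, seed = NULL, L = NULL) {
  if (inherits(x, "sv_breakpoints"))
    x <- build_graph(x, L = L %||% attr(x, "L"))
  if (inherits(x, "sv_bpgraph"))
    x <- chain_paths(x, seed = seed)
  stopifnot(inherits(x, "sv_chain"))
  chain <- x
  graph <- chain$graph
  partition <- graph$partition
  n <- graph$n
  observed <- if (nrow(graph$edges))
    codes_to_breakpoints(graph$edges[, 1], graph$edges[, 2], partition) else
    breakpoints(numeric(), character(), numeric(), character())

  comps <- chain$components
  in_chain <- unique(code_segment(chain$nodes))
  deleted <- sort(unlist(lapply(comps, function(cp)
    if (cp$kind == "isolated_segment" && !any(cp$segments %in% in_chain))
      cp$segments)))

  ## target main-line layout: the chained path, followed by one copy of
  ## each cycle's read-out appended at the chromosome end (appending there
  ## never disturbs an observed junction; the cycle's closing junction is
  ## realized afterwards by duplicating the block).  Every non-deleted
  ## segment thus has an explicit target position, so sorting leaves no
  ## stray copies between path junctions.
  extra <- c(comps[vapply(comps, function(cp) cp$kind == "cycle", TRUE)],
             comps[chain$leftover %||% integer()])
  perm_signed <- c(path_to_signed_permutation(chain),
                   unlist(lapply(extra, cycle_readout)))
  retained <- sort(abs(perm_signed))
  target <- match(abs(perm_signed), retained) * sign(perm_signed)
  inv_events <- reversal_sort(target)

  obs_keys <- junction_key(graph$edges[, 1], graph$edges[, 2])

  with_seed(seed, {
    ## interleave deletions among the inversions
    slots <- if (length(deleted))
      sort(stats::runif(length(deleted))) * (length(inv_events) + 1L) else
      numeric()
    plan <- c(
      lapply(inv_events, function(ev) list(op = "inversion", ev = ev)),
      lapply(deleted, function(g) list(op = "deletion", segment = g))
    )
    ord <- order(c(seq_along(inv_events), slots - 0.5))
    plan <- plan[ord]

    copies <- seq_len(n)
    events <- list()
    emit <- function(kind, from, to, phase) {
      before <- junction_multiset(copies)
      copies <<- apply_event_copies(copies, kind, from, to)
      after <- junction_multiset(copies)
      created <- diff_multiset(after, before)
      ev <- rearrangement_event(kind, from, to)
      ev$phase <- phase
      ev$creates <- code_keys_to_labels(intersect(unique(created), obs_keys),
                                        partition)
      ev$byproducts <- code_keys_to_labels(setdiff(unique(created), obs_keys),
                                           partition)
      events[[length(events) + 1L]] <<- ev
    }

    for (step in plan) {
      if (step$op == "inversion") {
        ridx <- which(abs(copies) %in% retained)
        emit("inversion", ridx[step$ev$from], ridx[step$ev$to],
             phase = "inversion_sort")
      } else {
        pos <- which(abs(copies) == step$segment)[1]
        if (is.na(pos))
          stop(sprintf("internal consistency error: segment %d already absent",
                       step$segment))
        emit("deletion", pos, pos, phase = "deletion")
      }
    }

    ## duplications and repair: realize every observed junction still
    ## missing.  Tandem duplications never destroy existing junctions, so
    ## they are tried first, then inversions, then deletions; every
    ## candidate must keep all currently-present observed junctions and a
    ## deletion may not remove the last copy of a segment some other
    ## missing junction still refers to.
    kinds <- c("inversion", "deletion", "tandem_duplication")
    repeat {
      present <- obs_keys %in% junction_multiset(copies)
      missing <- which(!present)
      if (!length(missing)) break
      progress <- FALSE
      miss_ord <- missing[sample.int(length(missing))]
      for (kind_code in c(3L, 1L, 2L)) {
        for (k in miss_ord) {
          cand <- find_realizations_codes(copies, graph$edges[k, 1],
                                          graph$edges[k, 2])
          cand <- cand[cand[, 1] == kind_code, , drop = FALSE]
          if (!nrow(cand)) next
          for (r in seq_len(nrow(cand))) {
            if (kind_code == 2L) {
              ## segments other missing junctions still need
              need <- unique(code_segment(c(graph$edges[setdiff(missing, k), ])))
              span_segs <- abs(copies[cand[r, 2]:cand[r, 3]])
              left <- tabulate(abs(copies), nbins = n) -
                tabulate(span_segs, nbins = n)
              if (any(left[intersect(need, span_segs)] == 0L)) next
            }
            trial <- apply_event_copies(copies, kinds[cand[r, 1]],
                                        cand[r, 2], cand[r, 3])
            keys_after <- junction_multiset(trial)
            if (all(obs_keys[present] %in% keys_after) &&
                obs_keys[k] %in% keys_after) {
              emit(kinds[cand[r, 1]], cand[r, 2], cand[r, 3],
                   phase = "duplication")
              progress <- TRUE
              break
            }
          }
          if (progress) break
        }
        if (progress) break
      }
      if (!progress) {
        ## no single event realizes any missing junction without damage:
        ## search for up to two non-damaging preparatory inversions (flips
        ## of the copies carrying the junction's end labels, or the block
        ## between them) after which one event does
        for (k in miss_ord) {
          plan <- plan_with_preps(copies, graph$edges[k, 1],
                                  graph$edges[k, 2], obs_keys, present, n)
          if (!is.null(plan)) {
            for (p in plan) emit(kinds[p[1]], p[2], p[3], phase = "duplication")
            progress <- TRUE
            break
          }
        }
      }
      if (!progress) break
    }

    structure(list(events = events, partition = partition,
                   observed = observed, chain = chain,
                   deleted_segments = deleted,
                   inversion_lower_bound = attr(inv_events, "lower_bound")),
              class = "sv_scenario")
  })
}

## signed read-out of a cycle component: one copy of the duplicated
## material, realizing all of the cycle's junctions except the closing one
cycle_readout <- function(comp) {
  nodes <- comp$nodes
  enter <- nodes[seq(1L, length(nodes), by = 2L)]
  ifelse(enter %% 2L == 0L, code_segment(enter), -code_segment(enter))
}

## Depth-limited search for non-damaging preparatory inversions followed by
## one realizing event.  Returns a list of (kind_code, from, to) rows, or
## NULL.  Preparatory candidates: single-copy flips of the copies carrying
## the target junction's end labels, and inversions of the block between an
## A-carrier and a B-carrier.
plan_with_preps <- function(copies, code_a, code_b, obs_keys, present, n,
                            depth = 2L) {
  kinds <- c("inversion", "deletion", "tandem_duplication")
  present_keys <- obs_keys[present]
  target_key <- junction_key(code_a, code_b)
  non_damaging <- function(cp) all(present_keys %in% junction_multiset(cp))

  finishing_event <- function(cp) {
    cand <- find_realizations_codes(cp, code_a, code_b)
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(match(cand[, 1], c(3L, 1L, 2L))), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      trial <- apply_event_copies(cp, kinds[cand[r, 1]], cand[r, 2], cand[r, 3])
      keys_after <- junction_multiset(trial)
      if (all(present_keys %in% keys_after) && target_key %in% keys_after)
        return(cand[r, ])
    }
    NULL
  }

  prep_candidates <- function(cp) {
    lc <- copy_left_codes(cp); rc <- copy_right_codes(cp)
    pa <- which(lc == code_a | rc == code_a)
    pb <- which(lc == code_b | rc == code_b)
    cands <- unique(c(pa, pb))
    preps <- lapply(cands, function(p) c(p, p))
    for (i in pa) for (j in pb) if (i != j)
      preps[[length(preps) + 1L]] <- c(min(i, j), max(i, j))
    unique(preps)
  }

  frontier <- list(list(copies = copies, preps = list()))
  for (d in 0:depth) {
    for (st in frontier) {
      fin <- finishing_event(st$copies)
      if (!is.null(fin))
        return(c(st$preps, list(fin)))
    }
    if (d == depth) break
    nxt <- list()
    for (st in frontier) {
      for (pr in prep_candidates(st$copies)) {
        trial <- apply_event_copies(st$copies, "inversion", pr[1], pr[2])
        if (non_damaging(trial))
          nxt[[length(nxt) + 1L]] <- list(
            copies = trial,
            preps = c(st$preps, list(c(1L, pr[1], pr[2]))))
      }
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  NULL
}

## unordered junction keys of every abnormal junction (with multiplicity)
junction_multiset <- function(copies) {
  if (length(copies) < 2L) return(character())
  rc <- copy_right_codes(copies[-length(copies)])
  lc <- copy_left_codes(copies[-1L])
  abn <- !junction_is_normal(rc, lc)
  junction_key(rc[abn], lc[abn])
}

junction_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

## translate internal code keys into canonical position/terminus keys
code_keys_to_labels <- function(keys, partition) {
  if (!length(keys)) return(character())
  parts <- do.call(rbind, strsplit(keys, " "))
  breakpoint_keys(codes_to_breakpoints(as.integer(parts[, 1]),
                                       as.integer(parts[, 2]), partition))
}

## elements of multiset `after` not accounted for by `before`
diff_multiset <- function(after, before) {
  tb <- table(before)
  out <- character()
  ta <- table(after)
  for (k in names(ta)) {
    extra <- ta[[k]] - if (k %in% names(tb)) tb[[k]] else 0L
    if (extra > 0L) out <- c(out, rep(k, extra))
  }
  out
}

#' @export
print.sv_scenario <- function(x, ...) {
  kinds <- vapply(x$events, `[[`, "", "kind")
  cat(sprintf(
    "<sv_scenario> %d events: %d inversions, %d deletions, %d tandem duplications\n",
    length(kinds), sum(kinds == "inversion"), sum(kinds == "deletion"),
    sum(kinds == "tandem_duplication")))
  invisible(x)
}

#' Replay a scenario from the intact chromosome
#'
#' @param scenario An [build_scenario()] result (or any list of events plus
#'   a partition).
#' @return The final `sv_arrangement`.
#' @export
replay_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sv_scenario"))
  copies <- seq_len(scenario$partition$n)
  for (i in seq_along(scenario$events)) {
    ev <- scenario$events[[i]]
    copies <- tryCatch(
      apply_event_copies(copies, ev$kind, ev$from, ev$to),
      error = function(e) stop(sprintf(
        "scenario invalid: event %d (%s [%d, %d]) failed: %s",
        i, ev$kind, ev$from, ev$to, conditionMessage(e))))
  }
  arrangement(copies, scenario$partition)
}

#' Verify a scenario against observed breakpoints
#'
#' Replays the scenario, extracts the distinct junctions of the final
#' arrangement (the PES view), and reports how many observed breakpoints
#' are reproduced, how many unobserved breakpoints were created, and the
#' event tallies by type.
#'
#' @param scenario An [build_scenario()] result.
#' @param observed An [breakpoints()] table (defaults to the scenario's own
#'   observed set).
#' @return An object of class `sv_verification`: `explained_count`,
#'   `explained_fraction` (1 when every observed breakpoint appears; an
#'   empty observed set is vacuously fully explained), `new_count`,
#'   `tallies`, and the final arrangement.
#' @export
verify_scenario <- function(scenario, observed = scenario$observed) {
  stopifnot(inherits(scenario, "sv_scenario"),
            inherits(observed, "sv_breakpoints"))
  final <- replay_scenario(scenario)
  final_keys <- unique(breakpoint_keys(extract_adjacencies(final)))
  obs_keys <- unique(breakpoint_keys(observed))
  explained <- sum(obs_keys %in% final_keys)
  kinds <- vapply(scenario$events, `[[`, "", "kind")
  structure(
    list(
      explained_count = explained,
      observed_count = length(obs_keys),
      explained_fraction = if (length(obs_keys)) explained / length(obs_keys)
                           else 1,
      new_count = sum(!final_keys %in% obs_keys),
      tallies = c(inversions = sum(kinds == "inversion"),
                  deletions = sum(kinds == "deletion"),
                  tandem_duplications = sum(kinds == "tandem_duplication")),
      final = final
    ),
    class = "sv_verification"
  )
}

#' @export
print.sv_verification <- function(x, ...) {
  cat(sprintf(
    "<sv_verification> %d/%d observed breakpoints explained (%.1f%%), %d new\n",
    x$explained_count, x$observed_count, 100 * x$explained_fraction,
    x$new_count))
  cat(sprintf("  events: %d inversions, %d deletions, %d tandem duplications\n",
              x$tallies[["inversions"]], x$tallies[["deletions"]],
              x$tallies[["tandem_duplications"]]))
  invisible(x)
}
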