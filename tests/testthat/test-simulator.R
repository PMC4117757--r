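test_that("breakpoint orientations determine the realizing operation class", {
  expect_equal(classify_operation(breakpoints(10, "tail", 40, "head")),
               "deletion")
  expect_equal(classify_operation(breakpoints(60, "head", 80, "tail")),
               "tandem_duplication")
  expect_equal(classify_operation(breakpoints(30, "tail", 50, "tail")),
               "inversion")
  expect_equal(classify_operation(breakpoints(20, "head", 70, "head")),
               "inversion")
})

test_that("find_realizations enumerates exactly the events that create the junction", {
  part <- didactic_partition()
  intact <- intact_chromosome(part)

  ## the worked example: duplicating g and h realizes (60,h)-(80,t)
  bp <- breakpoints(60, "head", 80, "tail")
  evs <- find_realizations(intact, bp)
  expect_true(any(vapply(evs, function(e)
    e$kind == "tandem_duplication" && e$from == 7 && e$to == 8, logical(1))))

  ## empty arrangement: nothing is realizable
  expect_length(find_realizations(arrangement(integer(), part), bp), 0)

  ## deletion case on a 3-copy arrangement; cross-check against brute force
  part3 <- segment_partition(40, c(10, 30))
  abc <- intact_chromosome(part3)
  bp_del <- breakpoints(10, "tail", 30, "head")
  evs <- find_realizations(abc, bp_del)
  expect_true(any(vapply(evs, function(e)
    e$kind == "deletion" && e$from == 2 && e$to == 2, logical(1))))

  ## brute-force oracle on the intact chromosome, where no junction
  ## pre-exists: an event realizes the breakpoint iff the junction appears
  ## after applying it, so enumeration and brute force must agree exactly
  brute <- function(arr, bp) {
    hits <- character()
    key <- shattersim:::breakpoint_keys(bp)
    len <- length(arr$copies)
    for (kind in c("inversion", "deletion", "tandem_duplication"))
      for (i in seq_len(len)) for (j in i:len) {
        if (kind == "deletion" && j - i + 1L == len) next
        out <- apply_event(arr, rearrangement_event(kind, i, j))
        if (key %in% shattersim:::breakpoint_keys(extract_adjacencies(out)))
          hits <- c(hits, paste(kind, i, j))
      }
    hits
  }
  for (seed in 1:5) {
    arr <- random_arrangement(seed, n_segments = 8, n_events = 4)
    adj <- extract_adjacencies(arr)
    if (nrow(adj) == 0) next
    bp1 <- adj[1, ]
    intact <- intact_chromosome(arr$partition)
    found <- find_realizations(intact, bp1)
    keys_found <- vapply(found, function(e)
      paste(e$kind, e$from, e$to), character(1))
    expect_setequal(keys_found, brute(intact, bp1))
    expect_gt(length(keys_found), 0)
  }
})

test_that("progressive simulation realizes observed sets reproducibly", {
  tbl1 <- table1_breakpoints()
  cfg <- sim_config(seed = 11)
  tr <- simulate_progressive(tbl1, cfg, L = 100)

  ## determinism
  tr2 <- simulate_progressive(tbl1, cfg, L = 100)
  expect_identical(tr$snapshots, tr2$snapshots)
  expect_identical(tr$final$copies, tr2$final$copies)

  ## every realized observed breakpoint is in the final junction set unless
  ## flagged destroyed
  realized_keys <- shattersim:::breakpoint_keys(tbl1[tr$realized, ])
  final_keys <- shattersim:::breakpoint_keys(extract_adjacencies(tr$final))
  expect_true(all(setdiff(realized_keys, tr$destroyed) %in% final_keys))

  ## the single-breakpoint case: one tandem duplication, one junction,
  ## two strict states
  one <- breakpoints(60, "head", 80, "tail"); attr(one, "L") <- 100
  tr1 <- simulate_progressive(one, sim_config(seed = 3), L = 100)
  expect_equal(nrow(tr1$snapshots), 1)
  expect_equal(tr1$snapshots$event_kind, "tandem_duplication")
  expect_equal(count_breakpoints(tr1$final, "pes"), 1L)
  expect_equal(count_copy_states(copy_number_profile(tr1$final), "strict"), 2L)

  ## empty observed set
  tr0 <- simulate_progressive(breakpoints(numeric(), character(),
                                          numeric(), character()),
                              sim_config(seed = 1), L = 100)
  expect_equal(nrow(tr0$snapshots), 0)
})

test_that("snapshots honor the configured counting modes", {
  bp <- snu_c1_like(seed = 5, n_breakpoints = 40, L = 1e6, unit = 1e3,
                    max_gap = 50)
  for (mode in c("adjacency", "pes")) {
    cfg <- sim_config(counting_mode = mode, seed = 9)
    tr <- simulate_progressive(bp, cfg)
    ## recompute each snapshot is impossible without replay; check the final
    expect_equal(tr$snapshots$n_breakpoints[nrow(tr$snapshots)],
                 count_breakpoints(tr$final, mode))
  }
  ## pes <= adjacency snapshot-by-snapshot (paired seeds give identical
  ## trajectories, only the recorded counts differ)
  ta <- simulate_progressive(bp, sim_config(counting_mode = "adjacency", seed = 9))
  tp <- simulate_progressive(bp, sim_config(counting_mode = "pes", seed = 9))
  expect_identical(ta$snapshots$event_kind, tp$snapshots$event_kind)
  expect_true(all(tp$snapshots$n_breakpoints <= ta$snapshots$n_breakpoints))
})

test_that("inversions alone leave the profile flat while junctions accumulate", {
  part <- segment_partition(2000, seq(10, 1990, by = 10))
  tr <- simulate_free(60, c(1, 0, 0), part, seed = 21)
  expect_equal(copy_number_profile(tr$final)$counts, rep(1L, part$n))
  expect_equal(count_breakpoints(tr$final, "microarray"), 0L)
  expect_gt(count_breakpoints(tr$final, "adjacency"), 0L)

  ## a single forced duplication has the head-tail junction signature
  tr_dup <- simulate_free(1, c(0, 0, 1), part, seed = 2)
  adj <- extract_adjacencies(tr_dup$final)
  expect_equal(count_breakpoints(tr_dup$final, "pes"), 1L)
  expect_equal(classify_operation(adj[1, ]), "tandem_duplication")

  expect_error(simulate_free(5, c(0, 0, 0), part), "zero")
  tr0 <- simulate_free(0, c(1, 1, 1), part, seed = 1)
  expect_equal(tr0$final$copies, seq_len(part$n))
})

test_that("sweeps aggregate running snapshots into breakpoint bins", {
  tbl1 <- table1_breakpoints()
  sw <- sweep_replicates(tbl1, sim_config(seed = 2), n_replicates = 1, L = 100)
  expect_gte(nrow(sw$snapshots), 1)
  one <- simulate_progressive(tbl1, sim_config(seed = shattersim:::derive_seeds(2, 1)),
                              L = 100)
  expect_equal(sw$snapshots$n_breakpoints, one$snapshots$n_breakpoints)

  bp <- snu_c1_like(seed = 31, n_breakpoints = 60, L = 1e6, unit = 1e3,
                    max_gap = 100)
  cfg <- sim_config(counting_mode = "pes", state_mode = "relaxed",
                    relaxed_fraction = 0.95, seed = 5)
  sw <- sweep_replicates(bp, cfg, n_replicates = 30)
  expect_setequal(names(sw$bins),
                  c("n_breakpoints", "n_obs", "median_states", "lo99", "hi99"))
  expect_true(all(sw$bins$lo99 <= sw$bins$median_states))
  expect_true(all(sw$bins$hi99 >= sw$bins$median_states))
  ## medians rise with breakpoint count overall
  b <- sw$bins[sw$bins$n_obs >= 10, ]
  expect_gt(suppressWarnings(cor(b$n_breakpoints, b$median_states,
                                 method = "spearman")), 0)

  ## an all-inversion observed set keeps one strict state in every row
  inv_bp <- snu_c1_like(seed = 7, n_breakpoints = 30, L = 1e6, unit = 1e3,
                        max_gap = 50,
                        class_counts = c(hh = 15, tt = 15, ht = 0, th = 0))
  swi <- sweep_replicates(inv_bp, sim_config(seed = 3), n_replicates = 5)
  expect_true(all(swi$snapshots$n_states == 1))

  sve <- sweep_replicates(bp, cfg, n_replicates = 5, endpoints_only = TRUE)
  expect_equal(nrow(sve$snapshots), 5)
})

test_that("footprint classification applies both thresholds", {
  expect_true(classify_footprint(67, 3))
  expect_false(classify_footprint(49, 2))
  expect_true(classify_footprint(239, 2))
  expect_false(classify_footprint(239, 4))
  crit <- footprint_criteria(min_breakpoints = 100, max_states = 2)
  expect_false(classify_footprint(67, 2, crit))
  expect_true(classify_footprint(100, 2, crit))
})
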