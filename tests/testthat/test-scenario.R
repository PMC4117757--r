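test_that("the didactic breakpoint table yields a fully explaining scenario", {
  tbl1 <- table1_breakpoints()
  sc <- build_scenario(tbl1, seed = 1, L = 100)
  v <- verify_scenario(sc, tbl1)
  expect_equal(v$explained_fraction, 1)
  expect_gte(v$new_count, 0)
  expect_equal(sum(v$tallies), length(sc$events))
  ## deletions equal the number of isolated components (b, d, f, i)
  expect_equal(unname(v$tallies["deletions"]), 4)

  ## replay determinism
  sc2 <- build_scenario(tbl1, seed = 1, L = 100)
  expect_identical(replay_scenario(sc)$copies, replay_scenario(sc2)$copies)

  ## empty input: empty scenario, vacuously explained
  empty <- breakpoints(numeric(), character(), numeric(), character())
  sc0 <- build_scenario(empty, seed = 1, L = 100)
  expect_length(sc0$events, 0)
  v0 <- verify_scenario(sc0, empty)
  expect_equal(v0$explained_fraction, 1)
  expect_equal(v0$new_count, 0)
})

test_that("scenarios from ground-truth histories explain every breakpoint", {
  set.seed(71)
  n_dup_cycles <- 0
  for (i in 1:25) {
    ns <- sample(8:60, 1)
    ne <- sample(2:10, 1)
    h <- generate_history(history_spec(n_segments = ns, n_events = ne,
                                       span_range = c(1, max(2, ns %/% 6)),
                                       seed = 5000 + i))
    sc <- build_scenario(h$breakpoints, seed = i)
    v <- verify_scenario(sc, h$breakpoints)
    expect_equal(v$explained_fraction, 1,
                 info = sprintf("history %d (%d segments, %d events)", i, ns, ne))
    ## duplications at least cover the cycle components
    comps <- classify_components(build_graph(h$breakpoints))
    n_cycles <- sum(vapply(comps, `[[`, "", "kind") == "cycle")
    expect_gte(unname(v$tallies["tandem_duplications"]), n_cycles)
    n_dup_cycles <- n_dup_cycles + n_cycles
  }
  ## the batch exercised at least one duplication cycle
  expect_gt(n_dup_cycles, 0)
})

test_that("scenario events are annotated and replay failures are caught", {
  tbl1 <- table1_breakpoints()
  sc <- build_scenario(tbl1, seed = 5, L = 100)
  phases <- vapply(sc$events, `[[`, "", "phase")
  expect_true(all(phases %in% c("inversion_sort", "deletion", "duplication")))
  created <- unlist(lapply(sc$events, `[[`, "creates"))
  ## every observed junction is created by some event
  expect_setequal(intersect(created, shattersim:::breakpoint_keys(tbl1)),
                  shattersim:::breakpoint_keys(tbl1))

  ## corrupt a span: replay reports the failing event index
  sc$events[[1]]$to <- 10000L
  expect_error(replay_scenario(sc), "event 1")
})
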