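test_that("histories are reproducible and respect their spec", {
  spec <- history_spec(n_segments = 15, n_events = 5, seed = 3)
  h1 <- generate_history(spec)
  h2 <- generate_history(spec)
  expect_identical(h1$arrangement$copies, h2$arrangement$copies)
  expect_identical(as.data.frame(h1$breakpoints), as.data.frame(h2$breakpoints))

  ## zero events: intact chromosome, empty breakpoint set
  h0 <- generate_history(history_spec(n_segments = 10, n_events = 0, seed = 1))
  expect_equal(h0$arrangement$copies, 1:10)
  expect_equal(nrow(h0$breakpoints), 0)

  ## inversions only: single copy state throughout; a lone inversion leaves
  ## only head-head/tail-tail junctions (adjacent inversions can compound
  ## into head-tail signatures, so the class claim holds per event only)
  hi <- generate_history(history_spec(n_segments = 30, n_events = 8,
                                      type_mix = c(1, 0, 0), seed = 2))
  expect_equal(unique(copy_number_profile(hi$arrangement)$counts), 1L)
  h1 <- generate_history(history_spec(n_segments = 30, n_events = 1,
                                      type_mix = c(1, 0, 0), seed = 2))
  expect_true(all(classify_operation(h1$breakpoints) == "inversion"))

  ## inversion+deletion regime: states confined to {0, 1}
  hd <- generate_history(history_spec(n_segments = 200, n_events = 40,
                                      type_mix = c(1, 1, 0),
                                      span_range = c(1, 8), seed = 4))
  expect_true(all(copy_number_profile(hd$arrangement)$counts %in% c(0L, 1L)))

  ## generated sets always build a valid graph
  for (i in 1:10) {
    h <- generate_history(history_spec(n_segments = 25, n_events = 6,
                                       seed = 100 + i))
    expect_silent(build_graph(h$breakpoints))
  }
})

test_that("the ground-truth scenario replays to the emitted arrangement", {
  for (i in 1:5) {
    h <- generate_history(history_spec(n_segments = 20, n_events = 6,
                                       seed = 300 + i))
    expect_identical(replay_scenario(h$scenario)$copies,
                     h$arrangement$copies)
  }
})

test_that("chromosome-scale synthetic breakpoint sets are well formed", {
  bp <- snu_c1_like(seed = 1)
  expect_equal(nrow(bp), 239)
  cls <- table(classify_operation(bp))
  expect_equal(unname(cls[["inversion"]]), 120)        # hh + tt
  expect_equal(unname(cls[["tandem_duplication"]]), 60)
  expect_equal(unname(cls[["deletion"]]), 59)

  ## canonical and node-disjoint: all positions distinct
  expect_true(all(bp$pos_low <= bp$pos_high))
  expect_false(any(duplicated(c(bp$pos_low, bp$pos_high))))
  expect_silent(build_graph(bp))

  ## different seeds: different sets, identical size and class mix
  bp2 <- snu_c1_like(seed = 2)
  expect_false(identical(as.data.frame(bp), as.data.frame(bp2)))
  expect_equal(table(classify_operation(bp2)), cls)

  ## custom class mix
  bpc <- snu_c1_like(seed = 3, n_breakpoints = 20,
                     class_counts = c(hh = 20, tt = 0, ht = 0, th = 0),
                     L = 1e6, unit = 1e3, max_gap = 30)
  expect_true(all(bpc$terminus_low == "head" & bpc$terminus_high == "head"))
})
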