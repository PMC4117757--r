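test_that("the three operators have exact copy semantics", {
  part <- didactic_partition()
  intact <- intact_chromosome(part)

  dup <- apply_event(intact, rearrangement_event("tandem_duplication", 7, 8))
  expect_equal(format_arrangement(dup), "a b c d e f g h g h i j")

  ## single-copy inversion flips orientation and nothing else
  inv1 <- apply_event(intact, rearrangement_event("inversion", 4, 4))
  expect_equal(inv1$copies, c(1:3, -4L, 5:10))
  expect_equal(copy_number_profile(inv1)$counts, rep(1L, 10))

  ## the worked mid-history inversion: profile is exactly preserved
  mid <- arrangement("a b c d e f g h g c d e f g h g h i j", part)
  inv <- apply_event(mid, rearrangement_event("inversion", 6, 10))
  expect_equal(format_arrangement(inv),
               "a b c d e -c -g -h -g -f d e f g h g h i j")
  expect_equal(copy_number_profile(inv)$counts,
               copy_number_profile(mid)$counts)

  del <- apply_event(intact, rearrangement_event("deletion", 2, 2))
  expect_equal(del$copies, c(1L, 3:10))

  expect_error(apply_event(intact, rearrangement_event("deletion", 5, 11)),
               "out of bounds")
  empty <- arrangement(integer(), part)
  expect_error(apply_event(empty, rearrangement_event("inversion", 1, 1)),
               "out of bounds")
})

test_that("copy-number profiles count multiplicity regardless of orientation", {
  part <- didactic_partition()
  expect_equal(copy_number_profile(intact_chromosome(part))$counts, rep(1L, 10))
  expect_equal(copy_number_profile(figure2_arrangement())$counts,
               c(1L, 0L, 1L, 1L, 2L, 2L, 4L, 3L, 1L, 1L))
  expect_equal(collapse_profile(copy_number_profile(figure2_arrangement()))$value,
               c(1, 0, 1, 2, 4, 3, 1))
  expect_equal(copy_number_profile(table1_arrangement())$counts,
               c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L))
})

test_that("inversions preserve profiles and duplications/deletions shift them", {
  for (seed in 1:20) {
    arr <- random_arrangement(seed)
    len <- length(arr$copies)
    if (len < 2) next
    set.seed(seed)
    from <- sample.int(len - 1L, 1L)
    to <- from + sample.int(len - from, 1L)
    before <- copy_number_profile(arr)$counts

    inv <- apply_event(arr, rearrangement_event("inversion", from, to))
    expect_identical(copy_number_profile(inv)$counts, before)

    span_mult <- tabulate(abs(arr$copies[from:to]), nbins = arr$partition$n)
    dup <- apply_event(arr, rearrangement_event("tandem_duplication", from, to))
    expect_identical(copy_number_profile(dup)$counts, before + span_mult)
    del <- apply_event(arr, rearrangement_event("deletion", from, to))
    expect_identical(copy_number_profile(del)$counts, before - span_mult)
    expect_true(all(copy_number_profile(del)$counts >= 0L))
  }
})

test_that("abnormal adjacencies are extracted in order with multiplicity", {
  expect_equal(nrow(extract_adjacencies(intact_chromosome(didactic_partition()))), 0)

  adj <- extract_adjacencies(figure2_arrangement())
  expect_equal(nrow(adj), 8)

  ## simple duplication: only the seam junction is abnormal
  part <- didactic_partition()
  abb <- arrangement(c(1, 2, 2, 3), part)
  adj2 <- extract_adjacencies(abb)
  expect_equal(nrow(adj2), 1)
  expect_equal(adj2$pos_low, 10)
  expect_equal(adj2$terminus_low, "head")
  expect_equal(adj2$pos_high, 20)
  expect_equal(adj2$terminus_high, "tail")
})

test_that("junctions map to the canonical breakpoint table rows", {
  part <- didactic_partition()
  expect_equal(as.data.frame(junction_to_breakpoint(1, 5, part)),
               data.frame(pos_low = 10, terminus_low = "tail",
                          pos_high = 40, terminus_high = "head"))
  expect_equal(as.data.frame(junction_to_breakpoint(5, -3, part)),
               data.frame(pos_low = 30, terminus_low = "tail",
                          pos_high = 50, terminus_high = "tail"))
  expect_equal(as.data.frame(junction_to_breakpoint(8, 7, part)),
               data.frame(pos_low = 60, terminus_low = "head",
                          pos_high = 80, terminus_high = "tail"))
  expect_error(junction_to_breakpoint(3, 4, part), "normal")

  ## the five-breakpoint arrangement reproduces the full table
  expect_equal(bp_df(extract_adjacencies(table1_arrangement())),
               bp_df(table1_breakpoints()))
})

test_that("the three breakpoint-counting modes are distinct but ordered", {
  arr <- figure2_arrangement()
  expect_equal(count_breakpoints(arr, "adjacency"), 8L)
  expect_equal(count_breakpoints(arr, "pes"), 7L)
  expect_equal(count_breakpoints(arr, "microarray"), 6L)
  expect_error(count_breakpoints(arr, "bogus"))

  for (seed in 1:25) {
    arr <- random_arrangement(seed)
    pes <- count_breakpoints(arr, "pes")
    adjc <- count_breakpoints(arr, "adjacency")
    expect_lte(pes, adjc)
    ## microarray = sign changes of the per-segment difference sequence
    counts <- copy_number_profile(arr)$counts
    expect_equal(count_breakpoints(arr, "microarray"), sum(diff(counts) != 0))
  }
})

test_that("strict and relaxed copy-state counting match the worked example", {
  prof <- copy_number_profile(figure2_arrangement())
  expect_equal(count_copy_states(prof, "strict"), 5L)
  expect_equal(count_copy_states(prof, "relaxed", fraction = 0.90), 4L)
  expect_error(count_copy_states(prof, "relaxed", fraction = 0), "fraction")
  expect_error(count_copy_states(prof, "relaxed", fraction = 1.2), "fraction")

  for (seed in 1:15) {
    prof <- copy_number_profile(random_arrangement(seed))
    strict <- count_copy_states(prof, "strict")
    expect_equal(count_copy_states(prof, "relaxed", fraction = 1), strict)
    ## relaxed count is non-increasing as the fraction shrinks
    fr <- c(1, 0.99, 0.95, 0.9, 0.75, 0.5, 0.25)
    ks <- vapply(fr, function(f) count_copy_states(prof, "relaxed", f),
                 integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("arrangement text formats round-trip", {
  expect_equal(parse_arrangement("1 5 -3 -7 -8 10"), c(1L, 5L, -3L, -7L, -8L, 10L))
  expect_equal(parse_arrangement("a e -c -g -h j"), c(1L, 5L, -3L, -7L, -8L, 10L))
  expect_equal(parse_arrangement("ae(-c)(-g)(-h)j"), c(1L, 5L, -3L, -7L, -8L, 10L))
  expect_error(parse_arrangement("a ? b"), "cannot parse")
  arr <- table1_arrangement()
  expect_equal(parse_arrangement(format_arrangement(arr)), arr$copies)
  expect_equal(parse_arrangement(format_arrangement(arr, letters_ok = FALSE)),
               arr$copies)
})

test_that("partitions validate their boundaries", {
  expect_error(segment_partition(100, c(10, 10)), "increasing")
  expect_error(segment_partition(100, c(0, 50)), "inside")
  expect_error(segment_partition(100, 100), "inside")
  p <- segment_partition(100)
  expect_equal(p$n, 1L)
  expect_equal(segment_lengths(p), 100)
  expect_equal(sum(segment_lengths(didactic_partition())), 100)
})
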