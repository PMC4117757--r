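test_that("reversal distances match the exhaustive oracle for tiny sizes", {
  for (m in 1:4) {
    oracle <- bfs_reversal_oracle(m)
    perms <- all_signed_perms(m)
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      expect_equal(reversal_distance(p)$d, oracle$lookup(p),
                   info = paste("perm", paste(p, collapse = ",")))
    }
  }
})

test_that("reversal_sort emits minimal sequences that replay to the target", {
  expect_length(reversal_sort(1:5), 0)
  expect_length(reversal_sort(-(5:1)), 1)     # one whole-chromosome flip
  expect_length(reversal_sort(c(2L, 1L)), 3)  # the classic hurdle pair

  ## distance formula ingredients are exposed
  d21 <- reversal_distance(c(2, 1))
  expect_equal(d21$b, 3)
  expect_equal(d21$h, 1)
  expect_equal(d21$d, 3)
  expect_lte(d21$lower_bound, d21$d)

  expect_error(reversal_sort(c(1, 1, 2)), "exactly once")

  ## random targets up to m = 50: the plan replays exactly and never beats
  ## the cycle lower bound
  set.seed(404)
  for (i in 1:15) {
    m <- sample(5:50, 1)
    p <- sample(m) * sample(c(-1L, 1L), m, replace = TRUE)
    ev <- reversal_sort(p)
    expect_identical(replay_inversions(ev, m), as.integer(p))
    expect_equal(length(ev), attr(ev, "distance"))
    expect_gte(length(ev), attr(ev, "lower_bound"))
  }
})
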