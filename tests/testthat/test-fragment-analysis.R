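let7a <- "TGAGGTAGTAGGTTGTATAGTT"

test_that("known one-directional fragments align without folds", {
  p2 <- find_transition_points("AGGTAGTAGGT", let7a)
  expect_equal(p2$start_position, 3)
  expect_length(p2$fold_points, 0)
  expect_equal(p2$identity, 1)
  expect_true(all(diff(p2$positions) == 1))

  p4 <- find_transition_points("TAGTAGGTTG", let7a)
  expect_equal(p4$start_position, 6)
  expect_length(p4$fold_points, 0)
  expect_equal(p4$identity, 1)
})

test_that("a constructed reversal yields exactly one fold point", {
  # read forward to the end, then re-read the last three bases backward
  fwd <- strsplit(let7a, "")[[1]][10:22]
  frag <- paste(c(fwd, rev(fwd)[2:4]), collapse = "")
  p <- find_transition_points(frag, let7a)
  expect_equal(p$identity, 1)
  expect_length(p$fold_points, 1)
  # the fold point is the extremum letter, after which reading reverses
  expect_equal(p$fold_points, length(fwd))
})

test_that("the walk DP equals exhaustive enumeration on small cases", {
  ref <- strsplit(let7a, "")[[1]]
  for (seed in 1:30) {
    frag <- tunnelcall:::with_local_seed(seed, {
      sample(c("T", "A", "G"), sample(2:8, 1), replace = TRUE)
    })
    got <- find_transition_points(paste(frag, collapse = ""), let7a)
    want <- brute_walk_align(frag, ref)
    expect_equal(sum(frag == ref[got$positions]), want$score)
    expect_equal(length(got$fold_points), want$folds)
  }
})

test_that("unalignable fragments are flagged below the identity floor", {
  p <- find_transition_points("AAAAAAAA", "TGTGTGTGTG")
  expect_false(p$alignable)
})

test_that("unfolding removes mirrored spans and is idempotent", {
  u <- unfold_palindrome("TGAGGGAGT")
  expect_equal(u$seq, "TGAGG")
  expect_true(u$unfolded)
  # no mirrored span: unchanged
  expect_equal(unfold_palindrome("TGAGG")$seq, "TGAGG")
  # idempotence over random folded reads
  tm <- translocation_model(reversal_prob = 0.3)
  seqs <- tunnelcall:::with_local_seed(8, {
    vapply(1:300, function(i) {
      p <- tunnelcall:::sim_path_impl(let7a, tm)
      paste(tunnelcall:::path_letters(p), collapse = "")
    }, character(1))
  })
  for (s in seqs) {
    once <- unfold_palindrome(s)
    twice <- unfold_palindrome(once)
    expect_identical(twice$seq, once$seq)
    expect_lte(nchar(once$seq), nchar(s))
  }
})

test_that("most folded reads unfold to a contiguous read of the source", {
  tm <- translocation_model(reversal_prob = 0.3)
  ok <- tunnelcall:::with_local_seed(9, {
    vapply(1:2000, function(i) {
      p <- tunnelcall:::sim_path_impl(let7a, tm)
      s <- paste(tunnelcall:::path_letters(p), collapse = "")
      is_contiguous_read(unfold_palindrome(s)$seq, let7a)
    }, logical(1))
  })
  expect_gte(mean(ok), 0.70)
})

test_that("velocity pooling reproduces exact and mixed slope inputs", {
  mk <- function(v, se) {
    structure(list(velocity = v, velocity_se = se, alignable = TRUE),
              class = "transition_profile")
  }
  same <- lapply(1:6, function(i) mk(1.5, 0.05))
  est <- estimate_velocity(same, seed = 1)
  expect_equal(est$velocity, 1.5)
  expect_equal(unname(diff(est$ci)), 0)
  mixed <- c(lapply(1:5, function(i) mk(1, 0.1)), lapply(1:5, function(i) mk(2, 0.1)))
  est2 <- estimate_velocity(mixed, seed = 1)
  expect_equal(est2$velocity, 1.5)
  expect_error(estimate_velocity(same[1:3], seed = 1),
               class = "tunnelcall_insufficient_data")
})

test_that("read lengths come from distinct walk positions with QC filters", {
  run <- shared_run()
  rl <- read_length_histogram(run$frags, let7a)
  expect_true(all(rl$lengths >= 1))
  expect_equal(sum(rl$histogram$count), length(rl$lengths))
  # the distribution support is dominated by the 12-base admission limit
  expect_gte(mean(rl$lengths <= 12), 0.999)
})
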