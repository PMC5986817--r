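test_that("moving-average baseline matches the brute-force oracle", {
  expect_equal(estimate_baseline(rep(3.5, 50), window = 10), rep(3.5, 50))
  x <- tunnelcall:::with_local_seed(1, rnorm(500, 10, 2))
  expect_equal(estimate_baseline(x, window = 40), brute_moving_average(x, 40))
  # step trace: transition confined to one window width around the step
  step <- c(rep(0, 300), rep(100, 300))
  b <- estimate_baseline(step, window = 100)
  expect_equal(b, brute_moving_average(step, 100))
  expect_true(all(b[1:250] == 0))
  expect_true(all(b[351:600] == 100))
  expect_error(estimate_baseline(x, window = 0), class = "tunnelcall_input_error")
})

test_that("baseline error on pure noise is bounded by the standard error", {
  s <- 4
  x <- tunnelcall:::with_local_seed(2, rnorm(20000, 0, s))
  b <- estimate_baseline(x, window = 2000)
  expect_lt(max(abs(b - 0)), 5 * s / sqrt(2000))
})

test_that("per-second sigma is recovered from Gaussian noise", {
  x <- tunnelcall:::with_local_seed(3, rnorm(100000, 0, 4))
  ns <- estimate_sigma(x, baseline = rep(0, length(x)))
  expect_length(ns$sigma, 10)
  expect_true(all(ns$sigma > 3.2 & ns$sigma < 4.8))
})

test_that("the sigma mode is robust to rare tall spikes", {
  x <- tunnelcall:::with_local_seed(4, rnorm(50000, 0, 4))
  clean <- estimate_sigma(x, rep(0, length(x)))
  spiked <- x
  # contaminate < 2% of the 20-sample windows with a tall excursion
  spike_at <- seq(1, length(x), by = 1100)
  spiked[spike_at] <- spiked[spike_at] + 300
  dirty <- estimate_sigma(spiked, rep(0, length(x)))
  expect_true(all(abs(dirty$sigma - clean$sigma) / clean$sigma < 0.10))
})

test_that("degenerate constant traces are rejected downstream", {
  x <- rep(5, 20000)
  b <- estimate_baseline(x)
  ns <- estimate_sigma(x, b)
  expect_true(all(ns$sigma == 0))
  expect_error(detect_signals(x, b, ns), class = "tunnelcall_input_error")
})

test_that("a noise-free event is detected with exact boundaries", {
  x <- rep(0, 3000)
  x[1001:1010] <- 102 # 1 ms at the guanine level
  ns <- structure(list(sigma = 4, block_size = 10000L, subwindow = 20L,
                       window_sds = list()), class = "noise_estimate")
  segs <- detect_signals(x, baseline = rep(0, 3000), noise = ns)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$start, 1001)
  expect_equal(segs[[1]]$end, 1011) # half-open
  expect_equal(segs[[1]]$sigma, 4)
  # shorter than the 0.5-ms minimum retention: discarded
  x2 <- rep(0, 3000)
  x2[1001:1004] <- 102
  expect_length(detect_signals(x2, rep(0, 3000), ns), 0)
})

test_that("pure baseline noise yields no signal segments", {
  tr <- render_trace(list(), conductance_model(), seed = 6)
  # no paths: single exponential gap of baseline
  x <- tunnelcall:::with_local_seed(6, rnorm(100000, 0, 4))
  det <- detect_pipeline(x)
  expect_length(det$segments, 0)
})

test_that("detection recalls annotated events with few spurious calls", {
  tr <- simulate_mixture(let7_sequences()["let7a"], n_events = 100, seed = 31)
  det <- detect_pipeline(tr)
  ev <- tr$events
  hit <- vapply(seq_len(nrow(ev)), function(i) {
    any(vapply(det$segments, function(s) s$start < ev$end[i] && s$end > ev$start[i],
               logical(1)))
  }, logical(1))
  expect_gte(sum(hit), 95)
  spurious <- sum(vapply(det$segments, function(s) {
    !any(ev$start < s$end & ev$end > s$start)
  }, logical(1)))
  expect_lte(spurious, 2)
})

test_that("the detection automaton equals the brute-force oracle", {
  ns <- structure(list(sigma = 4, block_size = 10000L, subwindow = 20L,
                       window_sds = list()), class = "noise_estimate")
  for (seed in 1:25) {
    x <- tunnelcall:::with_local_seed(seed, {
      x <- rnorm(200, 0, 4)
      # drop in a couple of random rectangular events
      for (k in 1:2) {
        at <- sample(20:150, 1)
        len <- sample(3:12, 1)
        x[at:(at + len)] <- x[at:(at + len)] + sample(c(45, 77, 102), 1)
      }
      x
    })
    got <- detect_signals(x, rep(0, length(x)), ns)
    want <- brute_hysteresis(x, 4)
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$start, want[[i]]$start)
      expect_equal(got[[i]]$end, want[[i]]$end)
    }
  }
})

test_that("raising the rise threshold never increases the segment count", {
  tr <- simulate_mixture(let7_sequences()["let7a"], n_events = 50, seed = 17)
  b <- estimate_baseline(tr)
  ns <- estimate_sigma(tr, b)
  n6 <- length(detect_signals(tr, b, ns, rise_mult = 6))
  n7 <- length(detect_signals(tr, b, ns, rise_mult = 7))
  expect_lte(n7, n6)
})

test_that("segments are disjoint, sorted, and satisfy the hysteresis rule", {
  tr <- simulate_mixture(let7_sequences()["let7a"], n_events = 80, seed = 23)
  det <- detect_pipeline(tr)
  starts <- vapply(det$segments, `[[`, numeric(1), "start")
  ends <- vapply(det$segments, `[[`, numeric(1), "end")
  expect_true(all(ends > starts))
  expect_true(all(starts[-1] >= ends[-length(ends)]))
  for (s in det$segments) {
    expect_gt(max(s$corrected), 6 * s$sigma)
    expect_true(all(s$corrected > s$sigma) || max(s$corrected) > 6 * s$sigma)
  }
})
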