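test_that("minimum-retention smoothing removes sub-retention spikes", {
  plateau <- rep(77, 20)
  spiked <- plateau
  spiked[10] <- 300
  sm <- smooth_segment(spiked)
  expect_equal(sm, plateau)
  # brute-force running-median oracle on random inputs
  for (seed in 1:10) {
    x <- tunnelcall:::with_local_seed(seed, rnorm(60, 50, 20))
    expect_equal(smooth_segment(x), brute_runmed(x, 5))
  }
  # an already-smooth ramp is unchanged except near the edges
  ramp <- seq(10, 100, length.out = 40)
  sm2 <- smooth_segment(ramp)
  expect_equal(sm2[3:38], ramp[3:38])
})

test_that("alternating sub-retention bursts cannot retain their levels", {
  x <- rep(c(45, 45, 102, 102), 10)
  sm <- smooth_segment(x)
  interior <- sm[3:(length(sm) - 2)]
  # medians over 5 samples mix the two levels: no full-level plateau of 5+
  r <- rle(interior)
  expect_true(all(r$lengths[r$values %in% c(45, 102)] < 5))
})

test_that("the histogram mixture fit recovers known components", {
  # two sharp, well-separated peaks with a single base component
  segs <- tunnelcall:::with_local_seed(5, {
    lapply(1:40, function(i) rnorm(50, sample(c(0.5, 80), 1, prob = c(0.3, 0.7)), 1.5))
  })
  fit1 <- fit_conductance_model(segs, n_bases = 1, alphabet = "G", min_samples = 500)
  expect_lt(abs(fit1$means[["G"]] - 80), 1)
  # three components with known weights
  segs3 <- tunnelcall:::with_local_seed(6, {
    lapply(1:200, function(i) {
      mu <- sample(c(45, 77, 102), 1, prob = c(0.2, 0.3, 0.5))
      rnorm(60, mu, 5)
    })
  })
  fit3 <- fit_conductance_model(segs3, min_samples = 1000)
  expect_lt(max(abs(fit3$means - c(45, 77, 102)) / c(45, 77, 102)), 0.05)
  w <- fit3$weights / sum(fit3$weights)
  expect_lt(max(abs(w - c(0.2, 0.3, 0.5))), 0.10 * 0.5 + 0.03)
  expect_error(fit_conductance_model(segs3[1:2], min_samples = 1e6),
               class = "tunnelcall_insufficient_data")
})

test_that("least-squares peak means agree with an EM mixture fit", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  run <- shared_run()
  pooled <- unlist(lapply(run$det$segments, smooth_segment))
  em <- mclust::Mclust(pooled, G = 4, modelNames = "V", verbose = FALSE)
  em_means <- sort(em$parameters$mean)
  ls_means <- unname(run$fit$means)
  # each least-squares base peak has an EM component within 2%
  for (m in ls_means) {
    expect_lt(min(abs(em_means - m)) / m, 0.02)
  }
})

test_that("interval calls integrate the densities and flag ties", {
  cm <- conductance_model()
  calls <- call_intervals(rep(102, 5), cm, smooth = FALSE)
  expect_equal(calls$label, "G")
  expect_gt(calls$posterior, 0.99)
  post <- attr(calls, "posteriors")
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  # equidistant between T (45) and A (77) with equal sds: tie toward T, flagged
  cm2 <- conductance_model(means = c(T = 45, A = 77, G = 102), sds = 8)
  calls2 <- call_intervals(rep(61, 5), cm2, smooth = FALSE)
  p2 <- attr(calls2, "posteriors")
  expect_lt(abs(p2[1, "T"] - p2[1, "A"]), 1e-6)
  expect_equal(calls2$label, "T")
  expect_true(calls2$low_conf)
})

test_that("run splitting turns call runs into dwell-aware letters", {
  cm <- conductance_model()
  mk_calls <- function(labels, durs) {
    structure(
      data.frame(start_ms = c(0, cumsum(durs))[seq_along(durs)],
                 duration_ms = durs, label = labels,
                 posterior = rep(0.95, length(labels)),
                 mean_cond = ifelse(labels == "G", 102, ifelse(labels == "A", 77, 45)),
                 low_conf = FALSE, stringsAsFactors = FALSE),
      class = c("interval_calls", "data.frame")
    )
  }
  # 1.0-ms G run rounds to one letter...
  f1 <- calls_to_fragment(mk_calls(c("G", "G", "A"), c(0.5, 0.5, 0.5)), cm)
  expect_equal(f1$seq, "GA")
  # ...and a 1.34-ms run to two
  f2 <- calls_to_fragment(mk_calls(c("G", "G", "G", "A"), c(0.5, 0.5, 0.34, 0.5)), cm)
  expect_equal(f2$seq, "GGA")
  f3 <- calls_to_fragment(mk_calls("T", 0.5), cm)
  expect_equal(f3$seq, "T")
  expect_true(all(diff(f2$times_ms) > 0))
  expect_null(calls_to_fragment(mk_calls(c("baseline", "baseline"), c(0.5, 0.5)), cm))
})

test_that("called fragments mostly read the true path contiguously", {
  run <- shared_run()
  tr <- run$trace
  seg_id <- vapply(run$frags, function(f) f$segment_id, integer(1))
  seg2ev <- vapply(run$det$segments, function(s) {
    h <- which(tr$events$start < s$end & tr$events$end > s$start)
    if (length(h) == 1) h else NA_integer_
  }, integer(1))
  ok <- vapply(seq_along(run$frags), function(i) {
    ei <- seg2ev[seg_id[i]]
    if (is.na(ei)) return(NA)
    pl <- paste(tunnelcall:::path_letters(tr$paths[[ei]]), collapse = "")
    u <- unfold_palindrome(run$frags[[i]])
    is_contiguous_read(u$seq, pl)
  }, logical(1))
  expect_gte(mean(ok, na.rm = TRUE), 0.80)
})
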