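# Signal detection: moving-average baseline, per-second robust sigma via the
# mode of 20-sample window standard deviations, and 6-sigma-rise/1-sigma-fall
# hysteresis extraction of signal segments.

#' Moving-average baseline of a trace
#'
#' Centred moving average over `window` samples (default 2000, i.e. 200 ms
#' at 10 kHz) with symmetric edge shrinkage: near the edges the window is
#' truncated, never padded.
#'
#' @param trace A `tc_trace` or a numeric vector of conductance samples.
#' @param window Window length in samples (>= 1).
#' @return Numeric vector of per-sample baseline values.
#' @examples
#' estimate_baseline(rep(3, 10), window = 4)
#' @export
estimate_baseline <- function(trace, window = 2000) {
  x <- if (inherits(trace, "tc_trace")) trace$samples else as.numeric(trace)
  if (length(x) < 1L) tc_input_error("trace must contain at least one sample")
  if (window < 1) tc_input_error("window must be >= 1")
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(1L, i - floor((window - 1) / 2))
  hi <- pmin(n, i + floor(window / 2))
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Mode of a continuous sample by histogram: Freedman-Diaconis bin width,
# midpoint of the most populated bin, ties broken toward the smaller value.
fd_mode <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(v[1L])
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  if (bw <= 0) {
    # Degenerate IQR: fall back to the most frequent exact value.
    tab <- table(v)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  breaks <- seq(rng[1L], rng[2L] + bw, by = bw)
  bin <- findInterval(v, breaks, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  k <- which.max(counts) # first maximum = smaller sigma on ties
  (breaks[k] + breaks[k + 1L]) / 2
}

#' Robust per-second noise estimate
#'
#' Partitions the baseline-corrected trace into consecutive one-second
#' blocks (10,000 samples at 10 kHz), computes the sample standard deviation
#' of each disjoint 20-sample window (500 per full block), and takes the
#' most frequent value — the midpoint of the most populated
#' Freedman-Diaconis histogram bin, ties toward the smaller value — as that
#' second's sigma. A trailing partial block uses as many whole 20-sample
#' windows as fit; a block shorter than one window inherits the previous
#' block's sigma.
#'
#' @param trace A `tc_trace` or numeric vector.
#' @param baseline Per-sample baseline (as from [estimate_baseline()]).
#' @param sample_rate Samples per second (block size).
#' @param subwindow Window length for the standard-deviation set.
#' @return An object of class `noise_estimate`: `$sigma` (one value per
#'   block, pS), `$block_size`, and the per-block window standard deviations
#'   in `$window_sds` (diagnostics).
#' @export
estimate_sigma <- function(trace, baseline, sample_rate = 10000, subwindow = 20) {
  x <- if (inherits(trace, "tc_trace")) trace$samples else as.numeric(trace)
  corrected <- x - baseline
  n <- length(corrected)
  n_blocks <- ceiling(n / sample_rate)
  sigma <- numeric(n_blocks)
  window_sds <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    from <- (b - 1L) * sample_rate + 1L
    to <- min(n, b * sample_rate)
    m <- (to - from + 1L) %/% subwindow
    if (m < 1L) {
      if (b == 1L) tc_insufficient("first block has fewer than %d samples; cannot estimate sigma", subwindow)
      sigma[b] <- sigma[b - 1L]
      window_sds[[b]] <- numeric(0)
      next
    }
    seg <- corrected[from:(from + m * subwindow - 1L)]
    sds <- col_sds(matrix(seg, nrow = subwindow))
    window_sds[[b]] <- sds
    sigma[b] <- fd_mode(sds)
  }
  structure(
    list(sigma = sigma, block_size = as.integer(sample_rate),
         subwindow = as.integer(subwindow), window_sds = window_sds),
    class = "noise_estimate"
  )
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("Noise estimate: %d one-second block(s), sigma %s pS\n",
              length(x$sigma),
              paste(sprintf("%.2f", utils::head(x$sigma, 8)), collapse = ", ")))
  invisible(x)
}

#' Extract signal segments by 6-sigma/1-sigma hysteresis
#'
#' A segment is triggered at a sample whose baseline-corrected value exceeds
#' `rise_mult` (6) times sigma; it extends backward to just after the most
#' recent sample at or below `fall_mult` (1) sigma and forward to just
#' before the first sample below it, so segment indices are half-open
#' `[start, end)` and every in-segment sample lies above the fall threshold.
#' Overlapping candidates are merged; each segment carries the sigma of the
#' second containing its trigger; segments shorter than the minimum
#' retention time (0.5 ms) are discarded.
#'
#' @param trace A `tc_trace` or numeric vector.
#' @param baseline Per-sample baseline.
#' @param noise A `noise_estimate`; every block sigma must be > 0.
#' @param rise_mult,fall_mult Hysteresis thresholds in units of sigma.
#' @param min_duration_ms Minimum retention time (segments shorter than this
#'   are discarded).
#' @param sample_rate Samples per second.
#' @return Object of class `signal_segments`: a list of segments, each with
#'   `start`, `end` (half-open sample indices), `sigma`, `baseline_local`
#'   and the baseline-corrected `corrected` samples.
#' @export
detect_signals <- function(trace, baseline, noise,
                           rise_mult = 6, fall_mult = 1,
                           min_duration_ms = 0.5, sample_rate = 10000) {
  x <- if (inherits(trace, "tc_trace")) trace$samples else as.numeric(trace)
  if (any(noise$sigma <= 0)) {
    tc_input_error("noise estimate has non-positive sigma in %d block(s); cannot detect signals",
                   sum(noise$sigma <= 0))
  }
  corrected <- x - baseline
  n <- length(corrected)
  sig_of <- function(i) noise$sigma[min(length(noise$sigma), ((i - 1L) %/% noise$block_size) + 1L)]
  sigma_per_sample <- noise$sigma[pmin(length(noise$sigma),
                                       ((seq_len(n) - 1L) %/% noise$block_size) + 1L)]
  triggers <- which(corrected > rise_mult * sigma_per_sample)
  min_len <- max(1L, as.integer(round(min_duration_ms * sample_rate / 1000)))

  segs <- list()
  scan_from <- 1L
  ti <- 1L
  while (ti <= length(triggers)) {
    t0 <- triggers[ti]
    if (t0 < scan_from) {
      ti <- ti + 1L
      next
    }
    sg <- sig_of(t0)
    thr <- fall_mult * sg
    # Backward: most recent sample <= 1 sigma; segment starts just after it.
    start <- t0
    j <- t0 - 1L
    while (j >= 1L && corrected[j] > thr) j <- j - 1L
    start <- j + 1L
    # Forward: first sample < 1 sigma ends the segment (exclusive).
    k <- t0 + 1L
    while (k <= n && corrected[k] >= thr) k <- k + 1L
    end <- k # half-open
    # Merge with previous segment on overlap.
    if (length(segs) > 0L && start <= segs[[length(segs)]]$end) {
      segs[[length(segs)]]$end <- max(segs[[length(segs)]]$end, end)
    } else {
      segs[[length(segs) + 1L]] <- list(start = start, end = end, sigma = sg)
    }
    scan_from <- end
    ti <- ti + 1L
  }
  segs <- Filter(function(s) (s$end - s$start) >= min_len, segs)
  segs <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    idx <- s$start:(s$end - 1L)
    structure(
      list(
        segment_id = i, start = s$start, end = s$end, sigma = s$sigma,
        baseline_local = mean(baseline[idx]),
        corrected = corrected[idx]
      ),
      class = "signal_segment"
    )
  })
  structure(segs,
            class = "signal_segments",
            n_samples = n, sample_rate = sample_rate,
            rise_mult = rise_mult, fall_mult = fall_mult)
}

#' @export
print.signal_segments <- function(x, ...) {
  cat(sprintf("%d signal segment(s) in %d samples\n", length(x), attr(x, "n_samples")))
  if (length(x) > 0) {
    d <- vapply(x, function(s) s$end - s$start, numeric(1))
    cat(sprintf("  duration: median %.0f samples, range %d-%d\n",
                stats::median(d), min(d), max(d)))
  }
  invisible(x)
}

#' Two-pass detection pipeline
#'
#' Pass 1 estimates the baseline from the raw moving average, estimates
#' per-second sigma, and detects segments. Pass 2 replaces detected segments
#' by linear interpolation (the molecule-free region), recomputes baseline
#' and sigma on the cleaned trace, and re-detects on the raw samples. This
#' resolves the circularity of defining the baseline as the level where no
#' molecule passes.
#'
#' @param trace A `tc_trace` or numeric vector.
#' @param window Moving-average window (samples).
#' @param two_pass If `FALSE`, stop after pass 1.
#' @param ... Passed on to [detect_signals()].
#' @param sample_rate Samples per second (taken from the trace if present).
#' @return Object of class `tc_detection`: `$segments`, `$baseline`,
#'   `$noise`, plus the pass-1 results in `$pass1`.
#' @export
detect_pipeline <- function(trace, window = 2000, two_pass = TRUE,
                            sample_rate = NULL, ...) {
  x <- if (inherits(trace, "tc_trace")) trace$samples else as.numeric(trace)
  sample_rate <- sample_rate %||%
    (if (inherits(trace, "tc_trace")) trace$sample_rate else 10000)
  b1 <- estimate_baseline(x, window)
  n1 <- estimate_sigma(x, b1, sample_rate)
  s1 <- detect_signals(x, b1, n1, sample_rate = sample_rate, ...)
  if (!two_pass) {
    return(structure(list(segments = s1, baseline = b1, noise = n1, pass1 = NULL),
                     class = "tc_detection"))
  }
  masked <- x
  for (s in s1) {
    lo <- max(1L, s$start - 1L)
    hi <- min(length(x), s$end)
    masked[s$start:(s$end - 1L)] <-
      stats::approx(c(lo, hi), x[c(lo, hi)], xout = s$start:(s$end - 1L))$y
  }
  b2 <- estimate_baseline(masked, window)
  n2 <- estimate_sigma(masked, b2, sample_rate)
  s2 <- detect_signals(x, b2, n2, sample_rate = sample_rate, ...)
  structure(
    list(segments = s2, baseline = b2, noise = n2,
         pass1 = list(segments = s1, baseline = b1, noise = n1)),
    class = "tc_detection"
  )
}

#' @export
print.tc_detection <- function(x, ...) {
  cat("Two-pass signal detection\n")
  if (!is.null(x$pass1)) cat(sprintf("  pass 1: %d segment(s)\n", length(x$pass1$segments)))
  cat(sprintf("  final:  %d segment(s); sigma median %.2f pS\n",
              length(x$segments), stats::median(x$noise$sigma)))
  invisible(x)
}
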