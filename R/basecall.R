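# Base calling: 0.5-ms minimum-retention smoothing, Gaussian-mixture fit of
# the pooled conductance histogram, per-interval most-probable-base calls,
# and dwell-aware conversion of call runs into fragment letters.

#' Minimum-retention smoothing of a signal segment
#'
#' Running median with a window equal to the minimum retention time (5
#' samples at 10 kHz), odd width, shrinking at the edges. Removes
#' sub-retention excursions while preserving plateaus of at least one
#' retention time.
#'
#' @param segment A `signal_segment` or numeric vector of corrected samples.
#' @param min_retention_ms Minimum retention time (ms).
#' @param sample_rate Samples per second.
#' @return Numeric vector of smoothed samples (same length).
#' @export
smooth_segment <- function(segment, min_retention_ms = 0.5, sample_rate = 10000) {
  x <- if (inherits(segment, "signal_segment")) segment$corrected else as.numeric(segment)
  if (length(x) == 0L) tc_input_error("segment must be non-empty")
  k <- as.integer(round(min_retention_ms * sample_rate / 1000))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(x) %% 2L == 1L) length(x) else length(x) - 1L)
  if (k < 3L) return(x)
  sm <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  # symmetric shrinking windows at the edges
  h <- (k - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(h)) {
    sm[i] <- stats::median(x[1:(2L * i - 1L)])
    sm[n - i + 1L] <- stats::median(x[(n - 2L * i + 2L):n])
  }
  sm
}

# Locate up to `n_peaks` local maxima of a lightly smoothed count histogram,
# ordered by prominence (height), enforcing a minimum separation.
find_histogram_peaks <- function(mids, counts, n_peaks, min_sep = 8) {
  sm <- as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  picked <- integer(0)
  for (i in cand) {
    if (all(abs(mids[i] - mids[picked]) >= min_sep)) picked <- c(picked, i)
    if (length(picked) >= n_peaks) break
  }
  sort(picked)
}

#' Fit the conductance histogram with Gaussian peaks
#'
#' Pools the smoothed baseline-corrected samples of all segments, builds a
#' count histogram (1-pS bins over `[0, 1.3 * max]`), and fits an
#' `n_bases + 1` component Gaussian mixture (baseline plus one peak per
#' base) by nonlinear least squares on the counts, initialized from the most
#' prominent local maxima. Fitted means are ordered ascending; the lowest is
#' assigned to the baseline, the highest to guanine, and the remaining peaks
#' in ascending order to the remaining alphabet (thymine then adenine by
#' default).
#'
#' @param segments A `signal_segments` collection (or list of numeric
#'   vectors of corrected samples).
#' @param n_bases Number of base peaks.
#' @param alphabet Base labels in order of increasing conductance.
#' @param bin_width Histogram bin width (pS).
#' @param min_samples Minimum pooled sample count required.
#' @param min_retention_ms,sample_rate Passed to [smooth_segment()].
#' @param baseline_sigma Initial guess for the baseline peak width (pS);
#'   defaults to 4.
#' @return An object of class `conductance_fit` (extends
#'   `conductance_model`): fitted `means`, `sds`, component `weights`
#'   (areas, normalized), the fitted baseline parameters, and the histogram
#'   with fitted curve in `$histogram`.
#' @export
fit_conductance_model <- function(segments, n_bases = 3,
                                  alphabet = c("T", "A", "G"),
                                  bin_width = 1, min_samples = 1000,
                                  min_retention_ms = 0.5, sample_rate = 10000,
                                  baseline_sigma = 4) {
  if (length(alphabet) != n_bases) tc_input_error("alphabet must have n_bases letters")
  pooled <- unlist(lapply(segments, smooth_segment,
                          min_retention_ms = min_retention_ms,
                          sample_rate = sample_rate))
  if (length(pooled) < min_samples) {
    tc_insufficient("only %d pooled samples (need >= %d)", length(pooled), min_samples)
  }
  hi <- 1.3 * max(pooled)
  breaks <- seq(min(0, floor(min(pooled))), hi + bin_width, by = bin_width)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts

  peaks <- find_histogram_peaks(mids, counts, n_bases, min_sep = 8)
  peaks <- peaks[mids[peaks] > 3 * baseline_sigma] # base peaks, not baseline
  if (length(peaks) < n_bases) {
    tc_fit_error("insufficient peak separation: found %d candidate base peak(s), need %d",
                 length(peaks), n_bases)
  }
  peaks <- utils::tail(peaks, n_bases)
  mu0 <- c(0, mids[peaks])
  a0 <- c(max(counts[mids <= 3 * baseline_sigma], 1), counts[peaks])
  s0 <- c(baseline_sigma, rep(8, n_bases))
  ncomp <- n_bases + 1L

  par0 <- c(a0, mu0, s0)
  names(par0) <- c(paste0("a", seq_len(ncomp)), paste0("m", seq_len(ncomp)),
                   paste0("s", seq_len(ncomp)))
  mix_counts <- function(par, mid) {
    a <- par[1:ncomp]; m <- par[ncomp + 1:ncomp]; s <- par[2 * ncomp + 1:ncomp]
    rowSums(vapply(seq_len(ncomp),
                   function(j) a[j] * exp(-(mid - m[j])^2 / (2 * s[j]^2)),
                   numeric(length(mid))))
  }
  lower <- c(rep(0, ncomp), min(0, min(pooled)), rep(0, n_bases), rep(0.5, ncomp))
  upper <- c(rep(Inf, ncomp), 0.6 * mu0[2], rep(max(mids), n_bases), rep(50, ncomp))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      fn = function(par) counts - mix_counts(par, mids),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) tc_fit_error("mixture fit failed: %s", conditionMessage(e))
  )
  par <- fit$par
  a <- par[1:ncomp]; m <- par[ncomp + 1:ncomp]; s <- par[2 * ncomp + 1:ncomp]
  ord <- order(m)
  a <- a[ord]; m <- m[ord]; s <- s[ord]
  areas <- a * s * sqrt(2 * pi)
  means <- stats::setNames(m[-1L], alphabet)
  sds <- stats::setNames(s[-1L], alphabet)
  if (any(diff(means) <= 0)) tc_fit_error("fitted base means are not strictly ordered")

  out <- conductance_model(means = means, sds = sds,
                           baseline_mean = m[1L], baseline_sd = s[1L])
  out$weights <- stats::setNames(areas[-1L] / sum(areas), alphabet)
  out$baseline_weight <- areas[1L] / sum(areas)
  out$histogram <- data.frame(mid = mids, count = counts,
                              fitted = mix_counts(par, mids))
  out$n_pooled <- length(pooled)
  out$deviance <- sum(fit$fvec^2)
  class(out) <- c("conductance_fit", class(out))
  out
}

#' @export
coef.conductance_fit <- function(object, ...) {
  c(stats::setNames(object$means, paste0("mean_", names(object$means))),
    stats::setNames(object$sds, paste0("sd_", names(object$sds))),
    baseline_mean = object$baseline_mean, baseline_sd = object$baseline_sd)
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit to %d pooled samples\n", x$n_pooled))
  NextMethod()
}

#' Most-probable-base call per 0.5-ms interval
#'
#' Partitions a smoothed segment into consecutive 0.5-ms intervals (a final
#' partial interval is kept if at least half an interval wide). For each
#' interval each label's probability density (alphabet plus baseline, equal
#' priors) is integrated over the interval — the score is the summed density
#' of the interval's samples, so the majority base wins even in boundary
#' intervals whose samples mix two dwelled bases; posteriors are the
#' normalized scores and the call is the posterior argmax, ties broken
#' toward the lower-conductance label and flagged. Calls whose top-two posterior gap is below `low_conf_gap` are
#' flagged low-confidence.
#'
#' @param segment A `signal_segment` (smoothed internally) or numeric vector
#'   of smoothed corrected samples.
#' @param cmodel A fitted [conductance_model()].
#' @param interval_ms Interval width (ms).
#' @param sample_rate Samples per second.
#' @param low_conf_gap Posterior-gap threshold for the low-confidence flag.
#' @param smooth Smooth the segment first (default `TRUE` for
#'   `signal_segment` input).
#' @return Object of class `interval_calls`: a data frame with one row per
#'   interval (`start_ms`, `duration_ms`, `label`, `posterior`, `mean_cond`,
#'   `low_conf`) and the full posterior matrix as attribute `"posteriors"`.
#' @export
call_intervals <- function(segment, cmodel, interval_ms = 0.5,
                           sample_rate = 10000, low_conf_gap = 0.1,
                           smooth = TRUE) {
  x <- if (inherits(segment, "signal_segment")) {
    if (smooth) smooth_segment(segment, sample_rate = sample_rate) else segment$corrected
  } else {
    as.numeric(segment)
  }
  n <- length(x)
  s <- max(1L, as.integer(round(interval_ms * sample_rate / 1000)))
  n_full <- n %/% s
  rem <- n - n_full * s
  idx <- rep(seq_len(n_full), each = s)
  if (rem >= s / 2) {
    idx <- c(idx, rep(n_full + 1L, rem))
  } else {
    x <- x[seq_len(n_full * s)]
  }
  n_int <- max(idx, 0L)
  if (n_int == 0L) {
    # Segment shorter than half an interval: call it as one interval anyway.
    idx <- rep(1L, n)
    x <- if (inherits(segment, "signal_segment")) x else as.numeric(segment)
    n_int <- 1L
  }

  labels <- c(cmodel$alphabet, "baseline")
  mu <- c(unname(cmodel$means), cmodel$baseline_mean)
  sd <- c(unname(cmodel$sds), cmodel$baseline_sd)
  # Integrate each label's probability density over the interval: the score
  # is the summed density of the interval's samples. Unlike a product of
  # densities, this is robust at interval boundaries, where samples from two
  # dwelled bases mix: the majority base wins rather than a spurious
  # intermediate level.
  dens <- vapply(seq_along(labels), function(j) {
    as.numeric(rowsum(stats::dnorm(x, mu[j], sd[j]), idx))
  }, numeric(n_int))
  dens <- matrix(dens, nrow = n_int, dimnames = list(NULL, labels))
  # Normalize per interval with equal priors; order columns by mean so that
  # argmax ties resolve toward the lower-conductance label.
  ord <- order(c(unname(cmodel$means), cmodel$baseline_mean))
  tot <- rowSums(dens)
  zero <- tot <= 0
  if (any(zero)) {
    # Densities underflowed (samples far outside every peak): fall back to
    # the nearest-mean label for those intervals.
    mean_int <- as.numeric(rowsum(x, idx)) / tabulate(idx, n_int)
    for (r in which(zero)) {
      dens[r, which.min(abs(mean_int[r] - mu))] <- 1
    }
    tot <- rowSums(dens)
  }
  post <- dens / tot
  lab <- apply(post[, ord, drop = FALSE], 1L, function(p) labels[ord][which.max(p)])
  top2 <- apply(post, 1L, function(p) {
    sp <- sort(p, decreasing = TRUE)
    sp[1L] - sp[2L]
  })
  dur <- as.numeric(tabulate(idx, n_int)) / sample_rate * 1000
  calls <- data.frame(
    start_ms = c(0, cumsum(dur))[seq_len(n_int)],
    duration_ms = dur,
    label = lab,
    posterior = post[cbind(seq_len(n_int), match(lab, labels))],
    mean_cond = as.numeric(rowsum(x, idx)) / tabulate(idx, n_int),
    low_conf = top2 < low_conf_gap,
    stringsAsFactors = FALSE
  )
  structure(calls, posteriors = post, class = c("interval_calls", "data.frame"))
}

#' Convert interval calls into a fragment
#'
#' Maximal runs of consecutive identical non-baseline labels are emitted as
#' `k = max(1, round(run duration / expected dwell))` letters, so a base
#' dwelling longer than one nominal dwell is emitted as a repeated letter.
#' Per-letter conductance is the run mean normalized by the fitted guanine
#' mean; per-letter time is `run start + (j - 0.5) * run duration / k`;
#' per-letter weight is the mean posterior over the run. Baseline-labelled
#' intervals separate runs but contribute no letters.
#'
#' @param calls An `interval_calls` object.
#' @param cmodel The fitted [conductance_model()] (for the guanine mean).
#' @param expected_dwell_ms Nominal dwell per base (ms).
#' @param segment_id,trace_id Identifiers stored with the fragment.
#' @return A `tc_fragment` (or `NULL` if every call is baseline): `$seq`,
#'   `$letters`, `$times_ms`, `$norm_cond`, `$weights`.
#' @export
calls_to_fragment <- function(calls, cmodel, expected_dwell_ms = 0.667,
                              segment_id = NA_integer_, trace_id = NA_character_) {
  if (all(calls$label == "baseline")) return(NULL)
  r <- rle(calls$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g_mean <- cmodel$means[[length(cmodel$means)]]
  letters <- character(0); times <- numeric(0); conds <- numeric(0); wts <- numeric(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] == "baseline") next
    ix <- starts[i]:ends[i]
    dur <- sum(calls$duration_ms[ix])
    k <- max(1L, as.integer(round(dur / expected_dwell_ms)))
    run_mean <- sum(calls$mean_cond[ix] * calls$duration_ms[ix]) / dur
    run_w <- mean(calls$posterior[ix])
    t0 <- calls$start_ms[starts[i]]
    letters <- c(letters, rep(r$values[i], k))
    times <- c(times, t0 + (seq_len(k) - 0.5) * dur / k)
    conds <- c(conds, rep(run_mean / g_mean, k))
    wts <- c(wts, rep(run_w, k))
  }
  new_fragment(letters, times, conds, wts, segment_id, trace_id)
}

new_fragment <- function(letters, times_ms, norm_cond, weights,
                         segment_id = NA_integer_, trace_id = NA_character_,
                         unfolded = FALSE) {
  structure(
    list(
      seq = join_letters(letters), letters = letters,
      times_ms = times_ms, norm_cond = norm_cond, weights = weights,
      segment_id = segment_id, trace_id = trace_id, unfolded = unfolded
    ),
    class = "tc_fragment"
  )
}

#' @export
print.tc_fragment <- function(x, ...) {
  cat(sprintf("Fragment %s (%d letters%s)\n", x$seq, length(x$letters),
              if (isTRUE(x$unfolded)) ", unfolded" else ""))
  invisible(x)
}

#' Length of a fragment in letters
#' @param x A `tc_fragment`.
#' @export
fragment_length <- function(x) length(x$letters)

#' Call fragments from every detected segment
#'
#' Smooths each segment, calls its 0.5-ms intervals against the fitted
#' conductance model, and converts the calls into fragments. Segments whose
#' calls are all baseline yield no fragment.
#'
#' @param segments A `signal_segments` collection.
#' @param cmodel Fitted [conductance_model()].
#' @param interval_ms,expected_dwell_ms,sample_rate,low_conf_gap See
#'   [call_intervals()] and [calls_to_fragment()].
#' @param trace_id Identifier stored with the fragments.
#' @return Object of class `tc_fragments`: list of `tc_fragment`, with the
#'   number of all-baseline segments in attribute `"n_empty"`.
#' @export
call_fragments <- function(segments, cmodel, interval_ms = 0.5,
                           expected_dwell_ms = 0.667, sample_rate = 10000,
                           low_conf_gap = 0.1, trace_id = NA_character_) {
  frags <- vector("list", length(segments))
  n_empty <- 0L
  for (i in seq_along(segments)) {
    calls <- call_intervals(segments[[i]], cmodel, interval_ms, sample_rate, low_conf_gap)
    f <- calls_to_fragment(calls, cmodel, expected_dwell_ms,
                           segment_id = segments[[i]]$segment_id, trace_id = trace_id)
    if (is.null(f)) {
      n_empty <- n_empty + 1L
    } else {
      f$duration_ms <- (segments[[i]]$end - segments[[i]]$start) / sample_rate * 1000
      frags[[i]] <- f
    }
  }
  frags <- Filter(Negate(is.null), frags)
  structure(frags, class = "tc_fragments", n_empty = n_empty)
}

#' @export
print.tc_fragments <- function(x, ...) {
  cat(sprintf("%d fragment(s) (%d all-baseline segment(s) skipped)\n",
              length(x), attr(x, "n_empty") %||% 0L))
  if (length(x) > 0) {
    len <- vapply(x, fragment_length, numeric(1))
    cat(sprintf("  letters: median %.0f, range %d-%d\n",
                stats::median(len), min(len), max(len)))
  }
  invisible(x)
}
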