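# Synthetic trace simulator: translocation paths, trace rendering, mixtures.
# All public entry points take an explicit seed and leave the caller's RNG
# state untouched; *_impl functions draw from the current RNG stream so that
# composite simulations remain reproducible from a single seed.

draw_read_length <- function(model) {
  k <- seq_len(model$max_read_length)
  p <- model$read_length_p
  w <- p * (1 - p)^(k - 1)
  sample(k, 1L, prob = w)
}

draw_dwell <- function(n, model) {
  model$min_dwell_ms + stats::rexp(n, rate = 1 / (model$mean_dwell_ms - model$min_dwell_ms + 1e-12))
}

sim_path_impl <- function(sequence, model, alphabet = c("T", "A", "G"),
                          sequence_id = "seq") {
  letters <- check_sequence(sequence, alphabet)
  n <- length(letters)
  L <- draw_read_length(model)
  window_len <- min(L, n)
  window_start <- sample.int(n - window_len + 1L, 1L)
  from_5p <- stats::runif(1) < model$entry_prob_5p
  if (from_5p) {
    pos <- window_start
    dir <- 1L
  } else {
    pos <- window_start + window_len - 1L
    dir <- -1L
  }
  positions <- integer(0)
  dwells <- numeric(0)
  visited <- logical(n)
  repeat {
    positions <- c(positions, pos)
    dwells <- c(dwells, draw_dwell(1L, model))
    visited[pos] <- TRUE
    if (sum(visited) >= L) break
    if (stats::runif(1) < model$reversal_prob) dir <- -dir
    pos <- pos + dir
    if (pos < 1L || pos > n) break
  }
  structure(
    list(
      steps = data.frame(position = positions, dwell_ms = dwells),
      sequence = join_letters(letters),
      sequence_id = sequence_id,
      entry_end = if (from_5p) "5p" else "3p",
      read_length_drawn = L
    ),
    class = "tc_path"
  )
}

#' Simulate one translocation path through the nanogap
#'
#' Draws a single-base-stepping random walk over a source sequence: a read
#' length from the truncated geometric law, a uniformly placed read window
#' entered from the 3' or 5' end, per-step direction reversals, and per-base
#' dwell times from a shifted exponential. The path terminates when the
#' drawn number of distinct bases has been dwelled on or the molecule steps
#' off either end of the sequence.
#'
#' @param sequence Base sequence (single string) over `alphabet`.
#' @param model A [translocation_model()].
#' @param seed Integer seed (required; simulation is reproducible).
#' @param alphabet Allowed letters.
#' @param sequence_id Identifier stored with the path.
#' @return An object of class `tc_path`: `$steps` is a data frame of
#'   1-based `position` and `dwell_ms`, consecutive positions differing by
#'   exactly 1.
#' @examples
#' p <- simulate_path(let7_sequences()["let7a"], translocation_model(), seed = 1)
#' p$steps
#' @export
simulate_path <- function(sequence, model = translocation_model(), seed,
                          alphabet = c("T", "A", "G"), sequence_id = "seq") {
  with_local_seed(seed, sim_path_impl(sequence, model, alphabet, sequence_id))
}

#' @export
print.tc_path <- function(x, ...) {
  cat(sprintf("Translocation path over %s (%s entry): %d dwells, %d distinct bases\n",
              x$sequence_id, x$entry_end, nrow(x$steps),
              length(unique(x$steps$position))))
  cat("  positions:", paste(x$steps$position, collapse = " "), "\n")
  invisible(x)
}

# True letters read by a path (in reading order, with revisits).
path_letters <- function(path) {
  split_letters(path$sequence)[path$steps$position]
}

render_impl <- function(paths, cmodel, sample_rate, gap_mean_ms, bias_v,
                        drift_amplitude = 0, drift_period_s = 10) {
  if (sample_rate <= 0) tc_input_error("sample rate must be > 0")
  spms <- sample_rate / 1000 # samples per ms
  n_ev <- length(paths)
  gaps <- stats::rexp(n_ev + 1L, rate = 1 / gap_mean_ms)
  gap_samp <- pmax(1L, as.integer(round(gaps * spms)))

  # Per-event sample counts per step, quantized cumulatively to avoid drift.
  step_samp <- lapply(paths, function(p) {
    b <- round(cumsum(c(0, p$steps$dwell_ms)) * spms)
    pmax(1L, as.integer(diff(b)))
  })
  ev_len <- vapply(step_samp, sum, integer(1))
  total <- sum(gap_samp) + sum(ev_len)

  samples <- numeric(total)
  base_index <- rep(NA_integer_, total)
  ev_start <- integer(n_ev)
  ev_end <- integer(n_ev)
  pos <- 1L
  for (i in seq_len(n_ev + 1L)) {
    g <- gap_samp[i]
    samples[pos:(pos + g - 1L)] <- stats::rnorm(g, cmodel$baseline_mean, cmodel$baseline_sd)
    pos <- pos + g
    if (i > n_ev) break
    p <- paths[[i]]
    ns <- step_samp[[i]]
    ev_start[i] <- pos
    lets <- split_letters(p$sequence)
    for (s in seq_along(ns)) {
      k <- ns[s]
      b <- lets[p$steps$position[s]]
      samples[pos:(pos + k - 1L)] <- stats::rnorm(k, cmodel$means[[b]], cmodel$sds[[b]])
      base_index[pos:(pos + k - 1L)] <- p$steps$position[s]
      pos <- pos + k
    }
    ev_end[i] <- pos # half-open
  }
  if (drift_amplitude > 0) {
    t_s <- (seq_len(total) - 1L) / sample_rate
    samples <- samples + drift_amplitude * sin(2 * pi * t_s / drift_period_s)
  }
  events <- data.frame(
    event_id = seq_len(n_ev),
    start = ev_start, end = ev_end,
    variant = vapply(paths, function(p) p$sequence_id, character(1)),
    entry_end = vapply(paths, function(p) p$entry_end, character(1)),
    read_length = vapply(paths, function(p) length(unique(p$steps$position)), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      samples = samples, sample_rate = sample_rate, bias_v = bias_v,
      events = events, base_index = base_index, paths = paths
    ),
    class = "tc_trace"
  )
}

#' Render translocation paths into a conductance-time trace
#'
#' Each path becomes one spike-like event: over every dwell, samples are
#' drawn from the Gaussian of the dwelled base; between events, samples come
#' from the baseline Gaussian. Ground-truth event intervals (half-open
#' sample indices) and the per-sample true base index are stored with the
#' trace.
#'
#' @param paths List of `tc_path` objects (or a single one).
#' @param cmodel A [conductance_model()].
#' @param sample_rate Sampling rate in Hz.
#' @param gap_mean_ms Mean exponential inter-event gap (ms).
#' @param bias_v Bias voltage metadata (V).
#' @param seed Integer seed.
#' @param drift_amplitude,drift_period_s Optional slow sinusoidal baseline
#'   drift (pS amplitude; default off) used to exercise the moving-average
#'   baseline estimator.
#' @return An object of class `tc_trace` with elements `samples` (pS),
#'   `sample_rate`, `bias_v`, `events`, `base_index`.
#' @examples
#' p <- simulate_path("TGA", translocation_model(reversal_prob = 0), seed = 2)
#' tr <- render_trace(list(p), conductance_model(), seed = 3)
#' @export
render_trace <- function(paths, cmodel = conductance_model(),
                         sample_rate = 10000, gap_mean_ms = 50,
                         bias_v = 0.1, seed,
                         drift_amplitude = 0, drift_period_s = 10) {
  if (inherits(paths, "tc_path")) paths <- list(paths)
  with_local_seed(seed, render_impl(paths, cmodel, sample_rate, gap_mean_ms,
                                    bias_v, drift_amplitude, drift_period_s))
}

#' Simulate a trace from a mixture of sequence variants
#'
#' Draws each event's source variant from the molar fractions, simulates a
#' translocation path for it, and renders all events into one annotated
#' trace. With a single variant this simulates a pure solution.
#'
#' @param variants Named character vector of sequences.
#' @param fractions Named numeric molar fractions (positive, summing to 1
#'   within 1e-9); defaults to equal fractions.
#' @param n_events Number of translocation events (>= 1).
#' @param tmodel A [translocation_model()].
#' @param cmodel A [conductance_model()].
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param sample_rate,bias_v,drift_amplitude,drift_period_s Passed to the
#'   renderer.
#' @return A `tc_trace`; `$events$variant` holds the ground-truth per-event
#'   source labels.
#' @examples
#' tr <- simulate_mixture(let7_sequences()[c("let7a", "let7f")],
#'                        fractions = c(let7a = 0.75, let7f = 0.25),
#'                        n_events = 10, seed = 1)
#' table(tr$events$variant)
#' @export
simulate_mixture <- function(variants, fractions = NULL, n_events,
                             tmodel = translocation_model(),
                             cmodel = conductance_model(),
                             seed, sample_rate = 10000, bias_v = 0.1,
                             drift_amplitude = 0, drift_period_s = 10) {
  if (is.null(names(variants))) tc_input_error("`variants` must be named")
  if (is.null(fractions)) {
    fractions <- stats::setNames(rep(1 / length(variants), length(variants)), names(variants))
  }
  fractions <- fractions[names(variants)]
  if (anyNA(fractions)) tc_input_error("`fractions` must be named like `variants`")
  if (any(fractions <= 0)) tc_input_error("fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9) {
    tc_input_error("fractions must sum to 1 (got %.12f)", sum(fractions))
  }
  if (n_events < 1) tc_input_error("n_events must be >= 1")
  with_local_seed(seed, {
    labels <- sample(names(variants), n_events, replace = TRUE, prob = fractions)
    paths <- lapply(labels, function(v) {
      sim_path_impl(variants[[v]], tmodel, alphabet = cmodel$alphabet, sequence_id = v)
    })
    render_impl(paths, cmodel, sample_rate, tmodel$gap_mean_ms, bias_v,
                drift_amplitude, drift_period_s)
  })
}

#' @export
print.tc_trace <- function(x, ...) {
  cat(sprintf("Conductance trace: %d samples at %g Hz (%.2f s), bias %g V\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$bias_v))
  if (!is.null(x$events) && nrow(x$events) > 0) {
    cat(sprintf("  ground truth: %d annotated events (%s)\n", nrow(x$events),
                paste(sprintf("%s: %d", names(table(x$events$variant)),
                              table(x$events$variant)), collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.tc_trace <- function(x, from_s = 0, to_s = NULL, ...) {
  n <- length(x$samples)
  to_s <- to_s %||% (n / x$sample_rate)
  idx <- max(1, floor(from_s * x$sample_rate)):min(n, ceiling(to_s * x$sample_rate))
  graphics::plot((idx - 1) / x$sample_rate, x$samples[idx], type = "l",
                 xlab = "time (s)", ylab = "conductance (pS)", ...)
  invisible(x)
}
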