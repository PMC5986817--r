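#' Per-base conductance model
#'
#' Describes the single-molecule conductance of each base as a Gaussian peak
#' (mean and standard deviation in pS) plus a baseline Gaussian. Defaults are
#' the empirical peak conductances of thymine, adenine and guanine (45, 77
#' and 102 pS) with an 8-pS peak width, and a baseline at 0 pS (after
#' baseline correction) with 4-pS noise. The alphabet is ordered by strictly
#' increasing mean conductance.
#'
#' @param means Named numeric vector of per-base mean conductances (pS),
#'   strictly increasing. Names define the alphabet.
#' @param sds Per-base peak standard deviations (pS); recycled to the
#'   alphabet length.
#' @param baseline_mean Baseline mean conductance (pS).
#' @param baseline_sd Baseline standard deviation (pS).
#' @return An object of class `conductance_model`.
#' @examples
#' conductance_model()
#' @export
conductance_model <- function(means = c(T = 45, A = 77, G = 102),
                              sds = 8,
                              baseline_mean = 0,
                              baseline_sd = 4) {
  if (is.null(names(means)) || any(!nzchar(names(means)))) {
    tc_input_error("`means` must be a named vector; names define the alphabet")
  }
  sds <- rep_len(sds, length(means))
  names(sds) <- names(means)
  if (any(diff(means) <= 0)) {
    tc_input_error("per-base means must be strictly increasing over the alphabet")
  }
  if (any(means <= baseline_mean)) {
    tc_input_error("all per-base means must exceed the baseline mean")
  }
  if (any(sds <= 0) || baseline_sd <= 0) tc_input_error("standard deviations must be > 0")
  structure(
    list(
      means = means, sds = sds,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      alphabet = names(means)
    ),
    class = "conductance_model"
  )
}

#' @export
print.conductance_model <- function(x, ...) {
  cat("Conductance model (", length(x$alphabet), " bases)\n", sep = "")
  tab <- data.frame(
    base = c(x$alphabet, "baseline"),
    mean_pS = c(unname(x$means), x$baseline_mean),
    sd_pS = c(unname(x$sds), x$baseline_sd)
  )
  if (!is.null(x$weights)) tab$weight <- c(unname(x$weights), x$baseline_weight %||% NA)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Per-base mean conductance normalized by the guanine (highest) peak.
norm_means <- function(cmodel) {
  cmodel$means / cmodel$means[[length(cmodel$means)]]
}

#' Translocation dynamics model
#'
#' Parameters of the stochastic single-base-step translocation of a DNA
#' molecule through the nanogap: memoryless dwell above a 0.5-ms floor with
#' mean 1/1.5 ms (so the mean velocity is 1.5 bases/ms), a per-step
#' probability of reversing the reading direction, equal probability of
#' entering from the 3' or 5' end, a geometric read-length law truncated at
#' 12 distinct bases, and an exponential inter-event gap.
#'
#' @param mean_dwell_ms Mean dwell per base (ms).
#' @param min_dwell_ms Minimum dwell per base (ms); must not exceed the mean.
#' @param reversal_prob Per-step probability of a direction reversal, in
#'   `[0, 1)`.
#' @param entry_prob_5p Probability that the molecule enters from the 5' end
#'   (is read in the forward direction), in `[0, 1]`.
#' @param read_length_p Success parameter of the geometric read-length
#'   distribution over distinct dwelled bases.
#' @param max_read_length Truncation cap of the read-length law.
#' @param gap_mean_ms Mean of the exponential inter-event gap (ms).
#' @return An object of class `translocation_model`.
#' @examples
#' translocation_model(reversal_prob = 0)
#' @export
translocation_model <- function(mean_dwell_ms = 0.667,
                                min_dwell_ms = 0.5,
                                reversal_prob = 0.05,
                                entry_prob_5p = 0.5,
                                read_length_p = 0.3,
                                max_read_length = 12,
                                gap_mean_ms = 50) {
  if (min_dwell_ms > mean_dwell_ms) tc_input_error("minimum dwell must not exceed mean dwell")
  if (min_dwell_ms < 0 || mean_dwell_ms <= 0) tc_input_error("dwell parameters must be positive")
  if (reversal_prob < 0 || reversal_prob >= 1) tc_input_error("reversal_prob must lie in [0, 1)")
  if (entry_prob_5p < 0 || entry_prob_5p > 1) tc_input_error("entry_prob_5p must lie in [0, 1]")
  if (read_length_p <= 0 || read_length_p >= 1) tc_input_error("read_length_p must lie in (0, 1)")
  if (max_read_length < 1) tc_input_error("max_read_length must be >= 1")
  if (gap_mean_ms <= 0) tc_input_error("gap_mean_ms must be > 0")
  structure(
    list(
      mean_dwell_ms = mean_dwell_ms, min_dwell_ms = min_dwell_ms,
      reversal_prob = reversal_prob, entry_prob_5p = entry_prob_5p,
      read_length_p = read_length_p, max_read_length = as.integer(max_read_length),
      gap_mean_ms = gap_mean_ms
    ),
    class = "translocation_model"
  )
}

#' @export
print.translocation_model <- function(x, ...) {
  cat("Translocation model\n")
  cat(sprintf("  dwell: mean %.3f ms, floor %.3f ms (velocity %.2f bases/ms)\n",
              x$mean_dwell_ms, x$min_dwell_ms, 1 / x$mean_dwell_ms))
  cat(sprintf("  reversal prob/step: %.3f; P(5' entry): %.2f\n",
              x$reversal_prob, x$entry_prob_5p))
  cat(sprintf("  read length: geometric(p = %.2f) truncated at %d\n",
              x$read_length_p, x$max_read_length))
  cat(sprintf("  inter-event gap: exponential, mean %.1f ms\n", x$gap_mean_ms))
  invisible(x)
}
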