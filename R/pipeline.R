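# Pipeline configuration and the end-to-end driver
# (simulate -> detect -> call -> analyze -> assemble -> quantify).

#' Pipeline configuration
#'
#' All module defaults in one schema-versioned list that round-trips through
#' YAML losslessly. The thresholds mirror the signal-detection and
#' base-calling procedure: 2000-sample moving-average baseline, per-second
#' sigma from 20-sample windows, 6-sigma rise / 1-sigma fall, 0.5-ms
#' minimum retention and calling interval, fragments of at least 5 letters,
#' exact overlaps of at least 4 for assembly.
#'
#' @param variants Named character vector of sequences to simulate.
#' @param fractions Molar fractions (named; default equal).
#' @param n_events Number of simulated translocation events.
#' @param seed Master seed for the run.
#' @param sample_rate Hz.
#' @param tmodel,cmodel Model parameter lists (see [translocation_model()]
#'   and [conductance_model()]).
#' @param baseline_window,rise_mult,fall_mult,min_duration_ms Detection.
#' @param interval_ms,expected_dwell_ms Calling.
#' @param min_fragment_len,min_overlap,max_mismatch Assembly.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(variants = let7_sequences()["let7a"],
                            fractions = NULL, n_events = 1000, seed = 1,
                            sample_rate = 10000,
                            tmodel = translocation_model(),
                            cmodel = conductance_model(),
                            baseline_window = 2000, rise_mult = 6,
                            fall_mult = 1, min_duration_ms = 0.5,
                            interval_ms = 0.5, expected_dwell_ms = 0.667,
                            min_fragment_len = 5, min_overlap = 4,
                            max_mismatch = 0) {
  stopifnot(baseline_window >= 1, rise_mult > 0, fall_mult > 0,
            min_duration_ms > 0, interval_ms > 0, expected_dwell_ms > 0,
            min_fragment_len >= 1, min_overlap >= 1, max_mismatch >= 0)
  structure(
    list(
      schema_version = "1.0",
      variants = as.list(variants),
      fractions = if (is.null(fractions)) NULL else as.list(fractions),
      n_events = n_events, seed = seed, sample_rate = sample_rate,
      tmodel = unclass(tmodel), cmodel = lapply(unclass(cmodel), function(x) {
        if (is.null(names(x))) x else as.list(x)
      }),
      baseline_window = baseline_window, rise_mult = rise_mult,
      fall_mult = fall_mult, min_duration_ms = min_duration_ms,
      interval_ms = interval_ms, expected_dwell_ms = expected_dwell_ms,
      min_fragment_len = min_fragment_len, min_overlap = min_overlap,
      max_mismatch = max_mismatch
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for `write_config`).
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

config_models <- function(config) {
  cm <- config$cmodel
  list(
    tmodel = do.call(translocation_model, config$tmodel),
    cmodel = conductance_model(
      means = unlist(cm$means), sds = unlist(cm$sds),
      baseline_mean = cm$baseline_mean, baseline_sd = cm$baseline_sd
    )
  )
}

#' Run the full quantum-sequencing pipeline
#'
#' Simulates (or loads) traces, detects signals, fits the conductance
#' model, calls fragments, runs transition-point analysis and velocity
#' estimation, assembles the consensus, and — for two-variant runs —
#' quantifies the mixture by marker counting. Every filter stage logs
#' input/output counts.
#'
#' @param config A [pipeline_config()].
#' @param trace Optional pre-built `tc_trace` (skips simulation).
#' @param out_dir Optional directory for the report files (consensus FASTA,
#'   heat-map TSV, quantitation JSON, read-length TSV, summary JSON, log).
#' @return Object of class `tc_report`: `$consensus`, `$heatmap`,
#'   `$velocity`, `$read_lengths`, `$quant` (or `NULL`), `$fit`, `$log`.
#' @export
run_pipeline <- function(config = pipeline_config(), trace = NULL, out_dir = NULL) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- sprintf("[%s] %s", stage, sprintf(...))
  }
  models <- config_models(config)
  variants <- unlist(config$variants)

  if (is.null(trace)) {
    trace <- simulate_mixture(
      variants,
      fractions = if (is.null(config$fractions)) NULL else unlist(config$fractions),
      n_events = config$n_events, tmodel = models$tmodel,
      cmodel = models$cmodel, seed = config$seed,
      sample_rate = config$sample_rate
    )
    note("simulate", "%d events, %d samples", nrow(trace$events), length(trace$samples))
  }
  if (length(trace$samples) == 0L) tc_input_error("empty trace at detect stage")

  det <- detect_pipeline(trace, window = config$baseline_window,
                         rise_mult = config$rise_mult, fall_mult = config$fall_mult,
                         min_duration_ms = config$min_duration_ms,
                         sample_rate = config$sample_rate)
  note("detect", "%d segments (pass 1: %d)", length(det$segments),
       length(det$pass1$segments))

  fit <- fit_conductance_model(det$segments, n_bases = length(models$cmodel$alphabet),
                               alphabet = models$cmodel$alphabet,
                               sample_rate = config$sample_rate)
  note("fit", "peak means %s pS", paste(sprintf("%.1f", fit$means), collapse = "/"))

  frags <- call_fragments(det$segments, fit, interval_ms = config$interval_ms,
                          expected_dwell_ms = config$expected_dwell_ms,
                          sample_rate = config$sample_rate)
  note("call", "%d fragments from %d segments (%d all-baseline)",
       length(frags), length(det$segments), attr(frags, "n_empty"))

  rl <- read_length_histogram(frags, reference = variants[[1L]])
  read_lengths <- rl$lengths
  note("readlen", "%d read lengths (max %d; %d residence-excluded, %d unalignable)",
       length(read_lengths), max(c(read_lengths, 0L)),
       rl$n_excluded_residence, rl$n_excluded_unalignable)

  profiles <- lapply(frags, find_transition_points, reference = variants[[1L]])
  n_align <- sum(vapply(profiles, function(p) isTRUE(p$alignable), logical(1)))
  note("analyze", "%d/%d fragments alignable to %s", n_align, length(profiles),
       names(variants)[1L] %||% "reference")
  velocity <- tryCatch(estimate_velocity(profiles, seed = config$seed),
                       tunnelcall_insufficient_data = function(e) NULL)

  consensus <- tryCatch(
    greedy_assemble(frags, min_fragment_len = config$min_fragment_len,
                    min_overlap = config$min_overlap,
                    max_mismatch = config$max_mismatch,
                    cmodel = fit, orient_to = variants[[1L]],
                    target_length = nchar(variants[[1L]])),
    tunnelcall_insufficient_data = function(e) NULL
  )
  if (!is.null(consensus)) {
    note("assemble", "consensus %d bases from %d fragments (%d short, %d unplaced)",
         nchar(consensus$consensus), consensus$n_fragments,
         consensus$n_discarded_short, consensus$n_unplaced)
  }

  quant <- NULL
  if (length(variants) == 2L) {
    spec <- marker_spec(variants)
    quant <- tryCatch(
      count_markers(frags, spec, min_len = config$min_fragment_len,
                    seed = config$seed),
      tunnelcall_insufficient_data = function(e) NULL
    )
    if (!is.null(quant)) {
      note("quantify", "ratio %.2f : %.2f (n = %d)", quant$ratio[[1L]],
           quant$ratio[[2L]], sum(quant$counts))
    }
  }

  report <- structure(
    list(consensus = consensus,
         heatmap = if (!is.null(consensus)) heatmap_table(consensus) else NULL,
         fit = fit, velocity = velocity, read_lengths = read_lengths,
         quant = quant, log = unlist(log), config = config),
    class = "tc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$consensus)) {
    ss <- Biostrings::DNAStringSet(report$consensus$consensus)
    names(ss) <- "consensus"
    Biostrings::writeXStringSet(ss, file.path(out_dir, "consensus.fasta"))
    hm <- report$heatmap
    hm$mean_norm_conductance <- sprintf("%.6f", hm$mean_norm_conductance)
    hm$sd_norm_conductance <- sprintf("%.6f", hm$sd_norm_conductance)
    utils::write.table(hm, file.path(out_dir, "heatmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  rl <- table(factor(report$read_lengths, levels = seq_len(max(c(report$read_lengths, 1)))))
  utils::write.table(
    data.frame(read_length = as.integer(names(rl)), count = as.integer(rl)),
    file.path(out_dir, "read_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  summary <- list(
    consensus = report$consensus$consensus %||% NA,
    peak_means_pS = as.list(report$fit$means),
    velocity_bases_per_ms = report$velocity$velocity %||% NA,
    n_fragments = length(report$read_lengths),
    max_read_length = max(c(report$read_lengths, 0))
  )
  if (!is.null(report$quant)) {
    q <- report$quant
    summary$quant <- list(
      counts = as.list(q$counts),
      ratio = as.list(q$ratio),
      fraction = q$fraction,
      fraction_ci = q$fraction_ci,
      rejections = as.list(stats::setNames(as.integer(q$rejections), names(q$rejections)))
    )
    jsonlite::write_json(summary$quant, file.path(out_dir, "quant.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' @export
print.tc_report <- function(x, ...) {
  cat("Quantum-sequencing pipeline report\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
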