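# Trace and fragment file formats.
#
# Traces: two-column text (time_s, conductance_pS) with '#'-prefixed header
# (sample_rate_hz, bias_v, seed), or raw little-endian float64 with a JSON
# sidecar. Fragments: FASTA plus a per-letter TSV sidecar.

#' Write / read a conductance trace
#'
#' Text format: header lines `# key: value` (at least `sample_rate_hz`,
#' plus `bias_v` and `seed`), then tab-separated `time_s` and
#' `conductance_pS` at full double precision. Binary format: raw
#' little-endian float64 samples plus a `<path>.json` metadata sidecar.
#' Round trips are lossless.
#'
#' @param trace A `tc_trace`.
#' @param path Output file.
#' @param format `"text"` or `"binary"`.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `tc_trace` (without ground-truth annotations).
#' @export
write_trace <- function(trace, path, format = c("text", "binary")) {
  format <- match.arg(format)
  seed <- trace$seed %||% NA
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# sample_rate_hz: %s", format(trace$sample_rate, digits = 17)),
      sprintf("# bias_v: %s", format(trace$bias_v, digits = 17)),
      sprintf("# seed: %s", seed)
    ), con)
    t_s <- (seq_along(trace$samples) - 1L) / trace$sample_rate
    utils::write.table(
      data.frame(time_s = sprintf("%.9f", t_s),
                 conductance_pS = sprintf("%.17g", trace$samples)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  } else {
    writeBin(as.numeric(trace$samples), path, size = 8L, endian = "little")
    jsonlite::write_json(
      list(sample_rate_hz = trace$sample_rate, bias_v = trace$bias_v,
           seed = seed, n_samples = length(trace$samples)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) tc_format_error("missing JSON sidecar %s", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$sample_rate_hz)) tc_format_error("sidecar lacks field `sample_rate_hz`")
    samples <- readBin(path, numeric(), n = meta$n_samples, size = 8L, endian = "little")
    return(structure(
      list(samples = samples, sample_rate = meta$sample_rate_hz,
           bias_v = meta$bias_v %||% NA_real_, events = NULL, base_index = NULL,
           seed = meta$seed),
      class = "tc_trace"
    ))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(kv) == 3L) meta[[trimws(kv[2L])]] <- trimws(kv[3L])
  }
  if (is.null(meta$sample_rate_hz)) {
    tc_format_error("trace header lacks required field `sample_rate_hz`")
  }
  rate <- as.numeric(meta$sample_rate_hz)
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            col.names = c("time_s", "conductance_pS"))
  if (nrow(body) > 1L) {
    dt <- diff(body$time_s)
    if (any(abs(dt - 1 / rate) > 1e-9)) {
      tc_format_error("time column is not uniform at 1/%g s (tolerance 1e-9)", rate)
    }
  }
  structure(
    list(samples = body$conductance_pS, sample_rate = rate,
         bias_v = as.numeric(meta$bias_v %||% NA), events = NULL,
         base_index = NULL,
         seed = if (!is.null(meta$seed) && meta$seed != "NA") as.numeric(meta$seed) else NA),
    class = "tc_trace"
  )
}

#' Write / read called fragments
#'
#' Fragments are stored as FASTA (via Biostrings) with ids `frag_000001`,
#' ..., plus a tab-separated sidecar carrying the per-letter times,
#' normalized conductances and posterior weights. The round trip is
#' lossless; ids must agree between the two files.
#'
#' @param fragments A `tc_fragments` list.
#' @param path FASTA output path; the sidecar is written next to it with
#'   extension `.tsv`.
#' @param alphabet Letters permitted in the FASTA.
#' @return `write_fragments` returns `path` invisibly; `read_fragments`
#'   returns a `tc_fragments` list.
#' @export
write_fragments <- function(fragments, path, alphabet = c("T", "A", "G")) {
  seqs <- vapply(fragments, function(f) f$seq, character(1))
  bad <- vapply(fragments, function(f) any(!f$letters %in% alphabet), logical(1))
  if (any(bad)) {
    tc_format_error("fragment(s) %s contain letters outside the alphabet; refusing to write",
                    paste(which(bad), collapse = ", "))
  }
  ids <- sprintf("frag_%06d", seq_along(fragments))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  tsv <- do.call(rbind, lapply(seq_along(fragments), function(i) {
    f <- fragments[[i]]
    data.frame(
      fragment_id = ids[i], letter_index = seq_along(f$letters),
      letter = f$letters, time_ms = f$times_ms,
      norm_conductance = f$norm_cond, weight = f$weights,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(tsv, fragment_sidecar_path(path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

fragment_sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".tsv")

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tsv <- utils::read.delim(fragment_sidecar_path(path), stringsAsFactors = FALSE)
  if (!setequal(unique(tsv$fragment_id), names(ss))) {
    tc_format_error("FASTA and sidecar fragment ids disagree")
  }
  frags <- lapply(names(ss), function(id) {
    rows <- tsv[tsv$fragment_id == id, ]
    rows <- rows[order(rows$letter_index), ]
    if (paste(rows$letter, collapse = "") != as.character(ss[[id]])) {
      tc_format_error("FASTA sequence and sidecar letters disagree for %s", id)
    }
    new_fragment(rows$letter, rows$time_ms, rows$norm_conductance, rows$weight)
  })
  structure(frags, class = "tc_fragments", n_empty = 0L)
}
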