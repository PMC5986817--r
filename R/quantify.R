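# Marker-based abundance quantitation for mixtures of two variants that
# differ at a single base: place fragments on the common scaffold, read the
# marker letter, count per variant, report ratios.

#' Marker specification for a two-variant mixture
#'
#' The two variants must differ at exactly one position (the marker); the
#' scaffold is their common sequence. Either pass the two variant sequences
#' (the marker is derived), or a scaffold plus marker position and the
#' expected base per variant.
#'
#' @param variants Named character vector of exactly two sequences.
#' @param scaffold,marker_position,variant_bases Alternative explicit form:
#'   scaffold sequence, 1-based marker position, and a named character
#'   vector mapping variant name to its expected marker base.
#' @return Object of class `marker_spec`.
#' @examples
#' s <- let7_sequences()
#' marker_spec(s[c("let7a", "let7f")]) # marker at position 12 (G vs A)
#' @export
marker_spec <- function(variants = NULL, scaffold = NULL,
                        marker_position = NULL, variant_bases = NULL) {
  if (!is.null(variants)) {
    if (length(variants) != 2L || is.null(names(variants))) {
      tc_input_error("`variants` must be a named vector of exactly two sequences")
    }
    a <- split_letters(variants[[1L]])
    b <- split_letters(variants[[2L]])
    if (length(a) != length(b)) tc_input_error("variant sequences must have equal length")
    diffs <- which(a != b)
    if (length(diffs) != 1L) {
      tc_input_error("variants must differ at exactly one position (found %d)", length(diffs))
    }
    marker_position <- diffs
    scaffold <- variants[[1L]]
    variant_bases <- stats::setNames(c(a[diffs], b[diffs]), names(variants))
  }
  if (is.null(scaffold) || is.null(marker_position) || is.null(variant_bases)) {
    tc_input_error("provide either `variants` or scaffold + marker_position + variant_bases")
  }
  sc <- split_letters(scaffold)
  if (marker_position < 1L || marker_position > length(sc)) {
    tc_input_error("marker position %d outside the scaffold", marker_position)
  }
  if (length(variant_bases) != 2L || variant_bases[[1L]] == variant_bases[[2L]]) {
    tc_input_error("the two variant marker bases must differ")
  }
  structure(
    list(scaffold = join_letters(sc), scaffold_letters = sc,
         marker_position = as.integer(marker_position),
         variant_bases = variant_bases),
    class = "marker_spec"
  )
}

# Full sequence of variant k: scaffold with its marker base substituted.
sub_marker <- function(spec, k) {
  sc <- spec$scaffold_letters
  sc[spec$marker_position] <- spec$variant_bases[[k]]
  join_letters(sc)
}

#' @export
print.marker_spec <- function(x, ...) {
  cat(sprintf("Marker at position %d of %s\n", x$marker_position, x$scaffold))
  cat(sprintf("  %s\n", paste(sprintf("%s = %s", names(x$variant_bases),
                                      x$variant_bases), collapse = ", ")))
  invisible(x)
}

#' Place a fragment on the marker scaffold
#'
#' The (unfolded) fragment is aligned to the scaffold at every offset and in
#' both orientations, allowing a mismatch only at the marker position. It is
#' accepted only if it has at least `min_len` letters, places uniquely, and
#' its placement spans the marker; rejections are categorized, never raised.
#'
#' @param fragment `tc_fragment` or letter string.
#' @param spec A [marker_spec()].
#' @param min_len Minimum fragment length.
#' @param unfold Unfold the fragment first.
#' @return A list: `status` (`"accepted"`, `"too_short"`, `"not_spanning"`,
#'   `"ambiguous"`, or `"unalignable"`), and for accepted placements
#'   `offset` (0-based), `orientation`, `marker_letter`, and the fragment's
#'   normalized conductance at the marker (`marker_norm_cond`).
#' @export
place_fragment <- function(fragment, spec, min_len = 5, unfold = TRUE) {
  frag <- if (inherits(fragment, "tc_fragment")) fragment else {
    lets <- split_letters(fragment)
    new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                 rep(NA_real_, length(lets)), rep(1, length(lets)))
  }
  if (unfold) frag <- unfold_palindrome(frag)
  lets <- frag$letters
  L <- length(lets)
  if (L < min_len) return(list(status = "too_short"))
  sc <- spec$scaffold_letters
  n <- length(sc)
  if (L > n) return(list(status = "unalignable"))
  mp <- spec$marker_position

  hits <- list()
  for (orient in c("forward", "reversed")) {
    v <- if (orient == "forward") lets else rev(lets)
    nc <- if (orient == "forward") frag$norm_cond else rev(frag$norm_cond)
    for (o in 0:(n - L)) {
      cols <- o + seq_len(L)
      mism <- which(sc[cols] != v)
      if (length(mism) == 0L || (length(mism) == 1L && cols[mism] == mp)) {
        spans <- mp >= o + 1L && mp <= o + L
        hits[[length(hits) + 1L]] <- list(
          offset = o, orientation = orient, spans = spans,
          marker_letter = if (spans) v[mp - o] else NA_character_,
          marker_norm_cond = if (spans) nc[mp - o] else NA_real_
        )
      }
    }
  }
  if (length(hits) == 0L) return(list(status = "unalignable"))
  key <- vapply(hits, function(h) paste(h$offset, h$marker_letter), character(1))
  uniq <- hits[!duplicated(key)]
  if (length(unique(vapply(uniq, `[[`, integer(1), "offset"))) > 1L ||
      length(unique(vapply(uniq, function(h) h$marker_letter %||% NA_character_, character(1)))) > 1L) {
    return(list(status = "ambiguous"))
  }
  h <- uniq[[1L]]
  if (!h$spans) return(list(status = "not_spanning"))
  list(status = "accepted", offset = h$offset, orientation = h$orientation,
       marker_letter = h$marker_letter, marker_norm_cond = h$marker_norm_cond,
       fragment = frag)
}

#' Count marker-spanning fragments and estimate the abundance ratio
#'
#' Places every fragment on the scaffold, counts accepted marker letters per
#' variant (marker letters matching neither expected variant base are
#' tallied as miscalls and excluded), and reports the ratio normalized so
#' the smaller side equals 1.0, with a seeded bootstrap confidence interval
#' on the first variant's fraction. Fragments the strict placement rejects
#' as unalignable get a second chance through an edit-distance classifier
#' against the two variant sequences (see `rescue_max_edits`), which removes
#' the acceptance asymmetry that dwell mis-splits adjacent to the marker
#' would otherwise introduce between the variants.
#'
#' @param fragments `tc_fragments` or list of letter strings.
#' @param spec A [marker_spec()].
#' @param min_len Minimum fragment length.
#' @param n_boot,seed,conf Bootstrap settings.
#' @param rescue_max_edits Maximum fitting-alignment edit distance for the
#'   rescue classifier; `0` disables it.
#' @return Object of class `quant_result`: `$counts` (per variant),
#'   `$ratio`, `$fraction` (first variant), `$fraction_ci`, `$rejections`,
#'   `$n_miscall`.
#' @export
count_markers <- function(fragments, spec, min_len = 5, n_boot = 1000,
                          seed = 1, conf = 0.95, rescue_max_edits = 2) {
  placements <- lapply(fragments, place_fragment, spec = spec, min_len = min_len)
  status <- vapply(placements, `[[`, character(1), "status")
  acc_letter <- vapply(placements, function(p) p$marker_letter %||% NA_character_,
                       character(1))
  clean <- status == "accepted" & acc_letter %in% spec$variant_bases
  letters <- acc_letter[clean]

  # Rescue path for fragments the strict ungapped placement cannot use: a
  # dwell mis-split next to the marker (for example the GG run adjacent to
  # the let-7a marker) shifts the read by one letter, making it either
  # unalignable or - worse - exactly placeable with its single conflict
  # falling on the marker itself, where a mismatch is allowed, so the read
  # contributes a phantom marker letter. Both effects hit the two variants
  # asymmetrically and shrink the ratio toward 1:1. Every fragment that did
  # not yield a clean marker letter is therefore classified by fitting-
  # alignment edit distance against the two variant sequences; a read is
  # counted for a variant only if it fits it strictly better (only reads
  # covering the marker can discriminate, since the variants differ nowhere
  # else) and within `rescue_max_edits`.
  n_rescued <- 0L
  n_miscall_resolved <- 0L
  rescued_from <- character(0)
  if (rescue_max_edits > 0) {
    seq_a <- split_letters(sub_marker(spec, 1L))
    seq_b <- split_letters(sub_marker(spec, 2L))
    for (i in which(!clean & status != "too_short")) {
      f <- fragments[[i]]
      lets <- if (inherits(f, "tc_fragment")) unfold_palindrome(f)$letters else split_letters(f)
      if (length(lets) < min_len) next
      ed_a <- min(fit_edit_dist(lets, seq_a), fit_edit_dist(rev(lets), seq_a))
      ed_b <- min(fit_edit_dist(lets, seq_b), fit_edit_dist(rev(lets), seq_b))
      if (min(ed_a, ed_b) > rescue_max_edits || ed_a == ed_b) next
      letters <- c(letters, spec$variant_bases[[if (ed_a < ed_b) 1L else 2L]])
      n_rescued <- n_rescued + 1L
      rescued_from <- c(rescued_from, status[i])
      if (status[i] == "accepted") n_miscall_resolved <- n_miscall_resolved + 1L
    }
  }
  vb <- spec$variant_bases
  counts <- stats::setNames(
    vapply(vb, function(b) sum(letters == b), numeric(1)),
    names(vb)
  )
  n_miscall <- sum(status == "accepted" & !acc_letter %in% vb) - n_miscall_resolved
  if (sum(counts) < 1) tc_insufficient("no accepted marker-spanning fragments")
  ratio <- counts / min(counts[counts > 0])
  frac <- counts[[1L]] / sum(counts)
  used <- letters[letters %in% vb]
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      s <- used[sample.int(length(used), replace = TRUE)]
      sum(s == vb[[1L]]) / length(s)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  rej <- table(factor(status, levels = c("accepted", "too_short",
                                         "not_spanning", "ambiguous",
                                         "unalignable")))
  for (s in rescued_from) {
    if (s != "accepted") {
      rej[[s]] <- rej[[s]] - 1L
      rej[["accepted"]] <- rej[["accepted"]] + 1L
    }
  }
  structure(
    list(
      counts = counts, ratio = ratio, fraction = frac,
      fraction_ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
      n_miscall = n_miscall, n_rescued = n_rescued,
      rejections = rej,
      n_input = length(placements)
    ),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat("Marker-based quantitation\n")
  cat(sprintf("  counts: %s (miscalls excluded: %d)\n",
              paste(sprintf("%s = %d", names(x$counts), as.integer(x$counts)),
                    collapse = ", "), x$n_miscall))
  cat(sprintf("  abundance ratio %s : %s = %.1f : %.1f\n",
              names(x$counts)[1L], names(x$counts)[2L], x$ratio[[1L]], x$ratio[[2L]]))
  cat(sprintf("  fraction %s = %.3f (95%% CI %.3f-%.3f)\n", names(x$counts)[1L],
              x$fraction, x$fraction_ci[1L], x$fraction_ci[2L]))
  rej <- x$rejections
  cat(sprintf("  fragments: %d in; %s\n", x$n_input,
              paste(sprintf("%s %d", names(rej), as.integer(rej)), collapse = ", ")))
  invisible(x)
}

#' Mixture heat map on the marker scaffold
#'
#' Builds a consensus profile from the accepted marker placements laid out
#' directly on the scaffold coordinates, and reports, at the marker column,
#' the per-letter weights and mean normalized conductances of the two
#' variant bases.
#'
#' @param fragments `tc_fragments` or list of letter strings.
#' @param spec A [marker_spec()].
#' @param cmodel Optional fitted model (tie-breaking of the plurality vote).
#' @param min_len Minimum fragment length.
#' @return A `consensus_profile` over the scaffold with an extra
#'   `$marker_levels` data frame (letter, count, weight,
#'   mean_norm_conductance).
#' @export
mixture_heatmap <- function(fragments, spec, cmodel = NULL, min_len = 5) {
  placements <- lapply(fragments, place_fragment, spec = spec, min_len = min_len)
  acc <- Filter(function(p) p$status == "accepted", placements)
  if (length(acc) == 0L) tc_insufficient("no accepted marker-spanning fragments")
  alphabet <- if (!is.null(cmodel)) cmodel$alphabet else
    sort(unique(c(spec$scaffold_letters, unlist(lapply(acc, function(p) p$fragment$letters)))))
  layout <- list(placements = lapply(acc, function(p) {
    list(frag = p$fragment, offset = p$offset, reversed = p$orientation == "reversed")
  }))
  cons <- layout_consensus(layout, alphabet,
                           if (!is.null(cmodel)) norm_means(cmodel) else NULL)
  count <- cons$count
  coverage <- as.integer(colSums(count))
  ci <- cbind(match(cons$consensus, alphabet), seq_along(cons$consensus))
  mean_nc <- cons$cond_sum[ci] / pmax(cons$count[ci], 1L)
  sd_nc <- sqrt(pmax(cons$cond_sq[ci] / pmax(cons$count[ci], 1L) - mean_nc^2, 0))
  mp <- spec$marker_position
  marker_levels <- data.frame(
    letter = alphabet,
    count = count[, mp],
    weight = cons$weight[, mp],
    mean_norm_conductance = cons$cond_sum[, mp] / pmax(count[, mp], 1L),
    stringsAsFactors = FALSE
  )
  marker_levels <- marker_levels[marker_levels$count > 0, , drop = FALSE]
  structure(
    list(
      consensus = join_letters(cons$consensus), coverage = coverage,
      base_count = count, base_weight = cons$weight,
      mean_norm_cond = mean_nc, sd_norm_cond = sd_nc,
      mean_weight = colSums(cons$weight) / pmax(coverage, 1L),
      n_fragments = length(acc), n_discarded_short = sum(
        vapply(placements, `[[`, character(1), "status") == "too_short"),
      n_unplaced = length(placements) - length(acc),
      flipped = FALSE, placements = layout$placements,
      marker_levels = marker_levels
    ),
    class = "consensus_profile"
  )
}
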