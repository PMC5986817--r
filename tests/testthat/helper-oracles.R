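# Independent brute-force oracles used to cross-check the implementation.

# Centred moving average with truncated windows, computed naively.
brute_moving_average <- function(x, window) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

# Odd-width running median with shrinking edge windows.
brute_runmed <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    # shrink symmetrically at the edges (odd sub-window)
    m <- min(i - lo, hi - i)
    stats::median(x[(i - m):(i + m)])
  }, numeric(1))
}

# Literal transcription of the rise/fall hysteresis automaton for a single
# constant sigma: trigger above rise*sigma, extend back past the most recent
# sample <= fall*sigma, extend forward to just before the first sample
# < fall*sigma; merge overlaps; drop short segments.
brute_hysteresis <- function(x, sigma, rise = 6, fall = 1, min_len = 5) {
  n <- length(x)
  segs <- list()
  scan_from <- 1
  for (t in which(x > rise * sigma)) {
    if (t < scan_from) next
    j <- t - 1
    while (j >= 1 && x[j] > fall * sigma) j <- j - 1
    start <- j + 1
    k <- t + 1
    while (k <= n && x[k] >= fall * sigma) k <- k + 1
    end <- k
    if (length(segs) > 0 && start <= segs[[length(segs)]]$end) {
      segs[[length(segs)]]$end <- max(segs[[length(segs)]]$end, end)
    } else {
      segs[[length(segs) + 1]] <- list(start = start, end = end)
    }
    scan_from <- end
  }
  Filter(function(s) s$end - s$start >= min_len, segs)
}

# Exhaustive enumeration of +/-1 walks on a reference for short fragments:
# maximize matches, break ties toward fewer direction changes.
brute_walk_align <- function(frag_letters, ref_letters) {
  m <- length(frag_letters)
  n <- length(ref_letters)
  best <- NULL
  if (m == 1) {
    sc <- vapply(seq_len(n), function(p) sum(frag_letters == ref_letters[p]), numeric(1))
    return(list(score = max(sc), folds = 0, positions = which.max(sc)))
  }
  for (start in seq_len(n)) {
    for (mask in 0:(2^(m - 1) - 1)) {
      dirs <- ifelse(bitwAnd(mask, 2^(0:(m - 2))) > 0, -1L, 1L)
      pos <- cumsum(c(start, dirs))
      if (any(pos < 1 | pos > n)) next
      score <- sum(frag_letters == ref_letters[pos])
      folds <- sum(diff(dirs) != 0)
      key <- c(score, -folds)
      if (is.null(best) || key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <- list(key = key, score = score, folds = folds, positions = pos)
      }
    }
  }
  best
}

# Build a tc_fragment from a letter string with nominal times and weights.
make_fragment <- function(s, norm_cond = NA_real_) {
  lets <- strsplit(s, "")[[1]]
  tunnelcall:::new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                            rep(norm_cond, length(lets)),
                            rep(1, length(lets)))
}

rev_string <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

is_contiguous_read <- function(s, ref) {
  grepl(s, ref, fixed = TRUE) || grepl(rev_string(s), ref, fixed = TRUE)
}
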