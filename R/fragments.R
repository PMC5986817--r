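# Fragment analysis: transition-point (reading-direction) inference by a
# +/-1-step walk alignment against the reference, reference-free unfolding of
# duplicated readouts, and translocation-velocity estimation.

#' Transition-point analysis of a fragment against a reference
#'
#' Aligns the fragment letters to walks on the reference that step exactly
#' one base per letter (the adjacency assumption), maximizing the number of
#' letter matches (ties broken toward fewer direction changes) by dynamic
#' programming over (position, direction) states. Direction changes of the
#' best walk are the fold points; translocation velocity is the
#' inverse-variance-weighted mean of per-stretch least-squares slopes of
#' base position versus letter time over monotone stretches of at least
#' `min_stretch` letters.
#'
#' @param fragment A `tc_fragment` (or character vector of letters, in which
#'   case letter times default to the nominal dwell grid).
#' @param reference Reference sequence (string).
#' @param min_identity Minimum letter identity of the best walk; below it
#'   the fragment is reported unalignable (`$alignable = FALSE`).
#' @param min_stretch Minimum monotone stretch length used for the velocity
#'   fit.
#' @return Object of class `transition_profile`: per-letter `times_ms` and
#'   `positions`, `directions`, `fold_points` (letter indices at which the
#'   direction reverses), `identity`, `velocity` (bases/ms), `velocity_se`,
#'   `alignable`.
#' @export
find_transition_points <- function(fragment, reference, min_identity = 0.6,
                                   min_stretch = 4) {
  f <- if (inherits(fragment, "tc_fragment")) fragment$letters else split_letters(fragment)
  times <- if (inherits(fragment, "tc_fragment")) fragment$times_ms else (seq_along(f) - 0.5) / 1.5
  r <- split_letters(reference)
  m <- length(f)
  n <- length(r)
  if (m < 1L) tc_input_error("fragment must be non-empty")

  # DP over states (position, direction of the step into the letter).
  # Value = matches * BIG - folds, so folds break score ties.
  BIG <- 1e6
  mval <- function(i, p) as.numeric(f[i] == r[p])
  # i = 1: direction undetermined.
  v1 <- vapply(seq_len(n), function(p) mval(1L, p) * BIG, numeric(1))
  if (m == 1L) {
    p <- which.max(v1)
    ident <- mval(1L, p)
    return(structure(
      list(times_ms = times, positions = p, directions = integer(0),
           fold_points = integer(0), identity = ident,
           velocity = NA_real_, velocity_se = NA_real_,
           alignable = ident >= min_identity, start_position = p,
           stretches = list()),
      class = "transition_profile"
    ))
  }
  # val[p, d]: best value ending at position p with last direction d (1=+1, 2=-1)
  val <- matrix(-Inf, n, 2)
  bp <- array(NA_integer_, c(m, n, 2)) # previous direction index (0 = start)
  for (p in seq_len(n)) {
    if (p > 1L) { # step +1 from p-1 (start state)
      cand <- v1[p - 1L] + mval(2L, p) * BIG
      if (cand > val[p, 1L]) { val[p, 1L] <- cand; bp[2L, p, 1L] <- 0L }
    }
    if (p < n) { # step -1 from p+1
      cand <- v1[p + 1L] + mval(2L, p) * BIG
      if (cand > val[p, 2L]) { val[p, 2L] <- cand; bp[2L, p, 2L] <- 0L }
    }
  }
  if (m > 2L) {
    for (i in 3:m) {
      newval <- matrix(-Inf, n, 2)
      for (p in seq_len(n)) {
        sc <- mval(i, p) * BIG
        if (p > 1L) { # arrive with direction +1 from p-1
          prev <- val[p - 1L, ] - c(0, 1) # fold penalty if previous direction was -1
          j <- which.max(prev)
          newval[p, 1L] <- prev[j] + sc
          bp[i, p, 1L] <- j
        }
        if (p < n) { # arrive with direction -1 from p+1
          prev <- val[p + 1L, ] - c(1, 0)
          j <- which.max(prev)
          newval[p, 2L] <- prev[j] + sc
          bp[i, p, 2L] <- j
        }
      }
      val <- newval
    }
  }
  best <- which(val == max(val), arr.ind = TRUE)[1L, ]
  positions <- integer(m)
  directions <- integer(m) # direction of step into letter i (i >= 2)
  p <- best[[1L]]
  d <- best[[2L]]
  positions[m] <- p
  for (i in m:2) {
    directions[i] <- if (d == 1L) 1L else -1L
    pd <- bp[i, p, d]
    p <- p - directions[i]
    d <- if (pd == 0L) NA_integer_ else pd
    positions[i - 1L] <- p
  }
  directions <- directions[-1L]
  score <- sum(f == r[positions])
  identity <- score / m
  fold_points <- which(diff(directions) != 0) + 1L # letter index where new direction starts

  # Monotone stretches: split letter indices at fold points. The velocity is
  # a single weighted least-squares slope of |position| vs time pooled over
  # all stretches of at least `min_stretch` letters (per-stretch intercepts,
  # common slope), so longer stretches carry more weight. Letter times are
  # quantized to the calling interval, so residuals can vanish by
  # construction; the residual variance is floored at the quantization
  # variance (interval^2/12 per letter) to keep the slope's standard error
  # honest.
  bounds <- c(1L, fold_points, m + 1L)
  stretches <- lapply(seq_len(length(bounds) - 1L), function(k) bounds[k]:(bounds[k + 1L] - 1L))
  stretches <- Filter(function(st) length(st) >= min_stretch, stretches)
  if (length(stretches) > 0) {
    sxx <- 0; sxy <- 0
    for (st in stretches) {
      tt <- times[st]
      pp <- positions[st] * sign(positions[st][length(st)] - positions[st][1L])
      sxx <- sxx + sum((tt - mean(tt))^2)
      sxy <- sxy + sum((tt - mean(tt)) * (pp - mean(pp)))
    }
    slope <- sxy / sxx
    rss <- 0; npts <- 0L
    for (st in stretches) {
      tt <- times[st]
      pp <- positions[st] * sign(positions[st][length(st)] - positions[st][1L])
      rss <- rss + sum((pp - mean(pp) - slope * (tt - mean(tt)))^2)
      npts <- npts + length(st)
    }
    interval_q <- stats::median(diff(times))
    if (!is.finite(interval_q) || interval_q <= 0) interval_q <- 0.5
    rss <- max(rss, npts * slope^2 * interval_q^2 / 12)
    df <- max(1L, npts - length(stretches) - 1L)
    velocity <- abs(slope)
    velocity_se <- sqrt(rss / df / sxx)
  } else {
    velocity <- NA_real_
    velocity_se <- NA_real_
  }
  fits <- stretches
  structure(
    list(times_ms = times, positions = positions, directions = directions,
         fold_points = fold_points, identity = identity,
         velocity = velocity, velocity_se = velocity_se,
         alignable = identity >= min_identity,
         start_position = positions[1L],
         stretches = fits),
    class = "transition_profile"
  )
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf("Transition profile: %d letters, start position %d, %d fold point(s), identity %.2f\n",
              length(x$positions), x$start_position, length(x$fold_points), x$identity))
  if (!is.na(x$velocity)) {
    cat(sprintf("  velocity %.3f bases/ms (se %.3f)\n", x$velocity, x$velocity_se))
  }
  if (!x$alignable) cat("  (unalignable: identity below the floor)\n")
  invisible(x)
}

# Best mirrored span: for fold index f, the largest j-run with at most
# `max_mismatch` mismatched pairs (s[f+j] vs s[f-j]), trimmed to end on a
# match. Returns NULL or list(f, m).
find_best_fold <- function(letters, min_span = 3, max_mismatch = 1) {
  L <- length(letters)
  best <- NULL
  for (f in 2:(L - 1L)) {
    mmax <- min(f - 1L, L - f)
    if (mmax < min_span) next
    mm <- 0L
    m <- 0L
    for (j in seq_len(mmax)) {
      if (letters[f + j] != letters[f - j]) {
        mm <- mm + 1L
        if (mm > max_mismatch) break
      }
      m <- j
    }
    while (m >= 1L && letters[f + m] != letters[f - m]) m <- m - 1L
    if (m >= min_span) {
      if (is.null(best) || m > best$m) best <- list(f = f, m = m)
    }
  }
  best
}

unfold_once <- function(frag, min_span, max_mismatch) {
  letters <- frag$letters
  L <- length(letters)
  if (L < 2L * min_span + 1L) return(NULL)
  fold <- find_best_fold(letters, min_span, max_mismatch)
  if (is.null(fold)) return(NULL)
  f <- fold$f
  m <- fold$m
  keep_meta <- function(ix, rev_ix = integer(0)) {
    ord <- c(rev(rev_ix), ix)
    new_fragment(letters[ord], rep(NA_real_, length(ord)),
                 frag$norm_cond[ord], frag$weights[ord],
                 frag$segment_id, frag$trace_id, unfolded = TRUE)
  }
  prefix <- seq_len(f)
  cont <- if (f + m < L) (f + m + 1L):L else integer(0)
  if (length(cont) == 0L) return(keep_meta(prefix))
  if (m == f - 1L) {
    # The backtrack consumed the whole prefix: the continuation extends the
    # read beyond the original start, still in the reversed direction.
    return(keep_meta(prefix, rev_ix = cont))
  }
  # The mirror ended mid-fragment: treat the continuation as a re-reversal
  # that first re-reads the backtracked span; drop that duplicate too when
  # it matches.
  dup <- min(m, length(cont))
  redup <- letters[cont[seq_len(dup)]]
  orig <- letters[(f - m + 1L):(f - m + dup)]
  if (sum(redup != orig) <= max_mismatch) {
    cont <- cont[-seq_len(dup)]
  }
  keep_meta(c(prefix, cont))
}

#' Reference-free unfolding of duplicated readouts
#'
#' Searches for a fold letter after which the fragment re-reads the bases
#' just read in reverse (a mirrored span of at least `min_span` letters,
#' allowing at most `max_mismatch` miscalls), drops the duplicated span, and
#' repeats until no fold remains (every accepted fold strictly shortens the
#' fragment, so the result is a fixed point and unfolding is idempotent).
#' Fragments without a detectable mirrored span are returned unchanged.
#'
#' @param fragment A `tc_fragment` or character vector of letters.
#' @param min_span Minimum mirrored-span length.
#' @param max_mismatch Maximum mismatches tolerated across a mirrored span.
#' @return The linearized `tc_fragment` (letter times are dropped once a
#'   fold has been removed, since the remaining letters are no longer a
#'   single time-ordered pass).
#' @examples
#' unfold_palindrome("TGAGGGAGT")$seq # folded read of TGAGG
#' @export
unfold_palindrome <- function(fragment, min_span = 3, max_mismatch = 1) {
  frag <- if (inherits(fragment, "tc_fragment")) {
    fragment
  } else {
    lets <- split_letters(fragment)
    new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                 rep(NA_real_, length(lets)), rep(1, length(lets)))
  }
  repeat {
    nxt <- unfold_once(frag, min_span, max_mismatch)
    if (is.null(nxt)) return(frag)
    frag <- nxt
  }
}

#' Read-length distribution of called fragments
#'
#' The read length of a fragment is the number of distinct base molecules it
#' visited: the count of distinct reference positions of its best
#' transition-point walk. Two quality filters apply, both consequences of
#' the single-molecule picture: fragments whose source segment lasted longer
#' than a full-length translocation plausibly can (`max_residence_ms`,
#' default 1.5 nominal dwells per admissible base — longer segments are
#' almost surely two molecules piled into one event) and fragments the walk
#' cannot align (identity below the floor) are excluded.
#'
#' @param fragments A `tc_fragments` list (fragments carry their source
#'   segment duration when produced by [call_fragments()]).
#' @param reference Reference sequence for the walk alignment.
#' @param max_residence_ms Residence-time cut (ms); `Inf` disables it.
#' @param min_identity Walk identity floor (see [find_transition_points()]).
#' @return A list with `lengths` (per-fragment read lengths), `histogram`
#'   (data frame of `read_length`, `count` over the observed support),
#'   `n_excluded_residence`, `n_excluded_unalignable`.
#' @export
read_length_histogram <- function(fragments, reference,
                                  max_residence_ms = 12 * 0.667 * 1.5,
                                  min_identity = 0.6) {
  durs <- vapply(fragments, function(f) f$duration_ms %||% NA_real_, numeric(1))
  keep <- is.na(durs) | durs <= max_residence_ms
  lengths <- integer(0)
  n_una <- 0L
  for (f in fragments[keep]) {
    p <- find_transition_points(f, reference, min_identity = min_identity)
    if (isTRUE(p$alignable)) {
      lengths <- c(lengths, length(unique(p$positions)))
    } else {
      n_una <- n_una + 1L
    }
  }
  counts <- tabulate(lengths, nbins = max(lengths, 1L))
  list(
    lengths = lengths,
    histogram = data.frame(read_length = seq_along(counts), count = counts),
    n_excluded_residence = sum(!keep),
    n_excluded_unalignable = n_una
  )
}

#' Pooled translocation-velocity estimate
#'
#' Inverse-variance-weighted mean of per-profile velocities with a seeded
#' bootstrap percentile confidence interval.
#'
#' @param profiles List of `transition_profile` objects.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return Object of class `velocity_estimate`: `$velocity` (bases/ms),
#'   `$ci`, `$n`.
#' @export
estimate_velocity <- function(profiles, n_boot = 1000, seed = 1, conf = 0.95) {
  keep <- Filter(function(p) isTRUE(p$alignable) && is.finite(p$velocity), profiles)
  if (length(keep) < 5L) {
    tc_insufficient("need >= 5 alignable profiles with a velocity fit (got %d)", length(keep))
  }
  v <- vapply(keep, `[[`, numeric(1), "velocity")
  se <- vapply(keep, `[[`, numeric(1), "velocity_se")
  w <- 1 / pmax(se, 1e-6)^2
  est <- sum(w * v) / sum(w)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(length(v), replace = TRUE)
      sum(w[ix] * v[ix]) / sum(w[ix])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  structure(
    list(velocity = est,
         ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
         n = length(keep), per_profile = data.frame(velocity = v, se = se)),
    class = "velocity_estimate"
  )
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("Translocation velocity: %.3f bases/ms (95%% CI %.3f-%.3f, n = %d profiles)\n",
              x$velocity, x$ci[1L], x$ci[2L], x$n))
  invisible(x)
}
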