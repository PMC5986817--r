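# Greedy overlap-consensus assembly of short fragments, per-position
# coverage/conductance profiles (heat-map tables), and a plurality-consensus
# error diagnostic.

frag_letters <- function(f) {
  if (inherits(f, "tc_fragment")) f$letters else split_letters(f)
}

# All candidate overlaps of b (letters) against a (letters) at a given
# orientation; offset = start of b minus 1 in a's coordinates (may be
# negative). Returns data frame of offset, length, mismatches.
overlap_candidates <- function(a, b, min_overlap) {
  La <- length(a)
  Lb <- length(b)
  offs <- (-Lb + min_overlap):(La - min_overlap)
  res <- lapply(offs, function(o) {
    lo <- max(1L, o + 1L)
    hi <- min(La, o + Lb)
    len <- hi - lo + 1L
    if (len < min_overlap) return(NULL)
    mm <- sum(a[lo:hi] != b[(lo - o):(hi - o)])
    c(offset = o, length = len, mismatches = mm)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) data.frame(offset = integer(0), length = integer(0), mismatches = integer(0))
  else as.data.frame(res)
}

#' Best overlap between two fragments
#'
#' Maximal-length overlap of `f2` against `f1` over both orientations of
#' `f2` (reversed means reversed letter order, never complemented — the
#' tunneling read carries base identity, not strand chemistry). Ties are
#' broken by fewer mismatches, then by the orientation requiring no
#' reversal, then by the smaller offset.
#'
#' @param f1,f2 `tc_fragment` objects or letter strings.
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch Maximum mismatches allowed in the overlap.
#' @return `NULL` if no admissible overlap, else a list with `offset`
#'   (start of `f2` minus 1 in `f1` coordinates; may be negative),
#'   `orientation` (`"forward"` or `"reversed"`), `length`, `mismatches`.
#' @examples
#' best_overlap("AGGTAGTAGGT", "TAGTAGGTTG") # fragments *2 and *4
#' @export
best_overlap <- function(f1, f2, min_overlap = 4, max_mismatch = 0) {
  a <- frag_letters(f1)
  b <- frag_letters(f2)
  if (length(a) < min_overlap || length(b) < min_overlap) return(NULL)
  fwd <- overlap_candidates(a, b, min_overlap)
  rev_ <- overlap_candidates(a, rev(b), min_overlap)
  if (nrow(fwd)) fwd$orientation <- "forward"
  if (nrow(rev_)) rev_$orientation <- "reversed"
  cand <- rbind(fwd, rev_)
  cand <- cand[cand$mismatches <= max_mismatch, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(-cand$length, cand$mismatches,
               cand$orientation != "forward", cand$offset)
  top <- cand[ord[1L], ]
  list(offset = as.integer(top$offset), orientation = top$orientation,
       length = as.integer(top$length), mismatches = as.integer(top$mismatches))
}

# Coverage-aware placement choice used inside the assembler: among
# admissible placements of `b` against the layout letters `a` (exact
# overlap of at least min_overlap, at most max_extension new letters),
# prefer the longest overlap, then the placement whose columns carry the
# most existing coverage (ambiguous fragments join the well-supported
# backbone instead of seeding spurious arms), then the un-reversed
# orientation, then the smaller offset.
best_overlap_cov <- function(a, cov, b, min_overlap, max_mismatch, max_extension) {
  Lb <- length(b)
  best <- NULL
  for (orient in c("forward", "reversed")) {
    bb <- if (orient == "forward") b else rev(b)
    cand <- overlap_candidates(a, bb, min_overlap)
    if (nrow(cand) == 0L) next
    cand <- cand[cand$mismatches <= max_mismatch &
                   (Lb - cand$length) <= max_extension, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      o <- cand$offset[r]
      cols <- max(1L, o + 1L):min(length(a), o + Lb)
      key <- c(cand$length[r], sum(cov[cols]), orient == "forward", -o)
      if (is.null(best) || key_gt(key, best$key)) {
        best <- list(key = key,
                     ov = list(offset = as.integer(o), orientation = orient,
                               length = as.integer(cand$length[r]),
                               mismatches = as.integer(cand$mismatches[r])))
      }
    }
  }
  best
}

key_gt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

# ---- layouts -------------------------------------------------------------

# A layout is a list of placements (fragment, offset, reversed) plus its
# consensus letters. Offsets are 0-based within the layout.
reverse_fragment <- function(f) {
  new_fragment(rev(f$letters), rev(-f$times_ms), rev(f$norm_cond),
               rev(f$weights), f$segment_id, f$trace_id, unfolded = f$unfolded)
}

placement_letters <- function(p) {
  l <- p$frag$letters
  if (p$reversed) rev(l) else l
}

placement_values <- function(p, field) {
  v <- p$frag[[field]]
  if (p$reversed) rev(v) else v
}

layout_consensus <- function(layout, alphabet, model_norm = NULL) {
  len <- max(vapply(layout$placements, function(p) p$offset + fragment_length(p$frag), integer(1)))
  wt <- matrix(0, length(alphabet), len, dimnames = list(alphabet, NULL))
  cnt <- matrix(0L, length(alphabet), len, dimnames = list(alphabet, NULL))
  cond_sum <- matrix(0, length(alphabet), len, dimnames = list(alphabet, NULL))
  cond_sq <- matrix(0, length(alphabet), len, dimnames = list(alphabet, NULL))
  for (p in layout$placements) {
    lets <- placement_letters(p)
    w <- placement_values(p, "weights")
    nc <- placement_values(p, "norm_cond")
    cols <- p$offset + seq_along(lets)
    for (j in seq_along(lets)) {
      li <- match(lets[j], alphabet)
      wt[li, cols[j]] <- wt[li, cols[j]] + (if (is.na(w[j])) 1 else w[j])
      cnt[li, cols[j]] <- cnt[li, cols[j]] + 1L
      if (!is.na(nc[j])) {
        cond_sum[li, cols[j]] <- cond_sum[li, cols[j]] + nc[j]
        cond_sq[li, cols[j]] <- cond_sq[li, cols[j]] + nc[j]^2
      }
    }
  }
  consensus <- vapply(seq_len(len), function(col) {
    w <- wt[, col]
    top <- which(w == max(w))
    if (length(top) > 1L && !is.null(model_norm)) {
      # tie: prefer the letter whose observed normalized conductance agrees
      # best with its model level
      obs <- cond_sum[top, col] / pmax(cnt[top, col], 1L)
      top <- top[which.min(abs(obs - model_norm[alphabet[top]]))]
    }
    alphabet[top[1L]]
  }, character(1))
  list(consensus = consensus, weight = wt, count = cnt,
       cond_sum = cond_sum, cond_sq = cond_sq)
}

# Initial consensus from the k-mer spectrum: count all k-letter windows of
# every fragment in both orientations, start from the most frequent k-mer,
# and extend in both directions by the highest-count continuation until its
# count drops below `stop_frac` of the starting k-mer's count. With coverage
# in the tens, true k-mers dominate error k-mers by an order of magnitude,
# so the walk recovers the molecule without the order dependence of pairwise
# merging. Returns NULL when the spectrum is too shallow to be trusted.
kmer_walk_init <- function(frags, alphabet, k = 6, min_total = 200,
                           min_start = 10, stop_frac = 0.1, max_len = 64) {
  kmers <- unlist(lapply(frags, function(f) {
    l <- f$letters
    n <- length(l)
    if (n < k) return(character(0))
    c(vapply(1:(n - k + 1L), function(i) paste(l[i:(i + k - 1L)], collapse = ""), character(1)),
      vapply(1:(n - k + 1L), function(i) paste(rev(l)[i:(i + k - 1L)], collapse = ""), character(1)))
  }))
  if (length(kmers) < min_total) return(NULL)
  counts <- table(kmers)
  if (max(counts) < min_start) return(NULL)
  start <- names(counts)[which.max(counts)]
  thr <- max(2, stop_frac * max(counts))
  cur <- split_letters(start)
  lookup <- function(key) {
    v <- counts[key]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  # Beam walk: where a competing continuation reaches at least
  # `branch_frac` of the best count (correlated miscalls can locally rival
  # the true branch), both are kept as candidates; the caller picks the
  # candidate that best explains the full fragments. A revisited k-mer
  # signals a repeat loop and ends the walk.
  branch_frac <- 0.5
  beam <- 8L
  extend <- function(states, side) {
    repeat {
      grew <- FALSE
      out <- list()
      for (st in states) {
        cur <- st$cur
        if (isTRUE(st$done) || length(cur) >= max_len) {
          out[[length(out) + 1L]] <- st
          next
        }
        key <- if (side == "right") {
          paste(cur[(length(cur) - k + 2L):length(cur)], collapse = "")
        } else {
          paste(cur[1:(k - 1L)], collapse = "")
        }
        kmers_next <- if (side == "right") paste0(key, alphabet) else paste0(alphabet, key)
        cnt <- lookup(kmers_next)
        ok <- which(cnt >= thr & cnt >= branch_frac * max(cnt) &
                      !kmers_next %in% st$visited)
        if (length(ok) == 0L) {
          st$done <- TRUE
          out[[length(out) + 1L]] <- st
          next
        }
        ok <- ok[order(-cnt[ok])]
        for (x in ok) {
          if (x != ok[1L] && length(states) + length(out) > beam) break
          st2 <- st
          st2$cur <- if (side == "right") c(cur, alphabet[x]) else c(alphabet[x], cur)
          st2$visited <- c(st$visited, kmers_next[x])
          out[[length(out) + 1L]] <- st2
          grew <- TRUE
        }
      }
      states <- out
      if (!grew) break
    }
    states
  }
  states <- list(list(cur = cur, visited = start, done = FALSE))
  states <- extend(states, "right")
  states <- lapply(states, function(st) { st$done <- FALSE; st })
  states <- extend(states, "left")
  cands <- unique(lapply(states, `[[`, "cur"))
  cands[order(vapply(cands, function(x) paste(x, collapse = ""), character(1)))]
}

# Consensus refinement: re-place every fragment independently against the
# fixed consensus letters (both orientations, ungapped, overhanging either
# end by at most `overhang` letters so that a truncated consensus can grow
# back). Placements are ranked by identity over the overlapped columns,
# then matches, then existing coverage of the occupied columns, then the
# un-reversed orientation, then the smaller offset; placements below
# `min_identity` are dropped. Votes are then recounted. Mismatch-tolerant
# re-placement breaks the order dependence of the exact greedy merge: a
# fragment with a single miscall settles at its true offset instead of a
# coincidental exact one.
refine_placements <- function(frags, cons_letters, cov, min_identity,
                              overhang = 2, min_overlap = 4) {
  L <- length(cons_letters)
  # The best placement depends only on the letter sequence, so identical
  # fragments (stacks) are placed once.
  seqs <- vapply(frags, `[[`, character(1), "seq")
  uniq <- !duplicated(seqs)
  best_by_seq <- lapply(which(uniq), function(i) {
    lets <- frags[[i]]$letters
    l <- length(lets)
    best <- NULL
    for (orient in c(FALSE, TRUE)) {
      v <- if (orient) rev(lets) else lets
      for (o in (-overhang):(L - l + overhang)) {
        lo <- max(1L, o + 1L)
        hi <- min(L, o + l)
        ov_len <- hi - lo + 1L
        if (ov_len < min(l, min_overlap)) next
        matches <- sum(cons_letters[lo:hi] == v[(lo - o):(hi - o)])
        # An end-overhanging placement may grow the consensus, so it must
        # be beyond doubt: its overlapped letters have to match exactly.
        if (ov_len < l && matches < ov_len) next
        key <- c(matches / ov_len, matches, sum(cov[lo:hi]), !orient, -o)
        if (is.null(best) || key_gt(key, best$key)) {
          best <- list(key = key, offset = o, reversed = orient,
                       identity = matches / ov_len)
        }
      }
    }
    best
  })
  names(best_by_seq) <- seqs[uniq]

  placements <- list()
  n_dropped <- 0L
  score_total <- 0
  for (i in seq_along(frags)) {
    best <- best_by_seq[[seqs[i]]]
    if (is.null(best) || best$identity < min_identity) {
      n_dropped <- n_dropped + 1L
      # An unexplained fragment costs more than any accepted placement's
      # mismatches, but a consensus is never rewarded for being longer.
      score_total <- score_total - 0.5 * fragment_length(frags[[i]])
      next
    }
    placements[[length(placements) + 1L]] <- list(frag = frags[[i]],
                                                  offset = best$offset,
                                                  reversed = best$reversed)
    # subtract the mismatch count over the overlapped columns
    score_total <- score_total - (best$key[2L] / best$key[1L] - best$key[2L])
  }
  list(placements = placements, n_dropped = n_dropped, score_total = score_total)
}

# Fitting-alignment edit distance of a read against a consensus: the read
# is consumed in full, the consensus ends are free (the read sits anywhere
# inside it). Unit costs; rows vectorized, with the horizontal pass done as
# a cumulative minimum.
fit_edit_dist <- function(v, cons) {
  n <- length(cons)
  idx <- 0:n
  D <- rep(0, n + 1L)
  for (i in seq_along(v)) {
    t <- pmin(D[1:n] + (v[i] != cons), D[2:(n + 1L)] + 1)
    b <- c(i, t)
    D <- cummin(b - idx) + idx
  }
  min(D)
}

# Parsimony score of a candidate consensus: the negated total edit distance
# of all fragments against it (each read's cost capped at half its length,
# the price of leaving it unexplained), minus a small per-column cost so
# that content-duplicating candidates — which can explain every fragment as
# well as the true sequence does — lose to the shortest equally explanatory
# one. Unlike an ungapped mismatch count, edit distance charges a dwell
# mis-split (one letter too many or too few in a homopolymer run) a single
# unit instead of shifting and discarding the whole read, so competing
# indel variants of the consensus are separated by the full weight of the
# cohort that crosses the run.
consensus_score <- function(frags, letters, min_identity) {
  seqs <- vapply(frags, `[[`, character(1), "seq")
  tab <- table(seqs)
  total <- 0
  for (s in names(tab)) {
    v <- split_letters(s)
    ed <- min(fit_edit_dist(v, letters), fit_edit_dist(rev(v), letters))
    total <- total - min(ed, 0.5 * length(v)) * tab[[s]]
  }
  total - 0.1 * length(letters)
}

# Homopolymer polishing: dwell-based letter multiplicity makes an over- or
# under-called copy inside a run of identical letters the dominant residual
# consensus error, and ungapped re-placement cannot repair an indel. Each
# round proposes deleting one copy of every run of length >= 2 and
# duplicating one copy of every run, accepts the move that most improves the
# total placement score, and stops when no move improves it.
polish_consensus <- function(frags, letters, min_identity, max_iter = 6,
                             max_len = Inf) {
  score_of <- function(cl) consensus_score(frags, cl, min_identity)
  cur <- letters
  cur_score <- score_of(cur)
  for (it in seq_len(max_iter)) {
    r <- rle(cur)
    ends <- cumsum(r$lengths)
    moves <- list()
    for (j in seq_along(r$values)) {
      if (r$lengths[j] >= 2L) moves[[length(moves) + 1L]] <- cur[-ends[j]]
      moves[[length(moves) + 1L]] <- append(cur, r$values[j], after = ends[j])
    }
    # terminal moves: drop a junk end column or grow a lost one
    alpha <- unique(cur)
    moves <- c(moves, list(cur[-1L], cur[-length(cur)]),
               lapply(alpha, function(x) c(x, cur)),
               lapply(alpha, function(x) c(cur, x)))
    # combined moves: an interior indel paired with a terminal letter, so a
    # shifted consensus (extra interior copy but a lost end, or vice versa)
    # is repaired in one step instead of through a worse intermediate
    for (j in seq_along(r$values)) {
      if (r$lengths[j] >= 2L) {
        del <- cur[-ends[j]]
        for (x in alpha) {
          moves[[length(moves) + 1L]] <- c(x, del)
          moves[[length(moves) + 1L]] <- c(del, x)
        }
      }
      ins <- append(cur, r$values[j], after = ends[j])
      moves[[length(moves) + 1L]] <- ins[-1L]
      moves[[length(moves) + 1L]] <- ins[-length(ins)]
    }
    moves <- Filter(function(m) length(m) <= max_len, moves)
    if (length(moves) == 0L) break
    scores <- vapply(moves, score_of, numeric(1))
    if (max(scores) <= cur_score) break
    cur <- moves[[which.max(scores)]]
    cur_score <- max(scores)
  }
  cur
}

# Best window of length `target` within a candidate, by parsimony score.
best_window <- function(frags, letters, target, min_identity) {
  if (length(letters) <= target) {
    return(list(letters = letters,
                score = consensus_score(frags, letters, min_identity)))
  }
  scores <- vapply(seq_len(length(letters) - target + 1L), function(s) {
    consensus_score(frags, letters[s:(s + target - 1L)], min_identity)
  }, numeric(1))
  s <- which.max(scores)
  list(letters = letters[s:(s + target - 1L)], score = scores[s])
}

merge_layouts <- function(la, lb, ov) {
  pb <- lb$placements
  if (ov$orientation == "reversed") {
    Lb <- length(lb$letters)
    pb <- lapply(pb, function(p) {
      list(frag = p$frag,
           offset = Lb - (p$offset + fragment_length(p$frag)),
           reversed = !p$reversed)
    })
  }
  pb <- lapply(pb, function(p) { p$offset <- p$offset + ov$offset; p })
  pa <- la$placements
  shift <- -min(0L, ov$offset)
  if (shift > 0L) {
    pa <- lapply(pa, function(p) { p$offset <- p$offset + shift; p })
    pb <- lapply(pb, function(p) { p$offset <- p$offset + shift; p })
  }
  list(placements = c(pa, pb), letters = NULL)
}

#' Greedy overlap-consensus assembly
#'
#' Filters fragments below `min_fragment_len` letters, unfolds duplicated
#' readouts, collapses identical letter sequences into stacks (the first
#' merges any greedy pass performs, since identical fragments share a
#' full-length overlap), seeds a layout at the most-supported stack, and
#' then repeatedly merges the stack with the best overlap against the
#' growing layout's consensus — longest, then most supporting fragments,
#' then fewest mismatches, then the un-reversed orientation — until no
#' admissible overlap remains (further layouts are seeded from the unused
#' stacks in the same way). The
#' largest layout (most fragments) becomes the consensus profile: per
#' position, the weighted-plurality letter, raw coverage counts, and the
#' mean and sd of the normalized conductances of consensus-matching
#' letters.
#'
#' @param fragments `tc_fragments` list (or list of letter strings).
#' @param min_fragment_len Fragments shorter than this are discarded.
#' @param min_overlap,max_mismatch Overlap admission rule (exact overlaps of
#'   at least 4 letters by default).
#' @param cmodel Optional fitted [conductance_model()], used only to break
#'   plurality ties toward the letter whose conductance level agrees with
#'   its model level.
#' @param orient_to Optional reference sequence; the final consensus is
#'   flipped if its reversal matches the reference better (the assembly
#'   itself is orientation-agnostic). Without it the lexicographically
#'   smaller of the consensus and its reversal is returned.
#' @param unfold Unfold fragments before assembly.
#' @param max_extension Maximum number of new letters a single merge may add
#'   beyond the current layout; larger dangling tails are characteristic of
#'   miscalled fragments and are left unplaced.
#' @param trim_frac Terminal consensus columns whose coverage falls below
#'   `trim_frac` times the maximum coverage are trimmed (mis-placed
#'   erroneous fragments can overhang the true layout with near-zero
#'   support; the heat map reports only well-supported positions). `0`
#'   disables trimming.
#' @param refine_rounds After the greedy layout, the consensus is refined:
#'   every fragment is re-placed against the fixed consensus (ungapped, both
#'   orientations, mismatches allowed, ties toward better-covered columns)
#'   and votes are recounted; repeated this many times. Re-placement breaks
#'   the order dependence of exact greedy merging.
#' @param refine_min_identity Minimum letter identity for a refined
#'   placement; fragments below it are left unplaced.
#' @param target_length Known molecule length in bases, if any (the let-7
#'   analogues are 22-mers). When the raw consensus is longer, it is cropped
#'   to the contiguous window of this length with maximal total coverage,
#'   mirroring the experimental situation in which the target's length is
#'   known even though its sequence is being determined. Overrides
#'   `trim_frac`.
#' @return Object of class `consensus_profile`.
#' @export
greedy_assemble <- function(fragments, min_fragment_len = 5, min_overlap = 4,
                            max_mismatch = 0, cmodel = NULL, orient_to = NULL,
                            unfold = TRUE, trim_frac = 0.1, max_extension = 2,
                            target_length = NULL, refine_rounds = 3,
                            refine_min_identity = 0.7) {
  frags <- lapply(fragments, function(f) {
    if (inherits(f, "tc_fragment")) f else {
      lets <- split_letters(f)
      new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                   rep(NA_real_, length(lets)), rep(1, length(lets)))
    }
  })
  n_in <- length(frags)
  frags <- Filter(function(f) fragment_length(f) >= min_fragment_len, frags)
  n_short <- n_in - length(frags)
  if (length(frags) == 0L) {
    tc_insufficient("no fragments of >= %d letters to assemble (%d discarded)",
                    min_fragment_len, n_short)
  }
  if (unfold) frags <- lapply(frags, unfold_palindrome)
  frags <- Filter(function(f) fragment_length(f) >= min_fragment_len, frags)
  if (length(frags) == 0L) tc_insufficient("no fragments survived unfolding")
  alphabet <- if (!is.null(cmodel)) cmodel$alphabet else sort(unique(unlist(lapply(frags, frag_letters))))
  model_norm <- if (!is.null(cmodel)) norm_means(cmodel) else NULL

  # When the fragment set is deep enough, the initial consensus comes from
  # the k-mer spectrum walk and the greedy merge phase is skipped: the
  # refinement rounds below then lay every fragment out against it. On
  # shallow input (the spectrum cannot be trusted) the layout is built by
  # the seed-and-extend greedy over stacks.
  cands <- if (refine_rounds > 0) kmer_walk_init(frags, alphabet) else NULL
  if (is.null(cands)) {
    main <- greedy_layout(frags, alphabet, model_norm, min_overlap,
                          max_mismatch, max_extension)
  } else {
    # Among beam-walk candidates, keep the consensus that best explains the
    # fragments. With a known molecule length, every candidate is first
    # cropped to its best window of that length: candidates longer than the
    # molecule (e.g. a walk that bridged into the mirror-orientation
    # spectrum through residual folded reads) cannot win on duplicated
    # content.
    if (!is.null(target_length)) {
      wins <- lapply(cands, best_window, frags = frags, target = target_length,
                     min_identity = refine_min_identity)
      init_letters <- wins[[which.max(vapply(wins, `[[`, numeric(1), "score"))]]$letters
    } else if (length(cands) > 1L) {
      scores <- vapply(cands, function(cl) {
        consensus_score(frags, cl, refine_min_identity)
      }, numeric(1))
      init_letters <- cands[[which.max(scores)]]
    } else {
      init_letters <- cands[[1L]]
    }
    main <- list(placements = list(), letters = init_letters)
  }

  # Consensus refinement rounds over all fragments.
  letters_r <- main$letters
  cov_r <- if (length(main$placements) > 0) {
    colSums(layout_consensus(main, alphabet, model_norm)$count)
  } else {
    rep(1, length(letters_r))
  }
  refine_once <- function(letters_r, cov_r) {
    rp <- refine_placements(frags, letters_r, cov_r, refine_min_identity)
    if (length(rp$placements) == 0L) return(NULL)
    offs <- vapply(rp$placements, `[[`, integer(1), "offset")
    shift <- -min(0L, min(offs))
    lapply(rp$placements, function(p) {
      p$offset <- p$offset + shift
      p
    })
  }
  for (r in seq_len(refine_rounds)) {
    pl <- refine_once(letters_r, cov_r)
    if (is.null(pl)) break
    main$placements <- pl
    cons_r <- layout_consensus(main, alphabet, model_norm)
    letters_r <- cons_r$consensus
    cov_r <- colSums(cons_r$count)
  }
  if (length(main$placements) == 0L) {
    tc_insufficient("no fragment could be placed on the consensus")
  }
  if (refine_rounds > 0) {
    if (!is.null(target_length) && length(letters_r) > target_length) {
      letters_r <- best_window(frags, letters_r, target_length,
                               refine_min_identity)$letters
    }
    polished <- polish_consensus(frags, letters_r, refine_min_identity,
                                 max_len = if (is.null(target_length)) Inf
                                           else target_length)
    if (!identical(polished, letters_r)) {
      pl <- refine_once(polished, rep(1, length(polished)))
      if (!is.null(pl)) main$placements <- pl
    }
  }

  flipped <- FALSE
  cons0 <- layout_consensus(main, alphabet, model_norm)
  cons_str <- join_letters(cons0$consensus)
  rev_str <- join_letters(rev(cons0$consensus))
  greedy_assemble_rest(main, cons0, cons_str, rev_str, orient_to, alphabet,
                       model_norm, trim_frac, target_length, n_short,
                       length(frags), flipped, frags, refine_min_identity)
}

# Seed-and-extend greedy layout over stacks of identical (orientation-
# canonicalized) fragment sequences.
greedy_layout <- function(frags, alphabet, model_norm, min_overlap,
                          max_mismatch, max_extension) {
  # Stack fragments that read the same molecule stretch: a read and its
  # reversal are the same stretch seen from the other entry end, so stacks
  # are keyed by the lexicographically smaller of (seq, reversed seq),
  # pooling the support of both entry directions. Each stack's
  # representative orientation is the majority orientation of its members
  # (ties toward the as-given orientation in canonical order).
  seqs <- vapply(frags, function(f) f$seq, character(1))
  keys <- vapply(frags, function(f) {
    r <- join_letters(rev(f$letters))
    if (r < f$seq) r else f$seq
  }, character(1))
  ord <- order(-nchar(keys), keys, seqs)
  frags <- frags[ord]
  seqs <- seqs[ord]
  keys <- keys[ord]
  layouts <- lapply(split(seq_along(frags), factor(keys, levels = unique(keys))), function(ix) {
    grp_seqs <- seqs[ix]
    tab <- sort(table(grp_seqs), decreasing = TRUE)
    rep_seq <- names(tab)[1L]
    members <- lapply(ix, function(i) {
      if (seqs[i] == rep_seq) frags[[i]] else reverse_fragment(frags[[i]])
    })
    list(placements = lapply(members, function(f) list(frag = f, offset = 0L, reversed = FALSE)),
         letters = members[[1L]]$letters)
  })
  names(layouts) <- NULL

  # Seed-and-extend greedy: seed each layout at the most-supported unused
  # stack, then repeatedly merge the stack with the best overlap against the
  # growing layout's consensus (longest, then most members, then fewest
  # mismatches, then the un-reversed orientation). Merging stacks only into
  # a layout — never stack-against-stack — keeps systematically miscalled
  # fragments (which stack together and overlap each other consistently)
  # from chaining into a competing chimeric contig.
  stack_size <- vapply(layouts, function(l) length(l$placements), integer(1))
  unused <- rep(TRUE, length(layouts))
  done <- list()
  while (any(unused)) {
    seed <- which(unused)[which.max(stack_size[unused])]
    unused[seed] <- FALSE
    cur <- layouts[[seed]]
    cur_cons <- layout_consensus(cur, alphabet, model_norm)
    cur$letters <- cur_cons$consensus
    cur_cov <- colSums(cur_cons$count)
    repeat {
      cand <- which(unused)
      if (length(cand) == 0L) break
      best <- NULL
      for (j in cand) {
        # A merge may add at most `max_extension` new letters: erroneous
        # fragments (dropped repeat letters, residual folds) typically
        # attach by a minimal overlap with a long dangling tail, whereas
        # genuine end extension proceeds in small, well-overlapped steps.
        hit <- best_overlap_cov(cur$letters, cur_cov, layouts[[j]]$letters,
                                min_overlap, max_mismatch, max_extension)
        if (is.null(hit)) next
        key <- c(hit$key, stack_size[j])
        if (is.null(best) || key_gt(key, best$key2)) {
          best <- list(j = j, ov = hit$ov, key2 = key)
        }
      }
      if (is.null(best)) break
      cur <- merge_layouts(cur, layouts[[best$j]], best$ov)
      cur_cons <- layout_consensus(cur, alphabet, model_norm)
      cur$letters <- cur_cons$consensus
      cur_cov <- colSums(cur_cons$count)
      unused[best$j] <- FALSE
    }
    done[[length(done) + 1L]] <- cur
  }
  layouts <- done

  sizes <- vapply(layouts, function(l) length(l$placements), integer(1))
  lens <- vapply(layouts, function(l) {
    max(vapply(l$placements, function(p) p$offset + fragment_length(p$frag), integer(1)))
  }, integer(1))
  pick <- order(-sizes, -lens)[1L]
  main <- layouts[[pick]]
  main$letters <- layout_consensus(main, alphabet, model_norm)$consensus
  main
}

# Orientation, cropping/trimming and profile construction shared by the
# spectrum-initialized and greedy-initialized paths.
greedy_assemble_rest <- function(main, cons0, cons_str, rev_str, orient_to,
                                 alphabet, model_norm, trim_frac,
                                 target_length, n_short, n_frags, flipped,
                                 frags, refine_min_identity) {
  flip <- if (!is.null(orient_to)) {
    # orientation score: matches of each orientation against the reference
    sf <- max_alignment_matches(cons0$consensus, split_letters(orient_to))
    sr <- max_alignment_matches(rev(cons0$consensus), split_letters(orient_to))
    sr > sf
  } else {
    rev_str < cons_str
  }
  if (flip) {
    L <- length(cons0$consensus)
    main$placements <- lapply(main$placements, function(p) {
      list(frag = p$frag, offset = L - (p$offset + fragment_length(p$frag)),
           reversed = !p$reversed)
    })
    flipped <- TRUE
  }
  cons <- layout_consensus(main, alphabet, model_norm)

  # Crop to the known molecule length (the maximum-coverage window), or trim
  # weakly supported overhangs at the two ends.
  cov_all <- colSums(cons$count)
  if (!is.null(target_length) && length(cov_all) > target_length) {
    # The window of the known molecule length that best explains the
    # fragments (weakly supported overhang columns force mismatches or
    # dropped placements and lose).
    win_score <- vapply(seq_len(length(cov_all) - target_length + 1L), function(s) {
      consensus_score(frags, cons$consensus[s:(s + target_length - 1L)],
                      refine_min_identity)
    }, numeric(1))
    lo <- which.max(win_score)
    hi <- lo + target_length - 1L
  } else {
    keep <- cov_all >= trim_frac * max(cov_all)
    lo <- which(keep)[1L]
    hi <- which(keep)[sum(keep)]
  }
  if (lo > 1L || hi < length(cov_all)) {
    cons$consensus <- cons$consensus[lo:hi]
    cons$count <- cons$count[, lo:hi, drop = FALSE]
    cons$weight <- cons$weight[, lo:hi, drop = FALSE]
    cons$cond_sum <- cons$cond_sum[, lo:hi, drop = FALSE]
    cons$cond_sq <- cons$cond_sq[, lo:hi, drop = FALSE]
    main$placements <- lapply(main$placements, function(p) {
      p$offset <- p$offset - (lo - 1L)
      p
    })
  }

  count <- cons$count
  coverage <- as.integer(colSums(count))
  ci <- cbind(match(cons$consensus, alphabet), seq_along(cons$consensus))
  mean_nc <- cons$cond_sum[ci] / pmax(cons$count[ci], 1L)
  var_nc <- cons$cond_sq[ci] / pmax(cons$count[ci], 1L) - mean_nc^2
  sd_nc <- sqrt(pmax(var_nc, 0))
  mean_w <- colSums(cons$weight) / pmax(coverage, 1L)

  structure(
    list(
      consensus = join_letters(cons$consensus),
      coverage = coverage,
      base_count = count,
      base_weight = cons$weight,
      mean_norm_cond = mean_nc,
      sd_norm_cond = sd_nc,
      mean_weight = mean_w,
      n_fragments = length(main$placements),
      n_discarded_short = n_short,
      n_unplaced = n_frags - length(main$placements),
      flipped = flipped,
      placements = main$placements
    ),
    class = "consensus_profile"
  )
}

# Best ungapped alignment match count of letter vector `a` against `b` over
# all relative offsets (used only to orient a consensus to a reference).
max_alignment_matches <- function(a, b) {
  best <- 0L
  for (o in (-length(a) + 1L):(length(b) - 1L)) {
    lo <- max(1L, o + 1L)
    hi <- min(length(b), o + length(a))
    if (hi < lo) next
    best <- max(best, sum(b[lo:hi] == a[(lo - o):(hi - o)]))
  }
  best
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("Consensus (%d positions, %d fragments%s):\n  %s\n",
              nchar(x$consensus), x$n_fragments,
              if (x$n_unplaced > 0) sprintf(", %d unplaced", x$n_unplaced) else "",
              x$consensus))
  cat(sprintf("  coverage: min %d, max %d\n", min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' @export
plot.consensus_profile <- function(x, ...) {
  tab <- heatmap_table(x)
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::barplot(tab$coverage, names.arg = tab$consensus_base, border = NA,
                    col = "grey85", xlab = "base position", ylab = "coverage", ...)
  graphics::par(new = TRUE)
  graphics::plot(seq_len(nrow(tab)), tab$mean_norm_conductance, pch = 19,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1.2),
                 col = "firebrick")
  graphics::axis(4)
  graphics::mtext("normalized conductance (G = 1)", side = 4, line = 2.5)
  invisible(x)
}

#' Heat-map table of a consensus profile
#'
#' One row per consensus position (1-based): consensus base, coverage, and
#' the mean and sd of the normalized conductance (guanine = 1) of the
#' letters supporting the consensus.
#'
#' @param profile A `consensus_profile`.
#' @return A data frame with columns `position`, `consensus_base`,
#'   `coverage`, `mean_norm_conductance`, `sd_norm_conductance`.
#' @export
heatmap_table <- function(profile) {
  if (nchar(profile$consensus) == 0L) tc_input_error("empty consensus profile")
  data.frame(
    position = seq_len(nchar(profile$consensus)),
    consensus_base = split_letters(profile$consensus),
    coverage = profile$coverage,
    mean_norm_conductance = profile$mean_norm_cond,
    sd_norm_conductance = profile$sd_norm_cond,
    stringsAsFactors = FALSE
  )
}

#' Plurality-consensus error diagnostic
#'
#' Monte-Carlo estimate of the probability that a plurality vote over
#' `coverage` independent reads misses the true base, when each read is
#' correct with probability `accuracy` and otherwise uniform over
#' `n_alternatives` wrong letters. Ties count as errors (conservative).
#' This is a diagnostic for coverage planning, not a reproduction of any
#' published coverage-error relation.
#'
#' @param coverage Read depth (vectorized).
#' @param accuracy Per-read accuracy.
#' @param n_alternatives Number of wrong letters a miscall can take.
#' @param n_rep Monte-Carlo replicates.
#' @param seed Seed.
#' @return Numeric vector of error probabilities, one per coverage.
#' @export
consensus_error_rate <- function(coverage, accuracy = 0.75, n_alternatives = 2,
                                 n_rep = 1000, seed = 1) {
  with_local_seed(seed, {
    vapply(coverage, function(cov) {
      errs <- vapply(seq_len(n_rep), function(r) {
        reads <- sample.int(n_alternatives + 1L, cov, replace = TRUE,
                            prob = c(accuracy, rep((1 - accuracy) / n_alternatives, n_alternatives)))
        counts <- tabulate(reads, n_alternatives + 1L)
        as.numeric(counts[1L] <= max(counts[-1L]))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
  })
}
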