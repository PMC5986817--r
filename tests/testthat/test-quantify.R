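s7 <- let7_sequences()

test_that("marker specs are derived from variant pairs", {
  spec <- marker_spec(s7[c("let7a", "let7f")])
  expect_equal(spec$marker_position, 12L)
  expect_equal(unname(spec$variant_bases), c("G", "A"))
  spec_c <- marker_spec(s7[c("let7a", "let7c")])
  expect_equal(spec_c$marker_position, 19L)
  expect_error(marker_spec(c(a = "TGA", b = "ACT")), class = "tunnelcall_input_error")
  expect_error(marker_spec(s7[c("let7a", "let7a")]), class = "tunnelcall_input_error")
})

test_that("fragments place on the scaffold with categorized rejections", {
  spec <- marker_spec(s7[c("let7a", "let7f")])
  # exact match at scaffold 12-20, spanning the marker with a G
  p1 <- place_fragment("GTTGTATAG", spec)
  expect_equal(p1$status, "accepted")
  expect_equal(p1$offset, 11L)
  expect_equal(p1$marker_letter, "G")
  # exact match at 13-21, which does not span position 12
  p2 <- place_fragment("TTGTATAGT", spec)
  expect_equal(p2$status, "not_spanning")
  expect_equal(place_fragment("AGTA", spec)$status, "too_short")
  # the let-7f marker neighbourhood reads A at position 12
  p3 <- place_fragment("AGTAGATTG", spec)
  expect_equal(p3$status, "accepted")
  expect_equal(p3$marker_letter, "A")
  expect_equal(place_fragment("AAAAAGGGG", spec)$status, "unalignable")
})

test_that("marker counting is exact arithmetic on clean fragments", {
  spec <- marker_spec(s7[c("let7a", "let7f")])
  frags <- c(rep(list("GTAGGTTGT"), 300), rep(list("GTAGATTGT"), 100))
  q <- count_markers(frags, spec, seed = 1)
  expect_equal(unname(q$counts), c(300, 100))
  expect_equal(unname(q$ratio), c(3, 1))
  expect_equal(q$fraction, 0.75)
  expect_error(count_markers(list("TGAGG"), spec, seed = 1),
               class = "tunnelcall_insufficient_data")
})

test_that("swapping the variant labels swaps counts and inverts the ratio", {
  spec_af <- marker_spec(s7[c("let7a", "let7f")])
  spec_fa <- marker_spec(s7[c("let7f", "let7a")])
  frags <- path_fragments(c(let7a = 0.7, let7f = 0.3), 400, seed = 31)
  q1 <- count_markers(frags, spec_af, seed = 1)
  q2 <- count_markers(frags, spec_fa, seed = 1)
  expect_equal(unname(q1$counts), unname(rev(q2$counts)))
  expect_equal(q1$fraction, 1 - q2$fraction)
})

test_that("acceptance and rejection tallies conserve the input count", {
  spec <- marker_spec(s7[c("let7a", "let7f")])
  frags <- path_fragments(c(let7a = 0.5, let7f = 0.5), 500, seed = 12)
  q <- count_markers(frags, spec, seed = 2)
  expect_equal(sum(q$rejections), q$n_input)
  expect_equal(q$n_input, 500)
})

test_that("charged 3:1 and 1:3 mixtures are recovered symmetrically", {
  # sized so that over two thousand placements are accepted, at which the
  # binomial sampling error of the ratio is comfortably below 10%
  spec <- marker_spec(s7[c("let7a", "let7f")])
  frags31 <- path_fragments(c(let7a = 0.75, let7f = 0.25), 25000, seed = 77)
  q31 <- count_markers(frags31, spec, n_boot = 100, seed = 3)
  expect_gte(sum(q31$counts), 2000)
  expect_lt(abs(q31$ratio[[1]] / q31$ratio[[2]] - 3) / 3, 0.10)
  frags13 <- path_fragments(c(let7a = 0.25, let7f = 0.75), 25000, seed = 78)
  q13 <- count_markers(frags13, spec, n_boot = 100, seed = 3)
  expect_lt(abs(q13$ratio[[2]] / q13$ratio[[1]] - 3) / 3, 0.10)
})

test_that("the mixture heat map reports both marker levels", {
  spec <- marker_spec(s7[c("let7a", "let7f")])
  cm <- conductance_model()
  nm <- c(T = 45 / 102, A = 77 / 102, G = 1)
  mk <- function(s) {
    lets <- strsplit(s, "")[[1]]
    tunnelcall:::new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                              unname(nm[lets]), rep(1, length(lets)))
  }
  frags <- c(rep(list(mk("GTAGGTTGT")), 6), rep(list(mk("GTAGATTGT")), 2))
  hm <- mixture_heatmap(frags, spec, cmodel = cm)
  lv <- hm$marker_levels
  expect_setequal(lv$letter, c("G", "A"))
  expect_equal(lv$mean_norm_conductance[lv$letter == "G"], 1, tolerance = 1e-9)
  expect_equal(lv$mean_norm_conductance[lv$letter == "A"], 77 / 102, tolerance = 1e-9)
  expect_equal(unname(lv$count[lv$letter == "G"]), 6)
  # single-variant input: a single marker level
  hm1 <- mixture_heatmap(rep(list(mk("GTAGGTTGT")), 4), spec, cmodel = cm)
  expect_equal(nrow(hm1$marker_levels), 1)
})

test_that("the marker-weight split of a default-noise mixture is binomial", {
  spec <- marker_spec(s7[c("let7a", "let7f")])
  tr <- simulate_mixture(s7[c("let7a", "let7f")],
                         fractions = c(let7a = 0.75, let7f = 0.25),
                         n_events = 1500, seed = 55)
  det <- detect_pipeline(tr)
  fit <- fit_conductance_model(det$segments)
  frags <- call_fragments(det$segments, fit)
  hm <- mixture_heatmap(frags, spec, cmodel = fit)
  lv <- hm$marker_levels
  n_g <- lv$count[lv$letter == "G"]
  n_a <- lv$count[lv$letter == "A"]
  n <- n_g + n_a
  sigma <- sqrt(n * 0.75 * 0.25)
  # within 3 binomial sigma of the charged split, allowing the small
  # asymmetric loss of marker-run reads discussed in the vignette
  expect_lt(abs(n_g - 0.75 * n), 3 * sigma + 0.05 * n)
})
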