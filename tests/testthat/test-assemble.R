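let7a <- "TGAGGTAGTAGGTTGTATAGTT"

test_that("best_overlap finds the documented fragment overlaps", {
  ov <- best_overlap("AGGTAGTAGGT", "TAGTAGGTTG")
  expect_equal(ov$length, 8)
  expect_equal(ov$offset, 3)
  expect_equal(ov$orientation, "forward")
  expect_equal(ov$mismatches, 0)
  # any fragment against itself: full-length overlap at offset 0
  self <- best_overlap("TGAGG", "TGAGG")
  expect_equal(self$length, 5)
  expect_equal(self$offset, 0)
  # reversed read: overlap only in the reversed orientation
  rv <- best_overlap("TGAGG", "GGAGT")
  expect_equal(rv$orientation, "reversed")
  expect_equal(rv$length, 5)
  expect_null(best_overlap("TGAGG", "TTTTT"))
})

test_that("clean 5-mer tilings reassemble with the expected coverage", {
  win <- lapply(1:18, function(i) substr(let7a, i, i + 4))
  prof <- greedy_assemble(win, orient_to = let7a)
  expect_equal(nchar(prof$consensus), 22)
  expect_equal(prof$coverage, c(1:4, rep(5, 14), 4:1))
  expect_equal(prof$n_fragments, 18)
  # the consensus uses exactly the input window multiset
  out_win <- vapply(1:18, function(i) substr(prof$consensus, i, i + 4), character(1))
  expect_setequal(sort(out_win), sort(unlist(win)))
  # coverage equals the column sums of the base-count matrix
  expect_equal(prof$coverage, as.integer(colSums(prof$base_count)))
})

test_that("longer clean tilings reassemble exactly", {
  w7 <- lapply(1:16, function(i) substr(let7a, i, i + 6))
  w5 <- lapply(1:18, function(i) substr(let7a, i, i + 4))
  prof <- greedy_assemble(c(w7, w7, w5), orient_to = let7a)
  expect_equal(prof$consensus, let7a)
  # a single fragment assembles to itself with coverage one
  one <- greedy_assemble(list("TGAGGTA"))
  expect_equal(nchar(one$consensus), 7)
  expect_true(all(one$coverage == 1))
  expect_error(greedy_assemble(list("TAG")), class = "tunnelcall_insufficient_data")
})

test_that("every input fragment is either placed or reported unplaced", {
  win <- lapply(c(1, 3, 5, 8, 11, 14), function(i) substr(let7a, i, i + 5))
  prof <- greedy_assemble(win, orient_to = let7a)
  expect_equal(prof$n_fragments + prof$n_unplaced, length(win))
  expect_true(all(prof$coverage >= 1))
})

test_that("heat-map rows carry the normalized conductance levels", {
  cm <- conductance_model()
  # noise-free fragments at exactly the model levels
  nm <- c(T = 45 / 102, A = 77 / 102, G = 1)
  frags <- lapply(1:18, function(i) {
    s <- substr(let7a, i, i + 4)
    lets <- strsplit(s, "")[[1]]
    tunnelcall:::new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                              unname(nm[lets]), rep(1, length(lets)))
  })
  prof <- greedy_assemble(frags, cmodel = cm, orient_to = let7a)
  tab <- heatmap_table(prof)
  expect_equal(nrow(tab), nchar(prof$consensus))
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$mean_norm_conductance[r],
                 unname(nm[tab$consensus_base[r]]), tolerance = 1e-9)
  }
  expect_error(heatmap_table(list(consensus = "")), class = "tunnelcall_input_error")
})

test_that("consensus error decreases with coverage at 75% letter accuracy", {
  err <- consensus_error_rate(c(3, 6, 11), accuracy = 0.75, n_rep = 1000, seed = 12)
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("assembly is deterministic", {
  win <- lapply(1:18, function(i) substr(let7a, i, i + 4))
  p1 <- greedy_assemble(win, orient_to = let7a)
  p2 <- greedy_assemble(win, orient_to = let7a)
  expect_identical(p1$consensus, p2$consensus)
  expect_identical(p1$coverage, p2$coverage)
})
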