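mk_row <- function(chrom, pos, pap = c(10, 0), nonpap = c(0, 10),
                   class = "SNP") {
  tibble::tibble(
    marker_class = class, chrom = chrom, pos = as.integer(pos),
    ref = "A", alt = "G", parent1_gt = "0/0", parent2_gt = "1/1",
    pap_p1 = pap[1], pap_nonp1 = pap[2],
    nonpap_p1 = nonpap[1], nonpap_nonp1 = nonpap[2]
  )
}

test_that("the index is the non-P1 read fraction and delta its bulk difference", {
  tbl <- dplyr::bind_rows(
    mk_row("chr1", 100, pap = c(10, 0), nonpap = c(0, 12)), # 0 vs 1
    mk_row("chr1", 200, pap = c(8, 4), nonpap = c(3, 9)), # 1/3 vs 3/4
    mk_row("chr1", 300, pap = c(0, 0), nonpap = c(5, 5)) # zero depth: excluded
  )
  tr <- compute_index(tbl)
  expect_equal(nrow(tr), 2)
  expect_equal(attr(tr, "zero_depth_excluded"), 1)
  expect_equal(tr$index_papilla, c(0, 1 / 3))
  expect_equal(tr$index_nonpapilla, c(1, 3 / 4))
  expect_equal(tr$delta_index, tr$index_nonpapilla - tr$index_papilla)
  # dominant-model expectation: papilla 1/3, non-papilla 1 gives delta 2/3
  tbl2 <- mk_row("chr1", 100, pap = c(20, 10), nonpap = c(0, 30))
  expect_equal(compute_index(tbl2)$delta_index, 2 / 3)
})

test_that("indices and deltas stay in bounds over randomized tables", {
  for (s in 1:25) {
    tr <- compute_index(random_marker_table(s, n_markers = 40))
    expect_true(all(tr$index_papilla >= 0 & tr$index_papilla <= 1))
    expect_true(all(tr$index_nonpapilla >= 0 & tr$index_nonpapilla <= 1))
    expect_true(all(tr$delta_index >= -1 & tr$delta_index <= 1))
    expect_equal(tr$delta_index, tr$index_nonpapilla - tr$index_papilla)
  }
})

test_that("window means are arithmetic marker means; empty windows are flagged", {
  tbl <- dplyr::bind_rows(
    mk_row("chr1", 1000, pap = c(16, 4), nonpap = c(0, 10)), # delta 0.8
    mk_row("chr1", 2000, pap = c(10, 10), nonpap = c(1, 9)) # delta 0.4
  )
  tr <- compute_index(tbl)
  # one window covering both markers
  wt <- window_track(tr, window_size = 5000, step = 5000, chrom_lengths = c(chr1 = 5000))
  expect_equal(nrow(wt), 1)
  expect_equal(wt$mean_delta, 0.6)
  expect_equal(wt$n_markers, 2L)
  # single-marker window: mean of one
  wt1 <- window_track(tr[1, ], window_size = 5000, step = 5000, chrom_lengths = c(chr1 = 5000))
  expect_equal(wt1$mean_delta, 0.8)
  # all-zero track gives all-zero means
  tr0 <- tr
  tr0$delta_index <- 0
  wt0 <- window_track(tr0, window_size = 1000, step = 500, chrom_lengths = c(chr1 = 3000))
  expect_true(all(wt0$mean_delta[!wt0$empty] == 0))
  # trailing windows with no markers are flagged empty, never thresholded
  wtg <- window_track(tr, window_size = 1000, step = 1000, chrom_lengths = c(chr1 = 10000))
  expect_true(any(wtg$empty))
  expect_true(all(is.na(wtg$mean_delta[wtg$empty])))
  expect_error(window_track(tr, window_size = 100, step = 200), "window_size")
})

test_that("interval calling thresholds, merges and locates peaks", {
  # two above-threshold runs separated by a sub-threshold gap
  deltas <- c(0.7, 0.75, 0.1, 0.05, 0.8, 0.9)
  tbl <- dplyr::bind_rows(purrr::map2(
    seq_along(deltas) * 1000, deltas,
    function(p, d) mk_row("chr1", p, pap = c(20, 0), nonpap = c(round(20 * (1 - d)), round(20 * d)))
  ))
  tr <- compute_index(tbl)
  wt <- window_track(tr, window_size = 1000, step = 1000, chrom_lengths = c(chr1 = 6500))
  iv <- call_intervals(wt, tr, threshold = 0.5, min_markers = 1)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$n_windows, c(2L, 2L))
  expect_equal(iv$peak_delta, c(0.75, 0.9))
  # nothing clears the threshold -> empty call set
  none <- call_intervals(wt, tr, threshold = 0.95, min_markers = 1)
  expect_equal(nrow(none), 0)
  # low-marker windows never form intervals
  sparse <- call_intervals(wt, tr, threshold = 0.5, min_markers = 5)
  expect_equal(nrow(sparse), 0)
  expect_error(call_intervals(wt, tr, threshold = 0), "threshold")
})

test_that("negative delta runs are called on absolute value", {
  tbl <- dplyr::bind_rows(purrr::map(
    1:6 * 1000,
    function(p) mk_row("chr1", p, pap = c(2, 18), nonpap = c(19, 1))
  ))
  tr <- compute_index(tbl) # delta approx -0.85
  wt <- window_track(tr, window_size = 2000, step = 1000, chrom_lengths = c(chr1 = 6000))
  iv <- call_intervals(wt, tr, threshold = 0.5, min_markers = 1)
  expect_equal(nrow(iv), 1)
  expect_lt(iv$peak_delta, 0)
})

test_that("swapping bulk labels negates deltas and preserves |delta| intervals", {
  for (s in c(3, 14)) {
    tbl <- random_marker_table(s, n_markers = 50, max_pos = 2e4)
    swapped <- tbl
    swapped$pap_p1 <- tbl$nonpap_p1
    swapped$pap_nonp1 <- tbl$nonpap_nonp1
    swapped$nonpap_p1 <- tbl$pap_p1
    swapped$nonpap_nonp1 <- tbl$pap_nonp1
    tr <- compute_index(tbl)
    trs <- compute_index(swapped)
    expect_equal(trs$delta_index, -tr$delta_index)
    lens <- c(chr1 = 2e4, chr2 = 2e4)
    iv <- call_intervals(
      window_track(tr, 5000, 1000, lens), tr,
      threshold = 0.2, min_markers = 1
    )
    ivs <- call_intervals(
      window_track(trs, 5000, 1000, lens), trs,
      threshold = 0.2, min_markers = 1
    )
    expect_equal(ivs[c("chrom", "start", "end", "n_windows", "n_markers", "peak_pos")],
      iv[c("chrom", "start", "end", "n_windows", "n_markers", "peak_pos")])
    expect_equal(ivs$peak_delta, -iv$peak_delta)
  }
})

test_that("interval calling matches the brute-force enumeration oracle", {
  for (s in 1:20) {
    tbl <- random_marker_table(100 + s, n_markers = sample(5:50, 1), max_pos = 3e4)
    tr <- compute_index(tbl)
    lens <- c(chr1 = 3e4, chr2 = 3e4)
    w <- sample(c(2000, 5000, 8000), 1)
    st <- sample(c(1000, 2000), 1)
    thr <- runif(1, 0.1, 0.6)
    mm <- sample(1:3, 1)
    mine <- call_intervals(window_track(tr, w, st, lens), tr,
      threshold = thr, min_markers = mm
    )
    oracle <- brute_intervals(tr, lens, w, st, thr, mm)
    expect_equal(
      as.data.frame(mine[c("chrom", "start", "end")]),
      as.data.frame(oracle),
      ignore_attr = TRUE
    )
  }
})

test_that("chromosome summaries count threshold markers and locate the argmax", {
  tbl <- dplyr::bind_rows(
    mk_row("chr1", 100, pap = c(10, 0), nonpap = c(9, 1)), # 0.1
    mk_row("chr2", 200, pap = c(10, 0), nonpap = c(4, 6)) # 0.6
  )
  tr <- compute_index(tbl)
  sm <- summarize_chromosomes(tr, threshold = 0.5)
  expect_equal(sm$n_above_threshold[sm$chrom == "chr2"], 1L)
  expect_equal(sm$n_above_threshold[sm$chrom == "chr1"], 0L)
  gl <- glance_chromosome_summary(sm)
  expect_equal(gl$argmax_chrom, "chr2")
  expect_equal(gl$argmax_pos, 200)
  expect_equal(gl$top_count_chrom, "chr2")
  # all-zero track: counts 0, argmax reported as none
  tr0 <- tr
  tr0$delta_index <- 0
  sm0 <- summarize_chromosomes(tr0, threshold = 0.5)
  expect_true(all(sm0$n_above_threshold == 0))
  expect_true(is.na(glance_chromosome_summary(sm0)$argmax_chrom))
})

test_that("track plots build for full, windowed and empty inputs", {
  tbl <- random_marker_table(5, n_markers = 30, max_pos = 2e4)
  tr <- compute_index(tbl)
  wt <- window_track(tr, 5000, 1000, c(chr1 = 2e4, chr2 = 2e4))
  iv <- call_intervals(wt, tr, threshold = 0.2, min_markers = 1)
  p <- plot_delta_track(tr, wt, iv)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".png")
  suppressMessages(ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 72))
  expect_true(file.exists(path) && file.size(path) > 0)
  # empty track renders without crashing
  expect_s3_class(plot_delta_track(tr[0, ]), "ggplot")
})
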