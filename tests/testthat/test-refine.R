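test_that("positive calls use a strict probability threshold", {
  sr <- structure(list(
    windows = data.frame(chrom = "chr1", start = c(0, 500, 1000, 1500),
                         end = c(4000, 4500, 5000, 5500),
                         prob = c(0.3, 0.500, 0.51, 0.9)),
    threshold = 0.5, window = 4000L, step = 500L, bin_size = 10L),
    class = "scan_result")
  sr$windows$positive <- sr$windows$prob > sr$threshold
  expect_equal(sum(sr$windows$positive), 2L)
  merged <- merge_original(sr)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(1000, 5500))
})

test_that("merging unifies overlapping and book-ended windows", {
  w <- intervals(c("chr1", "chr1"), c(0, 500), c(4000, 4500))
  m <- merge_intervals(w)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 4500))

  disj <- intervals(c("chr1", "chr1"), c(0, 10000), c(4000, 14000))
  expect_same_intervals(merge_intervals(disj), disj)

  # book-ended intervals fuse (gap 0)
  be <- intervals(c("chr1", "chr1"), c(0, 4000), c(4000, 8000))
  expect_equal(nrow(merge_intervals(be)), 1L)

  chain <- intervals(rep("chr1", 8), seq(0, 3500, 500), seq(0, 3500, 500) + 4000)
  m <- merge_intervals(chain)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end - m$start, 7500)
})

test_that("interval merging matches a per-base oracle on random sets", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      s <- sample(0:95000, 40)
      x <- intervals("chrZ", s, s + sample(10:5000, 40, replace = TRUE))
      m <- merge_intervals(x)
      expect_identical(naive_coverage(m, 100000L), naive_coverage(x, 100000L))
      # merged output is sorted and strictly separated
      if (nrow(m) > 1L) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    }
  })
})

test_that("the global cutoff is the flat mean over all positive bins", {
  expect_equal(global_cutoff(list(c(1, 1), c(3, 3))), 2)
  expect_equal(global_cutoff(list(rep(0.37, 400))), 0.37)
  withr::with_seed(3, {
    maps <- replicate(100, runif(400), simplify = FALSE)
    expect_equal(global_cutoff(maps), mean(unlist(maps)))
  })
  expect_error(global_cutoff(list()), "no positive windows")
})

test_that("refine_window maps selected bins to genomic intervals", {
  w <- intervals("chr1", 11000, 11040)
  out <- refine_window(w, c(0, 0, 1, 1), cutoff = 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(11020, 11040))

  # ties with the cutoff are excluded (strict inequality)
  expect_equal(nrow(refine_window(w, rep(0.5, 4), cutoff = 0.5)), 0L)

  out <- refine_window(w, c(0, 1, 0, 1), cutoff = 0.5)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(11010, 11030))

  expect_error(refine_window(w, 1:5, cutoff = 0), "length")
})

test_that("refinement agrees with a per-base oracle and is cutoff-monotone", {
  w <- intervals("chrQ", 2000, 6000)
  withr::with_seed(21, {
    sc <- runif(400)
    prev_cov <- Inf
    for (cutoff in c(0.1, 0.5, 0.9)) {
      out <- refine_window(w, sc, cutoff)
      # per-base oracle: a base is refined iff its bin's score > cutoff
      base <- rep(sc > cutoff, each = 10)
      got <- logical(4000)
      for (i in seq_len(nrow(out)))
        got[(out$start[i] - 2000 + 1):(out$end[i] - 2000)] <- TRUE
      expect_identical(got, base)
      cov <- sum(got)
      expect_lte(cov, prev_cov)
      prev_cov <- cov
    }
  })
})

test_that("condense produces refined annotations inside the original footprint", {
  sim <- fx_sim_centered()
  fitted <- fx_model_centered()
  scan <- fx("scan_centered", function()
    scan_genome(fitted, sim$tracks, sim$chrom_sizes))
  ann <- fx("ann_centered", function() condense(scan, fitted, sim$tracks))

  expect_gt(nrow(ann$original), 0L)
  expect_gt(nrow(ann$refined), 0L)
  # refined is a strict sub-footprint of original
  len <- max(sim$chrom_sizes)
  for (ch in names(sim$chrom_sizes)) {
    ro <- ann$original[ann$original$chrom == ch, ]
    rr <- ann$refined[ann$refined$chrom == ch, ]
    if (nrow(rr) == 0L) next
    expect_true(all(naive_coverage(ro, len)[naive_coverage(rr, len)]))
  }
  expect_lt(coverage_ratio(ann$refined, ann$original), 1)
  # 10 bp granularity and valid sorted non-overlapping BED
  expect_true(all(ann$refined$start %% 10 == 0))
  expect_true(all(ann$refined$end %% 10 == 0))
  ord <- order(ann$refined$chrom, ann$refined$start)
  expect_identical(ord, seq_len(nrow(ann$refined)))
  expect_true(all(ann$refined$score >= 0))
})

test_that("condense without positives warns and returns empty annotations", {
  sim <- fx_sim_centered()
  zero <- build_model(model_config(n_filters = 4L), sim$dataset$panel)
  zero$params <- lapply(zero$params, function(w) w * 0)  # constant 0.5 < strict
  scan <- scan_genome(zero, sim$tracks,
                      c(chrS = 20000))
  expect_equal(sum(scan$windows$positive), 0L)
  expect_warning(ann <- condense(scan, zero, sim$tracks), "no positive")
  expect_equal(nrow(ann$refined), 0L)
})

test_that("scan output files are deterministic byte for byte", {
  sim <- fx_sim_centered()
  fitted <- fx_model_centered()
  scan1 <- scan_genome(fitted, sim$tracks, c(chrS = 100000))
  scan2 <- scan_genome(fitted, sim$tracks, c(chrS = 100000))
  expect_identical(scan1$windows, scan2$windows)
  ann1 <- condense(scan1, fitted, sim$tracks)
  ann2 <- condense(scan2, fitted, sim$tracks)
  d <- withr::local_tempdir()
  write_scan_outputs(scan1, ann1, file.path(d, "a"))
  write_scan_outputs(scan2, ann2, file.path(d, "b"))
  for (suffix in c(".windows.tsv", ".original.bed", ".refined.bed",
                   ".gradcam.bedgraph")) {
    fa <- file.path(d, paste0("a", suffix))
    fb <- file.path(d, paste0("b", suffix))
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
  }
})
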