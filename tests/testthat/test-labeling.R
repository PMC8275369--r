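test_that("positive calling requires accessibility AND a histone overlap", {
  starr <- intervals(c("chr1", "chr1"), c(0, 1000), c(100, 1100))
  acc <- intervals(c("chr1", "chr1"), c(50, 1050), c(150, 1200))
  k27 <- intervals("chr1", 90, 95)
  pos <- call_positive_regions(starr, acc, list(k27, empty_intervals()))
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$start, 0)
  expect_equal(pos$end, 100)

  expect_equal(nrow(call_positive_regions(empty_intervals(), acc, list(k27))), 0L)

  # overlapping two histone marks still yields the peak exactly once
  k4 <- intervals("chr1", 10, 40)
  pos2 <- call_positive_regions(starr, acc, list(k27, k4))
  expect_equal(nrow(pos2), 1L)
})

test_that("positive calling is monotone in the histone evidence", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      rnd <- function(n) {
        s <- sort(sample(0:5000, n))
        intervals("chr1", s, s + sample(20:300, n, replace = TRUE))
      }
      starr <- rnd(15); acc <- rnd(10)
      h1 <- rnd(5); h2 <- rnd(5)
      p1 <- call_positive_regions(starr, acc, list(h1))
      p2 <- call_positive_regions(starr, acc, list(h1, h2))
      expect_true(all(paste(p1$start, p1$end) %in% paste(p2$start, p2$end)))
    }
  })
})

test_that("center_and_extend centers on the midpoint and clamps at boundaries", {
  out <- center_and_extend(intervals("chr1", 10000, 10200), chrom_length = 1e6)
  expect_equal(out$start, 8100)
  expect_equal(out$end, 12100)

  out <- center_and_extend(intervals("chr1", 100, 200), chrom_length = 1e6)
  expect_equal(out$start, 0)
  expect_equal(out$end, 4000)

  # right-boundary clamp
  out <- center_and_extend(intervals("chr1", 999000, 999100),
                           chrom_length = 1e6)
  expect_equal(out$end, 1e6)

  centered <- intervals("chr1", 6000, 10000)
  expect_same_intervals(center_and_extend(centered, chrom_length = 1e6),
                        centered)

  expect_error(center_and_extend(intervals("chr1", 0, 10), chrom_length = 1000),
               ">= window length")
})

test_that("negative sampling honours ratio, masks and seed", {
  sizes <- c(chrA = 200000)
  pos <- intervals(rep("chrA", 5), seq(10000, 90000, by = 20000),
                   seq(10000, 90000, by = 20000) + 4000)
  neg <- sample_negatives(sizes, pos, ratio = 10L, seed = 7L)
  expect_equal(nrow(neg), 50L)
  expect_true(all(neg$end - neg$start == 4000))
  expect_false(any(overlaps_any <- encore:::overlaps_any(neg, pos)))

  neg2 <- sample_negatives(sizes, pos, ratio = 10L, seed = 7L)
  expect_identical(neg, neg2)
  neg3 <- sample_negatives(sizes, pos, ratio = 10L, seed = 8L)
  expect_false(identical(neg$start, neg3$start))

  # extra peak sets are masked too
  extra <- intervals("chrA", 100000, 180000)
  neg4 <- sample_negatives(sizes, pos, exclude = list(extra), ratio = 2L,
                           seed = 1L)
  expect_false(any(encore:::overlaps_any(neg4, extra)))

  expect_error(sample_negatives(sizes, pos, ratio = 0L), "ratio")
  expect_error(sample_negatives(sizes, empty_intervals()), "non-empty")
  # a fully masked genome cannot be sampled from
  expect_error(sample_negatives(c(chrA = 10000), intervals("chrA", 0, 10000)),
               "insufficient background")
})

test_that("build_dataset assembles labels, tags and matrices", {
  tracks <- fx_const_tracks(len = 60000L)
  pos <- intervals(c("chr1", "chr1"), c(1000, 9000), c(5000, 13000))
  neg <- intervals(rep("chr1", 20), seq(16000, 54000, by = 2000),
                   seq(16000, 54000, by = 2000) + 4000)
  ds <- build_dataset(tracks, pos, neg, cell_type = "toy")
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(dim(ds$x), c(5L, 400L, 22L))
  expect_equal(sum(ds$label), 2L)
  expect_equal(unique(ds$cell_type), "toy")
  expect_true(all(ds$x[3, , 1] == 3))  # accessibility row of constant track

  expect_warning(ds2 <- build_dataset(tracks, pos, empty_intervals()),
                 "positives only")
  expect_equal(length(ds2$label), 2L)

  # label counts invariant under permutation
  perm <- sample(22L)
  expect_equal(sum(subset_dataset(ds, perm)$label), 2L)
  expect_equal(subset_dataset(ds, perm)$label, ds$label[perm])
})
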