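#' Configuration for the synthetic five-assay genome
#'
#' The generator emulates the canonical epigenetic footprint of an active
#' enhancer: a smooth unimodal peak in chromatin accessibility centered on
#' the enhancer core, and a peak-trough-peak shape in the four histone
#' marks (two flanking bumps outside the core with the background
#' suppressed over the core).  Bumps are Gaussian profiles truncated at
#' 4 standard deviations; the background is exponentiated Gaussian noise
#' smoothed with a 50 bp moving average, giving non-negative,
#' autocorrelated coverage-like values.  All tracks are generated at 10 bp
#' granularity (the resolution at which windows are binned).
#'
#' @param n_positive number of planted enhancers.
#' @param neg_ratio negatives per positive in [simulate_dataset()]
#'   (default 10).
#' @param chrom_lengths named vector of chromosome lengths; by default two
#'   chromosomes sized to give each enhancer ~25 kb of genome.
#' @param enhancer_length length range of enhancer cores in bp
#'   (default c(50, 1500)).
#' @param acc_amplitude accessibility peak amplitude over background
#'   (default 10).
#' @param histone_amplitude flanking histone peak amplitude (default 6).
#' @param trough_depth fraction of background suppressed over the core in
#'   histone tracks (default 0.8).
#' @param flank_offset distance from core edge to flanking histone peak
#'   center in bp (default 300).
#' @param flank_sd standard deviation of flanking bumps in bp (default 150).
#' @param noise_scale standard deviation of the log-background noise
#'   (default 0.5; 0 gives a flat background of 1).
#' @param offset_range positive windows are centered on the core midpoint
#'   plus a uniform offset in `[-offset_range, offset_range]` bp
#'   (default 500).
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_positive = 100L, neg_ratio = 10L,
                       chrom_lengths = NULL,
                       enhancer_length = c(50L, 1500L),
                       acc_amplitude = 10, histone_amplitude = 6,
                       trough_depth = 0.8, flank_offset = 300L,
                       flank_sd = 150L, noise_scale = 0.5,
                       offset_range = 500L, seed = 1L) {
  if (enhancer_length[1L] < 50L || enhancer_length[2L] > 1500L)
    stop("enhancer lengths must lie within [50, 1500] bp")
  if (acc_amplitude <= 0 || histone_amplitude <= 0) stop("amplitudes must be > 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (is.null(chrom_lengths)) {
    per_chrom <- ceiling(n_positive / 2) * 25000
    chrom_lengths <- c(chrS = per_chrom, chrT = per_chrom)
  }
  chrom_lengths <- floor(chrom_lengths / 10) * 10
  structure(list(n_positive = as.integer(n_positive),
                 neg_ratio = as.integer(neg_ratio),
                 chrom_lengths = chrom_lengths,
                 enhancer_length = enhancer_length,
                 acc_amplitude = acc_amplitude,
                 histone_amplitude = histone_amplitude,
                 trough_depth = trough_depth,
                 flank_offset = as.integer(flank_offset),
                 flank_sd = as.integer(flank_sd),
                 noise_scale = noise_scale,
                 offset_range = as.integer(offset_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# smoothed exponentiated Gaussian background at 10 bp bins
sim_background <- function(nbin, noise_scale) {
  if (noise_scale == 0) return(rep(1, nbin))
  z <- rnorm(nbin)
  zs <- as.numeric(stats::filter(z, rep(1 / 5, 5), sides = 2))
  zs[is.na(zs)] <- 0
  exp(noise_scale * zs)
}

# add a truncated Gaussian bump (support +/- 4 sd) to a 10 bp-binned signal
# vector in place-ish; only the covered bins are touched
add_bump <- function(sig, center, sd, amplitude, bin = 10) {
  nbin <- length(sig)
  lo <- max(1L, floor((center - 4 * sd) / bin) + 1L)
  hi <- min(nbin, ceiling((center + 4 * sd) / bin))
  if (lo > hi) return(sig)
  xc <- (lo:hi - 1) * bin + bin / 2
  sig[lo:hi] <- sig[lo:hi] + amplitude * exp(-0.5 * ((xc - center) / sd)^2)
  sig
}

#' Simulate five co-registered signal tracks with planted enhancers
#'
#' Places `n_positive` non-overlapping enhancer cores (uniform lengths in
#' `enhancer_length`, jittered within evenly spaced slots so that cores are
#' well separated), then builds one accessibility and four histone tracks
#' per the shape model described in [sim_config()].  Reproducible for a
#' given seed.
#'
#' @param config a [sim_config()].
#' @param panel the [assay_panel()] naming the five tracks.
#' @return list with `tracks` (named list of [signal_track()]s), `truth`
#'   (interval data.frame of enhancer cores with a `length` column),
#'   `chrom_sizes` and `config`.
#' @export
simulate_tracks <- function(config, panel = assay_panel()) {
  margin <- 4000L
  sizes <- config$chrom_lengths
  n_ch <- length(sizes)
  n_per <- diff(round(seq(0, config$n_positive, length.out = n_ch + 1)))
  slot <- floor((sizes - 2 * margin) / pmax(n_per, 1L))
  if (any(n_per > 0 & slot < 8000))
    stop("enhancers do not fit: < 8 kb of genome per enhancer after margins")
  acc <- attr(panel, "accessibility")
  withr::with_seed(config$seed, {
    truth <- list()
    for (ci in seq_len(n_ch)) {
      if (n_per[ci] == 0L) next
      centers <- margin + (seq_len(n_per[ci]) - 0.5) * slot[ci] +
        runif(n_per[ci], -slot[ci] / 4, slot[ci] / 4)
      len <- round(runif(n_per[ci], config$enhancer_length[1L],
                         config$enhancer_length[2L]) / 10) * 10
      s <- round((centers - len / 2) / 10) * 10
      truth[[ci]] <- intervals(rep(names(sizes)[ci], n_per[ci]), s, s + len)
      truth[[ci]]$length <- len
    }
    truth <- do.call(rbind, truth)
    tracks <- lapply(unclass(panel), function(a) {
      vals <- lapply(names(sizes), function(ch) {
        nbin <- sizes[[ch]] %/% 10L
        bg <- sim_background(nbin, config$noise_scale)
        tr <- truth[truth$chrom == ch, , drop = FALSE]
        sig <- numeric(nbin)
        for (i in seq_len(nrow(tr))) {
          s <- tr$start[i]; e <- tr$end[i]; m <- (s + e) / 2
          if (a == acc) {
            sig <- add_bump(sig, m, max((e - s) / 4, 10), config$acc_amplitude)
          } else {
            sig <- add_bump(sig, s - config$flank_offset, config$flank_sd,
                            config$histone_amplitude)
            sig <- add_bump(sig, e + config$flank_offset, config$flank_sd,
                            config$histone_amplitude)
            core <- (floor(s / 10) + 1L):ceiling(e / 10)
            bg[core] <- bg[core] * (1 - config$trough_depth)
          }
        }
        S4Vectors::Rle(values = bg + sig, lengths = rep(10L, nbin))
      })
      names(vals) <- names(sizes)
      signal_track(vals, assay = a)
    })
  })
  names(tracks) <- unclass(panel)
  class(truth) <- c("intervals", "data.frame")
  list(tracks = tracks, truth = truth, chrom_sizes = sizes, config = config)
}

#' Simulate a labeled training dataset with ground truth
#'
#' Generates tracks with [simulate_tracks()], centers one positive 4 kb
#' window on each enhancer core (shifted by a uniform offset of up to
#' `offset_range` bp), samples `neg_ratio` background windows per positive
#' (touching neither a core nor a positive window), and extracts all input
#' matrices.
#'
#' @param config a [sim_config()].
#' @param panel the [assay_panel()].
#' @return list with `dataset` (a `labeled_dataset`), `truth`, `tracks`,
#'   `chrom_sizes` and `config`.
#' @export
simulate_dataset <- function(config, panel = assay_panel()) {
  sim <- simulate_tracks(config, panel)
  sizes <- sim$chrom_sizes
  offsets <- withr::with_seed(config$seed + 1L, {
    round(runif(nrow(sim$truth), -config$offset_range,
                config$offset_range) / 10) * 10
  })
  mid <- interval_midpoint(sim$truth)
  start <- floor((mid + offsets - 2000) / 10) * 10
  start <- pmax(0, pmin(start, unname(sizes[sim$truth$chrom]) - 4000))
  positives <- intervals(sim$truth$chrom, start, start + 4000)
  negatives <- sample_negatives(sizes, positives,
                                exclude = list(sim$truth[, c("chrom", "start", "end")]),
                                ratio = config$neg_ratio, length = 4000L,
                                seed = config$seed + 2L, align = 10L)
  dataset <- build_dataset(sim$tracks, positives, negatives, panel,
                           cell_type = "synthetic")
  list(dataset = dataset, truth = sim$truth, tracks = sim$tracks,
       chrom_sizes = sizes, config = config)
}

#' Write simulated tracks and truth to disk
#'
#' Writes one bedGraph per assay, the ground-truth cores as BED and a
#' chromosome-sizes table.
#'
#' @param sim result of [simulate_tracks()] or [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (a in names(sim$tracks)) {
    p <- file.path(dir, paste0(a, ".bedGraph"))
    parts <- lapply(names(sim$tracks[[a]]$values), function(ch) {
      r <- sim$tracks[[a]]$values[[ch]]
      ends <- cumsum(S4Vectors::runLength(r))
      data.frame(chrom = ch, start = ends - S4Vectors::runLength(r),
                 end = ends, score = signif(S4Vectors::runValue(r), 6))
    })
    write_bedgraph(do.call(rbind, parts), p)
    paths[a] <- p
  }
  paths["truth"] <- file.path(dir, "truth.bed")
  write_bed(sim$truth, paths[["truth"]])
  paths["chrom_sizes"] <- file.path(dir, "chrom.sizes")
  data.table::fwrite(data.frame(names(sim$chrom_sizes),
                                format(unname(sim$chrom_sizes),
                                       scientific = FALSE, trim = TRUE)),
                     paths[["chrom_sizes"]], sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
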