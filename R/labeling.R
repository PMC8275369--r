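#' Call positive (active enhancer) regions from peak overlaps
#'
#' A STARR-seq peak is labeled an active enhancer when it overlaps (by at
#' least one base) both an accessibility peak and a peak of at least one
#' active histone enhancer mark.  Each STARR-seq peak is returned at most
#' once, in input order.
#'
#' @param starr STARR-seq peak intervals.
#' @param accessibility chromatin-accessibility (ATAC/DNase) peak intervals.
#' @param histone_sets list of histone-mark peak interval sets.
#' @return the subset of `starr` called positive.
#' @export
call_positive_regions <- function(starr, accessibility, histone_sets) {
  if (nrow(starr) == 0L) return(empty_intervals())
  acc_hit <- overlaps_any(starr, accessibility)
  his_hit <- rep(FALSE, nrow(starr))
  for (hs in histone_sets) his_hit <- his_hit | overlaps_any(starr, hs)
  out <- starr[acc_hit & his_hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intervals", "data.frame")
  out
}

#' Extend intervals to a fixed length about their midpoints
#'
#' Each interval is replaced by a `length`-bp window centered on its
#' midpoint (`floor((start + end) / 2)`).  Windows that would extend past a
#' chromosome boundary are shifted minimally inward so that every output
#' window is fully inside `[0, chrom_length)`.
#'
#' @param x interval data.frame.
#' @param length target window length (default 4000).
#' @param chrom_length chromosome length(s): a single number or a named
#'   vector indexed by chromosome.
#' @return interval data.frame of fixed-length windows, same row count.
#' @export
center_and_extend <- function(x, length = 4000L, chrom_length) {
  if (nrow(x) == 0L) return(empty_intervals())
  clen <- if (is.null(names(chrom_length))) rep(chrom_length, nrow(x))
          else unname(chrom_length[x$chrom])
  if (any(is.na(clen))) stop("chromosome length missing for some intervals")
  if (any(clen < length)) stop("chrom_length must be >= window length")
  mid <- interval_midpoint(x)
  start <- mid - length %/% 2
  start <- pmax(0, pmin(start, clen - length))
  intervals(x$chrom, start, start + length)
}

#' Sample negative background windows
#'
#' Draws fixed-length windows uniformly from the genome, rejecting any
#' window that overlaps a positive region or any of the input peak sets
#' (the "background" is the genome minus all peak evidence).  The draw is
#' reproducible for a given seed.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param positives positive intervals (must be non-empty).
#' @param exclude optional list of further interval sets to mask (e.g. the
#'   raw STARR-seq and accessibility peaks).
#' @param ratio negatives per positive (default 10).
#' @param length window length (default 4000).
#' @param seed integer seed.
#' @param align round sampled window starts down to a multiple of this
#'   (default 1 = no alignment); aligning to the bin size keeps genomic
#'   bins on a shared 10 bp grid.
#' @return interval data.frame of `ratio * nrow(positives)` windows.
#' @export
sample_negatives <- function(chrom_sizes, positives, exclude = list(),
                             ratio = 10L, length = 4000L, seed = 1L,
                             align = 1L) {
  if (ratio < 1L) stop("ratio must be >= 1")
  if (nrow(positives) == 0L) stop("positives must be non-empty")
  mask <- merge_intervals(do.call(rbind, c(list(positives[, c("chrom", "start", "end")]),
                                           lapply(exclude, function(e)
                                             e[, c("chrom", "start", "end"), drop = FALSE]))))
  n_needed <- ratio * nrow(positives)
  usable <- chrom_sizes[chrom_sizes >= length]
  if (!length(usable)) stop("no chromosome long enough for a window")
  withr::with_seed(seed, {
    got <- empty_intervals()
    tries <- 0L
    while (nrow(got) < n_needed) {
      tries <- tries + 1L
      if (tries > 200L)
        stop("insufficient background space to sample ", n_needed, " negatives")
      n_draw <- 2L * (n_needed - nrow(got)) + 10L
      ch <- sample(names(usable), n_draw, replace = TRUE,
                   prob = usable - length + 1)
      st <- floor(runif(n_draw) * (usable[ch] - length + 1))
      if (align > 1L) st <- floor(st / align) * align
      cand <- intervals(ch, st, st + length)
      keep <- !overlaps_any(cand, mask)
      got <- rbind(got, cand[keep, , drop = FALSE])
    }
    got <- got[seq_len(n_needed), , drop = FALSE]
  })
  rownames(got) <- NULL
  class(got) <- c("intervals", "data.frame")
  got
}

#' Assemble a labeled window dataset
#'
#' Extracts the 5 x 400 input matrix for every positive and negative window
#' and attaches labels and grouping tags (cell type, chromosome) used by
#' the grouped cross-validation schemes.
#'
#' @param tracks named list of [signal_track()]s covering all windows.
#' @param positives,negatives fixed-length window intervals.
#' @param panel an [assay_panel()].
#' @param cell_type cell-type tag recorded per window.
#' @param bin_size bin width in bp (default 10).
#' @return a `labeled_dataset`: list with `x` (array `5 x 400 x n`),
#'   `label` (0/1), `chrom`, `cell_type`, `windows`, `panel`.
#' @export
build_dataset <- function(tracks, positives, negatives, panel = assay_panel(),
                          cell_type = "unknown", bin_size = 10L) {
  if (nrow(negatives) == 0L)
    warning("no negative windows; dataset contains positives only")
  win <- rbind(positives[, c("chrom", "start", "end")],
               negatives[, c("chrom", "start", "end")])
  label <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  if (nrow(win) == 0L) stop("no windows supplied")
  wsize <- win$end[1L] - win$start[1L]
  nb <- wsize %/% bin_size
  x <- array(0, dim = c(5L, nb, nrow(win)))
  aligned <- all(win$start %% bin_size == 0)
  if (aligned) {
    # bin each chromosome once and slice windows out of the binned grid
    for (ch in unique(win$chrom)) {
      idx <- which(win$chrom == ch)
      Xf <- windows_input_matrix(tracks, win[idx, , drop = FALSE], panel,
                                 bin_size, wsize)
      for (j in seq_along(idx)) x[, , idx[j]] <- matrix(Xf[j, ], nrow = 5L)
    }
  } else {
    for (i in seq_len(nrow(win)))
      x[, , i] <- extract_window_matrix(tracks, win[i, ], panel,
                                        bin_size = bin_size, window_size = wsize)
  }
  structure(list(x = x, label = label, chrom = win$chrom,
                 cell_type = rep(cell_type, nrow(win)),
                 windows = intervals(win$chrom, win$start, win$end),
                 panel = panel, bin_size = bin_size),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", dim(x$x)[3L], "windows (",
      sum(x$label == 1L), "positive /", sum(x$label == 0L), "negative ),",
      dim(x$x)[1L], "x", dim(x$x)[2L], "matrices\n")
  invisible(x)
}

#' Subset a labeled dataset by window index
#'
#' @param dataset a `labeled_dataset`.
#' @param idx integer or logical index over windows.
#' @return the subsetted `labeled_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(x = dataset$x[, , idx, drop = FALSE],
                 label = dataset$label[idx],
                 chrom = dataset$chrom[idx],
                 cell_type = dataset$cell_type[idx],
                 windows = dataset$windows[idx, , drop = FALSE],
                 panel = dataset$panel, bin_size = dataset$bin_size),
            class = "labeled_dataset")
}

# flatten the window array to the n x 2000 matrix the C++ backend consumes
# (each row is one 5 x 400 matrix flattened column-major)
dataset_matrix <- function(dataset) {
  d <- dim(dataset$x)
  t(matrix(dataset$x, nrow = d[1L] * d[2L], ncol = d[3L]))
}

window_matrix_row <- function(m) matrix(as.numeric(m), nrow = 1L)
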