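#' Genome-wide sliding-window scan
#'
#' Tiles every chromosome with 4 kb windows at 500 bp steps, extracts the
#' 5 x 400 input matrix for each window and scores it with the classifier.
#' Windows with probability strictly greater than the threshold are flagged
#' positive.
#'
#' @param model a trained `enhancer_cnn`.
#' @param tracks named list of [signal_track()]s (one per panel assay).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window,step window size and step in bp (defaults 4000 / 500).
#' @param threshold positive-call probability threshold (default 0.5,
#'   strict inequality).
#' @param bin_size bin width in bp (default 10).
#' @return object of class `"scan_result"`: `windows` data.frame (`chrom`,
#'   `start`, `end`, `prob`, `positive`) sorted by coordinate, plus the
#'   scan settings.
#' @export
scan_genome <- function(model, tracks, chrom_sizes, window = 4000L,
                        step = 500L, threshold = 0.5, bin_size = 10L) {
  missing <- setdiff(unclass(model$panel), names(tracks))
  if (length(missing)) stop("missing track(s): ", paste(missing, collapse = ", "))
  res <- list()
  for (ch in names(chrom_sizes)) {
    win <- sliding_windows(chrom_sizes[[ch]], window, step, chrom = ch)
    if (nrow(win) == 0L) next
    X <- windows_input_matrix(tracks, win, model$panel, bin_size, window)
    prob <- predict(model, X)
    win$prob <- prob
    res[[ch]] <- win
  }
  windows <- if (length(res)) do.call(rbind, res) else {
    w <- empty_intervals(); w$prob <- numeric(0); w
  }
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  windows$positive <- windows$prob > threshold
  structure(list(windows = windows, threshold = threshold, window = window,
                 step = step, bin_size = bin_size),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>", nrow(x$windows), "windows,", sum(x$windows$positive),
      "positive at threshold", x$threshold, "\n")
  invisible(x)
}

# Bin a whole chromosome once per track, then slice windows out of the
# binned vector (valid because window starts are multiples of bin_size).
windows_input_matrix <- function(tracks, win, panel, bin_size, window) {
  if (any(win$start %% bin_size != 0))
    stop("window starts must be multiples of bin_size")
  ch <- win$chrom[1L]
  nb <- window %/% bin_size
  last_end <- max(win$end)
  binned <- lapply(unclass(panel), function(a) {
    r <- chrom_rle(tracks[[a]], ch, last_end)
    starts <- seq(1L, last_end - bin_size + 1L, by = bin_size)
    as.numeric(IRanges::viewMeans(IRanges::Views(r, start = starts,
                                                 width = bin_size)))
  })
  X <- matrix(0, nrow(win), 5L * nb)
  for (i in seq_len(nrow(win))) {
    b0 <- win$start[i] %/% bin_size
    m <- do.call(rbind, lapply(binned, function(v) v[(b0 + 1L):(b0 + nb)]))
    X[i, ] <- as.numeric(m)
  }
  X
}

#' Merge positive windows into the original annotation
#'
#' The union of overlapping and book-ended positive windows forms the
#' *original* (coarse) enhancer prediction set.
#'
#' @param x a `scan_result` or an interval data.frame of positive windows.
#' @return merged interval data.frame.
#' @export
merge_original <- function(x) {
  if (inherits(x, "scan_result"))
    x <- x$windows[x$windows$positive, c("chrom", "start", "end"), drop = FALSE]
  merge_intervals(x)
}

#' Global Grad-CAM score cutoff
#'
#' The refinement cutoff is the arithmetic mean Grad-CAM score over every
#' 10 bp bin of every positive window (unweighted by window), so filtering
#' can only happen after all positive windows have been processed.
#'
#' @param maps list of position-wise score vectors, one per positive window.
#' @return scalar mean score.
#' @export
global_cutoff <- function(maps) {
  if (length(maps) == 0L) stop("no positive windows: cutoff undefined")
  mean(unlist(maps, use.names = FALSE))
}

#' Refine one window to high-importance bins
#'
#' Selects the 10 bp bins whose position-wise score is strictly greater
#' than the global cutoff, maps them to genomic coordinates and merges
#' adjacent selected bins.
#'
#' @param window single-row interval data.frame (the 4 kb window).
#' @param scores position-wise score vector aligned to the window's bins.
#' @param cutoff global score cutoff from [global_cutoff()].
#' @param bin_size bin width in bp (default 10).
#' @return interval data.frame of refined intervals (possibly zero rows);
#'   all boundaries are `bin_size` multiples relative to the window start.
#' @export
refine_window <- function(window, scores, cutoff, bin_size = 10L) {
  nb <- (window$end - window$start) %/% bin_size
  if (length(scores) != nb)
    stop("scores length (", length(scores), ") != number of bins (", nb, ")")
  sel <- scores > cutoff
  if (!any(sel)) return(empty_intervals())
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  intervals(rep(window$chrom, length(keep)),
            window$start + (starts[keep] - 1L) * bin_size,
            window$start + ends[keep] * bin_size)
}

#' Condense positive windows into refined enhancer annotations
#'
#' Runs the full object-detection stage on a scan result: position-wise
#' Grad-CAM maps for every positive window, the global mean-score cutoff,
#' per-window bin selection, and a union across overlapping windows (a
#' genomic bin is kept if selected in any window covering it).  The
#' refined set is therefore always contained in the original annotation's
#' footprint.
#'
#' @param scan a [scan_genome()] result obtained with `model` and `tracks`.
#' @param model the same trained `enhancer_cnn` used for the scan.
#' @param tracks the same named list of [signal_track()]s.
#' @return object of class `"condensed_annotation"`: `original` and
#'   `refined` interval data.frames (the latter with a per-interval mean
#'   Grad-CAM `score` column), the `cutoff`, and per-bin mean scores
#'   (`bin_scores`) for bedGraph export.
#' @export
condense <- function(scan, model, tracks) {
  pos <- scan$windows[scan$windows$positive, , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no positive windows; returning empty annotations")
    return(structure(list(original = empty_intervals(),
                          refined = empty_intervals(), cutoff = NA_real_,
                          bin_scores = NULL),
                     class = "condensed_annotation"))
  }
  bs <- scan$bin_size
  maps <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    m <- extract_window_matrix(tracks, pos[i, ], model$panel, bs, scan$window)
    maps[[i]] <- positionwise_scores(model, m)
  }
  cutoff <- global_cutoff(maps)
  nb <- scan$window %/% bs
  # per genomic bin: mean score across covering windows (for reporting)
  bin_dt <- data.table::data.table(
    chrom = rep(pos$chrom, each = nb),
    start = as.numeric(vapply(pos$start, function(s) s + (0:(nb - 1)) * bs,
                              numeric(nb))),
    score = unlist(maps, use.names = FALSE))
  bin_scores <- bin_dt[, list(score = mean(score)), by = c("chrom", "start")]
  bin_scores$end <- bin_scores$start + bs
  data.table::setorderv(bin_scores, c("chrom", "start"))
  refined_parts <- lapply(seq_len(nrow(pos)), function(i)
    refine_window(pos[i, ], maps[[i]], cutoff, bs))
  refined <- merge_intervals(do.call(rbind, refined_parts))
  if (nrow(refined)) {
    sc <- numeric(nrow(refined))
    bdf <- as.data.frame(bin_scores)
    for (i in seq_len(nrow(refined))) {
      inb <- bdf$chrom == refined$chrom[i] & bdf$start >= refined$start[i] &
        bdf$end <= refined$end[i]
      sc[i] <- mean(bdf$score[inb])
    }
    refined$score <- sc
  }
  structure(list(original = merge_original(scan), refined = refined,
                 cutoff = cutoff,
                 bin_scores = as.data.frame(bin_scores)[, c("chrom", "start",
                                                            "end", "score")]),
            class = "condensed_annotation")
}

#' @export
print.condensed_annotation <- function(x, ...) {
  co <- total_coverage(x$original); cr <- total_coverage(x$refined)
  cat("<condensed_annotation>", nrow(x$original), "original /",
      nrow(x$refined), "refined elements;",
      sprintf("refined coverage %.1f%% of original\n",
              if (co > 0) 100 * cr / co else NA_real_))
  invisible(x)
}

#' Write scan and condensation outputs
#'
#' Writes `<prefix>.windows.tsv` (per-window probabilities),
#' `<prefix>.original.bed`, `<prefix>.refined.bed` (with mean Grad-CAM
#' score in column 5) and `<prefix>.gradcam.bedgraph` (per-bin mean
#' position-wise scores).
#'
#' @param scan a `scan_result`.
#' @param annotation a `condensed_annotation` from [condense()].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_scan_outputs <- function(scan, annotation, prefix) {
  paths <- c(windows = paste0(prefix, ".windows.tsv"),
             original = paste0(prefix, ".original.bed"),
             refined = paste0(prefix, ".refined.bed"),
             gradcam = paste0(prefix, ".gradcam.bedgraph"))
  w <- scan$windows
  w$prob <- sprintf("%.6f", w$prob)
  data.table::fwrite(w, paths[["windows"]], sep = "\t", quote = FALSE)
  write_bed(annotation$original, paths[["original"]])
  write_bed(annotation$refined, paths[["refined"]],
            scores = annotation$refined$score)
  if (!is.null(annotation$bin_scores)) {
    bg <- annotation$bin_scores
    bg$score <- signif(bg$score, 6)
    write_bedgraph(bg, paths[["gradcam"]])
  }
  invisible(paths)
}
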