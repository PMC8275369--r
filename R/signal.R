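#' Assay panels
#'
#' An assay panel fixes the row order of the five epigenetic assays in every
#' window matrix.  Chromatin accessibility must occupy the middle row
#' (row 3 of 5) so that the 5 x 10 convolution kernels see accessibility
#' flanked by histone marks on both sides, maximising cross-assay
#' interaction within a kernel.
#'
#' @param assays character vector of exactly five assay labels.
#' @param accessibility label of the accessibility assay (must sit at
#'   position 3).
#' @return character vector of class `"assay_panel"`.
#' @export
assay_panel <- function(assays = c("H3K4me3", "H3K9ac", "accessibility",
                                   "H3K27ac", "H3K4me1"),
                        accessibility = "accessibility") {
  if (length(assays) != 5L) stop("an assay panel has exactly 5 assays")
  if (anyDuplicated(assays)) stop("assay labels must be unique")
  if (!accessibility %in% assays) stop("accessibility assay not in panel")
  if (match(accessibility, assays) != 3L)
    stop("the accessibility assay must occupy the middle row (position 3)")
  structure(assays, accessibility = accessibility, class = "assay_panel")
}

#' Per-assay signal track
#'
#' A signal track stores non-negative base-resolution coverage for one
#' assay, one run-length-encoded vector ([S4Vectors::Rle]) per chromosome.
#' Positions beyond the stored vectors are defined as 0 (absent coverage).
#'
#' @param values named list of numeric vectors or `Rle` objects, one per
#'   chromosome.
#' @param assay assay label.
#' @return object of class `"signal_track"`.
#' @export
signal_track <- function(values, assay = "signal") {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("per-chromosome values must be named by chromosome")
  vals <- lapply(values, function(v) {
    r <- if (methods::is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    rv <- S4Vectors::runValue(r)
    if (any(!is.finite(rv)) || any(rv < 0))
      stop("signal values must be finite and >= 0")
    r
  })
  structure(list(assay = assay, values = vals), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  lens <- vapply(x$values, length, 0)
  cat("<signal_track>", x$assay, "|", length(lens), "chromosome(s),",
      format(sum(lens), big.mark = ","), "bp\n")
  invisible(x)
}

#' Read a signal track from bedGraph or bigWig
#'
#' Converts interval-valued coverage into a base-resolution run-length
#' track.  Regions without coverage are 0.
#'
#' @param path bedGraph (text) or bigWig file.
#' @param assay assay label.
#' @param format `"auto"` (by extension), `"bedGraph"` or `"bigWig"`.
#' @return a [signal_track()].
#' @export
read_signal_track <- function(path, assay = "signal", format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", tolower(path))) "bigWig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  cov <- GenomicRanges::coverage(gr, weight = "score")
  signal_track(as.list(cov), assay = assay)
}

#' Write a per-bin score vector as bedGraph
#'
#' @param scores data.frame with columns `chrom`, `start`, `end`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(scores, path) {
  data.table::fwrite(scores[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Rle for one chromosome, zero-padded to cover [0, end)
chrom_rle <- function(track, chrom, end) {
  r <- track$values[[chrom]]
  if (is.null(r)) r <- S4Vectors::Rle(numeric(0))
  if (length(r) < end) r <- c(r, S4Vectors::Rle(0, end - length(r)))
  r
}

#' Aggregate signal into fixed-size bins over a window
#'
#' Computes the arithmetic mean of base-resolution signal in consecutive
#' `bin_size`-bp bins across a genomic window.  Uncovered bases contribute
#' 0, so `sum(bins) * bin_size` equals the total signal mass in the window.
#'
#' @param track a [signal_track()].
#' @param window single-row interval data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param bin_size bin width in bp; must divide the window length
#'   (default 10).
#' @return numeric vector of length `(end - start) / bin_size`.
#' @export
bin_signal <- function(track, window, bin_size = 10L) {
  len <- window$end - window$start
  if (len %% bin_size != 0)
    stop("window length (", len, ") not divisible by bin_size (", bin_size, ")")
  r <- chrom_rle(track, window$chrom, window$end)
  nb <- len %/% bin_size
  starts <- window$start + seq_len(nb) * bin_size - bin_size + 1L  # 1-based
  v <- IRanges::Views(r, start = starts, width = bin_size)
  as.numeric(IRanges::viewMeans(v))
}

#' Extract the 5 x 400 input matrix for one window
#'
#' Builds the classifier input: one row per panel assay (accessibility in
#' the middle), one column per 10 bp bin.
#'
#' @param tracks named list of [signal_track()]s keyed by assay label; must
#'   contain every assay in `panel`.
#' @param window single-row interval data.frame of length `window_size`.
#' @param panel an [assay_panel()].
#' @param bin_size bin width in bp (default 10).
#' @param window_size expected window length (default 4000).
#' @return matrix with `length(panel)` rows and `window_size / bin_size`
#'   columns, with assay labels as rownames.
#' @export
extract_window_matrix <- function(tracks, window, panel = assay_panel(),
                                  bin_size = 10L, window_size = 4000L) {
  if ((window$end - window$start) != window_size)
    stop("window must be exactly ", window_size, " bp")
  missing <- setdiff(unclass(panel), names(tracks))
  if (length(missing)) stop("missing track(s): ", paste(missing, collapse = ", "))
  m <- t(vapply(unclass(panel), function(a) bin_signal(tracks[[a]], window, bin_size),
                numeric(window_size %/% bin_size)))
  rownames(m) <- unclass(panel)
  m
}
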