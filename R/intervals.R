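#' Genomic intervals as plain data frames
#'
#' Throughout the package genomic intervals are plain `data.frame`s with
#' columns `chrom` (character), `start`, `end` (0-based, half-open, BED
#' convention) and optionally `score`.  These helpers validate, read and
#' write that representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `0 <= start < end`.
#' @param score optional numeric vector.
#' @return A data.frame with class `"intervals"` prepended.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer(),
                      score = NULL) {
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  class(df) <- c("intervals", "data.frame")
  df
}

empty_intervals <- function() intervals()

#' Read a BED file of intervals
#'
#' Parses a (>= 3 column) tab-separated BED file into an interval
#' data.frame, reporting malformed lines by line number.  Column 5 (BED
#' score) is kept when present.
#'
#' @param path path to an existing BED file.
#' @return interval data.frame in file order (possibly zero rows).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  raw <- raw[!grepl("^(track|browser|#)", raw)]
  if (length(raw) == 0L) return(empty_intervals())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop("line ", which(ncols < 3L)[1L], ": fewer than 3 tab-separated columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", bad[1L], ": non-integer coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("line ", bad[1L], ": invalid interval (end <= start or start < 0)")
  score <- NULL
  if (all(ncols >= 5L)) {
    s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
    if (!anyNA(s)) score <- s
  }
  intervals(chrom, start, end, score)
}

#' Write intervals as BED
#'
#' @param x interval data.frame.
#' @param path output path.
#' @param scores optional numeric vector written as BED column 5 (with a
#'   placeholder name column 4).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, scores = NULL) {
  df <- data.frame(chrom = x$chrom,
                   start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(scores)) {
    df$name <- sprintf("region_%d", seq_len(nrow(df)))
    df$score <- signif(scores, 6)
  }
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-separated file with chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length")[1:2])
  sizes <- as.numeric(df[[2]])
  names(sizes) <- as.character(df[[1]])
  if (any(sizes <= 0)) stop("chromosome lengths must be positive")
  sizes
}

# 0-based half-open -> IRanges (1-based closed) for one chromosome subset
to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

from_iranges <- function(ir, chrom) {
  if (length(ir) == 0L) return(empty_intervals())
  intervals(rep(chrom, length(ir)), IRanges::start(ir) - 1L, IRanges::end(ir))
}

# row-bind interval data.frames and sort by chrom, start
sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("intervals", "data.frame")
  x
}

#' Merge overlapping and book-ended intervals
#'
#' Computes the union of a set of intervals: overlapping or directly
#' adjacent (gap 0) intervals are fused; the result is sorted and
#' non-overlapping.
#'
#' @param x interval data.frame.
#' @return merged interval data.frame.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(empty_intervals())
  out <- lapply(split(x, x$chrom), function(d) {
    from_iranges(IRanges::reduce(to_iranges(d)), d$chrom[1L])
  })
  sort_intervals(do.call(rbind, out))
}

# logical: does each interval in x overlap (>= 1 bp) any interval in y?
overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  hit <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- y[y$chrom == ch, , drop = FALSE]
    if (nrow(yi) == 0L) next
    n <- IRanges::countOverlaps(to_iranges(x[xi, , drop = FALSE]), to_iranges(yi))
    hit[xi] <- n > 0L
  }
  hit
}

# total base coverage of a (merged) interval set
total_coverage <- function(x) {
  if (nrow(x) == 0L) return(0)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

#' Tile a chromosome with fixed-size sliding windows
#'
#' Windows start at multiples of `step`; windows that would extend past the
#' chromosome end are dropped (not clipped), so every window has exactly
#' `window` bases.
#'
#' @param chrom_length chromosome length in bp (> 0).
#' @param window window size in bp (default 4000).
#' @param step step between window starts in bp (default 500).
#' @param chrom chromosome name used in the output (default "chr").
#' @return interval data.frame of windows (possibly zero rows).
#' @export
sliding_windows <- function(chrom_length, window = 4000L, step = 500L,
                            chrom = "chr") {
  if (chrom_length <= 0) stop("chrom_length must be > 0")
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  if (chrom_length < window) return(empty_intervals())
  starts <- seq(0, chrom_length - window, by = step)
  intervals(rep(chrom, length(starts)), starts, starts + window)
}

# midpoint of [s, e): floor((s + e) / 2)
interval_midpoint <- function(x) floor((x$start + x$end) / 2)
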