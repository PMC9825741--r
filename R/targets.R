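#' Capture-target regions
#'
#' A `target_regions` object is a tibble of merged, sorted capture intervals
#' with columns `chrom`, `start`, `end` (0-based half-open), carrying the total
#' captured length as an attribute. Overlapping or book-ended input intervals
#' are merged; intervals are sorted by chromosome then start.
#'
#' @param df A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open coordinates).
#' @return A `target_regions` tibble.
#' @examples
#' target_regions(tibble::tibble(chrom = "chr1",
#'                               start = c(100, 150), end = c(200, 300)))
#' @export
target_regions <- function(df) {
  df <- as_tibble(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop_validation("target regions need columns chrom, start, end")
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop_parse("target coordinates must be integers")
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop_validation(sprintf("target interval with end <= start (row %d: %s:%d-%d)",
                            bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end)))
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
  structure(out,
            total_length = sum(out$end - out$start),
            class = c("target_regions", class(out)))
}

#' Read a capture panel from a BED file
#'
#' Reads the first three columns of a BED file (0-based half-open), merges
#' overlapping and book-ended intervals and returns sorted [target_regions()].
#' Lines starting with `track`, `browser` or `#` are ignored.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A `target_regions` tibble.
#' @export
read_targets <- function(path) {
  check_file_exists(path, "BED file")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) stop_parse(sprintf("no intervals in BED file %s", path))
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    ln <- rows[which(nf < 3L)[1]]
    stop_parse(sprintf("malformed BED line %d in %s: fewer than 3 columns", ln, path))
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_parse(sprintf("malformed BED line %d in %s: non-integer coordinates",
                       rows[bad[1]], path))
  }
  inv <- which(end <= start)
  if (length(inv)) {
    stop_validation(sprintf("BED line %d in %s: end (%d) <= start (%d)",
                            rows[inv[1]], path, end[inv[1]], start[inv[1]]))
  }
  target_regions(tibble(chrom = chrom, start = start, end = end))
}

#' Total captured length of a panel
#' @param x A `target_regions` object.
#' @return Total number of captured bases.
#' @export
target_length <- function(x) {
  stopifnot(inherits(x, "target_regions"))
  attr(x, "total_length")
}

target_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' @export
print.target_regions <- function(x, ...) {
  cat(sprintf("<target_regions> %d regions, %d captured bases\n",
              nrow(x), target_length(x)))
  NextMethod()
}
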