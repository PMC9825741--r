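# Internal helpers: error conditions, coordinate arithmetic, small utilities.
# All genomic coordinates are 0-based half-open internally; user-facing files
# follow their format's native convention (BED 0-based, VCF/TSV 1-based).

onc_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "oncoreads_error"), ...)
}

stop_parse      <- function(msg, ...) onc_abort(msg, "oncoreads_parse_error", ...)
stop_validation <- function(msg, ...) onc_abort(msg, "oncoreads_validation_error", ...)
stop_input      <- function(msg, ...) onc_abort(msg, "oncoreads_input_error", ...)
stop_model      <- function(msg, ...) onc_abort(msg, "oncoreads_model_error", ...)
stop_generation <- function(msg, ...) onc_abort(msg, "oncoreads_generation_error", ...)
stop_bundle     <- function(msg, ...) onc_abort(msg, "oncoreads_bundle_error", ...)
stop_version    <- function(msg, ...) onc_abort(msg, c("oncoreads_version_error",
                                                       "oncoreads_bundle_error"), ...)

BASES <- c("A", "C", "G", "T")

# For each base, the three possible substitution targets (rows indexed by base).
OTHER_BASES <- rbind(
  A = c("C", "G", "T"),
  C = c("A", "G", "T"),
  G = c("A", "C", "T"),
  T = c("A", "C", "G")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

phred_chars <- function(q) {
  # Phred+33 encoding, q an integer vector in 0..93
  intToUtf8(q + 33L, multiple = TRUE)
}

#' Cumulative-overlap lookup table for a set of disjoint sorted intervals
#'
#' Used to count, in O(log k), how many bases of an arbitrary interval fall
#' inside the merged capture space of one chromosome.
#' @noRd
interval_cumulator <- function(starts, ends) {
  stopifnot(all(diff(starts) > 0), all(ends > starts))
  cum_before <- c(0, cumsum(ends - starts))[seq_along(starts)]
  # covered(x): number of covered bases strictly before coordinate x
  function(x) {
    i <- findInterval(x, starts)
    out <- numeric(length(x))
    hit <- i > 0L
    ih <- i[hit]
    out[hit] <- cum_before[ih] + pmin(x[hit], ends[ih]) - starts[ih]
    out
  }
}

#' Count on-target bases of intervals [start, end) against target regions
#' @noRd
on_target_bases <- function(chrom, start, end, targets) {
  tt <- as_tibble(targets)
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tc <- tt[tt$chrom == ch, ]
    if (nrow(tc) == 0L) next
    cov <- interval_cumulator(tc$start, tc$end)
    out[sel] <- cov(end[sel]) - cov(start[sel])
  }
  out
}

check_file_exists <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input(sprintf("%s not found: %s", what, paste(path, collapse = ", ")))
  }
  invisible(path)
}

fasta_seqlengths <- function(reference) {
  check_file_exists(reference, "reference FASTA")
  if (!file.exists(paste0(reference, ".fai"))) Rsamtools::indexFa(reference)
  idx <- Rsamtools::scanFaIndex(reference)
  setNames(GenomicRanges::width(idx), as.character(GenomicRanges::seqnames(idx)))
}

fetch_ref_base <- function(reference, chrom, pos0) {
  if (length(pos0) == 0L) return(character(0))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L))
  unname(as.character(Biostrings::getSeq(Rsamtools::FaFile(reference), gr)))
}
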