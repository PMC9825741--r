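# Decomposition of the target space into disjoint dosage segments.
#
# Each segment carries the cell-population mixture at its span: normal cells
# (fraction 1 - t, copies (1,1)), each tumor clone (fraction t * clonality,
# copies of the innermost CNA of that clone covering the segment, or (1,1)),
# and unassigned background tumor cells (fraction t * (1 - sum clonality),
# copies (1,1)). Nesting within a clone means the inner event replaces the
# outer one on its span.

#' Resolve somatic CNAs into disjoint dosage segments
#'
#' Partitions the capture space at every CNA breakpoint and computes, per
#' segment, the cell-population mixture and the effective (mixture-averaged)
#' copy number of each haplotype. Within one clone, overlapping CNAs must be
#' strictly nested; clonalities are validated by [genome_profile()] semantics
#' (disjoint clones summing to at most 1).
#'
#' @param cnas CNA tibble (see [genome_profile()]); `NULL` or empty for a
#'   copy-neutral genome.
#' @param targets A [target_regions()] panel.
#' @param tumor_content Fraction of tumor cells in the sample, in `[0, 1]`.
#' @param clones Optional clone table (`clone_id`, `clonality`) defining the
#'   full clone universe; defaults to the clones named by `cnas`. Pass the
#'   profile's table when clones carry point mutations but no CNA, so that
#'   they still exist as cell populations.
#' @return A `segment_dosage` tibble: `segment_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `effective_a`, `effective_b`, `coverage_factor`
#'   (= (effective_a + effective_b) / 2) and `expected_log2`. The per-segment
#'   population mixture is attached as attribute `"populations"` (tibble with
#'   `segment_id`, `population`, `fraction`, `copies_a`, `copies_b`).
#' @examples
#' tr <- target_regions(tibble::tibble(chrom = "chr1", start = 0, end = 1000))
#' cna <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
#'                       copies_a = 1L, copies_b = 0L,
#'                       clone_id = "c1", clonality = 1)
#' resolve_segments(cna, tr, tumor_content = 0.8)
#' @export
resolve_segments <- function(cnas, targets, tumor_content, clones = NULL) {
  stopifnot(inherits(targets, "target_regions"),
            tumor_content >= 0, tumor_content <= 1)
  cnas <- validate_cna_table(cnas %||% empty_cnas())
  check_clone_nesting(cnas)
  clones <- clones %||% clone_table(cnas, empty_pms())
  t <- tumor_content

  tgr <- target_granges(targets)
  brk <- tgr
  if (nrow(cnas)) {
    cgr <- GenomicRanges::GRanges(cnas$chrom,
                                  IRanges::IRanges(cnas$start + 1L, cnas$end))
    brk <- c(tgr, IRanges::subsetByOverlaps(cgr, tgr))
  }
  dj <- GenomicRanges::disjoin(brk)
  dj <- IRanges::subsetByOverlaps(dj, tgr, type = "within")
  dj <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(dj))
  seg <- tibble(chrom = as.character(GenomicRanges::seqnames(dj)),
                start = GenomicRanges::start(dj) - 1L,
                end = GenomicRanges::end(dj))
  seg$segment_id <- seq_len(nrow(seg))

  pops <- purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    segment_populations(seg$chrom[i], seg$start[i], seg$end[i],
                        cnas, clones, t, seg$segment_id[i])
  })
  eff <- pops |>
    group_by(.data$segment_id) |>
    summarise(effective_a = sum(.data$fraction * .data$copies_a),
              effective_b = sum(.data$fraction * .data$copies_b),
              .groups = "drop")
  out <- left_join(seg, eff, by = "segment_id") |>
    mutate(coverage_factor = (.data$effective_a + .data$effective_b) / 2,
           expected_log2 = ifelse(.data$coverage_factor > 0,
                                  log2(.data$coverage_factor), -Inf)) |>
    select("segment_id", "chrom", "start", "end", "effective_a",
           "effective_b", "coverage_factor", "expected_log2")
  structure(out, populations = pops,
            tumor_content = t,
            class = c("segment_dosage", class(out)))
}

segment_populations <- function(chrom, start, end, cnas, clones, t, segment_id) {
  rows <- list(tibble(segment_id = segment_id, population = "normal",
                      fraction = 1 - t, copies_a = 1, copies_b = 1))
  if (nrow(clones)) {
    for (k in seq_len(nrow(clones))) {
      cid <- clones$clone_id[k]
      cov <- cnas[cnas$clone_id == cid & cnas$chrom == chrom &
                    cnas$start <= start & cnas$end >= end, ]
      if (nrow(cov)) {
        inner <- cov[which.min(cov$end - cov$start), ]
        ca <- inner$copies_a; cb <- inner$copies_b
      } else {
        ca <- 1; cb <- 1
      }
      rows[[length(rows) + 1L]] <- tibble(
        segment_id = segment_id, population = cid,
        fraction = t * clones$clonality[k], copies_a = ca, copies_b = cb)
    }
  }
  bg <- t * (1 - sum(clones$clonality))
  if (bg > 1e-12 || nrow(clones) == 0) {
    rows[[length(rows) + 1L]] <- tibble(
      segment_id = segment_id, population = "background_tumor",
      fraction = bg, copies_a = 1, copies_b = 1)
  }
  bind_rows(rows)
}

# Within one clone, two CNAs may overlap only if one strictly contains the
# other; identical or partially overlapping intervals are errors.
check_clone_nesting <- function(cnas) {
  if (!nrow(cnas)) return(invisible(TRUE))
  for (cid in unique(cnas$clone_id)) {
    cc <- cnas[cnas$clone_id == cid, ]
    if (nrow(cc) < 2) next
    for (i in seq_len(nrow(cc) - 1L)) {
      for (j in seq(i + 1L, nrow(cc))) {
        if (cc$chrom[i] != cc$chrom[j]) next
        s1 <- cc$start[i]; e1 <- cc$end[i]
        s2 <- cc$start[j]; e2 <- cc$end[j]
        if (e1 <= s2 || e2 <= s1) next  # disjoint
        nested <- (s1 <= s2 && e2 <= e1 && (e1 - s1) > (e2 - s2)) ||
          (s2 <= s1 && e1 <= e2 && (e2 - s2) > (e1 - s1))
        if (!nested) {
          stop_validation(sprintf(
            "clone '%s': CNAs %s:%d-%d and %s:%d-%d overlap without strict nesting",
            cid, cc$chrom[i], s1 + 1L, e1, cc$chrom[j], s2 + 1L, e2))
        }
      }
    }
  }
  invisible(TRUE)
}

segment_of <- function(segments, chrom, pos) {
  # segment_id covering each (chrom, pos); NA when off-segment
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sc <- segments[segments$chrom == ch, ]
    if (!nrow(sc)) next
    i <- findInterval(pos[sel], sc$start)
    ok <- i > 0L & pos[sel] < sc$end[pmax(i, 1L)]
    out[sel[ok]] <- sc$segment_id[i[ok]]
  }
  out
}

#' Validate somatic point mutations against resolved dosage segments
#'
#' Checks that each PM's multiplicity does not exceed the copies of its allele
#' in its own clone at its position (a clone with no CNA at the locus has
#' copies (1,1)), and returns the checked table annotated with the clone's
#' local allele copy number and segment id.
#'
#' @param pms PM tibble (see [genome_profile()]).
#' @param segments Output of [resolve_segments()].
#' @param cnas The CNA tibble used to build `segments`.
#' @return The PM tibble with extra columns `segment_id` and `clone_copies`.
#' @export
validate_pms <- function(pms, segments, cnas) {
  pms <- validate_pm_table(pms %||% empty_pms())
  if (!nrow(pms)) return(mutate(pms, segment_id = integer(), clone_copies = integer()))
  cnas <- validate_cna_table(cnas %||% empty_cnas())
  clone_table(cnas, pms)  # consistency of clonalities across event types
  seg_id <- segment_of(segments, pms$chrom, pms$pos)
  clone_copies <- vapply(seq_len(nrow(pms)), function(i) {
    cov <- cnas[cnas$clone_id == pms$clone_id[i] & cnas$chrom == pms$chrom[i] &
                  cnas$start <= pms$pos[i] & cnas$end > pms$pos[i], ]
    if (!nrow(cov)) return(1L)
    inner <- cov[which.min(cov$end - cov$start), ]
    as.integer(if (pms$allele[i] == "A") inner$copies_a else inner$copies_b)
  }, 1L)
  bad <- which(pms$multiplicity > clone_copies)
  if (length(bad)) {
    i <- bad[1]
    stop_validation(sprintf(
      "PM at %s:%d: multiplicity %d exceeds the %d copies of allele %s in clone '%s'",
      pms$chrom[i], pms$pos[i] + 1L, pms$multiplicity[i], clone_copies[i],
      pms$allele[i], pms$clone_id[i]))
  }
  off <- which(is.na(seg_id))
  if (length(off)) {
    warn(sprintf("%d PM(s) fall outside the capture space and will never be sampled",
                 length(off)))
  }
  mutate(pms, segment_id = seg_id, clone_copies = clone_copies)
}
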