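# Closed-form dosage arithmetic shared by read generation, reports and tests.
#
# For a segment with effective per-haplotype copy numbers eA and eB across the
# cell-population mixture:
#   * a read drawn at the segment comes from haplotype A with probability
#     eA / (eA + eB);
#   * relative coverage scales with (eA + eB) / 2 (the coverage factor), so
#     the expected log2 tumor/control ratio is log2((eA + eB) / 2);
#   * a phased het SNP with its alternate allele on haplotype H has expected
#     alternate-allele fraction eH / (eA + eB);
#   * a point mutation carried by `multiplicity` copies of one allele in a
#     clone of clonality c, in a sample of tumor content t, has expected
#     variant-allele fraction t * c * multiplicity / (eA + eB).

#' Expected allele-level quantities at one locus
#'
#' @param segment One row of a [resolve_segments()] table (or any list with
#'   `effective_a` and `effective_b`).
#' @param snp Optional phased SNP row (needs `phase`).
#' @param pm Optional point-mutation row (needs `multiplicity`, `clonality`).
#' @param tumor_content Tumor content of the sample in `[0, 1]`.
#' @param clonality Clonality of the PM's clone; defaults to `pm$clonality`.
#' @return A one-row tibble: `p_allele_a`, `coverage_factor`,
#'   `expected_baf_alt`, `expected_vaf`, `expected_log2`.
#' @examples
#' tr <- target_regions(tibble::tibble(chrom = "chr1", start = 0, end = 1000))
#' cna <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, copies_a = 1L,
#'                       copies_b = 0L, clone_id = "c1", clonality = 1)
#' seg <- resolve_segments(cna, tr, tumor_content = 0.8)
#' locus_expectation(seg[1, ], snp = list(phase = "B"), tumor_content = 0.8)
#' @export
locus_expectation <- function(segment, snp = NULL, pm = NULL,
                              tumor_content = NA_real_, clonality = NULL) {
  ea <- segment$effective_a
  eb <- segment$effective_b
  tot <- ea + eb
  if (tot <= 0) {
    onc_abort("degenerate locus: total effective copy number is zero (homozygous deletion across all populations)",
              "oncoreads_degenerate_locus")
  }
  baf <- NA_real_
  if (!is.null(snp)) {
    baf <- if (identical(toupper(snp$phase), "A")) ea / tot else eb / tot
  }
  vaf <- NA_real_
  if (!is.null(pm)) {
    cl <- clonality %||% pm$clonality
    stopifnot(!is.na(tumor_content))
    vaf <- tumor_content * cl * pm$multiplicity / tot
  }
  tibble(p_allele_a = ea / tot,
         coverage_factor = tot / 2,
         expected_baf_alt = baf,
         expected_vaf = vaf,
         expected_log2 = log2(tot / 2))
}

#' Expected BAF/VAF/log2 for every event of a profile
#'
#' Resolves dosage segments at the given tumor content and tabulates, per
#' phased SNP, point mutation and CNA segment, the closed-form expectations
#' used by generation reports and acceptance checks.
#'
#' @param profile A [genome_profile()].
#' @param targets A [target_regions()] panel.
#' @param tumor_content Tumor content in `[0, 1]`.
#' @return A tibble with one row per event: `type` ("snp", "pm", "segment"),
#'   locus columns and the expectation columns of [locus_expectation()].
#' @export
expect_profile <- function(profile, targets, tumor_content) {
  stopifnot(inherits(profile, "genome_profile"))
  segments <- resolve_segments(profile$cnas, targets, tumor_content,
                               clones = profile$clones)
  pms <- validate_pms(profile$pms, segments, profile$cnas)
  rows <- list()
  if (nrow(profile$snps)) {
    sid <- segment_of(segments, profile$snps$chrom, profile$snps$pos)
    on <- !is.na(sid)
    if (any(on)) {
      sn <- profile$snps[on, ]
      segs <- segments[match(sid[on], segments$segment_id), ]
      ex <- purrr::map_dfr(seq_len(nrow(sn)), function(i) {
        locus_expectation(segs[i, ], snp = sn[i, ],
                          tumor_content = tumor_content)
      })
      rows$snps <- bind_rows(tibble(type = "snp", chrom = sn$chrom,
                                    pos = sn$pos, id = paste0("snp_", seq_len(nrow(sn))),
                                    segment_id = segs$segment_id)) |>
        bind_cols(ex)
    }
  }
  if (nrow(pms)) {
    on <- !is.na(pms$segment_id)
    if (any(on)) {
      pm <- pms[on, ]
      segs <- segments[match(pm$segment_id, segments$segment_id), ]
      ex <- purrr::map_dfr(seq_len(nrow(pm)), function(i) {
        locus_expectation(segs[i, ], pm = pm[i, ],
                          tumor_content = tumor_content)
      })
      rows$pms <- tibble(type = "pm", chrom = pm$chrom, pos = pm$pos,
                         id = paste0("pm_", pm$clone_id, "_", seq_len(nrow(pm))),
                         segment_id = pm$segment_id) |>
        bind_cols(ex)
    }
  }
  segs_ex <- segments |>
    mutate(type = "segment", pos = .data$start,
           id = paste0("seg_", .data$segment_id),
           p_allele_a = ifelse(.data$effective_a + .data$effective_b > 0,
                               .data$effective_a /
                                 (.data$effective_a + .data$effective_b), NA_real_),
           expected_baf_alt = NA_real_, expected_vaf = NA_real_) |>
    select("type", "chrom", "pos", "id", "segment_id", "p_allele_a",
           "coverage_factor", "expected_baf_alt", "expected_vaf",
           "expected_log2")
  bind_rows(rows$snps, rows$pms, as_tibble(segs_ex))
}
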