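# Germline/somatic genome specification: phased SNPs, clone-resolved
# allele-specific CNAs, somatic point mutations.
#
# Conventions (documented, tested):
#   * haplotypes are called A and B; in a phased VCF genotype a|b the allele
#     left of the bar sits on haplotype A, so GT 0|1 puts the alternate allele
#     on haplotype B and 1|0 on haplotype A;
#   * clonality is the fraction of tumor cells belonging to an event's clone;
#     distinct clone_ids are disjoint tumor-cell populations, so clonalities
#     must be consistent within a clone and sum to at most 1 over all clones;
#   * user-facing CNA/PM tables are 1-based inclusive; internally everything
#     is 0-based half-open.

#' Assemble a germline + somatic genome profile
#'
#' @param snps Tibble of phased heterozygous SNPs: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `phase` ("A" or "B": the haplotype carrying the alternate
#'   allele). Usually from [parse_snps()].
#' @param cnas Tibble of allele-specific somatic CNAs: `chrom`, `start`, `end`
#'   (0-based half-open), `copies_a`, `copies_b`, `clone_id`, `clonality`.
#'   Usually from [read_cna_table()]. May be `NULL`.
#' @param pms Tibble of somatic point mutations: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `allele` ("A"/"B"), `multiplicity`, `clone_id`, `clonality`.
#'   Usually from [read_pm_table()]. May be `NULL`.
#' @param reference Optional FASTA path; when given, `ref` fields are checked
#'   against the genome.
#' @return A `genome_profile` list with validated tibbles `snps`, `cnas`, `pms`.
#' @export
genome_profile <- function(snps = NULL, cnas = NULL, pms = NULL,
                           reference = NULL) {
  snps <- validate_snp_table(snps %||% empty_snps(), reference)
  cnas <- validate_cna_table(cnas %||% empty_cnas())
  pms <- validate_pm_table(pms %||% empty_pms(), reference)
  clones <- clone_table(cnas, pms)
  structure(list(snps = snps, cnas = cnas, pms = pms, clones = clones),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("<genome_profile> %d phased SNPs, %d CNAs, %d PMs, %d clones\n",
              nrow(x$snps), nrow(x$cnas), nrow(x$pms), nrow(x$clones)))
  invisible(x)
}

empty_snps <- function() tibble(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                phase = character())
empty_cnas <- function() tibble(chrom = character(), start = integer(),
                                end = integer(), copies_a = integer(),
                                copies_b = integer(), clone_id = character(),
                                clonality = numeric())
empty_pms <- function() tibble(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               allele = character(), multiplicity = integer(),
                               clone_id = character(), clonality = numeric())

validate_snp_table <- function(snps, reference = NULL) {
  snps <- as_tibble(snps)
  need <- c("chrom", "pos", "ref", "alt", "phase")
  if (!all(need %in% names(snps))) {
    stop_validation("SNP table needs columns chrom, pos, ref, alt, phase")
  }
  snps <- snps |>
    mutate(chrom = as.character(.data$chrom), pos = as.integer(.data$pos),
           ref = toupper(.data$ref), alt = toupper(.data$alt),
           phase = toupper(as.character(.data$phase))) |>
    select(dplyr::all_of(need))
  if (!all(snps$phase %in% c("A", "B"))) {
    stop_validation("SNP phase must be 'A' or 'B'")
  }
  if (!all(snps$ref %in% BASES) || !all(snps$alt %in% BASES)) {
    stop_validation("SNP ref/alt must be single bases in {A,C,G,T}")
  }
  if (any(snps$ref == snps$alt)) {
    stop_validation("SNP with identical ref and alt base")
  }
  if (anyDuplicated(paste(snps$chrom, snps$pos))) {
    stop_validation("duplicate SNP positions in table")
  }
  if (!is.null(reference) && nrow(snps)) {
    genome_ref <- fetch_ref_base(reference, snps$chrom, snps$pos)
    bad <- which(genome_ref != snps$ref)
    if (length(bad)) {
      stop_validation(sprintf(
        "SNP ref mismatch at %s:%d (table %s, genome %s)",
        snps$chrom[bad[1]], snps$pos[bad[1]] + 1L,
        snps$ref[bad[1]], genome_ref[bad[1]]))
    }
  }
  arrange(snps, .data$chrom, .data$pos)
}

validate_cna_table <- function(cnas) {
  cnas <- as_tibble(cnas)
  need <- c("chrom", "start", "end", "copies_a", "copies_b", "clone_id",
            "clonality")
  if (!all(need %in% names(cnas))) {
    stop_validation("CNA table needs columns chrom, start, end, copies_a, copies_b, clone_id, clonality")
  }
  cnas <- cnas |>
    mutate(chrom = as.character(.data$chrom), start = as.integer(.data$start),
           end = as.integer(.data$end),
           copies_a = as.integer(.data$copies_a),
           copies_b = as.integer(.data$copies_b),
           clone_id = as.character(.data$clone_id),
           clonality = as.numeric(.data$clonality)) |>
    select(dplyr::all_of(need))
  if (any(cnas$end <= cnas$start)) stop_validation("CNA with end <= start")
  if (any(cnas$copies_a < 0 | cnas$copies_b < 0)) {
    stop_validation("negative allele copy number")
  }
  if (any(cnas$copies_a == 1L & cnas$copies_b == 1L)) {
    stop_validation("CNA with copies (1,1) is not an alteration")
  }
  if (any(cnas$clonality <= 0 | cnas$clonality > 1)) {
    stop_validation("CNA clonality must lie in (0, 1]")
  }
  arrange(cnas, .data$chrom, .data$start)
}

validate_pm_table <- function(pms, reference = NULL) {
  pms <- as_tibble(pms)
  need <- c("chrom", "pos", "ref", "alt", "allele", "multiplicity",
            "clone_id", "clonality")
  if (!all(need %in% names(pms))) {
    stop_validation("PM table needs columns chrom, pos, ref, alt, allele, multiplicity, clone_id, clonality")
  }
  pms <- pms |>
    mutate(chrom = as.character(.data$chrom), pos = as.integer(.data$pos),
           ref = toupper(.data$ref), alt = toupper(.data$alt),
           allele = toupper(as.character(.data$allele)),
           multiplicity = as.integer(.data$multiplicity),
           clone_id = as.character(.data$clone_id),
           clonality = as.numeric(.data$clonality)) |>
    select(dplyr::all_of(need))
  if (!all(pms$allele %in% c("A", "B"))) {
    stop_validation("PM allele must be 'A' or 'B'")
  }
  if (any(pms$multiplicity < 1L)) stop_validation("PM multiplicity must be >= 1")
  if (any(pms$clonality <= 0 | pms$clonality > 1)) {
    stop_validation("PM clonality must lie in (0, 1]")
  }
  if (any(pms$ref == pms$alt)) stop_validation("PM with identical ref and alt")
  if (!is.null(reference) && nrow(pms)) {
    genome_ref <- fetch_ref_base(reference, pms$chrom, pms$pos)
    bad <- which(genome_ref != pms$ref)
    if (length(bad)) {
      stop_validation(sprintf("PM ref mismatch at %s:%d (table %s, genome %s)",
                              pms$chrom[bad[1]], pms$pos[bad[1]] + 1L,
                              pms$ref[bad[1]], genome_ref[bad[1]]))
    }
  }
  arrange(pms, .data$chrom, .data$pos)
}

# One row per clone_id; clonality must be consistent across a clone's events
# and sum to <= 1 over all clones (clones are disjoint tumor-cell populations).
clone_table <- function(cnas, pms) {
  ev <- bind_rows(
    if (nrow(cnas)) select(cnas, "clone_id", "clonality") else NULL,
    if (nrow(pms)) select(pms, "clone_id", "clonality") else NULL)
  if (is.null(ev) || !nrow(ev)) {
    return(tibble(clone_id = character(), clonality = numeric()))
  }
  cl <- distinct(ev, .data$clone_id, .data$clonality)
  dup <- cl$clone_id[duplicated(cl$clone_id)]
  if (length(dup)) {
    stop_validation(sprintf("clone '%s' has inconsistent clonality values across events",
                            dup[1]))
  }
  if (sum(cl$clonality) > 1 + 1e-9) {
    stop_validation(sprintf("clonalities of disjoint clones sum to %.3f > 1",
                            sum(cl$clonality)))
  }
  arrange(cl, .data$clone_id)
}

#' Parse phased germline SNPs from VCF or TSV
#'
#' Retains heterozygous, phased, biallelic SNVs of the first sample. VCF
#' genotype `0|1` places the alternate allele on haplotype B, `1|0` on
#' haplotype A. An unphased heterozygous genotype is an error; multiallelic or
#' non-SNV records are skipped with a warning. The TSV form has a header and
#' columns chrom, pos (1-based), ref, alt, phase (A/B).
#'
#' @param path VCF (`.vcf`/`.vcf.gz`) or tab-separated file.
#' @param reference Optional FASTA for reference-allele checking.
#' @return A tibble of phased SNPs (`chrom`, `pos` 0-based, `ref`, `alt`,
#'   `phase`).
#' @export
parse_snps <- function(path, reference = NULL) {
  check_file_exists(path, "SNP file")
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    parse_snps_vcf(path, reference)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(raw) <- tolower(names(raw))
    if (!all(c("chrom", "pos", "ref", "alt", "phase") %in% names(raw))) {
      stop_parse(sprintf("SNP TSV %s needs header columns chrom, pos, ref, alt, phase", path))
    }
    raw$pos <- as.integer(raw$pos) - 1L  # 1-based file to 0-based internal
    validate_snp_table(raw, reference)
  }
}

parse_snps_vcf <- function(path, reference = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) < 1L) stop_parse(sprintf("VCF %s has no sample columns", path))
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt_flat <- as.character(BiocGenerics::unlist(altl))
  alt1[n_alt >= 1L] <- alt_flat[cumsum(n_alt)[n_alt >= 1L] -
                                  n_alt[n_alt >= 1L] + 1L]
  het <- gt %in% c("0|1", "1|0", "0/1", "1/0")
  if (any(gt %in% c("0/1", "1/0"))) {
    i <- which(gt %in% c("0/1", "1/0"))[1]
    stop_validation(sprintf("unphased heterozygous genotype '%s' in %s at record %s",
                            gt[i], path, names(gt)[i] %||% as.character(i)))
  }
  snv <- nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L & n_alt == 1L
  skipped <- sum(het & !snv) + sum(!het & !gt %in% c("0|0", "1|1", "./."))
  if (any(het & !snv)) {
    warn(sprintf("%d multiallelic or non-SNV heterozygous records skipped in %s",
                 sum(het & !snv), path))
  }
  keep <- het & snv
  inform(sprintf("parse_snps: %d phased het SNVs kept, %d records skipped from %s",
                 sum(keep), length(gt) - sum(keep), path))
  snps <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep] - 1L,
    ref = ref[keep], alt = alt1[keep],
    # a|b: left of bar is haplotype A, so 1|0 puts alt on A, 0|1 on B
    phase = ifelse(gt[keep] == "1|0", "A", "B"))
  validate_snp_table(snps, reference)
}

#' Read a somatic CNA table
#'
#' Tab-separated with header: chrom, start, end (1-based inclusive), copies_a,
#' copies_b, clone_id, clonality.
#'
#' @param path TSV path.
#' @return Validated CNA tibble (0-based half-open internally).
#' @export
read_cna_table <- function(path) {
  check_file_exists(path, "CNA table")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  raw$start <- as.integer(raw$start) - 1L  # 1-based inclusive -> 0-based half-open
  validate_cna_table(raw)
}

#' Read a somatic point-mutation table
#'
#' Tab-separated with header: chrom, pos (1-based), ref, alt, allele,
#' multiplicity, clone_id, clonality.
#'
#' @param path TSV path.
#' @param reference Optional FASTA for reference-base checking.
#' @return Validated PM tibble (0-based positions internally).
#' @export
read_pm_table <- function(path, reference = NULL) {
  check_file_exists(path, "PM table")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  raw$pos <- as.integer(raw$pos) - 1L
  validate_pm_table(raw, reference)
}
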