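# Reference-model construction from control alignments.
#
# Three empirical models are built from one or more coordinate-sorted, indexed
# BAM files of non-cancer samples sequenced on a single platform:
#   * read-depth model (RDM): per-captured-position fragment-start weights plus
#     insert-size statistics; the sampling distribution for read generation;
#   * quality model (QM): per-read-cycle base-quality histograms;
#   * position-based error model (PBE): per-position systematic error rates and
#     alternate-base profiles supported by high-quality reads and bases.
# All builders skip secondary, supplementary, duplicate-flagged and unmapped
# records.

builder_flags <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isDuplicate = FALSE,
                         isSupplementaryAlignment = FALSE)
}

check_bam <- function(bam) {
  check_file_exists(bam, "BAM file")
  bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(bai))) {
    stop_input(sprintf("BAM file %s is not indexed (no .bai found); sort and index it first", bam))
  }
  invisible(bam)
}

# flag-bit helpers (SAM spec bit masks)
flag_paired    <- function(flag) bitwAnd(flag, 1L) > 0L
flag_proper    <- function(flag) bitwAnd(flag, 2L) > 0L
flag_mate_unm  <- function(flag) bitwAnd(flag, 8L) > 0L
flag_first     <- function(flag) bitwAnd(flag, 64L) > 0L

#' Build the read-depth model from control alignments
#'
#' Counts, for every captured position, the fragments whose leftmost aligned
#' coordinate falls on that position, pooled across all input files. For
#' paired-end data only the mate with the lower coordinate contributes, so each
#' fragment is counted once; for single-end data every primary alignment
#' contributes. Insert-size mean and standard deviation are computed from the
#' absolute template lengths of proper pairs whose leftmost mate starts inside
#' a target region (template lengths outside (0, 2000] are discarded as likely
#' chimeras).
#'
#' @param bams Character vector of coordinate-sorted, indexed BAM paths.
#' @param targets A [target_regions()] panel.
#' @param paired Logical; `TRUE` for paired-end input.
#' @param max_template_length Upper bound on template lengths entering the
#'   insert statistics.
#' @return An `rdm_model`: per-region weight vectors, normalization constant,
#'   insert statistics, observed read length.
#' @export
build_rdm <- function(bams, targets, paired = TRUE, max_template_length = 2000L) {
  stopifnot(inherits(x = targets, "target_regions"), length(bams) >= 1L)
  lapply(bams, check_bam)
  gr <- target_granges(targets)
  weights <- lapply(seq_len(nrow(targets)), function(i) {
    numeric(targets$end[i] - targets$start[i])
  })
  ins_n <- 0; ins_sum <- 0; ins_sumsq <- 0
  rl_obs <- 0L
  used <- 0L
  for (bam in bams) {
    param <- Rsamtools::ScanBamParam(
      which = gr, flag = builder_flags(),
      what = c("flag", "pos", "mpos", "isize", "qwidth"))
    res <- Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)
    for (i in seq_along(res)) {
      r <- res[[i]]
      if (!length(r$pos)) next
      pos0 <- r$pos - 1L
      if (paired) {
        pa <- flag_paired(r$flag)
        mate_ok <- pa & !flag_mate_unm(r$flag) & !is.na(r$mpos)
        leftmost <- mate_ok &
          (r$pos < r$mpos | (r$pos == r$mpos & flag_first(r$flag)))
        keep <- leftmost
      } else {
        keep <- rep(TRUE, length(pos0))
      }
      in_region <- pos0 >= targets$start[i] & pos0 < targets$end[i]
      keep <- keep & in_region & !is.na(pos0)
      if (any(keep)) {
        off <- pos0[keep] - targets$start[i] + 1L
        weights[[i]] <- weights[[i]] +
          tabulate(off, nbins = length(weights[[i]]))
        used <- used + sum(keep)
        rl_obs <- max(rl_obs, max(r$qwidth[keep], na.rm = TRUE))
        if (paired) {
          tl <- abs(r$isize[keep])
          ok <- flag_proper(r$flag[keep]) & !is.na(tl) &
            tl > 0L & tl <= max_template_length
          tl <- as.numeric(tl[ok])
          ins_n <- ins_n + length(tl)
          ins_sum <- ins_sum + sum(tl)
          ins_sumsq <- ins_sumsq + sum(tl^2)
        }
      }
    }
  }
  norm <- sum(vapply(weights, sum, 0))
  if (norm <= 0) stop_model("empty RDM: no on-target fragment starts in input")
  insert_mean <- insert_sd <- NA_real_
  if (paired && ins_n > 0) {
    insert_mean <- ins_sum / ins_n
    insert_sd <- if (ins_n > 1) {
      sqrt(max(0, (ins_sumsq - ins_n * insert_mean^2) / (ins_n - 1)))
    } else 0
  }
  new_rdm(regions = as_tibble(targets), weights = weights, norm = norm,
          insert_mean = insert_mean, insert_sd = insert_sd, paired = paired,
          read_length_observed = as.integer(rl_obs),
          n_source_samples = length(bams))
}

new_rdm <- function(regions, weights, norm, insert_mean, insert_sd, paired,
                    read_length_observed, n_source_samples) {
  stopifnot(all(vapply(weights, function(w) all(w >= 0), TRUE)))
  regions <- tibble(chrom = as.character(regions$chrom),
                    start = as.integer(regions$start),
                    end = as.integer(regions$end))
  structure(list(regions = regions, weights = weights, norm = norm,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 paired = paired, read_length_observed = read_length_observed,
                 n_source_samples = n_source_samples),
            class = "rdm_model")
}

#' @export
print.rdm_model <- function(x, ...) {
  cat(sprintf(
    "<rdm_model> %d regions, %s positions, norm %.0f, %s, read length %d\n",
    nrow(x$regions), format(sum(lengths(x$weights)), big.mark = ","), x$norm,
    if (isTRUE(x$paired)) {
      sprintf("paired (insert %.1f +/- %.1f)", x$insert_mean, x$insert_sd)
    } else "single-end",
    x$read_length_observed))
  invisible(x)
}

#' Build the base-quality model from control alignments
#'
#' Tallies the empirical distribution of Phred base qualities at each read
#' cycle (position within the read in original sequencing orientation;
#' reverse-strand alignments are un-reversed first) over all on-target primary
#' alignments across all files.
#'
#' @inheritParams build_rdm
#' @return A `quality_model` holding a 94 x max_read_length count matrix
#'   (Phred 0..93 by cycle).
#' @export
build_qm <- function(bams, targets) {
  stopifnot(inherits(targets, "target_regions"))
  lapply(bams, check_bam)
  gr <- target_granges(targets)
  counts <- NULL
  for (bam in bams) {
    param <- Rsamtools::ScanBamParam(
      which = gr, flag = builder_flags(),
      what = c("qname", "flag", "pos", "strand", "qual"))
    res <- Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)
    qname <- unlist(lapply(res, `[[`, "qname"), use.names = FALSE)
    if (!length(qname)) next
    flag <- unlist(lapply(res, `[[`, "flag"), use.names = FALSE)
    pos <- unlist(lapply(res, `[[`, "pos"), use.names = FALSE)
    strand <- unlist(lapply(res, function(r) as.character(r$strand)),
                     use.names = FALSE)
    ql <- do.call(c, unname(lapply(res, function(r) as(r$qual, "IntegerList"))))
    # a read overlapping two targets is returned once per target: deduplicate
    key <- paste(qname, flag, pos)
    first <- !duplicated(key)
    ql <- ql[first]
    strand <- strand[first]
    ql <- IRanges::revElements(ql, strand == "-")
    q <- BiocGenerics::unlist(ql, use.names = FALSE)
    cyc <- sequence(S4Vectors::elementNROWS(ql))
    maxlen <- max(cyc)
    m <- matrix(tabulate((cyc - 1L) * 94L + q + 1L, nbins = 94L * maxlen),
                nrow = 94L)
    if (is.null(counts)) {
      counts <- m
    } else {
      L <- max(ncol(counts), ncol(m))
      pad <- function(x) cbind(x, matrix(0, 94L, L - ncol(x)))
      counts <- pad(counts) + pad(m)
    }
  }
  if (is.null(counts) || sum(counts) == 0) {
    stop_model("empty QM: no on-target reads in input")
  }
  new_qm(counts)
}

new_qm <- function(counts) {
  stopifnot(nrow(counts) == 94L, all(counts >= 0))
  structure(list(counts = counts, max_read_length = ncol(counts)),
            class = "quality_model")
}

# per-cycle probability matrix; cycles with no observations fall back to the
# pooled distribution over all cycles
qm_probs <- function(qm) {
  cs <- colSums(qm$counts)
  probs <- qm$counts
  empty <- cs == 0
  if (any(!empty)) probs[, !empty] <- sweep(qm$counts[, !empty, drop = FALSE],
                                            2, cs[!empty], "/")
  if (any(empty)) {
    pooled <- rowSums(qm$counts) / sum(qm$counts)
    probs[, empty] <- pooled
  }
  probs
}

#' @export
print.quality_model <- function(x, ...) {
  mq <- sum((0:93) * rowSums(x$counts)) / sum(x$counts)
  cat(sprintf("<quality_model> %d cycles, %s bases, mean Q %.1f\n",
              x$max_read_length, format(sum(x$counts), big.mark = ","), mq))
  invisible(x)
}

#' Build the position-based systematic error model
#'
#' For every captured position not masked as a common SNP, tallies a pileup of
#' bases with base quality at least `hq_base_quality_min` from reads with
#' mapping quality at least `hq_mapping_quality_min`, pooled over all files. A
#' position enters the model when its high-quality depth reaches `min_depth`
#' and the pooled non-reference fraction reaches `min_error_rate`; the stored
#' error rate is the non-reference fraction and the alternate-base profile the
#' relative frequencies of the non-reference bases observed there.
#'
#' @inheritParams build_rdm
#' @param reference Path to the indexed reference FASTA.
#' @param snp_mask Optional common-SNP positions to exclude: a data frame with
#'   `chrom` and `pos` (0-based) columns, a phased-SNP table from
#'   [parse_snps()], or a path to a BED/VCF file.
#' @param hq_base_quality_min,hq_mapping_quality_min Phred thresholds defining
#'   high-quality bases and reads.
#' @param min_depth Minimum high-quality depth for a position to be assessed.
#' @param min_error_rate Minimum non-reference fraction stored.
#' @param max_depth Pileup depth cap.
#' @return A `pbe_model` with a site table (`chrom`, `pos`, `error_rate`,
#'   `p_A`..`p_T`) and the thresholds used.
#' @export
build_pbe <- function(bams, targets, reference, snp_mask = NULL,
                      hq_base_quality_min = 20L, hq_mapping_quality_min = 20L,
                      min_depth = 50L, min_error_rate = 0.005,
                      max_depth = 100000L) {
  stopifnot(inherits(targets, "target_regions"),
            hq_base_quality_min >= 0, hq_mapping_quality_min >= 0,
            min_depth >= 0, min_error_rate >= 0)
  lapply(bams, check_bam)
  sl <- fasta_seqlengths(reference)
  missing_chr <- setdiff(unique(targets$chrom), names(sl))
  if (length(missing_chr)) {
    stop_input(sprintf("target chromosomes absent from reference: %s",
                       paste(missing_chr, collapse = ", ")))
  }
  gr <- target_granges(targets)
  pp <- Rsamtools::PileupParam(
    max_depth = max_depth,
    min_base_quality = as.integer(hq_base_quality_min),
    min_mapq = as.integer(hq_mapping_quality_min),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  piles <- lapply(bams, function(bam) {
    Rsamtools::pileup(Rsamtools::BamFile(bam),
                      scanBamParam = Rsamtools::ScanBamParam(which = gr,
                                                             flag = builder_flags()),
                      pileupParam = pp)
  })
  pile <- bind_rows(piles)
  if (!nrow(pile)) {
    return(new_pbe(empty_pbe_sites(), hq_base_quality_min,
                   hq_mapping_quality_min, min_depth, min_error_rate))
  }
  pile <- pile |>
    mutate(chrom = as.character(.data$seqnames),
           pos = .data$pos - 1L,
           nucleotide = as.character(.data$nucleotide)) |>
    filter(.data$nucleotide %in% BASES) |>
    group_by(.data$chrom, .data$pos, .data$nucleotide) |>
    summarise(count = sum(.data$count), .groups = "drop")
  wide <- tidyr::pivot_wider(pile, names_from = "nucleotide",
                             values_from = "count", values_fill = 0)
  for (b in BASES) if (!b %in% names(wide)) wide[[b]] <- 0
  wide$depth <- wide$A + wide$C + wide$G + wide$T
  wide$ref <- fetch_ref_base(reference, wide$chrom, wide$pos)
  base_mat <- as.matrix(wide[, BASES])
  ref_idx <- match(wide$ref, BASES)
  ok_ref <- !is.na(ref_idx)
  ref_count <- numeric(nrow(wide))
  ref_count[ok_ref] <- base_mat[cbind(which(ok_ref), ref_idx[ok_ref])]
  nonref <- wide$depth - ref_count
  rate <- ifelse(wide$depth > 0, nonref / wide$depth, 0)
  keep <- ok_ref & wide$depth >= min_depth & nonref > 0 & rate >= min_error_rate
  mask <- normalize_mask(snp_mask)
  if (!is.null(mask) && nrow(mask)) {
    keep <- keep & !(paste(wide$chrom, wide$pos) %in% paste(mask$chrom, mask$pos))
  }
  alt_mat <- base_mat
  alt_mat[cbind(which(ok_ref), ref_idx[ok_ref])] <- 0
  prof <- alt_mat / pmax(rowSums(alt_mat), 1)
  sites <- tibble(chrom = wide$chrom, pos = wide$pos,
                  error_rate = rate,
                  p_A = prof[, 1], p_C = prof[, 2],
                  p_G = prof[, 3], p_T = prof[, 4])[keep, ] |>
    arrange(.data$chrom, .data$pos)
  new_pbe(sites, hq_base_quality_min, hq_mapping_quality_min,
          min_depth, min_error_rate)
}

empty_pbe_sites <- function() {
  tibble(chrom = character(), pos = integer(), error_rate = numeric(),
         p_A = numeric(), p_C = numeric(), p_G = numeric(), p_T = numeric())
}

new_pbe <- function(sites, hq_base_quality_min, hq_mapping_quality_min,
                    min_depth, min_error_rate) {
  stopifnot(all(sites$error_rate > 0), all(sites$error_rate <= 1))
  structure(list(sites = sites,
                 hq_base_quality_min = as.integer(hq_base_quality_min),
                 hq_mapping_quality_min = as.integer(hq_mapping_quality_min),
                 min_depth = as.integer(min_depth),
                 min_error_rate = min_error_rate),
            class = "pbe_model")
}

#' @export
print.pbe_model <- function(x, ...) {
  cat(sprintf("<pbe_model> %d systematic-error sites (BQ>=%d, MQ>=%d, depth>=%d, rate>=%g)\n",
              nrow(x$sites), x$hq_base_quality_min, x$hq_mapping_quality_min,
              x$min_depth, x$min_error_rate))
  invisible(x)
}

# Accept a mask as a tibble (chrom/pos), a phased-SNP table, or a BED/VCF path.
normalize_mask <- function(snp_mask) {
  if (is.null(snp_mask)) return(NULL)
  if (is.data.frame(snp_mask)) {
    stopifnot(all(c("chrom", "pos") %in% names(snp_mask)))
    return(tibble(chrom = as.character(snp_mask$chrom),
                  pos = as.integer(snp_mask$pos)))
  }
  check_file_exists(snp_mask, "SNP mask")
  if (grepl("\\.vcf(\\.gz)?$", snp_mask)) {
    snps <- parse_snps(snp_mask)
    return(tibble(chrom = snps$chrom, pos = snps$pos))
  }
  tr <- read_targets(snp_mask)
  tibble(chrom = rep(tr$chrom, tr$end - tr$start),
         pos = unlist(lapply(seq_len(nrow(tr)),
                             function(i) seq(tr$start[i], tr$end[i] - 1L))))
}
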