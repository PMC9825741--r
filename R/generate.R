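# Top-level sample generation: orchestration, read budget calibration, FASTQ
# and truth emission, generation report.

#' Generate a synthetic tumor or matched-control sample
#'
#' Runs the full generation pipeline: resolves dosage segments at the plan's
#' tumor content, modulates the read-depth model, samples fragments, builds
#' read sequences with phased SNPs and somatic events, applies base qualities
#' and sequencing errors and writes FASTQ (plus a per-fragment truth table).
#' Matched-control plans ignore all somatic events and use tumor content 0.
#'
#' When `coverage` is requested instead of `n_reads`, the fragment budget is
#' calibrated with a seeded Monte-Carlo estimate of the expected number of
#' on-target bases per fragment, so the realized mean on-target depth matches
#' the request in expectation even though reads overhang target edges.
#'
#' @param models A [model_bundle()] (or list with `rdm`, `qm`, `pbe`).
#' @param reference Indexed FASTA path.
#' @param profile A [genome_profile()].
#' @param plan A [sample_plan()].
#' @param out_prefix Output path prefix; paired-end reads go to
#'   `<prefix>_R1.fastq[.gz]` / `<prefix>_R2.fastq[.gz]`, single-end to
#'   `<prefix>.fastq[.gz]`; the truth table to `<prefix>.truth.tsv`.
#' @param threads Accepted for interface compatibility; generation is
#'   vectorised in-process and output never depends on this value.
#' @param gzip Compress FASTQ output.
#' @param chunk_size Fragments per processing chunk (fixed; does not affect
#'   output values).
#' @param pm_order `"after_errors"` (default: a point mutation overwrites a
#'   sequencing error at its own position, following the literal generation
#'   step order) or `"before_errors"`.
#' @param write_truth Write the per-fragment truth table.
#' @param calibration_draws Monte-Carlo draws for the coverage calibration.
#' @return A `generation_report` (see [tidy.generation_report()]): realized
#'   coverage, strand balance, insert statistics, per-segment fragment counts
#'   and per-event expected vs observed allele fractions.
#' @export
generate_sample <- function(models, reference, profile, plan, out_prefix,
                            threads = 1L, gzip = FALSE, chunk_size = 20000L,
                            pm_order = c("after_errors", "before_errors"),
                            write_truth = TRUE, calibration_draws = 10000L) {
  pm_order <- match.arg(pm_order)
  if (!inherits(models, "model_bundle")) {
    models <- model_bundle(models$rdm, models$qm, models$pbe)
  }
  stopifnot(inherits(profile, "genome_profile"), inherits(plan, "sample_plan"))
  rdm <- models$rdm; qm <- models$qm; pbe <- models$pbe
  L <- plan$read_length
  paired <- plan$paired
  targets <- target_regions(rdm$regions)
  chrom_lengths <- fasta_seqlengths(reference)

  is_control <- plan$kind == "matched_control"
  t_eff <- if (is_control) 0 else plan$tumor_content
  cnas <- if (is_control) empty_cnas() else profile$cnas
  pms <- if (is_control) empty_pms() else profile$pms

  segments <- resolve_segments(cnas, targets, t_eff,
                               clones = clone_table(cnas, pms))
  pms <- validate_pms(pms, segments, cnas)
  snps <- validate_snp_table(profile$snps, reference)
  pos_tab <- position_distribution(rdm, segments)

  insert_mean <- plan$insert_mean %||% rdm$insert_mean
  insert_sd <- plan$insert_sd %||% rdm$insert_sd
  check_headroom(targets, chrom_lengths, L, paired, insert_mean, insert_sd)

  set.seed(plan$seed)

  total_len <- target_length(targets)
  draw_args <- list(rdm = rdm, segments = segments, read_length = L,
                    paired = paired, strand_bias = plan$strand_bias,
                    insert_mean = insert_mean, insert_sd = insert_sd,
                    chrom_lengths = chrom_lengths, pos_tab = pos_tab)
  if (!is.null(plan$n_reads)) {
    n_frag <- as.integer(plan$n_reads)
  } else {
    cal <- do.call(sample_fragments, c(list(n = calibration_draws), draw_args))
    bases <- on_target_bases(cal$chrom, cal$start, cal$start + L, targets)
    if (paired) {
      bases <- bases + on_target_bases(cal$chrom, cal$end - L, cal$end, targets)
    }
    n_frag <- as.integer(round(plan$coverage * total_len / mean(bases)))
  }
  if (n_frag < 1L) stop_generation("requested read budget is zero fragments")

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  files <- if (paired) {
    c(paste0(out_prefix, "_R1", ext), paste0(out_prefix, "_R2", ext))
  } else {
    paste0(out_prefix, ext)
  }
  cons <- lapply(files, function(f) {
    if (gzip) gzfile(f, open = "wb") else file(f, open = "wb")
  })
  on.exit(lapply(cons, function(con) try(close(con), silent = TRUE)), add = TRUE)
  truth_path <- paste0(out_prefix, ".truth.tsv")
  truth_con <- NULL
  if (write_truth) {
    truth_con <- file(truth_path, open = "wb")
    on.exit(try(close(truth_con), silent = TRUE), add = TRUE)
    writeLines(paste(c("serial", "chrom", "start", "end", "strand",
                       "population", "haplotype", "copy_index", "insert",
                       "r1_start", "r1_end", "r2_start", "r2_end"),
                     collapse = "\t"), truth_con)
  }

  acc <- new_accumulator(segments, snps, pms)
  serial0 <- 0L
  remaining <- n_frag
  while (remaining > 0L) {
    m <- min(chunk_size, remaining)
    draws <- do.call(sample_fragments, c(list(n = m), draw_args))
    chunk <- process_chunk(draws, reference, snps, pms, qm, pbe, plan,
                           serial0, pm_order)
    acc <- accumulate_chunk(acc, draws, chunk, targets, L, paired)
    writeLines(chunk$rec1, cons[[1]], sep = "\n")
    if (paired) writeLines(chunk$rec2, cons[[2]], sep = "\n")
    if (write_truth) writeLines(chunk$truth, truth_con, sep = "\n")
    serial0 <- serial0 + m
    remaining <- remaining - m
  }
  lapply(cons, close)
  if (write_truth) close(truth_con)
  on.exit(NULL)

  build_report(acc, plan, t_eff, n_frag, segments, snps, pms, pos_tab,
               targets, files, truth_path, total_len, paired, L)
}

check_headroom <- function(targets, chrom_lengths, L, paired, insert_mean,
                           insert_sd) {
  need <- if (paired) {
    if (is.null(insert_mean) || is.na(insert_mean)) {
      stop_generation("paired generation requires insert statistics (none in model or plan)")
    }
    ceiling(insert_mean + 6 * max(0, insert_sd, na.rm = TRUE))
  } else L
  for (ch in unique(targets$chrom)) {
    if (!ch %in% names(chrom_lengths)) {
      stop_input(sprintf("target chromosome %s absent from reference", ch))
    }
    max_end <- max(targets$end[targets$chrom == ch])
    if (max_end - 1L + need > chrom_lengths[[ch]]) {
      stop_generation(sprintf(
        "chromosome %s too short for fragments starting at target end (need %d bases beyond position %d)",
        ch, need, max_end))
    }
  }
  invisible(TRUE)
}

process_chunk <- function(draws, reference, snps, pms, qm, pbe, plan,
                          serial0, pm_order) {
  L <- plan$read_length
  paired <- plan$paired
  seqs <- build_read_sequences(draws, reference, snps, L, paired)
  rev1 <- draws$strand == "-"
  # with forward fragments, mate 1 is the left end (sequenced forward) and
  # mate 2 the right end (sequenced in reverse); reverse fragments swap roles
  rev2 <- !rev1
  pm_fun <- function(mat, start0) apply_pms(mat, draws, start0, pms, L)
  if (pm_order == "before_errors") {
    seqs$mat1 <- pm_fun(seqs$mat1, seqs$start1)
    if (paired) seqs$mat2 <- pm_fun(seqs$mat2, seqs$start2)
  }
  qe1 <- apply_quality_and_errors(seqs$mat1, seqs$start1, draws$chrom, rev1,
                                  qm, pbe)
  mat1 <- qe1$mat
  if (paired) {
    qe2 <- apply_quality_and_errors(seqs$mat2, seqs$start2, draws$chrom, rev2,
                                    qm, pbe)
    mat2 <- qe2$mat
  }
  if (pm_order == "after_errors") {
    mat1 <- pm_fun(mat1, seqs$start1)
    if (paired) mat2 <- pm_fun(mat2, seqs$start2)
  }
  serial <- serial0 + seq_len(nrow(draws))
  names <- sprintf("%s:%d:%s:%d", plan$name, serial, draws$chrom,
                   draws$start + 1L)
  out1 <- revcomp_rows(mat1, which(rev1))
  rec1 <- fastq_records(names, collapse_rows(out1),
                        collapse_rows(matrix(phred_chars(qe1$qual),
                                             nrow(qe1$qual))))
  rec2 <- NULL
  if (paired) {
    out2 <- revcomp_rows(mat2, which(rev2))
    rec2 <- fastq_records(names, collapse_rows(out2),
                          collapse_rows(matrix(phred_chars(qe2$qual),
                                               nrow(qe2$qual))))
  }
  truth <- paste(serial, draws$chrom, draws$start, draws$end, draws$strand,
                 draws$population, draws$haplotype, draws$copy_index,
                 draws$insert,
                 seqs$start1, seqs$start1 + L,
                 if (paired) seqs$start2 else NA,
                 if (paired) seqs$start2 + L else NA,
                 sep = "\t")
  list(rec1 = rec1, rec2 = rec2, truth = truth,
       mat1 = mat1, mat2 = if (paired) mat2 else NULL,
       start1 = seqs$start1, start2 = seqs$start2)
}

new_accumulator <- function(segments, snps, pms) {
  ev <- event_table(snps, pms)
  list(seg_counts = setNames(rep(0, nrow(segments)),
                             as.character(segments$segment_id)),
       ev = ev,
       ev_depth = rep(0, nrow(ev)), ev_alt = rep(0, nrow(ev)),
       fwd = 0, n = 0, bases_on_target = 0,
       ins_n = 0, ins_sum = 0, ins_sumsq = 0)
}

event_table <- function(snps, pms) {
  out <- bind_rows(
    if (nrow(snps)) tibble(type = "snp", chrom = snps$chrom, pos = snps$pos,
                           alt = snps$alt,
                           id = paste0("snp_", seq_len(nrow(snps)))) else NULL,
    if (nrow(pms)) tibble(type = "pm", chrom = pms$chrom, pos = pms$pos,
                          alt = pms$alt,
                          id = paste0("pm_", pms$clone_id, "_",
                                      seq_len(nrow(pms)))) else NULL)
  if (!nrow(out)) {
    out <- tibble(type = character(), chrom = character(), pos = integer(),
                  alt = character(), id = character())
  }
  out
}

accumulate_chunk <- function(acc, draws, chunk, targets, L, paired) {
  tb <- table(draws$segment_id)
  acc$seg_counts[names(tb)] <- acc$seg_counts[names(tb)] + as.numeric(tb)
  acc$fwd <- acc$fwd + sum(draws$strand == "+")
  acc$n <- acc$n + nrow(draws)
  acc$bases_on_target <- acc$bases_on_target +
    sum(on_target_bases(draws$chrom, chunk$start1, chunk$start1 + L, targets))
  if (paired) {
    acc$bases_on_target <- acc$bases_on_target +
      sum(on_target_bases(draws$chrom, chunk$start2, chunk$start2 + L, targets))
    ins <- draws$insert
    acc$ins_n <- acc$ins_n + length(ins)
    acc$ins_sum <- acc$ins_sum + sum(ins)
    acc$ins_sumsq <- acc$ins_sumsq + sum(as.numeric(ins)^2)
  }
  if (nrow(acc$ev)) {
    tally <- function(mat, start0) {
      for (i in seq_len(nrow(acc$ev))) {
        rows <- which(draws$chrom == acc$ev$chrom[i] &
                        start0 <= acc$ev$pos[i] & acc$ev$pos[i] < start0 + L)
        if (!length(rows)) next
        acc$ev_depth[i] <<- acc$ev_depth[i] + length(rows)
        cols <- acc$ev$pos[i] - start0[rows] + 1L
        acc$ev_alt[i] <<- acc$ev_alt[i] +
          sum(mat[cbind(rows, cols)] == acc$ev$alt[i])
      }
    }
    tally(chunk$mat1, chunk$start1)
    if (paired) tally(chunk$mat2, chunk$start2)
  }
  acc
}

build_report <- function(acc, plan, t_eff, n_frag, segments, snps, pms,
                         pos_tab, targets, files, truth_path, total_len,
                         paired, L) {
  seg_tbl <- as_tibble(segments) |>
    mutate(expected_fraction = vapply(.data$segment_id, function(s) {
      sum(pos_tab$prob[pos_tab$segment_id == s])
    }, 0),
    n_fragments = as.numeric(acc$seg_counts[as.character(.data$segment_id)]))
  exp_tbl <- expectation_for_report(snps, pms, segments, t_eff)
  events <- exp_tbl |>
    left_join(tibble(id = acc$ev$id, depth = acc$ev_depth,
                     alt_count = acc$ev_alt), by = "id") |>
    mutate(observed_af = ifelse(.data$depth > 0,
                                .data$alt_count / .data$depth, NA_real_))
  structure(list(
    sample = plan$name, kind = plan$kind, tumor_content = t_eff,
    seed = plan$seed, paired = paired, read_length = L,
    requested_coverage = plan$coverage, requested_n_reads = plan$n_reads,
    n_fragments = n_frag,
    n_records = n_frag * (if (paired) 2L else 1L),
    realized_coverage = acc$bases_on_target / total_len,
    forward_fraction = acc$fwd / acc$n,
    insert_mean_realized = if (acc$ins_n > 0) acc$ins_sum / acc$ins_n else NA_real_,
    insert_sd_realized = if (acc$ins_n > 1) {
      sqrt(max(0, (acc$ins_sumsq - acc$ins_sum^2 / acc$ins_n) / (acc$ins_n - 1)))
    } else NA_real_,
    segments = seg_tbl, events = events,
    files = files, truth = truth_path), class = "generation_report")
}

# expected BAF per SNP and VAF per PM, from the closed-form dosage arithmetic
expectation_for_report <- function(snps, pms, segments, t_eff) {
  rows <- list()
  if (nrow(snps)) {
    sid <- segment_of(segments, snps$chrom, snps$pos)
    keep <- which(!is.na(sid))
    if (length(keep)) {
      segs <- segments[match(sid[keep], segments$segment_id), ]
      ex <- purrr::map_dfr(seq_along(keep), function(k) {
        locus_expectation(segs[k, ], snp = snps[keep[k], ],
                          tumor_content = t_eff)
      })
      rows$snp <- tibble(type = "snp", chrom = snps$chrom[keep],
                         pos = snps$pos[keep],
                         id = paste0("snp_", keep),
                         expected_af = ex$expected_baf_alt,
                         expected_log2 = ex$expected_log2)
    }
  }
  if (nrow(pms)) {
    sid <- if ("segment_id" %in% names(pms)) pms$segment_id else
      segment_of(segments, pms$chrom, pms$pos)
    keep <- which(!is.na(sid))
    if (length(keep)) {
      segs <- segments[match(sid[keep], segments$segment_id), ]
      ex <- purrr::map_dfr(seq_along(keep), function(k) {
        locus_expectation(segs[k, ], pm = pms[keep[k], ],
                          tumor_content = t_eff)
      })
      rows$pm <- tibble(type = "pm", chrom = pms$chrom[keep],
                        pos = pms$pos[keep],
                        id = paste0("pm_", pms$clone_id[keep], "_", keep),
                        expected_af = ex$expected_vaf,
                        expected_log2 = ex$expected_log2)
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(type = character(), chrom = character(), pos = integer(),
                  id = character(), expected_af = numeric(),
                  expected_log2 = numeric())
  }
  out
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("<generation_report> %s (%s)\n", x$sample, x$kind))
  cat(sprintf("  fragments: %d (%d FASTQ records), read length %d, %s\n",
              x$n_fragments, x$n_records, x$read_length,
              if (x$paired) "paired-end" else "single-end"))
  if (!is.null(x$requested_coverage)) {
    cat(sprintf("  coverage: requested %.1fx, realized %.2fx\n",
                x$requested_coverage, x$realized_coverage))
  } else {
    cat(sprintf("  realized coverage: %.2fx\n", x$realized_coverage))
  }
  cat(sprintf("  forward-strand fraction: %.4f\n", x$forward_fraction))
  if (x$paired && !is.na(x$insert_mean_realized)) {
    cat(sprintf("  insert size: %.1f +/- %.1f\n", x$insert_mean_realized,
                x$insert_sd_realized))
  }
  cat(sprintf("  %d dosage segments, %d tracked events\n",
              nrow(x$segments), nrow(x$events)))
  invisible(x)
}
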