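# Shared fixtures, built once per test run and cached. Everything is
# generated in code under tempdir(); nothing is stored in the repository.

fx_cache <- new.env(parent = emptyenv())

fx_get <- function(key, maker) {
  if (!exists(key, envir = fx_cache)) assign(key, maker(), envir = fx_cache)
  get(key, envir = fx_cache)
}

fx_dir <- function() {
  d <- file.path(tempdir(), "oncoreads_fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# Base fixture: 4 targets of 500 bp, 300 fragments/target, constant Q30,
# one injected systematic error mid-target (depth there ~90).
fx_base <- function() fx_get("base", function() {
  spec <- fixture_spec(n_targets = 4L, chromosome_length = 30000L,
                       fragments_per_target = 300L, insert_sd = 0,
                       seed = 42L)
  targets <- fixture_targets(spec)
  ref <- make_reference(spec, fx_dir())
  err_pos <- targets$start[2] + 250L
  err_ref <- oncoreads:::fetch_ref_base(ref, targets$chrom[2], err_pos)
  spec$error_positions <- tibble::tibble(
    chrom = targets$chrom[2], pos = err_pos,
    rate = 0.1, alt = setdiff(c("A", "C", "G", "T"), err_ref)[1])
  tb <- make_truth_bam(spec, ref, fx_dir())
  list(spec = spec, targets = targets, reference = ref,
       bam = tb$bam, truth = tb$truth, models = make_models_direct(spec))
})

# Generation fixture: 8 targets over 2 chromosomes, variable insert, no
# injected systematic errors.
fx_gen <- function() fx_get("gen", function() {
  spec <- fixture_spec(n_targets = 8L, n_chromosomes = 2L,
                       chromosome_length = 30000L, insert_sd = 30,
                       seed = 7L)
  ref <- make_reference(spec, fx_dir())
  list(spec = spec, targets = fixture_targets(spec), reference = ref,
       models = make_models_direct(spec))
})

# Write a toy BAM from explicit alignment records; returns the BAM path.
# records: data.frame with qname, flag, chrom, pos0, mapq, mpos0, tlen, seq, qual
write_toy_bam <- function(records, chrom_lengths, path_stem) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t%s",
                   records$qname, records$flag, records$chrom,
                   records$pos0 + 1L, records$mapq, nchar(records$seq),
                   ifelse(records$mpos0 >= 0L, "=", "*"),
                   records$mpos0 + 1L, records$tlen, records$seq,
                   records$qual)
  ord <- order(match(records$chrom, names(chrom_lengths)), records$pos0)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      unname(chrom_lengths)))
  sam <- paste0(path_stem, ".sam")
  writeLines(c(header, lines[ord]), sam)
  Rsamtools::asBam(sam, path_stem, overwrite = TRUE, indexDestination = TRUE)
}

q30 <- function(n) paste(rep("?", n), collapse = "")  # Phred 30, +33 encoding

# Per-cell enumeration oracle for effective dosages: simulate n cells assigned
# to populations by fraction and average their copy numbers.
enumerate_effective <- function(populations, n = 1e6, seed = 99) {
  withr::with_seed(seed, {
    k <- sample.int(nrow(populations), n, replace = TRUE,
                    prob = populations$fraction)
    c(effective_a = mean(populations$copies_a[k]),
      effective_b = mean(populations$copies_b[k]))
  })
}

# Naive, independent fragment-start pileup used as the RDM oracle: walks raw
# alignments with GenomicAlignments and counts leftmost fragment starts.
naive_fragment_starts <- function(bam, targets, paired = TRUE) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "pos", "mpos"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(ga)
  pos0 <- md$pos - 1L
  if (paired) {
    keep <- bitwAnd(md$flag, 1L) > 0L & bitwAnd(md$flag, 8L) == 0L &
      (md$pos < md$mpos | (md$pos == md$mpos & bitwAnd(md$flag, 64L) > 0L))
  } else {
    keep <- rep(TRUE, length(pos0))
  }
  chrom <- as.character(GenomeInfoDb::seqnames(ga))
  counts <- list()
  for (i in seq_len(nrow(targets))) {
    sel <- keep & chrom == targets$chrom[i] &
      pos0 >= targets$start[i] & pos0 < targets$end[i]
    counts[[i]] <- tabulate(pos0[sel] - targets$start[i] + 1L,
                            nbins = targets$end[i] - targets$start[i])
  }
  counts
}

# Measure per-event alternate-allele fraction directly from FASTQ + truth,
# independent of the generation report's internal tally.
measure_af_from_fastq <- function(prefix, events, read_length, paired = TRUE) {
  truth <- readr::read_tsv(paste0(prefix, ".truth.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  L <- read_length
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  read_seqs <- function(path) {
    lines <- readLines(path)
    lines[seq(2, length(lines), by = 4)]
  }
  mates <- if (paired) {
    list(list(seqs = read_seqs(paste0(prefix, "_R1.fastq")),
              start = truth$r1_start, fwd = truth$strand == "+"),
         list(seqs = read_seqs(paste0(prefix, "_R2.fastq")),
              start = truth$r2_start, fwd = truth$strand == "-"))
  } else {
    list(list(seqs = read_seqs(paste0(prefix, ".fastq")),
              start = truth$r1_start, fwd = truth$strand == "+"))
  }
  out <- events
  out$depth <- 0L; out$alt_count <- 0L
  for (m in mates) {
    for (i in seq_len(nrow(events))) {
      x <- events$pos[i]
      rows <- which(truth$chrom == events$chrom[i] & m$start <= x &
                      x < m$start + L)
      if (!length(rows)) next
      base <- vapply(rows, function(r) {
        off <- x - m$start[r]
        if (m$fwd[r]) {
          substr(m$seqs[r], off + 1L, off + 1L)
        } else {
          comp[[substr(m$seqs[r], L - off, L - off)]]
        }
      }, "")
      out$depth[i] <- out$depth[i] + length(base)
      out$alt_count[i] <- out$alt_count[i] + sum(base == events$alt[i])
    }
  }
  out$observed_af <- ifelse(out$depth > 0, out$alt_count / out$depth, NA_real_)
  out
}

# 99% binomial z-interval check (normal approximation at the depths we use)
within_binom_ci <- function(observed_count, n, p, level_z = 2.576) {
  if (n == 0) return(NA)
  phat <- observed_count / n
  se <- sqrt(p * (1 - p) / n)
  abs(phat - p) <= level_z * se + 1e-12
}
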