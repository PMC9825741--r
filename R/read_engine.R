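# Read generation: sample fragments from the dosage-modulated read-depth
# model, materialize sequences from reference + haplotype, inject SNPs,
# sequencing errors (position-based systematic errors first, then
# quality-driven random errors) and point mutations, choose strand, emit
# FASTQ.
#
# Per fragment: (i) a start position is sampled proportional to RDM weight
# times the local coverage factor; (ii) the read (pair) sequence is taken from
# the reference, with the insert size drawn from a normal distribution
# truncated to at least one read length; (iii) a cell population and haplotype
# copy are drawn hierarchically (population with probability proportional to
# cell fraction times its total copies at the segment, then one of its
# haplotype copies uniformly); (iv) phased SNPs on the drawn haplotype are
# substituted; (v) base qualities and errors are applied; (vi) point mutations
# carried by the drawn copy are substituted (literally after errors, so a
# mutation can overwrite an error at its own position; see `pm_order`);
# (vii) the fragment strand is forward with probability `strand_bias`.
#
# Generation is chunked and vectorised; output is a pure function of the
# inputs and the plan seed, independent of the `threads` argument.

#' Dosage-modulated fragment-start distribution
#'
#' Flattens the read-depth model into a per-position table and multiplies each
#' weight by the coverage factor of the dosage segment containing it,
#' renormalizing globally.
#'
#' @param rdm An `rdm_model`.
#' @param segments A [resolve_segments()] table (or `NULL` for copy-neutral).
#' @return Tibble: `chrom`, `pos` (0-based), `weight`, `segment_id`, `prob`.
#' @export
position_distribution <- function(rdm, segments = NULL) {
  stopifnot(inherits(rdm, "rdm_model"))
  tab <- tibble(
    chrom = rep(rdm$regions$chrom, lengths(rdm$weights)),
    pos = unlist(lapply(seq_len(nrow(rdm$regions)), function(i) {
      seq(rdm$regions$start[i], rdm$regions$end[i] - 1L)
    })),
    weight = unlist(rdm$weights))
  if (is.null(segments)) {
    tab$segment_id <- 1L
    tab$factor <- 1
  } else {
    tab$segment_id <- segment_of(segments, tab$chrom, tab$pos)
    tab$factor <- segments$coverage_factor[match(tab$segment_id,
                                                 segments$segment_id)]
    tab$factor[is.na(tab$factor)] <- 1
  }
  w <- tab$weight * tab$factor
  if (sum(w) <= 0) {
    stop_generation("all modulated fragment-start weights are zero")
  }
  tab$prob <- w / sum(w)
  tab
}

# per-segment table of (population, haplotype, copy_index) combinations, each
# weighted by its population's cell fraction (one row per allele copy)
segment_combos <- function(segments) {
  pops <- attr(segments, "populations")
  if (is.null(pops)) {
    pops <- tibble(segment_id = 1L, population = "normal", fraction = 1,
                   copies_a = 1, copies_b = 1)
  }
  split_rows <- function(df) {
    purrr::map_dfr(seq_len(nrow(df)), function(i) {
      ca <- df$copies_a[i]; cb <- df$copies_b[i]
      if (df$fraction[i] <= 0 || ca + cb == 0) return(NULL)
      tibble(population = df$population[i],
             haplotype = c(rep("A", ca), rep("B", cb)),
             copy_index = c(seq_len(ca), seq_len(cb)),
             w = df$fraction[i])
    })
  }
  lapply(split(pops, pops$segment_id), split_rows)
}

#' Sample fragment draws from the modulated read-depth model
#'
#' Low-level building block of [generate_sample()]; draws fragment start
#' positions, cell population, haplotype, haplotype copy, strand and insert
#' size for `n` fragments. Uses the current RNG state.
#'
#' @param rdm An `rdm_model`.
#' @param segments A [resolve_segments()] table or `NULL`.
#' @param n Number of fragments.
#' @param read_length Read length (lower truncation bound for inserts).
#' @param paired Paired-end flag; defaults to the model's.
#' @param strand_bias P(forward strand).
#' @param insert_mean,insert_sd Insert distribution; default from the model.
#' @param chrom_lengths Named vector of chromosome lengths (for bounding
#'   inserts); optional.
#' @param pos_tab Precomputed [position_distribution()] (optional, for reuse).
#' @return Tibble of fragment draws: `chrom`, `start` (0-based), `segment_id`,
#'   `population`, `haplotype`, `copy_index`, `strand`, `insert`, `end`.
#' @export
sample_fragments <- function(rdm, segments, n, read_length,
                             paired = rdm$paired, strand_bias = 0.5,
                             insert_mean = rdm$insert_mean,
                             insert_sd = rdm$insert_sd,
                             chrom_lengths = NULL, pos_tab = NULL) {
  if (is.null(pos_tab)) pos_tab <- position_distribution(rdm, segments)
  combos <- segment_combos(segments)
  L <- as.integer(read_length)
  idx <- sample.int(nrow(pos_tab), n, replace = TRUE, prob = pos_tab$prob)
  chrom <- pos_tab$chrom[idx]
  p <- pos_tab$pos[idx]
  seg <- pos_tab$segment_id[idx]
  population <- character(n); haplotype <- character(n)
  copy_index <- integer(n)
  for (s in unique(seg)) {
    rows <- which(seg == s)
    cmb <- combos[[as.character(s)]]
    if (is.null(cmb) || !nrow(cmb)) {
      stop_generation(sprintf("segment %s has no cells with positive copy number", s))
    }
    k <- sample.int(nrow(cmb), length(rows), replace = TRUE, prob = cmb$w)
    population[rows] <- cmb$population[k]
    haplotype[rows] <- cmb$haplotype[k]
    copy_index[rows] <- cmb$copy_index[k]
  }
  strand <- ifelse(runif(n) < strand_bias, "+", "-")
  if (paired) {
    if (is.null(insert_mean) || is.na(insert_mean)) {
      stop_generation("paired generation requires insert statistics (none in model or plan)")
    }
    if (is.na(insert_sd)) insert_sd <- 0
    maxlen <- if (!is.null(chrom_lengths)) {
      unname(chrom_lengths[chrom])
    } else rep(Inf, n)
    ins <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
    for (try in seq_len(100L)) {
      bad <- which(ins < L | p + ins > maxlen)
      if (!length(bad)) break
      ins[bad] <- as.integer(round(rnorm(length(bad), insert_mean, insert_sd)))
    }
    bad <- which(ins < L | p + ins > maxlen)
    if (length(bad)) {
      ins[bad] <- pmax(L, pmin(ins[bad], as.integer(maxlen[bad] - p[bad])))
    }
    frag_end <- p + ins
  } else {
    ins <- NA_integer_
    frag_end <- p + L
  }
  tibble(chrom = chrom, start = p, segment_id = seg, population = population,
         haplotype = haplotype, copy_index = copy_index, strand = strand,
         insert = ins, end = frag_end)
}

#' Materialize raw read sequences for fragment draws
#'
#' Extracts reference sequence for each mate and substitutes phased SNP
#' alleles matching the drawn haplotype. Matrices are kept in genomic (plus
#' strand) orientation; orientation flips happen at FASTQ emission.
#'
#' @param draws A [sample_fragments()] tibble.
#' @param reference FASTA path.
#' @param snps Phased SNP tibble (may be empty).
#' @param read_length Read length.
#' @param paired Paired-end flag.
#' @return List with per-mate base matrices (`mat1`, `mat2`) and 0-based mate
#'   start vectors (`start1`, `start2`); `mat2`/`start2` are `NULL` for
#'   single-end draws.
#' @export
build_read_sequences <- function(draws, reference, snps, read_length,
                                 paired = TRUE) {
  L <- as.integer(read_length)
  fa <- Rsamtools::FaFile(reference)
  start1 <- draws$start
  mat1 <- seq_matrix(fa, draws$chrom, start1, L)
  mat1 <- apply_snps(mat1, draws, start1, snps, L)
  mat2 <- NULL; start2 <- NULL
  if (paired) {
    start2 <- draws$end - L
    mat2 <- seq_matrix(fa, draws$chrom, start2, L)
    mat2 <- apply_snps(mat2, draws, start2, snps, L)
  }
  list(mat1 = mat1, mat2 = mat2, start1 = start1, start2 = start2)
}

seq_matrix <- function(fa, chrom, start0, L) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, width = L))
  m <- as.matrix(Biostrings::getSeq(fa, gr))
  m[] <- toupper(m)
  m
}

apply_snps <- function(mat, draws, start0, snps, L) {
  if (is.null(snps) || !nrow(snps)) return(mat)
  for (i in seq_len(nrow(snps))) {
    rows <- which(draws$chrom == snps$chrom[i] &
                    start0 <= snps$pos[i] & snps$pos[i] < start0 + L &
                    draws$haplotype == snps$phase[i])
    if (length(rows)) {
      mat[cbind(rows, snps$pos[i] - start0[rows] + 1L)] <- snps$alt[i]
    }
  }
  mat
}

apply_pms <- function(mat, draws, start0, pms, L) {
  if (is.null(pms) || !nrow(pms)) return(mat)
  for (i in seq_len(nrow(pms))) {
    rows <- which(draws$chrom == pms$chrom[i] &
                    start0 <= pms$pos[i] & pms$pos[i] < start0 + L &
                    draws$population == pms$clone_id[i] &
                    draws$haplotype == pms$allele[i] &
                    draws$copy_index <= pms$multiplicity[i])
    if (length(rows)) {
      mat[cbind(rows, pms$pos[i] - start0[rows] + 1L)] <- pms$alt[i]
    }
  }
  mat
}

#' Apply base qualities and sequencing errors to raw reads
#'
#' For each read cycle whose genomic position carries a position-based
#' systematic error, the base is substituted with that site's error rate using
#' its alternate-base profile; every other cycle draws a Phred quality Q from
#' the quality model's cycle histogram and is substituted with probability
#' 10^(-Q/10), uniformly among the three other bases. Qualities for all cycles
#' are drawn from the quality model. Matrices are in genomic orientation;
#' `reverse` marks reads sequenced right-to-left, whose cycles map to reversed
#' columns.
#'
#' @param mat Base matrix (reads by genomic offset).
#' @param start0 0-based genomic start of each row.
#' @param chrom Chromosome of each row.
#' @param reverse Logical per row: sequenced in reverse orientation.
#' @param qm A `quality_model`.
#' @param pbe A `pbe_model` (may have zero sites).
#' @return List: `mat` (bases after errors), `qual` (integer Phred matrix in
#'   cycle orientation, i.e. FASTQ order).
#' @export
apply_quality_and_errors <- function(mat, start0, chrom, reverse, qm, pbe) {
  n <- nrow(mat); L <- ncol(mat)
  probs <- qm_probs(qm)
  if (L > ncol(probs)) {
    stop_generation(sprintf("read length %d exceeds the %d cycles of the quality model",
                            L, ncol(probs)))
  }
  qcyc <- matrix(0L, n, L)
  for (cc in seq_len(L)) {
    qcyc[, cc] <- sample.int(94L, n, replace = TRUE, prob = probs[, cc]) - 1L
  }
  qg <- qcyc
  if (any(reverse)) qg[reverse, ] <- qg[reverse, L:1, drop = FALSE]
  is_pbe <- matrix(FALSE, n, L)
  sites <- pbe$sites
  if (nrow(sites)) {
    for (ch in unique(chrom)) {
      sc <- sites[sites$chrom == ch, ]
      if (!nrow(sc)) next
      cand <- which(chrom == ch)
      for (i in seq_len(nrow(sc))) {
        rows <- cand[start0[cand] <= sc$pos[i] & sc$pos[i] < start0[cand] + L]
        if (!length(rows)) next
        cols <- sc$pos[i] - start0[rows] + 1L
        is_pbe[cbind(rows, cols)] <- TRUE
        hit <- runif(length(rows)) < sc$error_rate[i]
        if (any(hit)) {
          prof <- c(sc$p_A[i], sc$p_C[i], sc$p_G[i], sc$p_T[i])
          alt <- BASES[sample.int(4L, sum(hit), replace = TRUE, prob = prof)]
          mat[cbind(rows[hit], cols[hit])] <- alt
        }
      }
    }
  }
  perr <- 10^(-qg / 10)
  sub <- matrix(runif(n * L), n, L) < perr & !is_pbe
  cells <- which(sub)
  if (length(cells)) {
    cur <- mat[cells]
    bi <- match(cur, BASES)
    pick <- sample.int(3L, length(cells), replace = TRUE)
    new <- ifelse(is.na(bi), BASES[sample.int(4L, length(cells), replace = TRUE)],
                  OTHER_BASES[cbind(pmax(bi, 1L), pick)])
    mat[cells] <- new
  }
  list(mat = mat, qual = qcyc)
}

revcomp_rows <- function(mat, rows) {
  if (!length(rows)) return(mat)
  L <- ncol(mat)
  flipped <- mat[rows, L:1, drop = FALSE]
  flipped[] <- COMPLEMENT[flipped]
  flipped[is.na(flipped)] <- "N"
  mat[rows, ] <- flipped
  mat
}

collapse_rows <- function(mat) do.call(paste0, asplit(mat, 2))

fastq_records <- function(names, seqs, quals) {
  as.vector(rbind(paste0("@", names), seqs, "+", quals))
}
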