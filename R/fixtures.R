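# Synthetic fixtures: toy reference genomes, capture panels,
# truth-parameterized BAM files and directly constructed reference models.
# Everything is generated programmatically from a seed, so the whole pipeline
# is testable without external data.

#' Specification for a synthetic test fixture
#'
#' @param n_chromosomes Number of toy chromosomes (`fix1`, `fix2`, ...).
#' @param chromosome_length Length of each chromosome in bases.
#' @param n_targets Total number of capture targets (spread round-robin over
#'   chromosomes).
#' @param target_length Length of each target in bases.
#' @param depth_profile `"uniform"` (equal fragment-start weights) or
#'   `"peaked"` (triangular peak at the target centre).
#' @param fragments_per_target Fragments per target written to truth BAMs.
#' @param quality_profile `"constant"` (all bases at `q_constant`) or
#'   `"ramp"` (linear decay from `q_constant` to `q_constant - 15` across the
#'   read, floored at 2).
#' @param q_constant Phred quality for the constant profile / ramp start.
#' @param error_positions Optional tibble of injected systematic errors:
#'   `chrom`, `pos` (0-based), `rate` in (0,1], `alt` base.
#' @param insert_mean,insert_sd Insert-size statistics; truth BAMs use a fixed
#'   template length of `insert_mean`.
#' @param read_length Read length.
#' @param paired Paired-end flag.
#' @param off_target_fragments Extra fragments placed between targets (to test
#'   off-target exclusion).
#' @param seed Seed controlling every random choice in the fixture.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chromosomes = 1L, chromosome_length = 30000L,
                         n_targets = 4L, target_length = 500L,
                         depth_profile = c("uniform", "peaked"),
                         fragments_per_target = 100L,
                         quality_profile = c("constant", "ramp"),
                         q_constant = 30L,
                         error_positions = NULL,
                         insert_mean = 300L, insert_sd = 0,
                         read_length = 100L, paired = TRUE,
                         off_target_fragments = 0L, seed = 1L) {
  depth_profile <- match.arg(depth_profile)
  quality_profile <- match.arg(quality_profile)
  if (!is.null(error_positions)) {
    error_positions <- as_tibble(error_positions)
    stopifnot(all(c("chrom", "pos", "rate", "alt") %in% names(error_positions)),
              all(error_positions$rate > 0), all(error_positions$rate <= 1))
  }
  margin <- insert_mean + 6 * insert_sd + read_length
  per_chrom <- ceiling(n_targets / n_chromosomes)
  if (margin * 2 + per_chrom * (target_length + 200) > chromosome_length) {
    stop_validation("targets do not fit within chromosomes; enlarge chromosome_length")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 n_targets = as.integer(n_targets),
                 target_length = as.integer(target_length),
                 depth_profile = depth_profile,
                 fragments_per_target = as.integer(fragments_per_target),
                 quality_profile = quality_profile,
                 q_constant = as.integer(q_constant),
                 error_positions = error_positions,
                 insert_mean = as.integer(insert_mean),
                 insert_sd = insert_sd,
                 read_length = as.integer(read_length), paired = paired,
                 off_target_fragments = as.integer(off_target_fragments),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_chrom_names <- function(spec) paste0("fix", seq_len(spec$n_chromosomes))

#' Capture panel implied by a fixture spec
#' @param spec A [fixture_spec()].
#' @return [target_regions()] with targets evenly spaced on each chromosome.
#' @export
fixture_targets <- function(spec) {
  chroms <- fixture_chrom_names(spec)
  margin <- spec$insert_mean + 6 * spec$insert_sd + spec$read_length
  idx <- rep(seq_along(chroms), length.out = spec$n_targets)
  rows <- lapply(seq_along(chroms), function(ci) {
    k <- sum(idx == ci)
    if (!k) return(NULL)
    span <- spec$chromosome_length - 2 * margin
    gap <- floor((span - k * spec$target_length) / max(1, k))
    start <- as.integer(margin + (seq_len(k) - 1L) * (spec$target_length + gap))
    tibble(chrom = chroms[ci], start = start,
           end = start + spec$target_length)
  })
  target_regions(bind_rows(rows))
}

#' Write a deterministic toy reference genome
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Path to the indexed FASTA.
#' @export
make_reference <- function(spec, dir = tempdir()) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("fixture_ref_seed%d.fa", spec$seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  seqs <- Biostrings::DNAStringSet(vapply(fixture_chrom_names(spec), function(ch) {
    paste(sample(BASES, spec$chromosome_length, replace = TRUE), collapse = "")
  }, ""))
  names(seqs) <- fixture_chrom_names(spec)
  Biostrings::writeXStringSet(seqs, path)
  Rsamtools::indexFa(path)
  path
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

fixture_qualities <- function(spec) {
  if (spec$quality_profile == "constant") {
    rep(spec$q_constant, spec$read_length)
  } else {
    pmax(2L, as.integer(round(seq(spec$q_constant, spec$q_constant - 15L,
                                  length.out = spec$read_length))))
  }
}

#' Write a truth-parameterized toy BAM
#'
#' Generates a coordinate-sorted, indexed BAM of error-free reads (except the
#' injected `error_positions`) with known per-position fragment-start counts,
#' the spec's quality profile and a fixed template length, plus a sidecar
#' truth object recording exact counts for oracle comparisons. Fragments
#' alternate between forward and reverse orientation so that reverse-strand
#' handling is exercised.
#'
#' @param spec A [fixture_spec()].
#' @param reference FASTA from [make_reference()].
#' @param dir Output directory.
#' @param n_duplicates Number of duplicate-flagged extra reads (filter tests).
#' @param n_lowmq Number of extra MAPQ-0 fragments (PBE filter tests).
#' @return List: `bam` path, `truth` (list with `start_counts`,
#'   `error_truth`, `qualities`, `template_length`, `n_fragments`).
#' @export
make_truth_bam <- function(spec, reference, dir = tempdir(),
                           n_duplicates = 0L, n_lowmq = 0L) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  targets <- fixture_targets(spec)
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*", "", names(ref))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed + 1L)
  L <- spec$read_length
  tlen <- spec$insert_mean
  quals <- fixture_qualities(spec)
  qstr_fwd <- paste(phred_chars(quals), collapse = "")
  qstr_rev <- paste(rev(phred_chars(quals)), collapse = "")

  starts <- list(); chroms <- list()
  for (i in seq_len(nrow(targets))) {
    cand <- seq(targets$start[i], targets$end[i] - 1L)
    pr <- if (spec$depth_profile == "uniform") {
      NULL
    } else {
      mid <- mean(range(cand))
      w <- 1 + pmax(0, 1 - abs(cand - mid) / (length(cand) / 2)) * 4
      w / sum(w)
    }
    starts[[i]] <- sample(cand, spec$fragments_per_target, replace = TRUE,
                          prob = pr)
    chroms[[i]] <- rep(targets$chrom[i], spec$fragments_per_target)
  }
  frag <- tibble(chrom = unlist(chroms), start = unlist(starts))
  if (spec$off_target_fragments > 0L) {
    gap_pos <- targets$end[1] + 5L * L  # between targets, outside capture
    frag_off <- tibble(chrom = targets$chrom[1],
                       start = rep(gap_pos, spec$off_target_fragments))
    frag_all <- bind_rows(frag, frag_off)
  } else {
    frag_all <- frag
  }
  n <- nrow(frag_all)
  fwd <- seq_len(n) %% 2L == 1L  # alternate fragment orientation

  err <- spec$error_positions
  if (!is.null(err) && nrow(err)) {
    refbase <- vapply(seq_len(nrow(err)), function(k) {
      as.character(Biostrings::subseq(ref[[err$chrom[k]]],
                                      err$pos[k] + 1L, err$pos[k] + 1L))
    }, "")
    clash <- which(toupper(err$alt) == refbase)
    if (length(clash)) {
      stop_validation(sprintf(
        "injected error alt base equals the reference base at %s:%d",
        err$chrom[clash[1]], err$pos[clash[1]] + 1L))
    }
  }
  err_depth <- err_alt <- if (!is.null(err)) rep(0L, nrow(err)) else integer(0)
  slice <- function(ch, s) {
    as.character(Biostrings::subseq(ref[[ch]], s + 1L, s + L))
  }
  lines <- character(0)
  add_read <- function(qname, flag, ch, pos0, mapq, mpos0, tl, seq, qual) {
    paste(qname, flag, ch, pos0 + 1L, mapq, paste0(L, "M"), "=",
          mpos0 + 1L, tl, seq, qual, sep = "\t")
  }
  inject <- function(seqs, ch, s0) {
    # seqs: character vector; s0: 0-based starts (same length)
    if (is.null(err)) return(seqs)
    for (k in seq_len(nrow(err))) {
      cover <- which(ch == err$chrom[k] & s0 <= err$pos[k] &
                       err$pos[k] < s0 + L)
      if (!length(cover)) next
      hit <- runif(length(cover)) < err$rate[k]
      err_depth[k] <<- err_depth[k] + length(cover)
      err_alt[k] <<- err_alt[k] + sum(hit)
      off <- err$pos[k] - s0[cover] + 1L
      for (j in which(hit)) {
        substr(seqs[cover[j]], off[j], off[j]) <- err$alt[k]
      }
    }
    seqs
  }
  mk_pair <- function(i, qname, mapq = 60L, dupflag = 0L) {
    ch <- frag_all$chrom[i]; p <- frag_all$start[i]
    s2 <- p + tlen - L
    seqs <- inject(c(slice(ch, p), slice(ch, s2)), c(ch, ch), c(p, s2))
    if (fwd[i]) {
      c(add_read(qname, 99L + dupflag, ch, p, mapq, s2, tlen, seqs[1], qstr_fwd),
        add_read(qname, 147L + dupflag, ch, s2, mapq, p, -tlen, seqs[2], qstr_rev))
    } else {
      # leftmost mate is the second-in-pair, read on the reverse strand at the
      # right end: R1 right reverse (83), R2 left forward (163)
      c(add_read(qname, 163L + dupflag, ch, p, mapq, s2, tlen, seqs[1], qstr_fwd),
        add_read(qname, 83L + dupflag, ch, s2, mapq, p, -tlen, seqs[2], qstr_rev))
    }
  }
  mk_single <- function(i, qname, mapq = 60L, dupflag = 0L) {
    ch <- frag_all$chrom[i]; p <- frag_all$start[i]
    seq <- inject(slice(ch, p), ch, p)
    if (fwd[i]) {
      add_read(qname, 0L + dupflag, ch, p, mapq, -1L, 0L, seq, qstr_fwd)
    } else {
      add_read(qname, 16L + dupflag, ch, p, mapq, -1L, 0L, seq, qstr_rev)
    }
  }
  for (i in seq_len(n)) {
    qname <- sprintf("frag%06d", i)
    lines <- c(lines, if (spec$paired) mk_pair(i, qname) else mk_single(i, qname))
  }
  if (n_duplicates > 0L) {
    for (i in seq_len(min(n_duplicates, n))) {
      qname <- sprintf("dup%06d", i)
      lines <- c(lines, if (spec$paired) mk_pair(i, qname, dupflag = 1024L)
                 else mk_single(i, qname, dupflag = 1024L))
    }
  }
  if (n_lowmq > 0L) {
    for (i in seq_len(min(n_lowmq, n))) {
      qname <- sprintf("lmq%06d", i)
      lines <- c(lines, if (spec$paired) mk_pair(i, qname, mapq = 0L)
                 else mk_single(i, qname, mapq = 0L))
    }
  }
  chrom_order <- setNames(seq_len(spec$n_chromosomes), fixture_chrom_names(spec))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ord <- order(chrom_order[vapply(fields, `[`, "", 3L)],
               as.integer(vapply(fields, `[`, "", 4L)))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", fixture_chrom_names(spec),
                      spec$chromosome_length))
  sam <- file.path(dir, sprintf("fixture_seed%d.sam", spec$seed))
  writeLines(c(header, lines[ord]), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                          indexDestination = TRUE)
  start_counts <- frag |>
    group_by(.data$chrom, .data$start) |>
    summarise(count = dplyr::n(), .groups = "drop") |>
    arrange(.data$chrom, .data$start)
  error_truth <- if (!is.null(err)) {
    mutate(err, depth = err_depth, alt_count = err_alt,
           observed_rate = ifelse(err_depth > 0, err_alt / err_depth, 0))
  } else NULL
  list(bam = bam,
       truth = list(start_counts = start_counts, error_truth = error_truth,
                    qualities = quals, template_length = tlen,
                    n_fragments = nrow(frag)))
}

#' Construct reference models directly from a fixture spec
#'
#' Builds the read-depth, quality and position-error models analytically,
#' bypassing BAM files; used to test the read engine in isolation and as the
#' expected value for models built from [make_truth_bam()] output.
#'
#' @param spec A [fixture_spec()].
#' @return A [model_bundle()].
#' @export
make_models_direct <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  targets <- fixture_targets(spec)
  weights <- lapply(seq_len(nrow(targets)), function(i) {
    len <- targets$end[i] - targets$start[i]
    if (spec$depth_profile == "uniform") {
      rep(1, len)
    } else {
      pos <- seq_len(len)
      1 + pmax(0, 1 - abs(pos - mean(range(pos))) / (len / 2)) * 4
    }
  })
  rdm <- new_rdm(regions = as_tibble(targets), weights = weights,
                 norm = sum(unlist(weights)),
                 insert_mean = as.numeric(spec$insert_mean),
                 insert_sd = as.numeric(spec$insert_sd),
                 paired = spec$paired,
                 read_length_observed = spec$read_length,
                 n_source_samples = 0L)
  quals <- fixture_qualities(spec)
  counts <- matrix(0, 94L, spec$read_length)
  counts[cbind(quals + 1L, seq_len(spec$read_length))] <- 1000
  qm <- new_qm(counts)
  err <- spec$error_positions
  sites <- if (is.null(err) || !nrow(err)) {
    empty_pbe_sites()
  } else {
    prof <- matrix(0, nrow(err), 4, dimnames = list(NULL, BASES))
    prof[cbind(seq_len(nrow(err)), match(toupper(err$alt), BASES))] <- 1
    tibble(chrom = err$chrom, pos = as.integer(err$pos),
           error_rate = err$rate,
           p_A = prof[, "A"], p_C = prof[, "C"],
           p_G = prof[, "G"], p_T = prof[, "T"]) |>
      arrange(.data$chrom, .data$pos)
  }
  pbe <- new_pbe(sites, 20L, 20L, 50L, 0.005)
  model_bundle(rdm, qm, pbe)
}

#' Place phased heterozygous SNPs evenly across a panel
#'
#' Convenience profile builder for simulations and tests: positions are spread
#' evenly over the captured space (optionally restricted to an interval), ref
#' bases taken from the genome, alternates chosen deterministically and phases
#' alternating A/B.
#'
#' @param reference FASTA path.
#' @param targets A [target_regions()] panel.
#' @param n Number of SNPs.
#' @param region Optional `c(chrom, start, end)`-style list restricting
#'   placement (`list(chrom=, start=, end=)`, 0-based half-open).
#' @return Phased-SNP tibble.
#' @export
place_phased_snps <- function(reference, targets, n, region = NULL) {
  tt <- as_tibble(targets)
  if (!is.null(region)) {
    tt <- tt |>
      filter(.data$chrom == region$chrom, .data$end > region$start,
             .data$start < region$end) |>
      mutate(start = pmax(.data$start, region$start),
             end = pmin(.data$end, region$end))
  }
  if (!nrow(tt)) stop_validation("no captured space to place SNPs in")
  all_pos <- tibble(chrom = rep(tt$chrom, tt$end - tt$start),
                    pos = unlist(purrr::map2(tt$start, tt$end,
                                             ~seq(.x, .y - 1L))))
  take <- unique(as.integer(round(seq(1, nrow(all_pos), length.out = n))))
  sel <- all_pos[take, ]
  ref <- fetch_ref_base(reference, sel$chrom, sel$pos)
  alt <- BASES[(match(ref, BASES) %% 4L) + 1L]
  tibble(chrom = sel$chrom, pos = sel$pos, ref = ref, alt = alt,
         phase = rep(c("A", "B"), length.out = nrow(sel)))
}
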