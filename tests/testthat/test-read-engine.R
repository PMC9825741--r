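# Read generation mechanics: budgets, determinism, haplotype carriage,
# error/quality application, strand and insert behavior.

test_that("the read budget is honored exactly and names encode provenance", {
  fx <- fx_gen()
  prof <- genome_profile()
  plan <- sample_plan(name = "bud", kind = "tumor", n_reads = 1000L,
                      read_length = 80L, paired = FALSE, seed = 2L)
  out <- file.path(fx_dir(), "budget")
  rep <- generate_sample(fx$models, fx$reference, prof, plan, out)
  lines <- readLines(paste0(out, ".fastq"))
  expect_equal(length(lines), 4000L)
  expect_equal(rep$n_records, 1000L)
  heads <- lines[seq(1, length(lines), 4)]
  expect_true(all(grepl("^@bud:\\d+:fix[12]:\\d+$", heads)))
  expect_false(any(duplicated(heads)))
  # every sequence has the requested read length
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == 80L))
})

test_that("output is byte-identical across worker counts and reruns", {
  fx <- fx_gen()
  prof <- genome_profile()
  md5 <- function(threads, tag) {
    plan <- sample_plan(name = "det", kind = "tumor", n_reads = 500L,
                        read_length = 60L, paired = TRUE, seed = 33L)
    out <- file.path(fx_dir(), paste0("det", tag))
    generate_sample(fx$models, fx$reference, prof, plan, out,
                    threads = threads)
    tools::md5sum(c(paste0(out, "_R1.fastq"), paste0(out, "_R2.fastq")))
  }
  a <- md5(1L, "a"); b <- md5(4L, "b"); c2 <- md5(1L, "c")
  expect_equal(unname(a), unname(b))
  expect_equal(unname(a), unname(c2))
})

test_that("zero tumor content draws only normal cells with balanced haplotypes", {
  fx <- fx_gen()
  cna <- tibble::tibble(chrom = fx$targets$chrom[1],
                        start = fx$targets$start[1], end = fx$targets$end[1],
                        copies_a = 3L, copies_b = 0L, clone_id = "c1",
                        clonality = 1)
  prof <- genome_profile(cnas = cna)
  plan <- sample_plan(name = "t0", kind = "tumor", tumor_content = 0,
                      n_reads = 4000L, read_length = 80L, paired = FALSE,
                      seed = 5L)
  out <- file.path(fx_dir(), "t0")
  rep <- generate_sample(fx$models, fx$reference, prof, plan, out)
  tr <- readr::read_tsv(paste0(out, ".truth.tsv"), show_col_types = FALSE)
  expect_true(all(tr$population == "normal"))
  expect_true(within_binom_ci(sum(tr$haplotype == "A"), nrow(tr), 0.5))
  # all segments stay diploid in the report
  expect_true(all(rep$segments$coverage_factor == 1))
})

test_that("a doubled-dosage segment is sampled at twice the per-base rate", {
  fx <- fx_gen()
  cna <- tibble::tibble(chrom = fx$targets$chrom[1],
                        start = fx$targets$start[1], end = fx$targets$end[1],
                        copies_a = 2L, copies_b = 2L, clone_id = "c1",
                        clonality = 1)
  segments <- resolve_segments(cna, fx$targets, tumor_content = 1)
  set.seed(8)
  draws <- sample_fragments(fx$models$rdm, segments, n = 50000L,
                            read_length = 80L, paired = FALSE)
  in_seg <- draws$chrom == fx$targets$chrom[1] &
    draws$start >= fx$targets$start[1] & draws$start < fx$targets$end[1]
  # uniform RDM over 8 equal targets; doubled segment expects share 2/9
  expect_true(within_binom_ci(sum(in_seg), length(in_seg), 2 / 9))
})

test_that("phased SNPs are carried by exactly the matching haplotype", {
  fx <- fx_gen()
  pos <- fx$targets$start[1] + 40L
  ref <- oncoreads:::fetch_ref_base(fx$reference, fx$targets$chrom[1], pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snps <- tibble::tibble(chrom = fx$targets$chrom[1], pos = pos,
                         ref = ref, alt = alt, phase = "B")
  draws <- tibble::tibble(chrom = fx$targets$chrom[1],
                          start = rep(fx$targets$start[1], 4L),
                          segment_id = 1L,
                          population = "normal",
                          haplotype = c("A", "B", "A", "B"),
                          copy_index = 1L, strand = "+",
                          insert = 300L, end = fx$targets$start[1] + 300L)
  seqs <- build_read_sequences(draws, fx$reference, snps,
                               read_length = 80L, paired = TRUE)
  col <- pos - fx$targets$start[1] + 1L
  expect_equal(seqs$mat1[, col], c(ref, alt, ref, alt), ignore_attr = TRUE)
  # reference base sanity for the unaffected mate
  expect_true(all(seqs$mat2[, 1] %in% c("A", "C", "G", "T")))
})

test_that("PM carriage respects population, allele and copy index", {
  fx <- fx_gen()
  pos <- fx$targets$start[1] + 10L
  ref <- oncoreads:::fetch_ref_base(fx$reference, fx$targets$chrom[1], pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  pms <- tibble::tibble(chrom = fx$targets$chrom[1], pos = pos, ref = ref,
                        alt = alt, allele = "A", multiplicity = 1L,
                        clone_id = "c1", clonality = 1)
  draws <- tibble::tibble(chrom = fx$targets$chrom[1],
                          start = rep(fx$targets$start[1], 4L),
                          segment_id = 1L,
                          population = c("c1", "c1", "c1", "normal"),
                          haplotype = c("A", "A", "B", "A"),
                          copy_index = c(1L, 2L, 1L, 1L),
                          strand = "+", insert = NA_integer_,
                          end = fx$targets$start[1] + 60L)
  mat <- matrix(ref, 4L, 60L)
  out <- oncoreads:::apply_pms(mat, draws, draws$start, pms, 60L)
  got <- out[, 11L]
  # only the clone's allele-A copy 1 carries the mutation (multiplicity 1 of 2)
  expect_equal(got, c(alt, ref, ref, ref), ignore_attr = TRUE)
})

test_that("degenerate PBE and quality settings behave as limits dictate", {
  fx <- fx_gen()
  # PBE with rate 1 and a point profile always substitutes that base
  pos <- fx$targets$start[1] + 5L
  pbe1 <- oncoreads:::new_pbe(tibble::tibble(
    chrom = fx$targets$chrom[1], pos = pos, error_rate = 1,
    p_A = 0, p_C = 0, p_G = 0, p_T = 1), 20L, 20L, 50L, 0.005)
  qm93 <- oncoreads:::new_qm({
    m <- matrix(0, 94, 60); m[94, ] <- 1; m
  })
  mat <- matrix("A", 200L, 60L)
  set.seed(1)
  res <- apply_quality_and_errors(mat, rep(fx$targets$start[1], 200L),
                                  rep(fx$targets$chrom[1], 200L),
                                  rep(FALSE, 200L), qm93, pbe1)
  expect_true(all(res$mat[, 6L] == "T"))
  # Q93: substitution probability 10^-9.3; nothing else changes in 200x60
  expect_true(all(res$mat[, -6L] == "A"))
  expect_true(all(res$qual == 93L))

  # Q10 point mass: per-base substitution rate ~0.1
  qm10 <- oncoreads:::new_qm({
    m <- matrix(0, 94, 60); m[11, ] <- 1; m
  })
  set.seed(2)
  res10 <- apply_quality_and_errors(matrix("A", 2000L, 60L),
                                    rep(fx$targets$start[1], 2000L),
                                    rep(fx$targets$chrom[1], 2000L),
                                    rep(FALSE, 2000L), qm10,
                                    oncoreads:::new_pbe(
                                      oncoreads:::empty_pbe_sites(),
                                      20L, 20L, 50L, 0.005))
  n_sub <- sum(res10$mat != "A")
  expect_true(within_binom_ci(n_sub, 2000L * 60L, 0.1))
})

test_that("constant insert model reproduces the template length exactly", {
  fx <- fx_base()  # insert_sd = 0
  prof <- genome_profile()
  plan <- sample_plan(name = "ins", kind = "tumor", n_reads = 400L,
                      read_length = 100L, paired = TRUE, seed = 12L)
  out <- file.path(fx_dir(), "ins0")
  rep <- generate_sample(fx$models, fx$reference, prof, plan, out)
  tr <- readr::read_tsv(paste0(out, ".truth.tsv"), show_col_types = FALSE)
  expect_true(all(tr$insert == 300L))
  expect_equal(rep$insert_mean_realized, 300)
  expect_equal(rep$insert_sd_realized, 0)
})

test_that("insert sampling recovers the model's normal distribution", {
  fx <- fx_gen()  # insert 300 +/- 30, read length below truncation range
  set.seed(21)
  draws <- sample_fragments(fx$models$rdm, resolve_segments(NULL, fx$targets, 0),
                            n = 30000L, read_length = 100L, paired = TRUE,
                            chrom_lengths = oncoreads:::fasta_seqlengths(fx$reference))
  expect_equal(mean(draws$insert), 300, tolerance = 0.01)
  expect_equal(sd(draws$insert), 30, tolerance = 0.05)
  expect_true(all(draws$insert >= 100L))
})

test_that("matched controls ignore somatic events entirely", {
  fx <- fx_gen()
  snps <- place_phased_snps(fx$reference, fx$targets, 6)
  cna <- tibble::tibble(chrom = fx$targets$chrom[1],
                        start = fx$targets$start[1], end = fx$targets$end[1],
                        copies_a = 0L, copies_b = 0L, clone_id = "c1",
                        clonality = 1)
  prof <- genome_profile(snps, cna, reference = fx$reference)
  plan <- sample_plan(name = "ctl", kind = "matched_control",
                      tumor_content = 0.9, n_reads = 1500L,
                      read_length = 80L, paired = FALSE, seed = 9L)
  out <- file.path(fx_dir(), "ctl")
  rep <- generate_sample(fx$models, fx$reference, prof, plan, out)
  expect_equal(rep$tumor_content, 0)
  expect_true(all(rep$segments$expected_log2 == 0))
  ev <- tidy(rep)
  expect_true(all(ev$expected_af[ev$type == "snp"] == 0.5))
})

test_that("report AF tallies agree with an independent FASTQ re-measurement", {
  fx <- fx_gen()
  snps <- place_phased_snps(fx$reference, fx$targets, 4)
  prof <- genome_profile(snps, reference = fx$reference)
  plan <- sample_plan(name = "dual", kind = "tumor", n_reads = 1200L,
                      read_length = 80L, paired = TRUE, seed = 14L)
  out <- file.path(fx_dir(), "dual")
  rep <- generate_sample(fx$models, fx$reference, prof, plan, out)
  ev <- tidy(rep)
  remeasured <- measure_af_from_fastq(
    out, dplyr::mutate(snps, alt = snps$alt), read_length = 80L,
    paired = TRUE)
  expect_equal(ev$depth, remeasured$depth)
  expect_equal(ev$alt_count, remeasured$alt_count)
})

test_that("all-zero modulated weights abort generation", {
  fx <- fx_gen()
  cna <- tibble::tibble(chrom = fx$targets$chrom,
                        start = fx$targets$start, end = fx$targets$end,
                        copies_a = 0L, copies_b = 0L, clone_id = "c1",
                        clonality = 1)
  segments <- resolve_segments(cna, fx$targets, tumor_content = 1)
  expect_error(position_distribution(fx$models$rdm, segments),
               class = "oncoreads_generation_error")
})
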