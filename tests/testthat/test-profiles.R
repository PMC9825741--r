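# Profile parsing and dosage-segment resolution.

write_vcf <- function(rows, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    rows), path)
  path
}

test_that("phased VCF genotypes map to haplotypes by the left-of-bar rule", {
  vcf <- write_vcf(c(
    "chr1\t101\t.\tA\tC\t.\tPASS\t.\tGT\t0|1",
    "chr1\t201\t.\tG\tT\t.\tPASS\t.\tGT\t1|0",
    "chr1\t301\t.\tT\tA\t.\tPASS\t.\tGT\t0|0",
    "chr1\t401\t.\tC\tG\t.\tPASS\t.\tGT\t1|1"),
    withr::local_tempfile(fileext = ".vcf"))
  snps <- suppressMessages(parse_snps(vcf))
  expect_equal(nrow(snps), 2L)
  # GT 0|1: alt on haplotype B; GT 1|0: alt on haplotype A
  expect_equal(snps$phase[snps$pos == 100L], "B")
  expect_equal(snps$phase[snps$pos == 200L], "A")
  # VCF 1-based to internal 0-based
  expect_equal(sort(snps$pos), c(100L, 200L))
})

test_that("unphased heterozygotes are an error; multiallelics are skipped", {
  vcf <- write_vcf("chr1\t101\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",
                   withr::local_tempfile(fileext = ".vcf"))
  expect_error(suppressMessages(parse_snps(vcf)),
               class = "oncoreads_validation_error", regexp = "unphased")

  vcf2 <- write_vcf(c("chr1\t101\t.\tA\tC,G\t.\tPASS\t.\tGT\t0|1",
                      "chr1\t201\t.\tG\tT\t.\tPASS\t.\tGT\t0|1"),
                    withr::local_tempfile(fileext = ".vcf"))
  expect_warning(snps <- suppressMessages(parse_snps(vcf2)),
                 regexp = "multiallelic")
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pos, 200L)
})

test_that("TSV SNP tables parse with 1-based positions and phases", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tphase",
               "chr1\t101\tA\tC\tB",
               "chr1\t201\tG\tT\tA"), tsv)
  snps <- parse_snps(tsv)
  expect_equal(snps$pos, c(100L, 200L))
  expect_equal(snps$phase, c("B", "A"))
})

test_that("CNA and PM tables convert 1-based user coordinates", {
  cna_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tcopies_a\tcopies_b\tclone_id\tclonality",
               "chr1\t101\t200\t2\t1\tc1\t0.5"), cna_tsv)
  cnas <- read_cna_table(cna_tsv)
  expect_equal(cnas$start, 100L)  # 1-based inclusive -> 0-based half-open
  expect_equal(cnas$end, 200L)

  pm_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tallele\tmultiplicity\tclone_id\tclonality",
               "chr1\t150\tA\tT\tA\t1\tc1\t0.5"), pm_tsv)
  pms <- read_pm_table(pm_tsv)
  expect_equal(pms$pos, 149L)
})

test_that("profile validation rejects malformed events", {
  expect_error(genome_profile(cnas = tibble::tibble(
    chrom = "chr1", start = 0, end = 100, copies_a = 1, copies_b = 1,
    clone_id = "c1", clonality = 1)),
    class = "oncoreads_validation_error", regexp = "\\(1,1\\)")
  expect_error(genome_profile(pms = tibble::tibble(
    chrom = "chr1", pos = 5, ref = "A", alt = "A", allele = "A",
    multiplicity = 1, clone_id = "c1", clonality = 1)),
    class = "oncoreads_validation_error")
  # inconsistent clonality within a clone
  expect_error(genome_profile(cnas = tibble::tibble(
    chrom = "chr1", start = c(0, 200), end = c(100, 300),
    copies_a = c(2, 3), copies_b = c(1, 1),
    clone_id = "c1", clonality = c(0.5, 0.6))),
    class = "oncoreads_validation_error", regexp = "inconsistent")
})

simple_targets <- function(len = 1000L) {
  target_regions(tibble::tibble(chrom = "chr1", start = 0L, end = len))
}

test_that("a clonal hemizygous deletion yields the closed-form dosage mixture", {
  cna <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                        copies_a = 1L, copies_b = 0L,
                        clone_id = "c1", clonality = 1)
  seg <- resolve_segments(cna, simple_targets(), tumor_content = 0.8)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$effective_a, 1.0)
  expect_equal(seg$effective_b, 0.2)
  pops <- attr(seg, "populations")
  expect_equal(sum(pops$fraction), 1, tolerance = 1e-9)
  expect_setequal(round(pops$fraction[pops$fraction > 0], 6), c(0.2, 0.8))
})

test_that("tumor content zero leaves every segment diploid", {
  cna <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L,
                        copies_a = 3L, copies_b = 0L,
                        clone_id = "c1", clonality = 0.7)
  seg <- resolve_segments(cna, simple_targets(), tumor_content = 0)
  expect_true(all(seg$effective_a == 1))
  expect_true(all(seg$effective_b == 1))
  expect_true(all(seg$coverage_factor == 1))
})

test_that("nested same-clone CNAs replace the outer copies on the inner span", {
  cnas <- tibble::tibble(chrom = "chr1",
                         start = c(100L, 300L), end = c(800L, 500L),
                         copies_a = c(2L, 3L), copies_b = c(1L, 1L),
                         clone_id = "c1", clonality = 0.6)
  seg <- resolve_segments(cnas, simple_targets(), tumor_content = 1)
  # spans: [0,100) diploid, [100,300) outer, [300,500) inner, [500,800) outer,
  # [800,1000) diploid
  expect_equal(nrow(seg), 5L)
  inner <- seg[seg$start == 300L, ]
  outer <- seg[seg$start == 100L, ]
  # clone c1 (60% of cells): inner uses (3,1), outer (2,1); remaining 40% (1,1)
  expect_equal(inner$effective_a, 0.6 * 3 + 0.4 * 1)
  expect_equal(outer$effective_a, 0.6 * 2 + 0.4 * 1)
  expect_equal(inner$effective_b, 1)
})

test_that("segments tile the capture space disjointly", {
  tr <- target_regions(tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                                      start = c(0L, 600L, 50L),
                                      end = c(400L, 900L, 250L)))
  cnas <- tibble::tibble(chrom = c("chr1", "chr2"),
                         start = c(200L, 0L), end = c(700L, 150L),
                         copies_a = c(2L, 0L), copies_b = c(2L, 1L),
                         clone_id = c("c1", "c2"), clonality = c(0.4, 0.5))
  seg <- resolve_segments(cnas, tr, tumor_content = 0.9)
  expect_equal(sum(seg$end - seg$start), target_length(tr))
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1L, seg$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0L)
})

test_that("invalid overlaps and clonality sums are rejected", {
  # same-clone partial overlap
  cnas <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                         end = c(200L, 300L), copies_a = c(2L, 3L),
                         copies_b = 1L, clone_id = "c1", clonality = 0.5)
  expect_error(resolve_segments(cnas, simple_targets(), 0.5),
               class = "oncoreads_validation_error", regexp = "nesting")
  # clonalities of disjoint clones exceeding 1
  cnas2 <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                          end = c(200L, 300L), copies_a = c(2L, 3L),
                          copies_b = 1L, clone_id = c("c1", "c2"),
                          clonality = c(0.7, 0.6))
  expect_error(resolve_segments(cnas2, simple_targets(), 0.5),
               class = "oncoreads_validation_error", regexp = "sum")
})

test_that("effective dosages match a per-cell enumeration oracle", {
  skip_if_not_installed("withr")
  set.seed(11)
  for (rep in 1:6) {
    n_clones <- sample(1:3, 1)
    cl <- round(runif(n_clones, 0.05, 0.9 / n_clones), 3)
    cnas <- dplyr::bind_rows(lapply(seq_len(n_clones), function(k) {
      s <- sample(0:800, 1)
      tibble::tibble(chrom = "chr1", start = s,
                     end = s + sample(50:190, 1),
                     copies_a = sample(0:3, 1), copies_b = sample(0:3, 1),
                     clone_id = paste0("c", k), clonality = cl[k])
    }))
    cnas <- cnas[!(cnas$copies_a == 1 & cnas$copies_b == 1), ]
    if (!nrow(cnas)) next
    t <- round(runif(1, 0.2, 1), 2)
    seg <- resolve_segments(cnas, simple_targets(), t)
    pops <- attr(seg, "populations")
    for (s in seg$segment_id) {
      p <- pops[pops$segment_id == s & pops$fraction > 0, ]
      eff <- enumerate_effective(p, n = 2e5, seed = 100 + s)
      expect_equal(unname(eff["effective_a"]),
                   seg$effective_a[seg$segment_id == s], tolerance = 0.01)
      expect_equal(unname(eff["effective_b"]),
                   seg$effective_b[seg$segment_id == s], tolerance = 0.01)
    }
  }
})

test_that("a vanishing-clonality CNA leaves dosages continuous at zero", {
  tr <- simple_targets()
  base <- resolve_segments(NULL, tr, 0.8)
  eps <- tibble::tibble(chrom = "chr1", start = 200L, end = 600L,
                        copies_a = 4L, copies_b = 0L,
                        clone_id = "c1", clonality = 1e-6)
  pert <- resolve_segments(eps, tr, 0.8)
  mid <- pert[pert$start == 200L, ]
  expect_equal(mid$effective_a, base$effective_a[1], tolerance = 1e-5)
  expect_equal(mid$effective_b, base$effective_b[1], tolerance = 1e-5)
})

test_that("PM multiplicity is validated against its clone's local dosage", {
  tr <- simple_targets()
  cnas <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L,
                         copies_a = 3L, copies_b = 1L,
                         clone_id = "c1", clonality = 0.5)
  seg <- resolve_segments(cnas, tr, 0.8)
  ok <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                       allele = "A", multiplicity = 2L, clone_id = "c1",
                       clonality = 0.5)
  out <- validate_pms(ok, seg, cnas)
  expect_equal(out$clone_copies, 3L)

  # allele B has 0 copies in a (2,0) CNA of the same clone
  cnas2 <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L,
                          copies_a = 2L, copies_b = 0L,
                          clone_id = "c1", clonality = 0.5)
  seg2 <- resolve_segments(cnas2, tr, 0.8)
  bad <- dplyr::mutate(ok, allele = "B", multiplicity = 1L)
  expect_error(validate_pms(bad, seg2, cnas2),
               class = "oncoreads_validation_error", regexp = "copies")

  # no CNA at the locus: clone copies default to (1,1)
  pm3 <- dplyr::mutate(ok, pos = 700L, multiplicity = 1L, clonality = 0.4,
                       clone_id = "c9")
  out3 <- validate_pms(pm3, resolve_segments(NULL, tr, 0.8), NULL)
  expect_equal(out3$clone_copies, 1L)
})
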