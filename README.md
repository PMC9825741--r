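# oncoreads

Data-driven simulation of tumor and matched-control capture sequencing (WES /
targeted panels) for benchmarking somatic-genomics tools.

Variant callers, allele-specific copy-number tools and tumor-purity
estimators are routinely validated on data where nobody knows the truth.
`oncoreads` generates FASTQ reads where every event is placed by
construction, while reproducing the platform texture of real capture data:

* **Mode 1 — model building.** From one or more coordinate-sorted, indexed
  control (non-cancer) BAM files over a capture BED, it learns a
  **read-depth model** (per-captured-position fragment-start weights plus
  insert-size statistics), a **quality model** (per-cycle Phred histograms)
  and a **position-based error model** (recurrent systematic errors supported
  by high-quality reads and bases, outside common-SNP positions).
* **Mode 2 — generation.** Given those models, an indexed reference FASTA and
  a genome profile — phased germline SNPs, clone-resolved allele-specific
  somatic CNAs `(copies_A, copies_B)` and point mutations — it emits tumor
  and matched-control reads at a chosen tumor content, coverage or read
  count, read length and strand bias, with a per-fragment truth table.

The allele arithmetic at the core: a dosage segment with effective
(cell-population-averaged) copies `eA`, `eB` yields

    P(read from haplotype A) = eA / (eA + eB)
    coverage factor          = (eA + eB) / 2        log2 = log2((eA+eB)/2)
    E[BAF of a het SNP]      = e_alt / (eA + eB)
    E[VAF of a mutation]     = t · clonality · multiplicity / (eA + eB)

where `eA = (1−t)·1 + t·Σ_clones clonality·copies_A + t·background`, `t` the
tumor content. The fragment sampler realizes these expectations exactly by
drawing position ∝ RDM weight × coverage factor, then population, haplotype
and allele copy hierarchically. Overlapping and nested CNAs are supported
(inner events replace outer ones within a clone); subclones are disjoint cell
populations with per-event clonality.

## Worked example

```r
library(oncoreads)

# a toy control experiment stands in for real platform BAMs
spec      <- fixture_spec(n_targets = 8, n_chromosomes = 2,
                          chromosome_length = 16000,
                          fragments_per_target = 400, insert_sd = 30, seed = 11)
reference <- make_reference(spec, "example")
panel     <- fixture_targets(spec)         # or read_targets("panel.bed")
control   <- make_truth_bam(spec, reference, "example")

rdm    <- build_rdm(control$bam, panel, paired = TRUE)
qm     <- build_qm(control$bam, panel)
pbe    <- build_pbe(control$bam, panel, reference)
models <- model_bundle(rdm, qm, pbe)
models
#> <model_bundle>
#> <rdm_model> 8 regions, 4,000 positions, norm 3200, paired (insert 300.0 +/- 0.0), read length 100
#> <quality_model> 100 cycles, 514,800 bases, mean Q 30.0
#> <pbe_model> 0 systematic-error sites (BQ>=20, MQ>=20, depth>=50, rate>=0.005)
save_models(models, "example/models.json")

# the simulated individual: 12 phased het SNPs, one clonal hemizygous
# deletion over three targets, one clonal point mutation
snps <- place_phased_snps(reference, panel, 12)
cnas <- tibble::tibble(chrom = panel$chrom[1], start = panel$start[1],
                       end = panel$end[3], copies_a = 1L, copies_b = 0L,
                       clone_id = "founder", clonality = 1)
pms  <- tibble::tibble(chrom = panel$chrom[4], pos = panel$start[4] + 200L,
                       ref = "T", alt = "A", allele = "A", multiplicity = 1L,
                       clone_id = "founder", clonality = 1)
profile <- genome_profile(snps, cnas, pms, reference = reference)

plan   <- sample_plan(name = "tumor_t80", kind = "tumor", tumor_content = 0.8,
                      coverage = 200, read_length = 100, paired = TRUE, seed = 42)
report <- generate_sample(models, reference, profile, plan, "example/tumor_t80")
report
#> <generation_report> tumor_t80 (tumor)
#>   fragments: 5622 (11244 FASTQ records), read length 100, paired-end
#>   coverage: requested 200.0x, realized 199.14x
#>   forward-strand fraction: 0.4975
#>   insert size: 300.0 +/- 0.0
#>   8 dosage segments, 13 tracked events
```

The realized mean on-target coverage (199.14×) matches the request because
the read budget is calibrated for target-edge overhang; the strand fraction
sits at the default bias 0.5. Per event, the report compares the observed
allele fraction in the emitted reads with the closed-form expectation — for
SNPs inside the `(1,0)` deletion at `t = 0.8` the expected BAF is
`0.2/1.2 = 0.167` (alternate on the lost haplotype) or `1/1.2 = 0.833`
(alternate on the retained one):

```r
dplyr::select(tidy(report), type, chrom, pos, expected_af, observed_af, depth)
#> # A tibble: 13 × 6
#>   type  chrom   pos expected_af observed_af depth
#>   <chr> <chr> <int>       <dbl>       <dbl> <dbl>
#> 1 snp   fix1    580       0.833       1         1
#> 2 snp   fix1    944       0.167       0.182   209
#> 3 snp   fix1   4517       0.833       0.849   139
#> 4 snp   fix1   8091       0.167       0.155    84
#> 5 snp   fix1   8454       0.833       0.814   204
#> 6 snp   fix1  12028       0.5         0.514   362
#> # ℹ 7 more rows
```

A matched control is one flag away (`kind = "matched_control"`: same SNPs,
somatic events ignored). `autoplot(report)` draws observed-versus-expected
allele fractions; `expect_profile()` prints the expectation table without
generating anything; `run_scenario()` drives tumor-content dilution series
and longitudinal subclone designs from one shared profile. A thin CLI with
`model-build`, `generate`, `expect`, `fixtures` and `scenario` subcommands
lives in `inst/cli/oncoreads`.

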