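---
title: "Simulating tumor and matched-control capture sequencing with oncoreads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tumor and matched-control capture sequencing with oncoreads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoreads)
```

## The problem

Benchmarking somatic variant callers, copy-number tools and tumor-purity
estimators requires sequencing data where the truth is known exactly. Real
tumor data never provides that; fully synthetic data often fails to reproduce
the platform-specific texture of capture sequencing — uneven coverage across
targets, cycle-dependent base quality, recurrent position-specific artifacts,
the insert-size distribution of the library. oncoreads takes the data-driven
middle road: it learns those properties from real control (non-cancer)
alignments of a platform and then generates tumor and matched-control FASTQ
reads in which every germline and somatic event is placed by construction.

Two modes mirror that split:

1. **Model building** turns one or more coordinate-sorted control BAM files
   over a capture panel into three empirical reference models.
2. **Generation** combines the models with a user-specified genome profile —
   phased germline SNPs plus clone-resolved allele-specific somatic CNAs and
   point mutations — and a per-sample plan (tumor content, coverage or read
   count, read length, strand bias, seed) to emit synthetic reads.

## Reference models

**Read-depth model (RDM).** For every captured position, the pooled count of
sequencing fragments whose leftmost aligned coordinate falls on that position.
For paired-end data only the mate with the lower coordinate contributes, so a
fragment is counted once; for single-end data every primary alignment counts.
This per-position weight vector, normalized, is the sampling distribution for
fragment starts during generation, and reproduces the intra-sample coverage
variability of the platform. Insert-size mean and standard deviation are
estimated from proper pairs whose leftmost mate starts on target; template
lengths outside (0, 2000] are discarded as likely chimeras or artifacts.

**Quality model (QM).** The empirical distribution of Phred base qualities at
each read cycle, pooled over all on-target primary alignments. Reverse-strand
alignments are un-reversed first so cycles refer to the original sequencing
order. We deliberately pool over strand and mate (read 1 versus read 2);
conditioning the histograms on either would be a straightforward extension,
but the pooled model is what the generation steps require and keeps bundles
small. Cycles never observed in the input fall back to the pooled
distribution over all cycles.

**Position-based error model (PBE).** Platform-specific systematic errors
recur at fixed genomic positions even in high-quality data. For every
captured position not masked as a common SNP, the builder piles up bases with
base quality ≥ 20 from reads with mapping quality ≥ 20 (both tunable), and a
position enters the model when high-quality depth reaches `min_depth`
(default 50) and the non-reference fraction reaches `min_error_rate` (default
0.005). The stored error rate is the non-reference fraction; the
alternate-base profile is the relative frequency of the non-reference bases
seen there. The thresholds are explicit parameters rather than claims about
any particular pipeline — "high quality" is platform- and pipeline-dependent,
so the defaults are conservative and command-line overridable. The common-SNP
mask is user-supplied (BED, VCF, or a parsed SNP table); when absent, the
phased SNP list used later for generation is the natural choice of mask.

All three builders skip secondary, supplementary, duplicate-flagged and
unmapped records — standard pileup hygiene. Bundles serialize to a single
JSON document (format version, builder parameters, flat arrays) written at
17 significant digits so a load–save round trip is exact.

## The genome profile

A simulated individual is described by tables, all tibbles:

* **Phased SNPs** — heterozygous biallelic SNVs with the alternate allele
  assigned to haplotype A or B. In VCF input, genotype `a|b` maps the allele
  left of the bar to haplotype A, so `0|1` puts the alternate on B. Unphased
  heterozygotes are an error rather than a guess.
* **Somatic CNAs** — allele-specific copy numbers `(copies_A, copies_B)` over
  an interval, attached to a clone with a clonality value.
* **Somatic point mutations** — a base substitution on one allele, with a
  multiplicity (how many copies of that allele carry it, relevant inside
  amplifications), attached to a clone.

**Clone semantics.** Clonality is the fraction of *tumor* cells belonging to
an event's clone. Distinct clone identifiers are disjoint cell populations:
clonality must be consistent across all events of one clone, and the sum over
all clones may not exceed 1 — with disjoint populations a sum above 1 is
unrepresentable regardless of whether the events overlap (the remaining
tumor fraction is copy-neutral "background tumor"). Within a clone, two CNAs
may overlap only if one strictly contains the other, and the inner event
*replaces* the outer one on its span. Replacement is the simplest semantics
consistent with nested events; a composition algebra (e.g. multiplying
dosages) would require assumptions about event order that the input cannot
express. Clones as nested lineages (one clone a subpopulation of another) are
intentionally not modeled.

`resolve_segments()` cuts the capture space at every CNA breakpoint and
computes, per resulting segment, the full cell-population mixture: normal
cells `(1 - t)` at copies (1,1), each clone at `t * clonality` with its
innermost covering CNA (or (1,1)), and background tumor at
`t * (1 - sum(clonality))`. The *effective* copy number of each haplotype is
the mixture average; tests verify it against an explicit enumeration of 10^6
simulated cells.

## Dosage arithmetic

With effective copies `eA`, `eB` at a locus:

* a read comes from haplotype A with probability `eA / (eA + eB)`;
* coverage scales with the factor `(eA + eB) / 2`, so the expected
  log2 tumor/control ratio is `log2((eA + eB) / 2)`;
* a het SNP with its alternate on haplotype H has expected B-allele fraction
  `eH / (eA + eB)`;
* a point mutation of multiplicity `m` in a clone of clonality `c` at tumor
  content `t` has expected VAF `t * c * m / (eA + eB)`.

Coverage modulation is *relative*: RDM weights are multiplied per segment by
the coverage factor and renormalized globally, so a requested read budget is
always met exactly while relative coverage reflects dosage. Absolute
modulation (deleting reads) would make the delivered coverage depend on the
profile, which is hostile to benchmarking designs that fix coverage.

These closed forms are exact by construction of the sampler: each fragment
draws its position from the modulated RDM, then a (population, haplotype,
copy) triple with probability proportional to cell fraction per allele copy.
A read carries a PM exactly when it drew the PM's clone, allele, and one of
its first `m` copies — making the VAF formula an identity, not an
approximation. `expect_profile()` exposes the same arithmetic as a table, and
generation reports always take their expected columns from it.

## Read generation

Per fragment: sample a start position; draw the insert length from
Normal(mean, sd) truncated to at least one read length (by resampling, up to
100 tries, rather than clamping, which would distort the distribution shape;
the residual divergence from an exact normal is negligible when
`insert_mean ≥ read_length + 4·insert_sd`); draw the population/haplotype/
copy; substitute phased SNPs matching the haplotype; apply base qualities and
errors; substitute carried point mutations; choose the forward strand with
probability `strand_bias` (default 0.5).

Base qualities are drawn per cycle from the QM. At cycles whose genomic
position is in the PBE, the base is substituted with that site's error rate
using its alternate-base profile; at all other cycles the base is substituted
with probability `10^(-Q/10)` uniformly among the three other bases. Point
mutations are applied *after* errors by default, following the literal order
of the generation steps — a PM can therefore overwrite a sequencing error at
its own position; `pm_order = "before_errors"` switches to the alternative.
Reads may overhang target boundaries into flanking reference, as real capture
reads do; fragment starts themselves are always on target, as the RDM
defines. Qualities are emitted as Phred+33.

**Read budget and coverage.** When a mean on-target coverage is requested,
the naive budget `coverage × target_length / (read_length × mates)` ignores
the bases that overhanging reads spend outside targets, which under-covers
captured positions by up to ~10% on sub-kilobase targets. The budget is
instead calibrated by a seeded Monte-Carlo estimate (10,000 draws from the
actual modulated sampler) of the expected on-target bases per fragment, so
the realized mean on-target coverage matches the request in expectation
(within ~0.5% at desk scale).

**Determinism.** Generation is chunked (20,000 fragments per chunk) and fully
vectorised; every value derives from the plan seed through one serial RNG
stream. The `threads` argument is accepted for interface compatibility and
never influences output, so byte-identical FASTQ across worker counts holds
trivially and is still asserted by a test. Read names encode
`sample:serial:chromosome:start` so every record can be traced to its truth
table row; an optional truth TSV records, per fragment, the population,
haplotype, copy index, strand, insert and both mate spans.

**Matched controls** share the phased SNPs, force tumor content 0 and ignore
all somatic tables.

## The synthetic fixture generator

`fixture_spec()` / `make_reference()` / `make_truth_bam()` /
`make_models_direct()` fabricate every input the pipeline needs: a
deterministic pseudo-random reference genome, an evenly spaced capture panel,
a coordinate-sorted indexed BAM of error-free paired (or single-end) reads
with known per-position fragment-start counts, fixed template length,
constant or ramped qualities, optional injected position-specific errors,
optional duplicate-flagged or MAPQ-0 records — plus a sidecar truth object
with the exact counts, and the analytically equivalent models built without
any BAM. Fixture BAMs are real BAM files written through SAM text and
samtools-compatible conversion, so the model builders are tested against the
genuine format.

What the fixtures emulate: capture-restricted coverage with edge falloff,
fragment-start stochasticity, per-cycle quality shapes, recurrent
position-specific errors, strand-alternating proper pairs. What they do not:
GC-dependent coverage waves, indels and soft-clipping, optical duplicates,
overlapping-mate correlation in error space, adapter read-through. Green
tests therefore certify the sampling and arithmetic machinery, not fidelity
to any particular instrument; fidelity to a platform comes from building
models on that platform's real controls.

## Scenarios

`run_scenario()` drives multi-sample designs from one shared profile: a
tumor-content dilution series (`dilution_samples()`) and longitudinal
sampling with regressing/emerging subclones via per-sample clonality
overrides (`longitudinal_samples()`), each tumor paired with one matched
control. The combined report tabulates expected versus observed BAF/VAF and
log2 per event per sample; expected values always come from the dosage
arithmetic above.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally; BED is read natively, VCF and
  the tabular CNA/PM formats are converted on input.
* Mixture fractions are validated to sum to 1 within 1e-9; model histograms
  to 1 within 1e-9.
* Insert statistics use the unbiased sample standard deviation; a single
  observation yields sd 0.
* Ties in innermost-CNA selection cannot occur (equal same-clone intervals
  are rejected); segment boundaries come from interval disjoinment, so
  segments tile the capture space exactly.
* Reads with more than 50% reference `N` would be redrawn; the bundled
  fixtures contain no `N`s, and fully `N` reference stretches are better
  excluded from panels.
* The test suite and acceptance checks run at desk scale by design: panels of
  2–20 targets of 400–500 bp, coverages of 100–1000×, 10^5-read strand
  checks, 10^6-cell enumeration oracles, and a 100-configuration grid over
  tumor content {0.1..1.0}, CNAs {(1,0),(2,0),(2,1),(3,1),(2,2)} and
  clonality {0.3, 1.0}. Statistical checks use 99% binomial/normal intervals
  per quantity; where many such checks aggregate, the suite asserts the
  coverage of the intervals (≥97% inside, no |z| above 4.5) rather than
  demanding that hundreds of independent 99% events all succeed at once,
  which the true model would fail with high probability.

## Known limitations

No indels or structural variants other than CNAs; no CRAM; no realignment or
base-quality recalibration; no GC-bias or duplicate modeling beyond what the
RDM captures empirically; clones are disjoint populations, not a phylogeny;
the QM is unconditioned on strand/mate. Coverage calibration targets the
mean, not per-position depth quantiles.
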