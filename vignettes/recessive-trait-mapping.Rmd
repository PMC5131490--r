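---
title: "Mapping recessive traits with carrier-informed haplotype association"
author: "recmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive traits with carrier-informed haplotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapr)
```

## The mapping problem

Autosomal recessive defects surface in livestock populations when a widely
used sire silently carries a deleterious allele: carrier-by-carrier matings
produce affected offspring, but by the time the condition is noticed only a
handful of affected animals may be available for genotyping — far too few
for a case-control genome-wide association study. The pedigree, however,
contains more information than the case count suggests. Every parent of an
affected animal is an *obligate carrier*, necessarily heterozygous for the
disease haplotype, and unrelated healthy animals are very unlikely to carry
it at all.

recmapr implements the three-stage strategy built on that observation:

1. **Carrier-informed haplotype association.** The expected number of
   disease-haplotype copies is used as a quantitative response, coded
   `y = 2` for affected animals, `1` for obligate carriers and `0` for
   controls. Within each sliding window of 20 contiguous SNPs (shifted in
   steps of 5), every phased haplotype with population frequency above 5%
   is tested one-vs-rest with the linear model
   \[
   y = \mu + \sum_{j=1}^{10} a_j\,\mathrm{PC}_j + b\,\mathrm{HT} + e,
   \]
   where HT is the 0/1/2 dosage of the tested haplotype and the
   \(\mathrm{PC}_j\) are principal components of the genomic relationship
   matrix, included as fixed covariates to absorb stratification and family
   structure. The residual is treated as normal; the p-value for \(b\) uses
   a t reference with \(n - k - 2\) degrees of freedom.
2. **Homozygosity mapping.** The affected animals, being autozygous for
   the causal region, share a run of homozygosity with an identical allele
   sequence. `shared_autozygosity()` extracts these segments and
   `exclude_control_homozygotes()` removes any segment that a healthy
   control also carries in the homozygous state.
3. **Recessive-compatibility variant filtering.** Within the mapped
   segment, sequence-level variants are filtered in a fixed cascade:
   restrict to the region; keep variants homozygous-alternate in every
   case and heterozygous in every obligate carrier; drop variants ever
   observed homozygous-alternate in a large healthy panel; keep coding and
   splice-site consequence classes. Each step's surviving count is
   reported, so the cascade's arithmetic is auditable.

## Model assumptions

* Fully penetrant, autosomal recessive inheritance with a single causal
  haplotype descending from one founder. Phenocopies, genetic
  heterogeneity and reduced penetrance are outside the model.
* The response coding assumes carrier status is known without error for
  the 2/1/0 groups; that is exactly what the obligate-carrier construction
  guarantees for parents of affected animals.
* The scan treats the discrete response under ordinary least squares with
  a normal residual. With tiny case counts this is a pragmatic choice —
  a logistic model would separate perfectly — but the t-based p-values
  are then approximate for the extreme tail; the permuted-status null
  battery quantifies how well they behave in aggregate.
* Phased haplotypes are an input contract. Phasing/imputation itself is
  upstream of this package (array data are typically phased with
  pedigree-aware tools); the simulator emits phased haplotypes directly.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `window_size` | 20 | SNPs | window span on medium-density arrays (~1 Mb) |
| `step` | 5 | SNPs | 4-fold window overlap; trailing partial windows are dropped |
| `min_freq` | 0.05 | haplotype frequency | strict floor ("above 5%"): rare haplotypes are untestable at n = 43 |
| `k` (PCs) | 10 | components | standard stratification correction for a structured sample of this size |
| `min_maf` | 0.005 | allele frequency | QC floor, strict inequality |
| `hwe_p_floor` | 1e-4 | p-value | exact-test floor, strict inequality |
| call-rate floors | 0.95 | fraction | per SNP and per sample, strict inequality |
| `min_snps` (ROH) | 20 | homozygous SNPs | segment support on array-density data; ROH is defined by SNP count, not bp |
| `max_het` (ROH) | 0 | calls | genotyping-error tolerance inside a run |
| `alpha` | 0.05 | FWER | Bonferroni over the number of haplotype tests actually performed |

All QC thresholds are strict inequalities exactly as conventionally
stated (MAF *above* the floor, call rate *higher than* the minimum, HWE
p *above* the floor). The QC filter order is fixed and logged — sample
call rate, then SNP call rate, MAF, HWE, each recomputed on what the
previous step retained — because the per-step accounting depends on the
order.

## What the simulator emulates — and what it does not

`simulate_population()` reproduces the study design the pipeline is
validated against: 2 affected animals, 14 obligate carriers (the parents
of affected offspring), 27 controls, and a healthy panel, genotyped at 5
chromosomes × 600 SNPs with a 10 Mb carrier region. The pedigree is a
fixed-depth half-sib design: one founder sire carries the disease
haplotype, his carrier descendants are mated pairwise, and affected
offspring are bred within a retry budget — mirroring how heavy AI-sire
usage makes obligate carriers identifiable in practice. Meiosis uses
Poisson crossover counts (default mean 1 per chromosome, roughly 1
Morgan for a 60 Mb bovine-scale chromosome) with uniform positions and
no interference. Founder alternate-allele frequencies are Beta(2, 2)
draws truncated to [0.05, 0.95] so that most loci survive QC and the
cascade counts are meaningful. Genotype missingness (default 1% per
call, matching array-typical call rates around 99%) is applied to the
genotype matrix only; haplotypes stay complete. The healthy panel is
scaled to 150 animals — large enough that a carrier-frequency allele is
reliably observed homozygous in it when common, small enough for desk-
scale runs.

Haplotypes are represented internally as mosaics of founder-haplotype
segments, so identity by descent is known exactly; region variants are
assigned to founder haplotypes and *descend through the same mosaics*,
which makes every variant genotype phase-consistent with the SNP
haplotypes and means adding variants never perturbs the genotypes (each
stage draws from its own deterministic sub-stream of the master seed).

The simulator does **not** model: realistic linkage maps or LD in
founders (founder alleles are drawn independently per locus, so
background LD is absent and window haplotypes are more diverse than on a
real array); genotyping error beyond missingness; incomplete pedigree
records; sex chromosomes; or coalescent founder history. Passing the
recovery battery therefore demonstrates that the machinery is correct
and well-calibrated under the stated design, not that its power
estimates transfer to any particular real population.

## Numerical choices

* **Exact HWE test.** Enumeration over all heterozygote counts consistent
  with the allele counts, in log-gamma arithmetic; probabilities no
  larger than the observed configuration's (with a 1e-12 relative guard
  for ties) are summed. Monomorphic input returns p = 1, not an error.
  The test suite checks it against an independent recurrence-based
  enumeration to 1e-12.
* **GRM.** Per-locus standardisation \((x - 2p)/\sqrt{2p(1-p)}\) with
  allele frequencies estimated from the analysis samples; loci
  monomorphic in the sample are excluded; missing genotypes are handled
  by pairwise-complete locus exclusion (a complete-case mode is a flag).
  Eigenvector signs are fixed by forcing each component's
  largest-magnitude loading positive, for reproducibility.
* **Perfect fits and ties.** When a window haplotype's dosage reproduces
  the response exactly (the expected outcome inside the causal region),
  the residual sum of squares is numerically zero and the p-value
  collapses to the smallest positive double — it is clamped there so p
  stays in (0, 1]. Several windows along the shared founder tract then
  tie at that floor; the recovery battery treats all windows attaining
  the minimum p as joint top hits, because no ordering among exact ties
  is meaningful.
* **Degrees of freedom.** \(n - k - 2\) (intercept, k PCs, haplotype).
  A constant or collinear dosage vector is flagged untestable rather
  than raising an error, and untestable results are excluded from the
  inflation factor.
* **Genomic control.** \(\lambda\) is the median of the implied 1-df
  chi-square statistics divided by 0.4549364 (the null median), computed
  over all tests including linked ones. At desk scale (~1,000 heavily
  correlated window tests, 43 samples, a discrete 2/14/27 response) the
  per-seed \(\lambda\) of a permuted-status scan is noisy, so the test
  suite asserts the across-seed median (reported by the acceptance
  script as `permuted_scan_lambda_median`) rather than a per-seed band;
  no permuted scan reaches Bonferroni significance in the battery.
* **ROH semantics.** Missing calls are neutral — they neither break a
  run nor count toward `min_snps`; a stricter convention would be too
  brittle at 95% call rates. Segment bounds are the first and last
  homozygous SNP positions (1-based inclusive), never midpoints to
  flanking SNPs. With `max_het > 0` maximal runs may overlap; nested
  runs are removed. Shared segments require every sample observed,
  homozygous, and identical at a locus for it to count as informative;
  conflicts (any het, or opposite homozygotes) break segments; loci with
  missing calls are tolerated but uncounted.
* **Control exclusion.** The default is to drop a segment whenever a
  control matches its shared homozygous allele at every informative SNP
  (missing tolerated, at least one observed match); a trim mode instead
  removes the control-covered loci and re-extracts runs.
* **Cascade role asymmetry.** Missing genotypes in cases or carriers
  make a variant incompatible (the evidence for compatibility is
  absent); missing panel genotypes never exclude (the panel can only
  exclude through an observed homozygous-alternate call).

## Design decisions that were genuinely open

* **MAP dialect.** A 4-column MAP cannot declare reference/alternate
  alleles, yet dosage must be collapsed against a declared reference.
  The native dialect is therefore the 6-column `.bim`-style MAP
  (chromosome, id, cM, bp, ref, alt); 4-column MAPs are accepted with
  alleles inferred from the PED (lexicographically smaller observed
  allele = reference), and an allele mismatch is a hard error — no
  strand auto-flipping.
* **HWE over all samples.** The exact test is computed over every scan
  sample, affected animals included. With 2 cases in 43 samples the
  affected genotypes cannot push a locus past the 1e-4 floor on their
  own; excluding cases would be defensible but is not the default.
* **One-vs-rest haplotype tests.** Each catalogued haplotype gets its
  own regression rather than a joint per-window model; the number of
  tests (and hence the Bonferroni threshold) is the number of
  catalogued haplotypes.
* **Haplotype frequency** is computed over all sample haplotypes (not
  within controls only), and the 5% floor is strict.
* **Pedigree depth.** `n_generations = 3` is founders → carriers →
  affecteds; larger values insert extra carrier-descent meioses before
  the carrier matings, shortening the shared founder tract.
* **Cascade region.** The end-to-end pipeline runs the cascade over the
  *detected* shared-autozygosity segment rather than the (unknown in
  practice) true region; the configured region is only a fallback when
  detection fails, and the recovery metrics record whether the fallback
  was used.

## Problem sizes and validation

The recovery battery (`evaluate_recovery()`) runs the full pipeline —
simulation, QC, GRM and 10 PCs, association scan, permuted-status null
scan, homozygosity mapping with control exclusion, region-variant
simulation and the cascade — over 20 seeds at the default design. Module
tests use a smaller population (2 chromosomes × 250 SNPs) and validate
each component against independent oracles: a recurrence-based HWE
enumeration, a normal-equations OLS solver, and exhaustive
interval scanners for ROH and shared segments on instances up to 1,000
SNPs. `scripts/acceptance.R` re-runs the battery and reports the
recovery rates alongside the analytic worked examples.

## Known limitations

* Absent background LD in founders makes window haplotypes more
  fragmented than on a real array, which lowers the number of catalogued
  haplotypes per window relative to real data.
* The OLS p-values for a 2/14/27 discrete response are approximate in
  the far tail; genome-wide inference should lean on the Bonferroni
  threshold and the permutation null, not on the literal magnitude of
  extreme p-values.
* Model-based IBD detection (HMMs over genotype likelihoods) and
  ROH-based inbreeding coefficients are out of scope, as are phasing,
  imputation, variant calling and consequence annotation.
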