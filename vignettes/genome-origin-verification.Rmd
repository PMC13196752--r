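---
title: "Verifying haploid induction from low-coverage sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying haploid induction from low-coverage sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplorigin)
```

## The problem

In doubled-haploid (DH) breeding, a male-sterile female is pollinated by an
*inducer* line whose genome is eliminated after fertilization, leaving an
embryo that carries only the maternal genome. Marker screens (fluorescence,
pigmentation) flag putative haploids cheaply, but they can be fooled: an
embryo that lost only *part* of the paternal genome — one chromosome, or a
segment — looks haploid to a presence/absence marker while actually being an
aneuploid diploid. Confirming genome origin therefore requires sequence-level
evidence, and for cost reasons that evidence is low-coverage (~5x) whole-genome
resequencing against deeply sequenced (~30x) parents.

`haplorigin` implements that verification, plus the screening arithmetic that
surrounds it in an induction program: per-cross haploid induction rates (HIR)
with exact binomial uncertainty, and categorization of spontaneous chromosome
doubling by seed set.

## The genome origin index

The statistic at the core is computed in three steps.

**Parent-informative markers.** A biallelic SNP site is informative when the
two inbred parents carry confident homozygous calls for *different* alleles,
so any offspring allele at that site is origin-assignable.
`extract_informative_markers()` applies exactly that rule to two parental
VCFs, discarding heterozygous, missing, multiallelic and indel records and
any record whose QUAL does not strictly exceed 20 in both parents (the
boundary value 20 itself is removed). The retained marker QUAL is the
smaller of the two parental QUALs — the site is only as trustworthy as its
weaker call.

**Origin-coded genotypes.** Each offspring genotype at a marker site is coded
`hom_maternal`, `hom_paternal`, `het`, or `missing`
(`code_offspring_genotypes()`). Called genotypes carrying an allele matching
neither parent are excluded and tallied as a QC statistic rather than being
forced into a class.

**Binned GOI.** Chromosomes are partitioned into consecutive nonoverlapping
100-kb bins (half-open `[start, end)`, 0-based internally and in TSV output;
marker positions stay 1-based as in VCF). With $M$, $P$ and $H$ the
maternal, paternal and heterozygous SNP counts in a bin,

$$\mathrm{GOI} = \frac{M - P}{M + P + H},$$

and a bin with fewer than five SNPs is ignored (GOI = NA; exactly five is
defined). GOI ≈ 1 marks a maternal haploid region, GOI ≈ 0 a biparental
diploid region, and a chromosome that sits at 1 while the rest of the genome
sits at 0 marks loss of that chromosome's paternal copy.

```{r goi}
compute_bin_goi(10, 0, 0)   # pure maternal bin
compute_bin_goi(2, 2, 6)    # balanced biparental bin
compute_bin_goi(2, 1, 1)    # 4 SNPs only: ignored
```

Two accounting choices here were genuinely open and are exposed as options:

* **Heterozygous sites.** By default a het SNP contributes to the
  denominator but to neither $M$ nor $P$ (`het_mode = "denominator-only"`).
  The alternative reading — counting it once as maternal and once as
  paternal — leaves the numerator $M - P$ unchanged and only inflates the
  denominator to $M + P + 2H$ (`het_mode = "both-counts"`); both give
  GOI = 1 for pure-maternal bins and ≈ 0 for diploid bins, so the choice
  only rescales mixed bins.
* **Missing calls.** At ~5x depth a nontrivial fraction of sites is
  uncalled. An uncalled site carries no origin information, so by default it
  is excluded from the bin total rather than being allowed to push a bin
  below the five-SNP threshold; `missing_in_total = TRUE` switches to
  counting all marker sites in the bin.

## From bins to a genome call

Published interpretation of GOI is qualitative ("one or close to one",
"around zero"). The classifier makes that quantitative with thresholds that
are deliberately conservative artifact choices (`classifier_config()`):

| parameter | default | meaning |
|---|---|---|
| `tau_maternal` | 0.8 | bin GOI ≥ this is maternal |
| `tau_paternal` | −0.8 | bin GOI ≤ this is paternal |
| `tau_biparental_abs` | 0.3 | bin \|GOI\| ≤ this is biparental |
| `chrom_consensus_fraction` | 0.8 | defined-bin consensus for a chromosome call |
| `min_defined_bins_per_chrom` | 5 | fewer defined bins → indeterminate |

The margin argument: at 5x Poisson depth with no base error, a heterozygous
site drops to an apparent homozygote with probability
$E[2(1/2)^D \mid D \ge 1] \approx 0.152$, split evenly between the two
parents. A diploid bin with $n \approx 12$ genotyped markers therefore has
GOI mean 0 and standard deviation
$\sqrt{0.152/12} \approx 0.11$, while a haploid bin sits at GOI ≈ 1 with
near-zero variance (only sequencing errors that happen to hit the paternal
base, probability ~`base_error`/3 per read, pull it down). The ±0.3 and 0.8
cutoffs are thus > 2.5σ from the diploid center and far from the haploid
center, and the 80% bin consensus across the ~60–80 bins of a chromosome
makes a wrong chromosome call vanishingly rare — which is what the recovery
tests measure.

Chromosome calls aggregate bins: a consensus class if ≥ 80% of defined bins
agree; otherwise, if maternal and biparental stretches coexist, each with at
least one run of ≥ 2 contiguous bins (single-bin flips are never segmental
evidence) and jointly making up the consensus fraction (a guard this package
adds so scattered ambiguous bins cannot fake a segmental call), the
chromosome is `mixed_segmental`; otherwise indeterminate.

Genome calls aggregate chromosomes: all maternal → `maternal_haploid`; all
biparental → `biparental_diploid`; any segmental chromosome →
`segmental_paternal_loss`; whole biparental and whole maternal chromosomes
mixed → `biparental_missing_paternal_chroms` with the maternal chromosomes
listed. The last rule is stated that way deliberately: *any* whole
biparental chromosome proves the embryo is diploid, so maternal-appearing
chromosomes in that context must have lost their paternal copy — no
majority requirement is needed, and requiring one would misreport genomes
where half or more of the chromosomes were lost. An all-paternal genome is
reported indeterminate with a warning, because the cross design cannot
produce it; it signals a sample swap.

## The synthetic cross

The simulator generates the data the verification consumes, under the study
conditions rather than as an adversarial stress test:

* two homozygous inbred parents whose informative SNPs are placed as a
  Poisson process (biallelic only, maternal ≠ paternal allele by
  construction);
* offspring truth layers per scenario — maternal haploid, biparental
  diploid, whole paternal chromosome loss, segmental paternal loss — with
  no recombination modeled (parents are inbred and offspring F1-like, so
  phase cannot affect origin counts);
* a sequencing layer: per-site depth ~ Poisson(`mean_depth`, default 5),
  per-read miscalls (`base_error`, default 0.005) that land uniformly on
  the three other bases, non-parental read alleles dropped, and a genotype
  called het iff both parental alleles are observed, hom iff exactly one,
  missing below `min_depth_call` informative reads (default 1 — the
  simplest rule consistent with ~5x data; real genotype callers' ploidy
  priors are deliberately not imitated, which is why the call rule is a
  parameter).

The default genome is 10 chromosomes at one tenth of sorghum-like lengths
(~68 Mb total), keeping full-genome simulations desk-scale while preserving
realistic bin counts per chromosome (~60–80). Recovery experiments use
~1,000 markers per chromosome, realized as a single genome-wide density of
1000/mean(chromosome length) so marker counts stay Poisson.

What the simulator does *not* emulate — and hence what passing tests do not
demonstrate about real data: alignment and variant-calling artifacts
(mapping bias, paralog collapse), depth heterogeneity beyond Poisson (GC,
repeats), triploid endosperm contamination of embryo dissections, residual
heterozygosity in the parents, and heterofertilization. The QC tallies
(non-parental alleles, missing fraction) and the marker-density report are
the hooks for noticing such problems on real inputs.

Seed-lot screening is simulated hierarchically (abortion → germination →
true haploid fraction → marker misclassification), conserving totals by
construction, which is what makes it a valid oracle for the HIR estimator's
bias and interval coverage.

## Screening arithmetic

HIR is reported as haploids over *germinated* seeds — aborted seeds are
excluded from the denominator; `denominator = "dissected"` switches to the
embryo-stage convention of dividing by every dissected seed. Averages
across crosses are unweighted means of the unrounded per-cross percentages
(a mean of rates, not a pooled rate). Percentages are rounded half-up to
two decimals at report time only; base R's banker's rounding would not
reproduce standard screening tables. Uncertainty is the Clopper–Pearson
exact interval from `binom.test()`. Spontaneous-doubling categories by
selfed seed set are none (0%), low (0–5%], medium (5–10%], high (>10%].

```{r hir}
tab <- read_seed_counts(system.file("extdata", "seed_screen_counts.csv",
                                    package = "haplorigin"))
res <- compute_hir(tab)
res
average_hir(res)
```

## Reproducibility and problem sizes

Every stochastic operation takes one explicit integer seed and restores the
caller's RNG state; identical seeds give byte-identical outputs, including
the files written by `run_pipeline()`. The validation suite runs, as the
package's own choice of desk-scale problem sizes: 200 simulated samples per
scenario at 5x depth for recovery rates, 500 simulated lots of 1,000 seeds
for estimator calibration, and ~10,000 sites for the allele-dropout check
against the summed Poisson series — all of which complete in well under a
minute each.

## Known limitations

* Dosage is inferred from genotype classes, not read counts: trisomies and
  other copy-number gains that preserve heterozygosity are invisible.
* Paternal haploids are outside the model (reported as likely sample
  swaps), as are mosaic and heterofertilized embryos.
* The five-SNP NA rule means resolution degrades with marker density;
  `marker_density_report()` should be consulted before interpreting
  segmental calls on sparse marker maps.
* Thresholds were chosen for ~5x data with ≥ ~10 markers per bin; very low
  depth or very sparse markers call for re-deriving the separation argument
  above.
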