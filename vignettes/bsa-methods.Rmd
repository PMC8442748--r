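---
title: "Mapping a recessive locus by bulked-segregant sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus by bulked-segregant sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The experimental design

Bulked-segregant analysis (BSA-seq) maps a Mendelian locus by sequencing
two DNA pools drawn from the phenotypic extremes of a segregating
population. `bsascan` implements the full computation for the classic
design: two fully homozygous inbred parents are crossed, the F1 is
selfed, and the F2 segregates a single fully penetrant recessive trait
(here, genic male sterility). Equal amounts of DNA from 30
recessive-phenotype and 30 dominant-phenotype F2 plants form the two
bulks, which are sequenced to roughly 34x each.

At a biallelic SNP fixed between the parents, define the **SNP index**
of a pool as the fraction of its reads carrying the sterile-parent
allele, and the **delta-SNP-index** as

$$\Delta\mathrm{SNPindex} = \mathrm{index}_{\text{sterile bulk}} -
  \mathrm{index}_{\text{fertile bulk}}.$$

Away from the trait locus both bulks are random draws from the F2 and
both indices hover around 1/2, so the delta is near 0. At the causal
locus the sterile bulk is pure `aa` (index 1) while the fertile bulk is
`AA:Aa = 1:2` (index 1/3), so the expected delta is

$$\Delta_{\text{theory}} = 1 - \tfrac{1}{3} = \tfrac{2}{3} \approx 0.667,$$

which `theoretical_delta(cross_model())` computes by enumerating the
conditional genotype classes. The same enumeration generalises to a
backcross design and to penetrance below one
(`expected_bulk_freq()`, `expected_ratio()`).

The second statistic is the per-site **Euclidean distance**
between the pools' allele-frequency vectors,
$ED = \sqrt{(p-q)^2 + ((1-p)-(1-q))^2} = \sqrt{2}\,\lvert p - q\rvert$
for a biallelic site, raised to a power $k$ (default 5) before fitting
to suppress background noise. ED is symmetric in the pools and
indifferent to allele orientation, which makes it a useful cross-check
on the oriented delta scan.

## Variant filtering

Four rules are applied, in a fixed order so that removal counts are
reproducible (each site is attributed to the first rule it fails):

1. **Multiallelic sites** (more than one alternate allele) are dropped.
2. **Low support**: sites where a pool has fewer than 4 reads are
   dropped. The phrase "fewer than four supporting reads" is ambiguous
   between per-pool and per-allele support; the default reads it
   per-pool, and `support_mode = "allele"` provides the stricter
   per-allele reading.
3. **Same pool genotype**: each pool is coarsely genotyped from its
   alternate-allele read fraction — below 0.2 reference-fixed, above
   0.8 alternate-fixed, otherwise heterozygous-like — and sites where
   both pools receive the same call are dropped. The 0.2/0.8 band is a
   package choice, selected to be robust to binomial read noise at
   ~34x depth ($\sqrt{0.25/34} \approx 0.086$, so a truly fixed pool
   essentially never strays into the band and a truly 1:1 pool
   essentially never leaves it); it is configurable.
4. **Recessive-parent consistency**: if the sterile pool is fixed for
   an allele the sterile parent does not carry, the site is dropped as
   a likely genotyping artefact.

Rule 3 deserves a remark: at unlinked segregating loci *both* bulks
look heterozygous-like, so on data where every site segregates — as in
the simulation — this rule removes the bulk of the genome and the
survivors concentrate on the causal chromosome plus sampling-noise
outliers. That is the rule working as intended, but it means that
desk-scale tracks contain far fewer null windows than a real
experiment, which matters for the data-dependent thresholds (below).

## Window fitting, thresholds and candidate regions

Raw per-site values are noisy (binomial with ~34 trials), so each
chromosome's track is fitted with a physical sliding-window mean:
windows of 1 Mb advanced by 10 kb, each summarising the sites in the
half-open interval $[c - w/2,\ c + w/2)$; windows with fewer than
`min_sites = 3` sites are reported missing. A window mean was chosen
over loess or splines deliberately: it is transparent, exactly
checkable against a brute-force oracle, and its value is always inside
the convex hull of the raw values it summarises.

Three threshold rules are provided:

* **theoretical** — the cross-model delta (2/3), the natural first
  threshold for the delta scan;
* **percentile** — the genome-wide 99th percentile of fitted values
  (linear interpolation, `stats::quantile` type 7). Computed
  genome-wide rather than per chromosome (the alternative reading);
  `fit_scan_track()` output can be subset per chromosome if wanted;
* **median3sd** — median plus three sample standard deviations
  (n − 1 denominator) of the fitted values, the usual rule for powered
  ED scans;
* a **fixed** user value, e.g. the relaxed 0.56 used when the
  theoretical threshold proves too strict for the realised noise level.

Candidate regions are maximal runs of consecutive windows whose fitted
value *strictly* exceeds the threshold (ties excluded; missing windows
break runs), with boundaries clipped to the outermost covered site
positions. Coordinates are 1-based inclusive internally; BED output
converts to 0-based half-open.

## The simulator

The synthetic-data generator reproduces the statistical structure the
scan assumes, one mechanism per stage:

* **Meiosis**: each F2 plant is the fusion of two independent gametes;
  each gamete is a recombinant mosaic of the parental haplotypes with
  a Poisson crossover count per chromosome and uniform crossover
  positions (Haldane model, no interference).
* **Phenotype**: sterile if and only if homozygous for the
  sterile-parent allele at the causal locus — full penetrance, one
  locus.
* **Bulks**: `bulk_size` plants per phenotype class, sampled without
  replacement (an explicit error names the class if the population
  cannot supply enough plants).
* **Pooled reads**: per site and pool, total depth is
  Poisson(`mean_depth`); each read carries the sterile-parent allele
  with probability equal to the bulk's true allele frequency and is
  flipped with probability `base_error` — the standard
  Poisson-total/binomial-split pool-seq approximation. No read-level
  artefacts (mapping bias, duplicates, indels) are modelled.
* **Orientation**: REF/ALT assignment is randomised per site, so
  downstream code must orient the SNP index from the parental
  genotypes rather than assuming ALT is the trait allele.

Defaults and the reasoning behind them:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 11 × 1 Mb | scaled 2n = 22 cucurbit karyotype, desk-scale |
| SNPs | ~2000, evenly spaced | ~0.2 SNP/kb keeps every 1 Mb window well populated |
| `n_f2` | 200 | ~50 expected sterile plants, so 30+30 bulks are reliably formable |
| `bulk_size` | 30 | the design's bulk size |
| `mean_depth` | 34 | the design's mean pool coverage |
| `base_error` | 0.01 | order of magnitude of post-filter sequencing error |
| `recomb_rate` | 0.05 / chromosome | preserves per-base recombination density (~5 cM/Mb, typical of cucurbit genomes) on the scaled 1 Mb chromosomes |

The `recomb_rate` choice is the one genuinely open decision. A 1 Mb
scaled chromosome could either preserve its real counterpart's *map
length* (~1 Morgan) or its *per-base density* (~0.05 Morgan/Mb). The
scan operates on physical windows, so density is the property worth
preserving: with 1 Morgan compressed into 1 Mb, a single fitting
window would span a full Morgan of recombination — something no real
BSA window does — and window averaging would erode the causal peak by
construction rather than by noise. With density preserved, the fitted
delta at the causal locus converges on 2/3 up to bulk-sampling noise,
matching the theory the thresholds are built on.

The simulator writes a standard four-sample VCF (two parents, two
bulks, `GT:AD`) and a plain-TSV truth sidecar recording the causal
locus and true bulk frequencies. The sidecar is read only by tests and
scoring code, never by the pipeline, so recovery experiments cannot
leak truth.

## What the simulation does and does not establish

Passing recovery tests on this generator shows that the pipeline
correctly implements the statistics and finds a fully penetrant
recessive locus under idealised pool-seq noise. It does **not**
establish robustness to mapping artefacts, segregation distortion,
mis-phenotyped plants, uneven SNP density, structural variation, or
polygenic traits — none of which are modelled. Two desk-scale
artefacts are worth keeping in mind:

* Because rule 3 removes most unlinked loci, data-dependent thresholds
  (99th percentile, median + 3 SD) are computed mostly from
  causal-chromosome windows and are therefore conservative here —
  in the bundled analysis the median + 3 SD ED threshold sits above
  every fitted window even though both statistics peak unambiguously
  on the causal chromosome. On a real dataset with hundreds of
  thousands of genome-wide loci the null fraction dominates and these
  thresholds behave as intended; the property tests therefore check
  the null behaviour with randomised bulks.
* Printed thresholds of the motivating experiment that depend on its
  particular data (an ED threshold of 0.37, region sizes, SNP counts)
  are not reproduction targets; only the rules that generate them are.

## Numerical conventions

* Percentiles: `stats::quantile` type 7 (linear interpolation).
* Standard deviation: sample SD with n − 1.
* Chi-square segregation test: Pearson statistic, 1 df, no continuity
  correction by default (a Yates flag exists).
* Window membership: half-open `[c - w/2, c + w/2)`; window means via
  cumulative sums (float error ~1e-13 on constant tracks).
* Thresholds: strict `>`; exact ties are excluded.
* Zero-depth pools give missing statistics, excluded from fitting.
* Codon classification uses NCBI translation table 1 embedded as a
  pure lookup; the test suite cross-checks all 576 single-base codon
  changes against `Biostrings::translate`.

## Problem sizes used by the test suite

Simulation-based tests run the default 2000-SNP, 11-chromosome layout;
recovery and concordance properties aggregate 50 seeds, and the
high-depth consistency check uses one simulation with 1000 plants,
200-plant bulks and 2000x depth. These sizes were chosen so the full
statistical behaviour (bulk-composition noise, read noise, window
averaging) is visible while the whole suite stays comfortably
interactive.
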