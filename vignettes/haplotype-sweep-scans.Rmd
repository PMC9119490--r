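---
title: "Haplotype-based selective sweep scans and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based selective sweep scans and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplosweep)
```

## Scientific problem

When a new advantageous variant rises quickly in frequency in one
population, it drags its chromosomal background along ("hitchhiking"). A
recent or ongoing hard sweep therefore leaves three correlated signatures
around the selected site:

1. **Unusually long haplotypes**: the swept allele sits on an extended
   stretch of identical sequence because recombination has not had time to
   break it up.
2. **Depressed heterozygosity**: most chromosomes carry the same haplotype,
   so windowed pooled heterozygosity drops.
3. **Reduced nucleotide diversity** in the swept population relative to a
   related, unswept one.

`haplosweep` computes the standard statistics for each signature from
phased two-population SNP data, turns them into 10-kb window calls, maps
significant windows to genes, and intersects the resulting gene sets with
differentially expressed genes (DEGs) from a companion expression contrast.
Genes supported by all four lines of evidence — iHS, XP-EHH, ZHp, and
differential expression — form the final report.

## Statistics

### EHH and iHH

For a core SNP and a set of $n$ carrier haplotypes, the extended haplotype
homozygosity at extension step $k$ is

$$\mathrm{EHH}_k \;=\; \sum_h \binom{n_h}{2} \Big/ \binom{n}{2},$$

where the sum runs over the distinct extended haplotypes $h$ (with counts
$n_h$) observed among the carriers over the $k$ flanking SNPs on one side
of the core. Identity is counted over the extension away from the core —
the core allele is shared by construction of an allele-class carrier set,
and population-level carrier sets inherit the same convention — so every
curve starts at 1 at offset 0 and is non-increasing. The curve is evaluated
at each successive SNP until it falls below a cutoff (default 0.05; the
first sub-cutoff node is kept) or the chromosome end is reached, in which
case the curve is flagged truncated.

The integrated haplotype homozygosity iHH is the trapezoid area under the
EHH curve against physical distance in bp, summed over the left and right
extensions. Physical distance is used because no genetic map is assumed;
units are bp·EHH.

```{r ehh-example}
a <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 1, 0), c(1, 1, 0))
hm <- haplotype_matrix("chr1", c(100L, 200L, 300L), rbind(a, a),
                       hap_labels = paste0("h", 1:8, "_", rep(1:2, 4)),
                       pop_of_hap = rep(c("A", "B"), each = 4))
ehh_curve(hm, core = 1L, carriers = 1:4, direction = "right", cutoff = 0)
```

### iHS

At each polarized, sufficiently common core site (derived frequency within
`maf_min = 0.05` of neither 0 nor 1), iHH is computed separately for the
ancestral- and derived-allele carriers and combined as
$\ln(\mathrm{iHH}_A / \mathrm{iHH}_D)$. Raw ratios depend strongly on the
derived-allele frequency, so they are standardized within 2%-wide
derived-frequency bins by default (bins holding fewer than `min_bin_n = 20`
scores are merged with their nearest occupied neighbour); global
standardization is available as an option. Strongly negative iHS marks long
derived-allele haplotypes; both tails are of interest genome-wide, so the
default p-value is two-sided normal-tail.

### XP-EHH

XP-EHH contrasts two populations at the same core site:
$\ln(\mathrm{iHH}_{\text{pop A}} / \mathrm{iHH}_{\text{pop B}})$, where
each population's iHH is computed over **all** of its haplotypes at the
core (the established cross-population convention; a per-allele-class mode
is available). Scores are standardized globally. Positive values mean
longer haplotypes — a sweep — in population A.

### Hp, ZHp and $\pi$

For each 10-kb window, pooled heterozygosity is

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
             {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$

with $\Sigma n_{MAJ}$ and $\Sigma n_{MIN}$ the summed major- and
minor-allele counts over all SNPs in the window. ZHp is the genome-wide
Z-transform of Hp; partial tail windows are excluded from the moment
estimates (but still transformed). Per-site nucleotide diversity uses the
unbiased pairwise estimator $2 c_0 c_1 / (n(n-1))$ and windowed $\pi$
divides the per-site sum by the window length in bp, so monomorphic
positions count toward the denominator.

### Window calls and gene integration

Per-site scores are aggregated into windows by the signed maximum-magnitude
value (mean aggregation is available). A window is called significant for
iHS or XP-EHH when $|z| \ge 1.5$ **and** $p \le 0.05$ (both inclusive), and
for ZHp when $z_{Hp} \le -1.5$ (heterozygosity deficits; a two-sided option
exists). Significant windows are mapped to genes by at least 1 bp of
overlap in 0-based half-open coordinates. DEGs are genes with
$|\log_2 FC| \ge 1.5$ and adjusted $p \le 0.05$. The four gene sets are
intersected; the package reports the 15-way Venn partition and a per-gene
table of signed extreme scores.

## Design decisions

* **Polarization.** Ancestral-allele assignment is rarely available for
  livestock panels. The default treats REF as ancestral (`ref_ancestral`);
  an `AA` INFO-tag mode and a major-allele mode are provided. The choice is
  recorded in the run manifest.
* **iHS population** (`ihs_pop = "pooled"`). With two small panels (8
  haplotypes each) jointly phased into one SNP set, per-population iHS is
  undefined exactly where a sweep is strongest: near-fixation leaves fewer
  than 2 carriers in one allele class. Scanning the pooled panel keeps both
  allele classes populated at swept sites while preserving the statistic's
  meaning; per-population scans remain available via `ihs_pop = "A"` etc.
* **Coordinates.** Internal coordinates are 0-based half-open
  (BED-compatible); all report files are 1-based inclusive.
* **Window geometry.** Non-overlapping 10-kb bins by default; a smaller
  step yields sliding windows. The final partial bin is kept and flagged.
* **Numerical conventions.** Sample SD ($n-1$) everywhere; trapezoid
  integration; ties in extended haplotypes need no tie-breaking because EHH
  is a set statistic.

## The synthetic-data generator

Real selective-sweep panels are tens of millions of SNPs; the package
validates its statistics instead on a deterministic two-population hard-
sweep simulator whose defaults are the package's study conditions: a 2-Mb
chromosome, 8 + 8 haplotypes (4 diploids per population), ~1 SNP/kb, and a
hard sweep in population A at mid-chromosome — one donor haplotype copied
onto 90% of the population's haplotypes over a 100-kb interval.

Neutral variation is built by Li–Stephens-style founder copying: 10 founder
haplotypes with a neutral-like frequency spectrum ($P(\text{count } i)
\propto 1/i$), each sample haplotype a mosaic of founders with a per-site
switch probability of 0.01. The copying process induces the linkage-
disequilibrium decay that haplotype statistics require; the imposed sweep
creates exact carrier identity over a known truth interval, written to
`truth.json` alongside the phased VCF, population map, gene BED and DEG
table. A fixed seed reproduces the dataset byte for byte.

```{r simulate, eval = FALSE}
params <- sweep_sim_params(seed = 1L)
sim <- simulate_dataset(params, "sim_out")
```

**Realism and limits.** The generator reproduces the features the scans
consume — LD decay, a frequency spectrum skewed toward rare variants, a
hard sweep with a truth interval — but it is not a coalescent simulator: no
mutation–recombination history, no demography, no soft sweeps, and the
sweep boundary is sharp rather than tapering. Haplotype signals genuinely
extend beyond the truth interval edges, which is why recovery checks score
window overlap rather than containment.

## Pipeline and problem sizes

`cmd_run_all()` chains simulate → scan → integrate and writes TSV/JSON
outputs plus `manifest.json` (package version, configuration, input MD5
checksums, stage timings, and — on failure — the stage and error message).
A thin command-line driver is installed at
`system.file("cli", "haplosweep.R", package = "haplosweep")`.

A default 2-Mb, 16-haplotype run completes in under 10 s on one core; the
EHH kernel is implemented in C++ and scales linearly in sites × haplotypes
for fixed curve length. These problem sizes are the package's validation
choice: large enough for ~200 windows of genome-wide moments, small enough
for routine testing.

## Limitations

* Diploid, phased, imputed input is assumed; sites with any missing,
  unphased, or multiallelic genotype are dropped (and counted in the load
  report) rather than imputed.
* Physical distance only; no genetic-map support.
* Two populations per scan; multi-way contrasts require repeated runs.
* Normal-tail p-values are calibrated by the genome-wide standardization;
  on short test chromosomes they are indicative rather than exact.
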