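---
title: "Methods: region-based eQTL scans with eqtlscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-based eQTL scans with eqtlscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlscan)
```

## The statistical model

`eqtlscan` treats a transcript's normalized expression level as a
quantitative trait and asks, SNP by SNP, whether genotype predicts it.
For individual $i$ with coded genotype $x_i$ the model is ordinary least
squares,

$$ y_i = \alpha + \beta x_i + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \sigma^2) \; \text{i.i.d.}, $$

and the reported p-value is the Wald test of $\beta = 0$:
$t = \hat\beta / \mathrm{SE}(\hat\beta)$ on $n - 2$ residual degrees of
freedom, two-sided. The t reference (rather than the asymptotic normal)
matches the standard quantitative-trait behavior of PLINK-style
association tools; at cohort sizes in the dozens to hundreds the two are
nearly indistinguishable, but the t is exact under the model.

The genotype coding is chosen per scan:

| model     | regressor(s)                      | test            |
|-----------|-----------------------------------|-----------------|
| additive  | minor-allele count $x \in \{0,1,2\}$ | t, $n-2$ df  |
| dominant  | $\mathbb{1}[x \ge 1]$             | t, $n-2$ df     |
| recessive | $\mathbb{1}[x = 2]$               | t, $n-2$ df     |
| genotypic | $x$ and $\mathbb{1}[x = 1]$       | joint F, $(2, n-3)$ df |

The genotypic parameterization is ADD + DOMDEV: the additive count plus
a heterozygote-deviation indicator, tested jointly with 2 df; the
reported effect and standard error are the additive term's. The additive
model is the default and the sensible first screen of a region; the
others exist because the true mode of action varies between loci.

Assumptions worth keeping in mind: residuals are taken as i.i.d.
Gaussian (the expression inputs are assumed already normalized —
`eqtlscan` applies no transformation); samples are treated as unrelated
once the founder filter has removed pedigree children; and no covariates
or population-stratification adjustment are applied, even in pooled
analyses. A pooled scan across populations that differ in both allele
frequency and expression mean can therefore show confounded signals;
per-population scans or externally adjusted phenotypes are the remedy.

## Sample handling

Genotypes arrive as PLINK-text PED/MAP. Population labels come from an
optional two-column sidecar (individual id → population) because PED
carries no population column. Two filters run before analysis:

* **population** — a single label, or `"pooled"` for everyone;
* **founders** — individuals whose paternal and maternal ids are both
  `"0"`. The default is founders-only (`founders_only = TRUE`): in a
  trio cohort the children duplicate parental alleles and would
  inflate the effective sample size. With the classic HapMap phase II
  structure (30 CEU trios, 45 + 45 unrelated CHB/JPT, 30 YRI trios) the
  filter keeps exactly 210 of 270 individuals. Setting
  `founders_only = FALSE` includes children for users who want them.

Expression and genotype samples are intersected by individual id,
preserving genotype order; dropped counts from each side are logged.
Within a scan, each SNP uses its own complete cases, so a call missing
at one SNP does not shrink the others.

The minor allele and MAF are computed on the analyzed (merged, filtered)
samples, not the full file; an exact 50/50 tie is broken alphabetically
so results are deterministic.

## Multiple testing

The family is the set of SNPs tested for one probe — each probe of a
multi-probe gene is a separate analysis with its own correction, and no
cross-probe adjustment is applied. Five procedures are available:
Bonferroni, Holm (step-down), single-step Šidák, Benjamini–Hochberg FDR
and Benjamini–Yekutieli FDR. Degenerate SNPs (see below) carry NA
p-values: they are excluded from the family size $m$ and remain NA in
every adjusted column.

Šidák is computed as $-\mathrm{expm1}(m \log1p(-p))$, the numerically
stable form of $1 - (1-p)^m$; the naive power underflows for
$p \lesssim 10^{-17}/m$ and would report an adjusted value *below* the
raw one.

## Numerical choices and degenerate inputs

* OLS is solved by normal equations with a Cholesky inverse; a singular
  cross-product (collinear design) yields an NA row rather than an
  error.
* **Monomorphic SNPs**, all-missing SNPs, genotypic designs with fewer
  than three genotype classes, and codings that are constant in the
  analyzed samples (e.g. recessive with no minor homozygote) are
  *degenerate*: the scan reports the SNP with NA effect and p plus a
  recorded reason, and tracks omit it rather than plotting a fake 0.
* **Perfect fits** (residual variance 0, as with noise-free synthetic
  data) would make $t = \beta/0$; instead `se = 0` is reported with the
  p-value floored at `p_floor` (default 1e-300).
* Track scores are $-\log_{10} p$ capped at `cap` (default 50) so a
  floored p cannot produce an unplottable value; bedGraph intervals are
  0-based half-open single-base, converted from the 1-based MAP
  positions.
* Result tables print 6 significant digits (p-values in scientific
  notation, `NA` literal for missing); fixture writers use full double
  precision so write → read round-trips are exact.

## The synthetic-data generator

`sim_config()` + `simulate_genotypes()` + `simulate_expression()`
emulate the data a scan consumes, with known ground truth. Defaults are
the conditions the package is calibrated under:

* **cohort** — the HapMap phase II shape: CEU 30 trios, CHB 45
  unrelated, JPT 45 unrelated, YRI 30 trios (270 individuals, 210
  founders);
* **SNPs** — `snp_panel()`: 20 evenly spaced SNPs on chromosome 4
  between 8,168,000 and 8,790,000 bp (a realistic single-gene cis
  window), MAF 0.3 — a common-variant frequency typical of genotyping
  panels;
* **genotypes** — founders drawn under Hardy–Weinberg at each SNP's MAF,
  independently across SNPs; trio children get one uniformly chosen
  allele from each parent; missing calls sprinkled completely at random;
* **expression** — `beta * coded(causal SNP) + N(0, noise_sd)` per
  individual, one independent noise draw per probe; pure noise
  (`sd = 1`) when no causal SNP is configured.

Everything is deterministic given the seed.

What this does *not* emulate: linkage disequilibrium (SNPs are
independent; the optional `ld_copy_of` block-copy mode creates a
correlated proxy for visualization, not a coalescent haplotype
structure), population allele-frequency divergence, batch or
normalization artifacts in expression, and non-Gaussian expression
tails. Tests passing on these fixtures therefore validate the
*computation* — coding, regression, correction, serialization — not the
robustness of eQTL inference to real-data pathologies.

## Calibration checks and problem sizes

The test suite ties the implementation to independent oracles and to its
operating characteristics. The sizes were chosen to make sampling noise
small relative to the tolerance being asserted:

* regression equals a normal-equations + reference-distribution oracle
  to 1e-8 on 100 random instances per model (and `stats::lm` /
  `anova()` agree as a second route);
* type-I error at $\alpha = 0.05$ over 5,000 null SNPs (n = 100,
  MAF 0.3) falls in [0.04, 0.06] for the 1-df models and
  [0.038, 0.062] for the genotypic F (binomial SE ≈ 0.003);
* the additive effect is recovered without bias: mean $\hat\beta$ over
  500 replicates (true $\beta = 0.5$, n = 500) within 0.03;
* adjustments match an independently coded textbook oracle to 1e-12
  (absolute) on 1,000 random p-vectors and obey the dominance orderings
  Bonferroni ≥ Šidák ≥ raw, Bonferroni ≥ Holm ≥ raw, BY ≥ BH ≥ raw;
* end-to-end, a planted causal SNP (β = 1, noise sd 0.5) among 20 nulls
  is the region's minimum p-value in at least 49 of 50 independent
  cohorts.

`scripts/acceptance.R` re-runs the founder count, the type-I rates, the
effect-recovery mean and the end-to-end detection rate from scratch and
writes them to JSON.

## Known limitations

* Text PED/MAP only — no PLINK binary (BED/BIM/FAM) or VCF input.
* Sex chromosomes are treated as diploid autosomes (flagged with a
  warning); no haploid male X handling.
* No covariates, kinship/mixed models, permutation p-values or LD
  computation; pooled analyses are unadjusted for stratification.
* Gene symbols are matched by case-folded equality only; probe → gene
  assignments are taken from the expression table as given.
* Expression values are used as-is; normalization choices (per
  population vs pooled) are represented by pointing the configuration at
  different input files, not recomputed.
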