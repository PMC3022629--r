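# eqtlscan

Region-based eQTL scans: per-SNP linear regression of transcript
expression on genotype, offline, from PLINK-text files.

## What it does

Gene expression can be treated as a quantitative trait. Given (i) SNP
genotypes for a cohort in PLINK text format (PED + MAP) and (ii) a
tab-delimited table of normalized expression values (transcript probes ×
individuals, with a probe → gene-symbol mapping), `eqtlscan` correlates
every SNP in a genomic window — or an explicit SNP list, which may sit on
a different chromosome than the gene (a trans scan) — with the expression
level of each probe representing a gene of interest.

For each SNP the genotype is coded under a selectable genetic model:

- **additive** — x ∈ {0, 1, 2}, the minor-allele count (recommended first
  screen);
- **dominant** — x = 1 if at least one minor allele;
- **recessive** — x = 1 only for the minor homozygote;
- **genotypic** — additive term plus a heterozygote-deviation term
  (ADD + DOMDEV), tested jointly with 2 df.

The model fitted per SNP is ordinary least squares,

    y_i = alpha + beta * x_i + e_i,   e_i ~ N(0, sigma^2)

with the Wald statistic t = beta / SE(beta) referred to a t distribution
on n − 2 df (two-sided) for the 1-df codings, and a joint F(2, n − 3)
test for the genotypic model. Per-SNP missingness is handled by
complete cases per SNP; the minor allele and MAF are computed on the
analyzed sample set. P-values are adjusted by Bonferroni, Holm,
single-step Šidák, Benjamini–Hochberg and Benjamini–Yekutieli, with the
family being the SNPs tested for one probe (each probe is a separate
analysis). Results are written as tab-delimited tables and as UCSC
Genome Browser custom tracks (bedGraph) carrying −log10(p), one parallel
track per probe × adjustment.

A synthetic-data module generates HapMap-structured cohorts (CEU 30
trios, CHB 45 unrelated, JPT 45 unrelated, YRI 30 trios; 270 individuals,
210 founders) with Hardy–Weinberg founder genotypes, Mendelian trio
transmission, and expression with a plantable genetic effect — so the
whole pipeline is testable offline with known ground truth.

## Worked example

```r
library(eqtlscan)

# simulate a cohort: 21 SNPs on chr4, one eQTL (rs000011, beta = 1)
cfg <- sim_config(snps = snp_panel(21),
                  causal = list(snp_id = "rs000011", model = "additive",
                                beta = 1, noise_sd = 0.5),
                  seed = 7, missing_rate = 0.02)
fx <- write_fixture(cfg, "fixture")

out <- run_eqtl_scan(run_config(
  gene = "GENE1", ped = fx$ped, map = fx$map, expr = fx$expression,
  sample_info = fx$sample_info, out_dir = "results_gene1",
  chromosome = "4", from_bp = 8168000, to_bp = 8790000))

r <- out$probes[[1]]$results
r[which.min(r$p), c("snp_id", "n_used", "maf", "beta", "se", "p")]
```

```
     snp_id n_used       maf     beta         se           p
11 rs000011    205 0.2658537 1.002576 0.05739977 2.60464e-42
```

The top SNP is the planted eQTL: over the 205 founders with a genotype
call, each copy of the minor allele raises expression by an estimated
1.00 units (true value 1), and the Wald p-value of 2.6e-42 dwarfs the 20
null SNPs. `results_gene1/` now contains, per probe,
`pvalues<PROBE>.linear.assoc.txt` (CHR SNP BP A1 N BETA SE STAT P),
`pvalues<PROBE>.linear.assoc.adjusted.txt` (all five adjustments),
`<PROBE>.qassoc.means.txt` (per-genotype-class counts, means, SDs),
`extracted_snps_with_expression_values<PROBE>.ped` (genotypes with the
expression value in the phenotype column), plus a shared
`customtrack.txt` ready for upload to the UCSC Genome Browser and a
`run.log` echoing every filtering step.

The same scan runs from a shell:

```sh
Rscript inst/scripts/eqtlscan.R --gene GENE1 --chrom 4 \
  --from-bp 8168000 --to-bp 8790000 \
  --ped fixture/genotypes.ped --map fixture/genotypes.map \
  --sample-info fixture/samples.tsv --expr fixture/expression.tsv \
  --out results_gene1 --model additive --pop pooled
```

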