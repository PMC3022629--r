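# -- synthetic HapMap-structured data ----------------------------------------

#' Default SNP panel for simulations
#'
#' A map of evenly spaced SNPs on one chromosome, by default 20 SNPs on
#' chromosome 4 spanning 8,168,000-8,790,000 bp (a region size typical of
#' a single-gene cis scan), each with the same minor allele frequency.
#'
#' @param n_snps number of SNPs.
#' @param chromosome chromosome label.
#' @param from_bp,to_bp region bounds; positions are evenly spaced across
#'   the region.
#' @param maf minor allele frequency, one value recycled or a vector of
#'   length `n_snps`; must lie in (0, 0.5].
#' @return data.frame with `snp_id`, `chromosome`, `position_bp`, `maf`.
#' @export
snp_panel <- function(n_snps = 20, chromosome = "4",
                      from_bp = 8168000, to_bp = 8790000, maf = 0.3) {
  maf <- rep_len(maf, n_snps)
  stopifnot(all(maf > 0 & maf <= 0.5))
  data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chromosome = as.character(chromosome),
    position_bp = round(seq(from_bp, to_bp, length.out = n_snps)),
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes a synthetic cohort with the HapMap phase II structure by
#' default: CEU 30 trios (90 individuals), CHB 45 unrelated, JPT 45
#' unrelated, YRI 30 trios (90 individuals) — 270 individuals of whom 210
#' are founders.
#'
#' @param populations data.frame with columns `label`, `n_unrelated`,
#'   `n_trios`; defaults to the HapMap phase II shape.
#' @param snps data.frame as from [snp_panel()].
#' @param causal optional list `(snp_id, model, beta, noise_sd)` planting
#'   a genetic effect on expression; `NULL` simulates a null gene
#'   (`noise_sd` then defaults to 1).
#' @param gene_symbol gene symbol attached to simulated probes.
#' @param n_probes_per_gene number of transcript probes sharing the
#'   genetic effect (independent noise per probe).
#' @param missing_rate per-call missing-genotype probability in \[0, 1).
#' @param seed integer RNG seed; every simulation is deterministic given
#'   the seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(populations = NULL, snps = snp_panel(),
                       causal = NULL, gene_symbol = "GENE1",
                       n_probes_per_gene = 1L, missing_rate = 0,
                       seed = 1L) {
  if (is.null(populations))
    populations <- data.frame(
      label = c("CEU", "CHB", "JPT", "YRI"),
      n_unrelated = c(0L, 45L, 45L, 0L),
      n_trios = c(30L, 0L, 0L, 30L),
      stringsAsFactors = FALSE
    )
  stopifnot(all(c("label", "n_unrelated", "n_trios") %in% names(populations)),
            all(snps$maf > 0 & snps$maf <= 0.5),
            missing_rate >= 0, missing_rate < 1,
            n_probes_per_gene >= 1L)
  ord <- order(snps$chromosome, snps$position_bp)
  if (any(diff(snps$position_bp[ord]) == 0 &
          diff(as.integer(factor(snps$chromosome[ord]))) == 0))
    stop("SNP positions must be strictly increasing within a chromosome")
  if (!is.null(causal)) {
    stopifnot(causal$snp_id %in% snps$snp_id,
              causal$model %in% GENETIC_MODELS,
              is.numeric(causal$beta), causal$noise_sd >= 0)
  }
  structure(list(populations = populations, snps = snps, causal = causal,
                 gene_symbol = gene_symbol,
                 n_probes_per_gene = as.integer(n_probes_per_gene),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# one founder genotype column: HWE given maf, returned as minor-allele counts
draw_founder_counts <- function(n, maf) {
  stats::rbinom(n, 2L, maf)
}

#' Simulate genotypes for a HapMap-like cohort
#'
#' Founder genotypes are drawn under Hardy-Weinberg equilibrium at each
#' SNP's configured minor allele frequency, independently across SNPs (no
#' linkage disequilibrium). Trio children receive one uniformly chosen
#' allele from each parent (Mendelian transmission). Missing calls are
#' sprinkled completely at random at `missing_rate`. Allele symbols are A
#' (minor at the configured frequency) and G (major).
#'
#' An optional LD proxy: set `ld_copy_of` and `ld_flip_rate` to replace a
#' SNP's genotypes with a noisy copy of another SNP's (each allele flipped
#' independently with the given rate), creating a correlated pair the way
#' tight LD does — a visualization aid, not a coalescent model.
#'
#' @param cfg a [sim_config()].
#' @param ld_copy_of optional named character vector: for each name (a
#'   SNP id in the panel), the id of the SNP whose genotypes it copies.
#' @param ld_flip_rate per-allele flip probability for the copies.
#' @return A `genotype_dataset`.
#' @export
simulate_genotypes <- function(cfg, ld_copy_of = NULL, ld_flip_rate = 0.05) {
  set.seed(cfg$seed)
  snps <- cfg$snps
  m <- nrow(snps)

  samples <- list()
  counts <- list()  # minor-allele counts per sample x snp, built rowwise
  for (pi in seq_len(nrow(cfg$populations))) {
    pop <- cfg$populations[pi, ]
    if (pop$n_unrelated > 0L) {
      iids <- sprintf("%s_U%03d", pop$label, seq_len(pop$n_unrelated))
      samples[[length(samples) + 1L]] <- data.frame(
        family_id = iids, individual_id = iids,
        paternal_id = "0", maternal_id = "0",
        sex = rep_len(c(1L, 2L), pop$n_unrelated),
        population = pop$label, stringsAsFactors = FALSE
      )
      counts[[length(counts) + 1L]] <-
        vapply(snps$maf, function(f) draw_founder_counts(pop$n_unrelated, f),
               numeric(pop$n_unrelated))
    }
    if (pop$n_trios > 0L) {
      for (tr in seq_len(pop$n_trios)) {
        fid <- sprintf("%s_T%03d", pop$label, tr)
        father <- vapply(snps$maf, function(f) draw_founder_counts(1L, f),
                         numeric(1L))
        mother <- vapply(snps$maf, function(f) draw_founder_counts(1L, f),
                         numeric(1L))
        # transmit one allele from each parent: from a parent with count c,
        # a minor allele is passed w.p. c/2
        child <- stats::rbinom(m, 1L, father / 2) +
          stats::rbinom(m, 1L, mother / 2)
        samples[[length(samples) + 1L]] <- data.frame(
          family_id = fid,
          individual_id = paste0(fid, c("_F", "_M", "_C")),
          paternal_id = c("0", "0", paste0(fid, "_F")),
          maternal_id = c("0", "0", paste0(fid, "_M")),
          sex = c(1L, 2L, sample(1:2, 1L)),
          population = pop$label, stringsAsFactors = FALSE
        )
        counts[[length(counts) + 1L]] <- rbind(father, mother, child)
      }
    }
  }
  samples <- do.call(rbind, samples)
  counts <- do.call(rbind, counts)
  n <- nrow(samples)

  if (!is.null(ld_copy_of)) {
    for (tgt in names(ld_copy_of)) {
      jt <- match(tgt, snps$snp_id)
      js <- match(ld_copy_of[[tgt]], snps$snp_id)
      if (is.na(jt) || is.na(js))
        stop("ld_copy_of refers to unknown SNP id")
      src <- counts[, js]
      # flip each of the two alleles independently
      flips <- stats::rbinom(n, 1L, ld_flip_rate) +
        stats::rbinom(n, 1L, ld_flip_rate)
      prop <- src + ifelse(src == 0, flips,
                           ifelse(src == 2, -flips,
                                  (stats::rbinom(n, 1L, 0.5) * 2L - 1L) *
                                    (flips > 0)))
      counts[, jt] <- pmin(pmax(prop, 0), 2)
    }
  }

  # counts -> allele symbols: A = minor at configured maf, G = major
  a1 <- ifelse(counts >= 1, "A", "G")
  a2 <- ifelse(counts == 2, "A", "G")
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
    a1[miss] <- "0"
    a2[miss] <- "0"
  }
  snp_df <- data.frame(snp_id = snps$snp_id,
                       chromosome = snps$chromosome,
                       position_bp = snps$position_bp,
                       stringsAsFactors = FALSE)
  snp_df$alleles <- lapply(seq_len(m), function(j)
    setdiff(sort(unique(c(a1[, j], a2[, j]))), "0"))
  genotype_dataset(samples, snp_df, a1, a2)
}

#' Simulate expression profiles over a simulated cohort
#'
#' Expression is `beta * coded(causal SNP, model) + Normal(0, noise_sd)`
#' per individual, or pure noise when no causal SNP is configured. Each of
#' `n_probes_per_gene` probes shares the genetic effect but receives an
#' independent noise draw. The coded genotype uses the true simulated
#' minor allele ("A"), so the planted `beta` is on the same scale the
#' association scan estimates.
#'
#' @param ds the `genotype_dataset` the expression belongs to.
#' @param cfg the [sim_config()] used to generate `ds`.
#' @return An `expression_table` covering every individual of `ds`.
#' @export
simulate_expression <- function(ds, cfg) {
  set.seed(cfg$seed + 1000003L)
  n <- nrow(ds$samples)
  genetic <- rep(0, n)
  noise_sd <- 1
  if (!is.null(cfg$causal)) {
    noise_sd <- cfg$causal$noise_sd
    j <- match(cfg$causal$snp_id, ds$snps$snp_id)
    add <- (ds$allele1[, j] == "A") + (ds$allele2[, j] == "A")
    add[ds$allele1[, j] == "0"] <- 0  # missing contributes no effect
    x <- switch(cfg$causal$model,
                additive = add,
                dominant = as.numeric(add >= 1),
                recessive = as.numeric(add == 2),
                genotypic = add)
    genetic <- cfg$causal$beta * x
  }
  k <- cfg$n_probes_per_gene
  values <- vapply(seq_len(k),
                   function(i) genetic + stats::rnorm(n, 0, noise_sd),
                   numeric(n))
  values <- t(values)
  probe_id <- sprintf("%s_probe%02d", cfg$gene_symbol, seq_len(k))
  rownames(values) <- probe_id
  colnames(values) <- ds$samples$individual_id
  structure(list(probe_id = probe_id,
                 gene_symbol = rep(cfg$gene_symbol, k),
                 values = values),
            class = "expression_table")
}

# -- fixture writers ---------------------------------------------------------

#' Write a genotype dataset as PLINK-text PED/MAP
#'
#' @param ds a `genotype_dataset`.
#' @param ped_file,map_file output paths.
#' @param phenotype optional numeric vector for PED column 6; defaults to
#'   the PLINK missing code `-9`.
#' @return Invisibly, the PED path.
#' @export
write_ped_map <- function(ds, ped_file, map_file, phenotype = NULL) {
  map <- sprintf("%s\t%s\t0\t%d", ds$snps$chromosome, ds$snps$snp_id,
                 as.integer(ds$snps$position_bp))
  writeLines(map, map_file)
  n <- nrow(ds$samples)
  pheno <- if (is.null(phenotype)) rep("-9", n) else format_full(phenotype)
  geno <- vapply(seq_len(n), function(i)
    paste(rbind(ds$allele1[i, ], ds$allele2[i, ]), collapse = "\t"),
    character(1L))
  rows <- paste(ds$samples$family_id, ds$samples$individual_id,
                ds$samples$paternal_id, ds$samples$maternal_id,
                ds$samples$sex, pheno, geno, sep = "\t")
  if (nrow(ds$snps) == 0L)
    rows <- paste(ds$samples$family_id, ds$samples$individual_id,
                  ds$samples$paternal_id, ds$samples$maternal_id,
                  ds$samples$sex, pheno, sep = "\t")
  writeLines(rows, ped_file)
  invisible(ped_file)
}

#' Write an expression table as TSV
#'
#' @param table an `expression_table`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_expression_table <- function(table, path) {
  header <- paste(c("ProbeID", "GeneSymbol", colnames(table$values)),
                  collapse = "\t")
  rows <- vapply(seq_along(table$probe_id), function(i)
    paste(c(table$probe_id[i], table$gene_symbol[i],
            format_full(table$values[i, ])), collapse = "\t"),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a sample-info sidecar (individual id -> population)
#'
#' @param ds a `genotype_dataset`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_sample_info <- function(ds, path) {
  writeLines(c("IID\tPOP",
               paste(ds$samples$individual_id, ds$samples$population,
                     sep = "\t")),
             path)
  invisible(path)
}

#' Write a complete synthetic fixture
#'
#' Emits `genotypes.ped`, `genotypes.map`, `samples.tsv` and
#' `expression.tsv` into `out_dir`, in exactly the dialects the package's
#' readers accept. Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the four paths plus the simulated
#'   objects as `genotypes` (a `genotype_dataset`) and `expr_table` (an
#'   `expression_table`).
#' @export
write_fixture <- function(cfg, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  ds <- simulate_genotypes(cfg)
  expr <- simulate_expression(ds, cfg)
  paths <- list(ped = file.path(out_dir, "genotypes.ped"),
                map = file.path(out_dir, "genotypes.map"),
                sample_info = file.path(out_dir, "samples.tsv"),
                expression = file.path(out_dir, "expression.tsv"))
  write_ped_map(ds, paths$ped, paths$map)
  write_sample_info(ds, paths$sample_info)
  write_expression_table(expr, paths$expression)
  invisible(c(paths, list(genotypes = ds, expr_table = expr)))
}
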