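test_that("genotype coding matches its definitions for every model", {
  a1 <- c("A", "A", "G", "A", "0")
  a2 <- c("A", "G", "G", "G", "0")
  # counts among non-missing: A = 4, G = 4 -> tie, minor = "A" (alphabetical)
  d <- code_genotypes(a1, a2, "additive")
  expect_equal(d$minor_allele, "A")
  expect_equal(d$major_allele, "G")
  expect_equal(d$kept_index, 1:4)
  expect_equal(unname(d$columns[, 1]), c(2, 1, 0, 1))
  expect_equal(unname(code_genotypes(a1, a2, "dominant")$columns[, 1]),
               c(1, 1, 0, 1))
  expect_equal(unname(code_genotypes(a1, a2, "recessive")$columns[, 1]),
               c(1, 0, 0, 0))
  g <- code_genotypes(a1, a2, "genotypic")
  expect_equal(colnames(g$columns), c("ADD", "DOMDEV"))
  expect_equal(unname(g$columns[, 2]), c(0, 1, 0, 1))
  expect_equal(d$maf, 0.5)
})

test_that("minor allele matches a brute-force frequency count", {
  set.seed(101)
  for (i in 1:50) {
    calls <- random_calls(40, maf = runif(1, 0.05, 0.5), miss = 0.1,
                          alleles = sample(c("A", "C", "G", "T"), 2))
    d <- code_genotypes(calls$a1, calls$a2, "additive")
    kept <- calls$a1 != "0"
    pool <- c(calls$a1[kept], calls$a2[kept])
    counts <- table(pool)
    if (length(counts) < 2) {
      expect_true(d$degenerate)
      next
    }
    expected_minor <- if (counts[1] == counts[2]) {
      sort(names(counts))[1]
    } else {
      names(counts)[which.min(counts)]
    }
    expect_equal(d$minor_allele, expected_minor)
    expect_equal(d$maf, min(counts) / sum(counts))
    expect_equal(unname(d$columns[, 1]),
                 unname((calls$a1[kept] == expected_minor) +
                          (calls$a2[kept] == expected_minor)))
  }
})

test_that("degenerate designs are flagged, not fitted", {
  mono <- code_genotypes(rep("G", 5), rep("G", 5), "additive")
  expect_true(mono$degenerate)
  expect_equal(mono$reason, "monomorphic")
  expect_equal(mono$maf, 0)
  fit <- fit_wald(mono, rnorm(5))
  expect_true(is.na(fit$p))
  # genotypic with only two genotype classes
  g2 <- code_genotypes(c("A", "A", "G", "G"), c("G", "G", "G", "G"),
                       "genotypic")
  expect_true(g2$degenerate)
  # recessive with no minor homozygote: constant regressor
  rec <- code_genotypes(c("A", "A", "G", "G"), c("G", "G", "G", "G"),
                        "recessive")
  expect_true(rec$degenerate)
  # >2 alleles is a data error
  expect_error(code_genotypes(c("A", "C", "G"), c("A", "C", "G"),
                              "additive"), "more than two alleles")
})

test_that("an exact linear fit is guarded with a floored p-value", {
  a1 <- c("A", "A", "A", "A", "G", "G")
  a2 <- c("A", "A", "G", "G", "G", "G")
  d <- code_genotypes(a1, a2, "additive")
  y <- 2 * d$columns[, 1] + 1
  fit <- fit_wald(d, y)
  expect_equal(fit$beta, 2)
  expect_equal(fit$se, 0)
  expect_equal(fit$p, 1e-300)
})

test_that("regression matches the normal-equations oracle and lm", {
  set.seed(202)
  for (model in c("additive", "dominant", "recessive", "genotypic")) {
    for (i in 1:20) {
      calls <- random_calls(30, maf = 0.4, miss = 0)
      d <- code_genotypes(calls$a1, calls$a2, model)
      if (d$degenerate) next
      y <- rnorm(30)
      fit <- fit_wald(d, y)
      orc <- ols_oracle(d$columns, y)
      expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
      expect_equal(fit$se, orc$se, tolerance = 1e-10)
      expect_equal(fit$statistic, orc$statistic, tolerance = 1e-10)
      expect_equal(fit$p, orc$p, tolerance = 1e-10)
      # reference implementation cross-check
      lm_fit <- lm(y ~ d$columns)
      expect_equal(fit$beta, unname(coef(lm_fit)[2]), tolerance = 1e-10)
      if (model != "genotypic") {
        expect_equal(fit$p,
                     summary(lm_fit)$coefficients[2, 4],
                     tolerance = 1e-10)
      } else {
        af <- anova(lm(y ~ 1), lm_fit)
        expect_equal(fit$statistic, af$F[2], tolerance = 1e-10)
        expect_equal(fit$p, af$`Pr(>F)`[2], tolerance = 1e-10)
      }
    }
  }
})

test_that("class summaries agree with brute-force aggregation", {
  # all heterozygotes, hand-computable
  cls <- class_summaries(c("A", "A", "A"), c("G", "G", "G"),
                         c(1, 2, 3), "A", "G")
  expect_equal(cls$n, c(0L, 3L, 0L))
  expect_equal(cls$mean[2], 2)
  expect_equal(cls$sd[2], 1)
  expect_true(all(is.na(cls$mean[c(1, 3)])))
  # single observation in a class -> sd NA
  one <- class_summaries(c("A", "A", "G"), c("A", "G", "G"),
                         c(5, 1, 2), "A", "G")
  expect_equal(one$n, c(1L, 1L, 1L))
  expect_true(all(is.na(one$sd)))
  # random fixture vs tapply
  set.seed(33)
  calls <- random_calls(60, maf = 0.3, miss = 0.1)
  y <- rnorm(60)
  d <- code_genotypes(calls$a1, calls$a2, "additive")
  cls <- class_summaries(calls$a1, calls$a2, y, d$minor_allele,
                         d$major_allele)
  kept <- calls$a1 != "0"
  g <- (calls$a1[kept] == d$minor_allele) + (calls$a2[kept] == d$minor_allele)
  for (k in 0:2) {
    yy <- y[kept][g == k]
    expect_equal(cls$n[k + 1], length(yy))
    if (length(yy)) expect_equal(cls$mean[k + 1], mean(yy))
    if (length(yy) >= 2) expect_equal(cls$sd[k + 1], sd(yy))
  }
})

test_that("region scan finds a planted causal SNP and handles missing", {
  cfg <- sim_config(snps = snp_panel(21),
                    causal = list(snp_id = "rs000011", model = "additive",
                                  beta = 1, noise_sd = 0.5),
                    seed = 77, missing_rate = 0.02)
  ds <- filter_founders(simulate_genotypes(cfg))
  expr <- simulate_expression(ds, cfg)
  prof <- expression_profile(expr, expr$probe_id[1])
  m <- merge_samples(ds, prof)
  res <- run_association(m$genotypes, m$phenotype, "additive")
  expect_s3_class(res, "association_result")
  expect_equal(res$snp_id, cfg$snps$snp_id)
  expect_equal(res$snp_id[which.min(res$p)], "rs000011")
  # per-SNP complete cases: n_used varies by SNP with sprinkled missing
  expect_true(all(res$n_used <= nrow(m$genotypes$samples)))
  # class counts conservation: counts + missing = merged n, per SNP
  n_missing <- colSums(m$genotypes$allele1 == "0")
  expect_equal(res$n_hom_major + res$n_het + res$n_hom_minor +
                 unname(n_missing),
               rep(nrow(m$genotypes$samples), nrow(res)))
})

test_that("all-missing SNPs give NA rows and duplicates identical rows", {
  samples <- data.frame(family_id = paste0("F", 1:6),
                        individual_id = paste0("I", 1:6),
                        paternal_id = "0", maternal_id = "0",
                        sex = 1L, population = "CEU",
                        stringsAsFactors = FALSE)
  a1 <- cbind(c("A", "A", "G", "A", "G", "G"), "0",
              c("A", "A", "G", "A", "G", "G"))
  a2 <- cbind(c("A", "G", "G", "G", "G", "G"), "0",
              c("A", "G", "G", "G", "G", "G"))
  snps <- data.frame(snp_id = c("rsA", "rsGone", "rsAdup"),
                     chromosome = "1", position_bp = c(10, 20, 30),
                     stringsAsFactors = FALSE)
  snps$alleles <- list(c("A", "G"), character(0), c("A", "G"))
  ds <- genotype_dataset(samples, snps, a1, a2)
  res <- run_association(ds, c(2.1, 1.0, 0.3, 1.2, 0.1, 0.5))
  expect_true(is.na(res$p[2]))
  expect_equal(res$n_used[2], 0)
  expect_equal(res$beta[1], res$beta[3])
  expect_equal(res$p[1], res$p[3])
})

test_that("allele relabeling leaves the test invariant", {
  set.seed(404)
  calls <- random_calls(80, maf = 0.25, miss = 0)
  y <- rnorm(80) + 0.4 * ((calls$a1 == "A") + (calls$a2 == "A"))
  for (model in c("additive", "dominant", "recessive", "genotypic")) {
    d1 <- code_genotypes(calls$a1, calls$a2, model)
    relab <- function(x) chartr("AG", "CT", x)
    d2 <- code_genotypes(relab(calls$a1), relab(calls$a2), model)
    f1 <- fit_wald(d1, y)
    f2 <- fit_wald(d2, y)
    expect_equal(abs(f1$statistic), abs(f2$statistic), tolerance = 1e-12)
    expect_equal(f1$p, f2$p, tolerance = 1e-12)
  }
  # forcing the major allele to be coded flips the additive sign
  d <- code_genotypes(calls$a1, calls$a2, "additive")
  swapped <- d
  swapped$columns <- cbind(ADD = 2 - d$columns[, 1])
  f <- fit_wald(d, y)
  fs <- fit_wald(swapped, y)
  expect_equal(fs$beta, -f$beta, tolerance = 1e-12)
  expect_equal(fs$p, f$p, tolerance = 1e-12)
})
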