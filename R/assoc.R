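# -- genetic-model coding ----------------------------------------------------

GENETIC_MODELS <- c("additive", "dominant", "recessive", "genotypic")

#' Code one SNP's calls under a genetic model
#'
#' Determines the minor allele from allele frequencies among the non-missing
#' calls of the analyzed sample set and builds the numeric regressor
#' column(s): additive = minor-allele count (0/1/2), dominant = carries at
#' least one minor allele, recessive = two minor alleles, genotypic = the
#' additive column plus a heterozygote indicator (PLINK's ADD + DOMDEV
#' parameterization, tested jointly with 2 df). An exact 50/50 allele
#' frequency tie is broken deterministically: the alphabetically first
#' allele is called minor.
#'
#' @param allele1,allele2 character vectors of allele calls for one SNP
#'   (one entry per sample; `"0"` = missing).
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"genotypic"`.
#' @param snp_id optional id carried through for reporting.
#' @return A `coded_design`: list with `snp_id`, `model`, `minor_allele`,
#'   `major_allele`, `maf`, `columns` (numeric matrix over kept samples),
#'   `kept_index` (positions of non-missing samples), `degenerate` flag and
#'   `reason`.
#' @export
code_genotypes <- function(allele1, allele2, model = "additive",
                           snp_id = NA_character_) {
  model <- match.arg(model, GENETIC_MODELS)
  stopifnot(length(allele1) == length(allele2))
  kept <- which(allele1 != "0" & allele2 != "0")
  res <- list(snp_id = snp_id, model = model,
              minor_allele = NA_character_, major_allele = NA_character_,
              maf = NA_real_, columns = NULL, kept_index = kept,
              degenerate = FALSE, reason = NA_character_)
  class(res) <- "coded_design"
  if (length(kept) == 0L) {
    res$degenerate <- TRUE
    res$reason <- "all calls missing"
    return(res)
  }
  counts <- table(c(allele1[kept], allele2[kept]))
  alleles <- names(counts)
  if (length(alleles) > 2L)
    stop("SNP ", snp_id, ": more than two alleles (",
         paste(alleles, collapse = ","), ")")
  if (length(alleles) == 1L) {
    res$major_allele <- alleles
    res$maf <- 0
    res$degenerate <- TRUE
    res$reason <- "monomorphic"
    return(res)
  }
  # minor = less frequent; exact tie -> alphabetically first (sorted names
  # break the tie because table() sorts its dimnames)
  ord <- order(counts, names(counts))
  res$minor_allele <- alleles[ord[1L]]
  res$major_allele <- alleles[ord[2L]]
  res$maf <- as.numeric(counts[ord[1L]] / sum(counts))
  add <- (allele1[kept] == res$minor_allele) +
    (allele2[kept] == res$minor_allele)
  res$columns <- switch(model,
    additive  = cbind(ADD = add),
    dominant  = cbind(DOM = as.numeric(add >= 1)),
    recessive = cbind(REC = as.numeric(add == 2)),
    genotypic = cbind(ADD = add, DOMDEV = as.numeric(add == 1))
  )
  if (model == "genotypic" && length(unique(add)) < 3L) {
    res$degenerate <- TRUE
    res$reason <- "fewer than 3 genotype classes for genotypic model"
  } else if (stats::var(res$columns[, 1L]) == 0 ||
             (ncol(res$columns) > 1L && stats::var(res$columns[, 2L]) == 0)) {
    res$degenerate <- TRUE
    res$reason <- "constant regressor under this model"
  }
  res
}

# -- regression --------------------------------------------------------------

#' Per-SNP linear regression with a Wald (or joint F) test
#'
#' Ordinary least squares of expression on the coded genotype. For 1-df
#' models the statistic is the Wald t = beta/se with p from the t
#' distribution on n - 2 residual df (two-sided). For the genotypic model
#' the statistic is the joint F for both genotype terms on (2, n - 3) df;
#' the reported beta/se belong to the additive term. A perfect fit
#' (residual variance 0) is guarded: se = 0 and p is reported as `p_floor`
#' rather than dividing by zero.
#'
#' @param design a `coded_design` from [code_genotypes()].
#' @param phenotype numeric expression vector over the full sample set
#'   (the design's `kept_index` selects the rows used).
#' @param p_floor smallest reportable p-value for perfect fits.
#' @return List with `beta`, `se`, `statistic`, `df1`, `df2`, `p`,
#'   `n_used` and `reason` (NA unless degenerate).
#' @export
fit_wald <- function(design, phenotype, p_floor = 1e-300) {
  na_fit <- function(reason, n_used = length(design$kept_index)) {
    list(beta = NA_real_, se = NA_real_, statistic = NA_real_,
         df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
         n_used = n_used, reason = reason)
  }
  if (isTRUE(design$degenerate)) return(na_fit(design$reason))
  y <- phenotype[design$kept_index]
  X <- cbind(`(Intercept)` = 1, design$columns)
  n <- length(y)
  k <- ncol(X)
  df1 <- k - 1L
  df2 <- n - k
  if (n < df1 + 2L || df2 < 1L)
    return(na_fit(sprintf("too few observations (n=%d) for %d-df model",
                          n, df1)))
  xtx <- crossprod(X)
  xtx_inv <- tryCatch(chol2inv(chol(xtx)),
                      error = function(e) NULL)
  if (is.null(xtx_inv)) return(na_fit("singular design"))
  beta_hat <- drop(xtx_inv %*% crossprod(X, y))
  resid <- y - drop(X %*% beta_hat)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  beta <- beta_hat[2L]  # additive/only genotype term
  if (rss <= 1e-12 * max(tss, 1)) {
    return(list(beta = beta, se = 0, statistic = Inf,
                df1 = df1, df2 = df2, p = p_floor, n_used = n,
                reason = "perfect fit; p floored"))
  }
  sigma2 <- rss / df2
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  if (df1 == 1L) {
    statistic <- beta / se
    p <- 2 * stats::pt(-abs(statistic), df2)
  } else {
    statistic <- ((tss - rss) / df1) / sigma2
    p <- stats::pf(statistic, df1, df2, lower.tail = FALSE)
  }
  list(beta = unname(beta), se = unname(se), statistic = unname(statistic),
       df1 = df1, df2 = df2, p = max(p, p_floor), n_used = n,
       reason = NA_character_)
}

#' Per-genotype-class phenotype summaries
#'
#' Counts, means and sample standard deviations (n - 1 denominator) of the
#' phenotype within the three genotype classes, keyed homMajor / het /
#' homMinor relative to the supplied allele assignment. Empty classes get
#' count 0 and NA mean/sd; a single observation gives NA sd.
#'
#' @param allele1,allele2 allele calls for one SNP.
#' @param phenotype numeric vector aligned with the calls.
#' @param minor_allele,major_allele allele symbols defining the classes.
#' @return data.frame with columns `class`, `n`, `mean`, `sd`.
#' @export
class_summaries <- function(allele1, allele2, phenotype,
                            minor_allele, major_allele) {
  kept <- which(allele1 != "0" & allele2 != "0")
  add <- if (is.na(minor_allele)) {
    rep(0, length(kept))
  } else {
    (allele1[kept] == minor_allele) + (allele2[kept] == minor_allele)
  }
  y <- phenotype[kept]
  out <- data.frame(class = c("homMajor", "het", "homMinor"),
                    n = NA_integer_, mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in 0:2) {
    yy <- y[add == g]
    i <- g + 1L
    out$n[i] <- length(yy)
    out$mean[i] <- if (length(yy)) mean(yy) else NA_real_
    out$sd[i] <- if (length(yy) >= 2L) stats::sd(yy) else NA_real_
  }
  out
}

#' Region-wide association scan for one probe
#'
#' Runs [code_genotypes()] + [fit_wald()] + [class_summaries()] for every
#' SNP of the dataset, in map order. Missing-genotype exclusion is
#' complete-cases per SNP (each SNP uses all samples with a call for it),
#' not listwise across the region. Degenerate SNPs yield NA statistics
#' with the reason recorded.
#'
#' @param ds a `genotype_dataset` whose samples are already aligned with
#'   `phenotype` (see [merge_samples()]).
#' @param phenotype numeric expression vector, one value per sample.
#' @param model genetic model name.
#' @param p_floor smallest reportable p-value.
#' @return data.frame of class `association_result` with one row per SNP:
#'   id/position columns, `n_used`, alleles, `maf`, `beta`, `se`,
#'   `statistic`, `df1`, `df2`, `p`, per-class counts/means/sds and
#'   `reason`.
#' @export
run_association <- function(ds, phenotype, model = "additive",
                            p_floor = 1e-300) {
  model <- match.arg(model, GENETIC_MODELS)
  stopifnot(length(phenotype) == nrow(ds$samples))
  m <- nrow(ds$snps)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    a1 <- ds$allele1[, j]
    a2 <- ds$allele2[, j]
    design <- code_genotypes(a1, a2, model, snp_id = ds$snps$snp_id[j])
    fit <- fit_wald(design, phenotype, p_floor = p_floor)
    cls <- class_summaries(a1, a2, phenotype,
                           design$minor_allele, design$major_allele)
    rows[[j]] <- data.frame(
      snp_id = ds$snps$snp_id[j],
      chromosome = ds$snps$chromosome[j],
      position_bp = ds$snps$position_bp[j],
      n_used = fit$n_used,
      minor_allele = design$minor_allele,
      major_allele = design$major_allele,
      maf = design$maf,
      beta = fit$beta, se = fit$se, statistic = fit$statistic,
      df1 = fit$df1, df2 = fit$df2, p = fit$p,
      n_hom_major = cls$n[1L], n_het = cls$n[2L], n_hom_minor = cls$n[3L],
      mean_hom_major = cls$mean[1L], mean_het = cls$mean[2L],
      mean_hom_minor = cls$mean[3L],
      sd_hom_major = cls$sd[1L], sd_het = cls$sd[2L],
      sd_hom_minor = cls$sd[3L],
      reason = fit$reason,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}
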