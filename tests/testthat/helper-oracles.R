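# Independent oracles used across tests. These deliberately take a
# different computational route from the package code they check.

# OLS by explicit normal equations (X'X)^-1 X'y, with t / F p-values from
# R's reference distribution functions.
ols_oracle <- function(x_cols, y) {
  X <- cbind(1, x_cols)
  XtX_inv <- solve(t(X) %*% X)
  beta <- drop(XtX_inv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  n <- length(y)
  k <- ncol(X)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k)
  se <- sqrt(sigma2 * diag(XtX_inv))
  if (k == 2L) {
    stat <- beta[2L] / se[2L]
    p <- 2 * pt(-abs(stat), n - 2)
  } else {
    stat <- ((tss - rss) / (k - 1L)) / sigma2
    p <- pf(stat, k - 1L, n - k, lower.tail = FALSE)
  }
  list(beta = unname(beta[2L]), se = unname(se[2L]),
       statistic = unname(stat), p = unname(p))
}

# Step procedures coded directly from their published definitions, with
# explicit loops over the sorted order (no p.adjust, no cummax/cummin).
adjust_oracle <- function(p, method) {
  m <- length(p)
  switch(method,
    bonferroni = pmin(1, m * p),
    sidak = 1 - (1 - p)^m,
    holm = {
      o <- order(p)
      adj <- numeric(m)
      running <- 0
      for (i in seq_len(m)) {
        running <- max(running, (m - i + 1) * p[o[i]])
        adj[o[i]] <- min(1, running)
      }
      adj
    },
    bh = {
      o <- order(p, decreasing = TRUE)
      adj <- numeric(m)
      running <- Inf
      for (i in seq_len(m)) {
        rank <- m - i + 1
        running <- min(running, m / rank * p[o[i]])
        adj[o[i]] <- min(1, running)
      }
      adj
    },
    by = {
      cm <- sum(1 / seq_len(m))
      o <- order(p, decreasing = TRUE)
      adj <- numeric(m)
      running <- Inf
      for (i in seq_len(m)) {
        rank <- m - i + 1
        running <- min(running, cm * m / rank * p[o[i]])
        adj[o[i]] <- min(1, running)
      }
      adj
    },
    stop("unknown method")
  )
}

# bedGraph grammar check: one or more blocks, each a track declaration
# line followed by chrom<TAB>start<TAB>end<TAB>score rows with integer
# coordinates, start < end and a finite numeric score.
validate_bedgraph <- function(lines) {
  track_re <- '^track type=bedGraph name="[^"]+" description="[^"]*"$'
  data_re <- "^chr(([1-9]|1[0-9]|2[0-2])|X|Y|XY|MT)\t[0-9]+\t[0-9]+\t[-0-9.eE+]+$"
  if (length(lines) == 0 || !grepl(track_re, lines[1])) return(FALSE)
  for (ln in lines) {
    if (grepl(track_re, ln)) next
    if (!grepl(data_re, ln)) return(FALSE)
    f <- strsplit(ln, "\t")[[1]]
    if (as.numeric(f[2]) >= as.numeric(f[3])) return(FALSE)
    if (!is.finite(as.numeric(f[4]))) return(FALSE)
  }
  TRUE
}

# random allele-call vectors for one SNP (characters, "0" = missing)
random_calls <- function(n, maf = 0.3, miss = 0.05,
                         alleles = c("A", "G")) {
  cnt <- rbinom(n, 2, maf)
  a1 <- ifelse(cnt >= 1, alleles[1], alleles[2])
  a2 <- ifelse(cnt == 2, alleles[1], alleles[2])
  gone <- runif(n) < miss
  a1[gone] <- "0"
  a2[gone] <- "0"
  list(a1 = a1, a2 = a2)
}

# tiny hand-writable PED/MAP fixture
write_tiny_ped_map <- function(dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  map <- c("1\trs1\t0\t100", "1\trs2\t0\t200", "1\trs3\t0\t300")
  ped <- c("F1\tI1\t0\t0\t1\t-9\tA\tA\tA\tG\tG\tG",
           "F2\tI2\t0\t0\t2\t-9\tA\tG\tG\tG\t0\t0")
  map_f <- file.path(dir, "tiny.map")
  ped_f <- file.path(dir, "tiny.ped")
  writeLines(map, map_f)
  writeLines(ped, ped_f)
  list(ped = ped_f, map = map_f, dir = dir)
}
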