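# -- multiple-testing adjustment ---------------------------------------------

ADJUST_METHODS <- c("bonferroni", "holm", "sidak", "bh", "by")

#' Adjust p-values for multiple testing
#'
#' Five procedures over the family of SNPs tested for one probe:
#' Bonferroni (`min(1, m p)`), Holm's step-down, single-step Sidak
#' (`1 - (1 - p)^m`), Benjamini-Hochberg step-up FDR and
#' Benjamini-Yekutieli FDR (BH with the extra `sum(1/i)` factor). NA
#' inputs (degenerate SNPs) are excluded from the family size `m` and stay
#' NA in the output. Bonferroni, Holm, BH and BY are computed with
#' [stats::p.adjust()]; Sidak is computed directly.
#'
#' @param p numeric vector of raw p-values in (0, 1], NAs allowed.
#' @param method one of `"bonferroni"`, `"holm"`, `"sidak"`, `"bh"`,
#'   `"by"`.
#' @return List of class `adjusted_pvalues` with `method`, `values`
#'   (aligned with the input) and `m` (number of non-NA tests).
#' @export
adjust_pvalues <- function(p, method) {
  method <- match.arg(tolower(method), ADJUST_METHODS)
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]; got ",
         paste(utils::head(p[ok][p[ok] <= 0 | p[ok] > 1], 3), collapse = ", "))
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m > 0L) {
    pp <- p[ok]
    out[ok] <- switch(method,
      bonferroni = stats::p.adjust(pp, "bonferroni", n = m),
      holm       = stats::p.adjust(pp, "holm", n = m),
      bh         = stats::p.adjust(pp, "BH", n = m),
      by         = stats::p.adjust(pp, "BY", n = m),
      # stable form of 1 - (1 - p)^m; the naive power underflows to 0
      # below p ~ 1e-17/m, which would report an adjusted p SMALLER than
      # the raw one
      sidak      = pmax(pp, -expm1(m * log1p(-pp)))
    )
  }
  structure(list(method = method, values = out, m = m),
            class = "adjusted_pvalues")
}

#' All five adjustments side by side
#'
#' @param p numeric vector of raw p-values in (0, 1], NAs allowed.
#' @return data.frame with columns `raw`, `bonferroni`, `holm`, `sidak`,
#'   `bh`, `by`, row-aligned with the input.
#' @export
adjust_all <- function(p) {
  cols <- lapply(ADJUST_METHODS, function(m) adjust_pvalues(p, m)$values)
  names(cols) <- ADJUST_METHODS
  out <- data.frame(raw = p, cols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
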