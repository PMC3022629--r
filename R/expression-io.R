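# -- expression table --------------------------------------------------------

#' Read a probe-level expression table
#'
#' Tab-delimited, header `ProbeID<TAB>GeneSymbol<TAB><IID1><TAB><IID2>...`,
#' one row per transcript probe. Values are normalized intensities and are
#' used as-is (no transformation). Cells must parse as decimal or
#' scientific-notation numbers; anything else (including `NA`) is rejected
#' with the offending row and column named.
#'
#' @param path path to the TSV file.
#' @return An object of class `expression_table`: a list with `probe_id`,
#'   `gene_symbol` (character vectors) and `values` (numeric matrix, probes
#'   in rows, individual ids as column names).
#' @export
read_expression_table <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) < 2L)
    stop("expression table ", path, ": no data rows")
  tok <- strsplit(lines, "\t", fixed = TRUE)
  header <- tok[[1L]]
  if (length(header) < 3L)
    stop("expression table ", path,
         ": header needs ProbeID, GeneSymbol and at least one sample")
  iids <- header[-(1:2)]
  if (anyDuplicated(iids))
    stop("expression table ", path, ": duplicate individual id in header")
  rows <- tok[-1L]
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("expression table ", path, ": row ", bad[1L] + 1L, " has ",
         lengths(rows)[bad[1L]], " fields, expected ", length(header))
  tab <- do.call(rbind, rows)
  probe_id <- tab[, 1L]
  if (anyDuplicated(probe_id))
    stop("expression table ", path, ": duplicate probe id: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  raw <- tab[, -(1:2), drop = FALSE]
  values <- suppressWarnings(
    matrix(as.numeric(raw), nrow = nrow(raw), ncol = ncol(raw)))
  if (anyNA(values)) {
    w <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("expression table ", path, ": non-numeric cell '",
         raw[w[1L], w[2L]], "' at row ", w[1L] + 1L, " (probe ",
         probe_id[w[1L]], "), column ", iids[w[2L]])
  }
  rownames(values) <- probe_id
  colnames(values) <- iids
  structure(list(probe_id = probe_id, gene_symbol = tab[, 2L],
                 values = values),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table> ", length(x$probe_id), " probes x ",
      ncol(x$values), " individuals, ",
      length(unique(x$gene_symbol)), " gene(s)\n", sep = "")
  invisible(x)
}

#' Probes representing a gene
#'
#' A gene may be represented by several transcript probes on the array;
#' each is analyzed separately downstream. Matching is exact after case
#' folding (no alias or Entrez resolution).
#'
#' @param table an `expression_table`.
#' @param gene_symbol NCBI gene symbol, case-insensitive.
#' @return Character vector of probe ids, in table order.
#' @export
probes_for_gene <- function(table, gene_symbol) {
  hit <- toupper(table$gene_symbol) == toupper(gene_symbol)
  if (!any(hit))
    stop("gene '", gene_symbol, "' not found in expression table")
  table$probe_id[hit]
}

#' One probe's expression profile
#'
#' @param table an `expression_table`.
#' @param probe_id probe identifier present in the table.
#' @return An `expression_profile`: list with `probe_id`, `gene_symbol` and
#'   `values` (named numeric vector keyed by individual id).
#' @export
expression_profile <- function(table, probe_id) {
  i <- match(probe_id, table$probe_id)
  if (is.na(i)) stop("probe '", probe_id, "' not in expression table")
  structure(list(probe_id = probe_id, gene_symbol = table$gene_symbol[i],
                 values = table$values[i, ]),
            class = "expression_profile")
}

#' Align expression values with genotyped samples
#'
#' Intersects the individuals of a genotype dataset with those covered by
#' an expression profile. Retains exactly the individuals present in both,
#' preserving genotype sample order, and reports how many were dropped
#' from each side.
#'
#' @param ds a `genotype_dataset`.
#' @param profile an `expression_profile`.
#' @return List with `genotypes` (the subset `genotype_dataset`),
#'   `phenotype` (numeric expression vector aligned index-for-index with
#'   the genotype samples), `n_dropped_genotypes` and
#'   `n_dropped_expression`.
#' @export
merge_samples <- function(ds, profile) {
  geno_ids <- ds$samples$individual_id
  expr_ids <- names(profile$values)
  keep <- geno_ids %in% expr_ids
  if (!any(keep))
    stop("no overlap between genotyped individuals and expression ",
         "individuals for probe ", profile$probe_id)
  ds2 <- subset_samples(ds, which(keep))
  phen <- unname(profile$values[ds2$samples$individual_id])
  list(genotypes = ds2,
       phenotype = phen,
       n_dropped_genotypes = sum(!keep),
       n_dropped_expression = sum(!expr_ids %in% geno_ids))
}
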