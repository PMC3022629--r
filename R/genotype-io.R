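# -- genotype dataset container ----------------------------------------------

#' Construct a genotype dataset
#'
#' Bundles pedigree metadata, a SNP map and an allele-call matrix into a
#' single object. Users normally obtain one from [read_ped_map()] or
#' [simulate_genotypes()] rather than calling this directly.
#'
#' @param samples data.frame with columns `family_id`, `individual_id`,
#'   `paternal_id`, `maternal_id`, `sex` (1 = male, 2 = female, 0 = unknown)
#'   and `population`.
#' @param snps data.frame with columns `snp_id`, `chromosome` (one of
#'   1..22, X, Y, XY, MT), `position_bp` (1-based) and a list column
#'   `alleles` holding the allele symbols observed for the SNP.
#' @param allele1,allele2 character matrices, samples in rows and SNPs in
#'   columns, holding the two allele calls per genotype; `"0"` marks a
#'   missing allele. A call must be missing in both alleles or neither.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, snps, allele1, allele2) {
  stopifnot(is.data.frame(samples), is.data.frame(snps),
            is.matrix(allele1), is.matrix(allele2))
  n <- nrow(samples)
  m <- nrow(snps)
  if (!identical(dim(allele1), c(n, m)) || !identical(dim(allele2), c(n, m)))
    stop("call matrices must be n_samples x n_snps (", n, " x ", m, ")")
  if (anyDuplicated(samples$individual_id))
    stop("duplicate individual_id: ",
         paste(unique(samples$individual_id[duplicated(samples$individual_id)]),
               collapse = ", "))
  half <- xor(allele1 == "0", allele2 == "0")
  if (any(half))
    stop("half-missing genotype call(s) present (one allele '0'); ",
         "refusing to coerce")
  rownames(allele1) <- rownames(allele2) <- samples$individual_id
  colnames(allele1) <- colnames(allele2) <- snps$snp_id
  structure(list(samples = samples, snps = snps,
                 allele1 = allele1, allele2 = allele2),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$samples), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  cat("  chromosomes:", paste(unique(x$snps$chromosome), collapse = ", "), "\n")
  cat("  founders:", sum(is_founder(x$samples)), "\n")
  pops <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s=%d", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(nrow(x$samples), nrow(x$snps))

is_founder <- function(samples) {
  samples$paternal_id == "0" & samples$maternal_id == "0"
}

# internal row/column subsetting; keeps metadata and calls in lockstep
subset_samples <- function(ds, idx) {
  genotype_dataset(ds$samples[idx, , drop = FALSE],
                   ds$snps,
                   ds$allele1[idx, , drop = FALSE],
                   ds$allele2[idx, , drop = FALSE])
}

subset_snps <- function(ds, idx) {
  genotype_dataset(ds$samples,
                   ds$snps[idx, , drop = FALSE],
                   ds$allele1[, idx, drop = FALSE],
                   ds$allele2[, idx, drop = FALSE])
}

VALID_CHROMS <- c(as.character(1:22), "X", "Y", "XY", "MT")

# -- readers -----------------------------------------------------------------

#' Read PLINK-text genotype files (PED + MAP)
#'
#' Parses a whitespace-delimited PED/MAP pair into a [genotype_dataset()].
#' The MAP file must have four columns (chromosome, SNP id, genetic distance,
#' base-pair position); the genetic-distance column is parsed and discarded.
#' The PED file must have six metadata columns (FID IID PAT MAT SEX PHENO;
#' the phenotype column is ignored on read) followed by two allele columns
#' per MAP SNP, in MAP order.
#'
#' MAP rows with a negative base-pair position (PLINK's exclusion
#' convention) are dropped with a warning, along with their PED columns.
#' Sex chromosomes are read as diploid autosomes and flagged with a warning.
#'
#' @param ped_file,map_file paths to the PED and MAP files.
#' @param sample_info optional path to a two-column tab-delimited sidecar
#'   mapping individual id to population label (optional header
#'   `IID<TAB>POP`), or a named character vector of populations keyed by
#'   individual id (family id matched as a fallback).
#' @param population default population label for samples not covered by
#'   `sample_info`.
#' @return A `genotype_dataset`.
#' @export
read_ped_map <- function(ped_file, map_file, sample_info = NULL,
                         population = "UNKNOWN") {
  map_lines <- read_nonempty_lines(map_file)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad))
    stop("MAP file ", map_file, ": line ", bad[1L], " has ",
         lengths(map_tok)[bad[1L]], " fields, expected 4")
  map <- data.frame(
    chromosome  = vapply(map_tok, `[`, "", 1L),
    snp_id      = vapply(map_tok, `[`, "", 2L),
    position_bp = as.numeric(vapply(map_tok, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(map$position_bp))
    stop("MAP file ", map_file, ": non-numeric base-pair position")
  unknown_chr <- setdiff(unique(map$chromosome), VALID_CHROMS)
  if (length(unknown_chr))
    stop("MAP file ", map_file, ": unknown chromosome label(s): ",
         paste(unknown_chr, collapse = ", "))
  keep_snp <- map$position_bp >= 0
  if (!all(keep_snp))
    warning(sum(!keep_snp), " MAP row(s) with negative position dropped ",
            "(PLINK exclusion convention)")
  if (any(map$chromosome %in% c("X", "Y")))
    warning("sex chromosome SNPs present; treated as diploid autosomes")

  m_all <- nrow(map)
  ped_lines <- read_nonempty_lines(ped_file)
  n <- length(ped_lines)
  if (n == 0L) stop("PED file ", ped_file, " is empty")
  expected <- 6L + 2L * m_all
  meta <- vector("list", n)
  a1 <- matrix("", n, m_all)
  a2 <- matrix("", n, m_all)
  odd <- seq(7L, expected - 1L, by = 2L)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1L]]
    if (length(tok) != expected)
      stop("PED file ", ped_file, ": line ", i, " has ", length(tok),
           " fields, expected ", expected, " for a ", m_all, "-SNP MAP")
    meta[[i]] <- tok[1:6]
    a1[i, ] <- tok[odd]
    a2[i, ] <- tok[odd + 1L]
  }
  meta <- do.call(rbind, meta)
  samples <- data.frame(
    family_id     = meta[, 1L],
    individual_id = meta[, 2L],
    paternal_id   = meta[, 3L],
    maternal_id   = meta[, 4L],
    sex           = as.integer(meta[, 5L]),
    stringsAsFactors = FALSE
  )
  samples$population <- resolve_population(samples, sample_info, population)

  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1L, ]
    stop("PED file ", ped_file, ": half-missing genotype at line ", w[1L],
         ", SNP ", map$snp_id[w[2L]], " ('", a1[w[1L], w[2L]], " ",
         a2[w[1L], w[2L]], "')")
  }

  map <- map[keep_snp, , drop = FALSE]
  a1 <- a1[, keep_snp, drop = FALSE]
  a2 <- a2[, keep_snp, drop = FALSE]
  map$alleles <- lapply(seq_len(nrow(map)), function(j) {
    al <- setdiff(sort(unique(c(a1[, j], a2[, j]))), "0")
    if (length(al) > 2L)
      stop("SNP ", map$snp_id[j], " has ", length(al),
           " distinct alleles (", paste(al, collapse = ","),
           "); malformed file")
    al
  })
  rownames(map) <- NULL
  genotype_dataset(samples, map, a1, a2)
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

#' Read a sample-information sidecar file
#'
#' Two-column tab-delimited file mapping individual id to population label,
#' with an optional `IID<TAB>POP` header.
#'
#' @param path file path.
#' @return Named character vector: populations keyed by individual id.
#' @export
read_sample_info <- function(path) {
  lines <- read_nonempty_lines(path)
  tok <- strsplit(trimws(lines), "\t")
  if (any(lengths(tok) != 2L))
    stop("sample-info file ", path, ": expected 2 tab-delimited columns")
  tab <- do.call(rbind, tok)
  if (toupper(tab[1L, 1L]) == "IID" && toupper(tab[1L, 2L]) == "POP")
    tab <- tab[-1L, , drop = FALSE]
  stats::setNames(tab[, 2L], tab[, 1L])
}

resolve_population <- function(samples, sample_info, default) {
  if (is.null(sample_info)) return(rep(default, nrow(samples)))
  if (is.character(sample_info) && length(sample_info) == 1L &&
      is.null(names(sample_info)))
    sample_info <- read_sample_info(sample_info)
  pop <- unname(sample_info[samples$individual_id])
  miss <- is.na(pop)
  pop[miss] <- unname(sample_info[samples$family_id[miss]])
  pop[is.na(pop)] <- default
  pop
}

# -- subsetting operations ---------------------------------------------------

#' Extract SNPs in a genomic region
#'
#' Retains SNPs on `chromosome` with `start_bp <= position_bp <= end_bp`
#' (both ends inclusive), sorted by position. The sample list is unchanged.
#'
#' @param ds a `genotype_dataset`.
#' @param chromosome chromosome label (e.g. `"4"`).
#' @param start_bp,end_bp region bounds in base pairs, 1-based inclusive.
#' @return A `genotype_dataset` restricted to the region.
#' @export
extract_region <- function(ds, chromosome, start_bp, end_bp) {
  chromosome <- as.character(chromosome)
  if (start_bp > end_bp)
    stop("start_bp (", start_bp, ") exceeds end_bp (", end_bp, ")")
  hit <- ds$snps$chromosome == chromosome &
    ds$snps$position_bp >= start_bp & ds$snps$position_bp <= end_bp
  if (!any(hit))
    stop("no SNPs on chromosome ", chromosome, " in [", start_bp, ", ",
         end_bp, "]; widen the window or check the chromosome label")
  idx <- which(hit)[order(ds$snps$position_bp[hit])]
  subset_snps(ds, idx)
}

#' Extract SNPs by identifier
#'
#' Retains the listed SNPs in map order. Unknown ids trigger a warning
#' naming every miss; if none of the ids is present, an error lists them
#' all.
#'
#' @param ds a `genotype_dataset`.
#' @param snp_ids character vector of SNP ids (e.g. rs numbers).
#' @return A `genotype_dataset` restricted to the found SNPs.
#' @export
extract_snps <- function(ds, snp_ids) {
  if (length(snp_ids) == 0L) stop("snp_ids must be non-empty")
  missing_ids <- setdiff(snp_ids, ds$snps$snp_id)
  if (length(missing_ids) == length(unique(snp_ids)))
    stop("none of the requested SNPs found: ",
         paste(missing_ids, collapse = ", "))
  if (length(missing_ids))
    warning("SNP id(s) not in MAP, skipped: ",
            paste(missing_ids, collapse = ", "))
  subset_snps(ds, which(ds$snps$snp_id %in% snp_ids))
}

#' Keep founders only
#'
#' Retains samples whose paternal and maternal ids are both the null code
#' `"0"` — in HapMap trios, the parents; children are removed. Idempotent.
#'
#' @param ds a `genotype_dataset`.
#' @return A `genotype_dataset` of founders.
#' @export
filter_founders <- function(ds) {
  subset_samples(ds, which(is_founder(ds$samples)))
}

#' Select a population (or pool all)
#'
#' `"pooled"` returns the dataset unchanged; any other value retains
#' samples whose population label matches.
#'
#' @param ds a `genotype_dataset`.
#' @param selection population label (e.g. `"CEU"`) or `"pooled"`.
#' @return A `genotype_dataset`.
#' @export
filter_population <- function(ds, selection) {
  if (identical(selection, "pooled")) return(ds)
  avail <- unique(ds$samples$population)
  if (!selection %in% avail)
    stop("unknown population '", selection, "'; available: ",
         paste(sort(avail), collapse = ", "), ", pooled")
  subset_samples(ds, which(ds$samples$population == selection))
}
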