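# -- UCSC custom tracks ------------------------------------------------------

#' Build score tracks from association results
#'
#' One track per (probe x adjustment) combination, where "raw" means the
#' unadjusted p-values. Scores are `-log10(p)` capped at `cap`; SNPs with
#' NA p (degenerate designs) are omitted from the track rather than scored
#' 0, so they cannot masquerade as null signals on the browser. Entries
#' use 0-based half-open single-base intervals per the UCSC convention
#' (start = position - 1, end = position).
#'
#' @param results an `association_result` data.frame.
#' @param adjusted data.frame from [adjust_all()] aligned with `results`
#'   (its `raw` column must equal `results$p`).
#' @param probe_id probe identifier, embedded in the track names.
#' @param adjustments which adjusted columns to emit alongside the raw
#'   track; subset of `c("bonferroni","holm","sidak","bh","by")`.
#' @param cap ceiling for `-log10(p)` scores.
#' @return List of class `track_set`; each element has `name`,
#'   `description` and `entries` (data.frame chrom/start/end/score, sorted
#'   by position).
#' @export
make_tracks <- function(results, adjusted, probe_id,
                        adjustments = ADJUST_METHODS, cap = 50) {
  if (length(adjustments))
    adjustments <- match.arg(adjustments, ADJUST_METHODS, several.ok = TRUE)
  one <- function(p, label) {
    keep <- !is.na(p)
    ord <- order(results$position_bp[keep])
    entries <- data.frame(
      chrom = paste0("chr", results$chromosome[keep]),
      start = as.integer(results$position_bp[keep] - 1L),
      end = as.integer(results$position_bp[keep]),
      score = pmin(-log10(p[keep]), cap),
      stringsAsFactors = FALSE
    )[ord, , drop = FALSE]
    rownames(entries) <- NULL
    list(name = paste0(probe_id, "_", label),
         description = paste0("-log10(", label, " p) for probe ", probe_id),
         entries = entries)
  }
  tracks <- c(list(one(results$p, "raw")),
              lapply(adjustments, function(m) one(adjusted[[m]], m)))
  structure(tracks, class = "track_set")
}

#' Write a track set as a UCSC bedGraph custom track file
#'
#' Emits one `track type=bedGraph name=... description=...` line per
#' track, followed by `chrom<TAB>start<TAB>end<TAB>score` rows.
#'
#' @param track_set a `track_set` from [make_tracks()], or a list of them
#'   (concatenated into one file as parallel tracks).
#' @param path output path.
#' @param append append to an existing file instead of overwriting.
#' @return Invisibly, the path.
#' @export
write_custom_track <- function(track_set, path, append = FALSE) {
  if (inherits(track_set, "track_set")) track_set <- list(track_set)
  con <- tryCatch(file(path, if (append) "a" else "w"),
                  error = function(e)
                    stop("cannot open track file ", path, ": ",
                         conditionMessage(e)))
  on.exit(close(con))
  for (ts in track_set) {
    for (tr in ts) {
      writeLines(sprintf('track type=bedGraph name="%s" description="%s"',
                         tr$name, tr$description), con)
      if (nrow(tr$entries))
        writeLines(sprintf("%s\t%d\t%d\t%s", tr$entries$chrom,
                           tr$entries$start, tr$entries$end,
                           format_num(tr$entries$score)), con)
    }
  }
  invisible(path)
}

# -- result tables -----------------------------------------------------------

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite)
    stop("output file exists: ", path, " (use overwrite = TRUE)")
  path
}

#' Write the per-SNP association table
#'
#' Tab-delimited with header `CHR SNP BP A1 N BETA SE STAT P`; A1 is the
#' minor (coded) allele, P is in scientific notation, other numerics carry
#' 6 significant digits, missing values print as `NA`.
#'
#' @param results an `association_result`.
#' @param path output path.
#' @param overwrite allow clobbering an existing file.
#' @return Invisibly, the path.
#' @export
write_assoc_table <- function(results, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  rows <- paste(results$chromosome, results$snp_id,
                as.integer(results$position_bp),
                ifelse(is.na(results$minor_allele), "NA",
                       results$minor_allele),
                results$n_used,
                format_num(results$beta), format_num(results$se),
                format_num(results$statistic),
                format_num(results$p, scientific = TRUE),
                sep = "\t")
  writeLines(c("CHR\tSNP\tBP\tA1\tN\tBETA\tSE\tSTAT\tP", rows), path)
  invisible(path)
}

#' Write the adjusted p-value table
#'
#' Header `SNP RAW BONF HOLM SIDAK BH BY`; all p-values in scientific
#' notation.
#'
#' @param results an `association_result`.
#' @param adjusted data.frame from [adjust_all()] aligned with `results`.
#' @inheritParams write_assoc_table
#' @return Invisibly, the path.
#' @export
write_adjusted_table <- function(results, adjusted, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  fmt <- function(x) format_num(x, scientific = TRUE)
  rows <- paste(results$snp_id, fmt(adjusted$raw), fmt(adjusted$bonferroni),
                fmt(adjusted$holm), fmt(adjusted$sidak), fmt(adjusted$bh),
                fmt(adjusted$by), sep = "\t")
  writeLines(c("SNP\tRAW\tBONF\tHOLM\tSIDAK\tBH\tBY", rows), path)
  invisible(path)
}

#' Write the per-genotype-class means table
#'
#' Long format, header `SNP CLASS N MEAN SD`, three rows per SNP
#' (homMajor, het, homMinor).
#'
#' @inheritParams write_assoc_table
#' @return Invisibly, the path.
#' @export
write_means_table <- function(results, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  cls <- c("homMajor", "het", "homMinor")
  n <- as.vector(rbind(results$n_hom_major, results$n_het,
                       results$n_hom_minor))
  mu <- as.vector(rbind(results$mean_hom_major, results$mean_het,
                        results$mean_hom_minor))
  sd_ <- as.vector(rbind(results$sd_hom_major, results$sd_het,
                         results$sd_hom_minor))
  rows <- paste(rep(results$snp_id, each = 3L), rep(cls, nrow(results)),
                n, format_num(mu), format_num(sd_), sep = "\t")
  writeLines(c("SNP\tCLASS\tN\tMEAN\tSD", rows), path)
  invisible(path)
}

#' Write extracted genotypes with expression as PED phenotype
#'
#' The merged expression value is placed in PED column 6 (the phenotype
#' column) at full precision, so re-reading the file recovers it exactly.
#'
#' @param ds the merged `genotype_dataset`.
#' @param phenotype numeric expression vector aligned with `ds` samples.
#' @param path output PED path; the matching MAP is written alongside
#'   with extension `.map`.
#' @param overwrite allow clobbering existing files.
#' @return Invisibly, the PED path.
#' @export
write_ped_with_phenotype <- function(ds, phenotype, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  check_overwrite(map_path, overwrite)
  write_ped_map(ds, path, map_path, phenotype = phenotype)
  invisible(path)
}

# -- run log -----------------------------------------------------------------

#' Create a run logger
#'
#' Collects messages in chronological order; [write_log()] flushes them to
#' a file. Used by the pipeline to record the configuration echo, sample
#' and SNP counts after each filter, warnings and per-probe summaries.
#' Entries carry no wall-clock timestamps so identical runs produce
#' byte-identical logs.
#'
#' @return An environment with `add(...)` (sprintf-style) and `entries()`.
#' @export
run_logger <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env$add <- function(fmt, ...) {
    msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
    env$lines <- c(env$lines, msg)
    invisible(NULL)
  }
  env$entries <- function() env$lines
  env
}

#' Write the run log
#'
#' @param logger a [run_logger()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_log <- function(logger, path) {
  writeLines(logger$entries(), path)
  invisible(path)
}
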