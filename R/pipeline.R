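# -- run configuration -------------------------------------------------------

#' Configure an eQTL scan
#'
#' Exactly one of a base-pair region (`from_bp`/`to_bp` on `chromosome`)
#' or an explicit SNP-id list must be given. The gene and the SNPs may sit
#' on different chromosomes: nothing in the regression couples them, so
#' trans scans run exactly like cis scans.
#'
#' @param gene NCBI gene symbol to look up in the expression table.
#' @param ped,map,expr input file paths (PLINK-text PED/MAP and the
#'   expression TSV).
#' @param out_dir output directory.
#' @param chromosome chromosome of the scan region (required with
#'   `from_bp`/`to_bp`).
#' @param from_bp,to_bp inclusive region bounds in base pairs.
#' @param snps character vector of SNP ids (alternative to a region).
#' @param sample_info optional sample-info sidecar path.
#' @param population population label or `"pooled"` (default).
#' @param founders_only drop pedigree children before analysis (default
#'   TRUE, matching analyses of the 210 unrelated HapMap individuals).
#' @param model genetic model (default `"additive"`, the recommended
#'   first-screen choice).
#' @param adjustments `"all"`, `"none"`, or a subset of
#'   `c("bonferroni","holm","sidak","bh","by")`.
#' @param cap ceiling for `-log10(p)` track scores.
#' @param overwrite allow clobbering existing output files.
#' @return List of class `run_config`.
#' @export
run_config <- function(gene, ped, map, expr, out_dir,
                       chromosome = NULL, from_bp = NULL, to_bp = NULL,
                       snps = NULL, sample_info = NULL,
                       population = "pooled", founders_only = TRUE,
                       model = "additive", adjustments = "all",
                       cap = 50, overwrite = FALSE) {
  have_region <- !is.null(from_bp) || !is.null(to_bp)
  have_snps <- !is.null(snps) && length(snps) > 0
  if (have_region == have_snps)
    stop("exactly one of a bp region (chromosome + from_bp/to_bp) or a ",
         "SNP-id list must be given")
  if (have_region && (is.null(chromosome) || is.null(from_bp) ||
                      is.null(to_bp)))
    stop("a region needs chromosome, from_bp and to_bp")
  model <- match.arg(model, GENETIC_MODELS)
  adjustments <- if (identical(adjustments, "all")) ADJUST_METHODS
    else if (identical(adjustments, "none")) character(0)
    else match.arg(adjustments, ADJUST_METHODS, several.ok = TRUE)
  structure(list(gene = gene, ped = ped, map = map, expr = expr,
                 out_dir = out_dir, chromosome = chromosome,
                 from_bp = from_bp, to_bp = to_bp, snps = snps,
                 sample_info = sample_info, population = population,
                 founders_only = isTRUE(founders_only), model = model,
                 adjustments = adjustments, cap = cap,
                 overwrite = isTRUE(overwrite)),
            class = "run_config")
}

# -- pipeline ----------------------------------------------------------------

#' Run the full eQTL scan
#'
#' For each transcript probe of the configured gene: extract the region or
#' SNP-list genotypes, apply population and founder filters, merge the
#' expression phenotype, fit per-SNP regressions under the genetic model,
#' adjust p-values, and write the per-probe tables plus a shared custom
#' track file and run log into `out_dir`:
#'
#' * `extracted_snps_with_expression_values<PROBE>.ped` / `.map`
#' * `pvalues<PROBE>.linear.assoc.txt`
#' * `pvalues<PROBE>.linear.assoc.adjusted.txt`
#' * `<PROBE>.qassoc.means.txt`
#' * `customtrack.txt` (all probes' parallel tracks)
#' * `run.log`
#'
#' A failure at any stage aborts with the stage named; files already
#' written for this run are removed so no partial output bundle remains.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with one element per probe (each holding
#'   `results`, `adjusted`, `merged` counts) plus `tracks`, `files` and
#'   `log_lines`.
#' @export
run_eqtl_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- run_logger()
  created <- character(0)
  stage <- "setup"
  note <- function(path) { created <<- c(created, path); path }
  on_fail <- function(e) {
    unlink(created)
    stop("eQTL scan failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!dir.exists(config$out_dir) &&
        !dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory ", config$out_dir)
    log$add("run configuration:")
    for (f in c("gene", "chromosome", "from_bp", "to_bp", "population",
                "model", "cap")) {
      log$add("  %s = %s", f,
              if (is.null(config[[f]])) "<unset>" else
                paste(config[[f]], collapse = ","))
    }
    log$add("  snps = %s",
            if (is.null(config$snps)) "<unset>" else
              paste(config$snps, collapse = ","))
    log$add("  adjustments = %s",
            if (length(config$adjustments))
              paste(config$adjustments, collapse = ",") else "none")
    log$add("  founders_only = %s", config$founders_only)

    stage <- "read expression"
    expr <- read_expression_table(config$expr)
    probes <- probes_for_gene(expr, config$gene)
    log$add("gene %s: %d probe(s): %s", config$gene, length(probes),
            paste(probes, collapse = ", "))

    stage <- "read genotypes"
    ds <- withCallingHandlers(
      read_ped_map(config$ped, config$map, sample_info = config$sample_info),
      warning = function(w) {
        log$add("warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log$add("genotypes: %d samples x %d SNPs", nrow(ds$samples),
            nrow(ds$snps))

    stage <- "extract SNPs"
    ds <- if (!is.null(config$snps)) {
      withCallingHandlers(extract_snps(ds, config$snps),
        warning = function(w) {
          log$add("warning: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    } else {
      extract_region(ds, config$chromosome, config$from_bp, config$to_bp)
    }
    log$add("after region/SNP extraction: %d SNPs", nrow(ds$snps))

    stage <- "filter samples"
    ds <- filter_population(ds, config$population)
    log$add("after population filter (%s): %d samples", config$population,
            nrow(ds$samples))
    if (config$founders_only) {
      ds <- filter_founders(ds)
      log$add("after founder filter: %d samples", nrow(ds$samples))
    }

    track_path <- file.path(config$out_dir, "customtrack.txt")
    check_overwrite(track_path, config$overwrite)
    if (file.exists(track_path)) { file.remove(track_path); }
    note(track_path)

    per_probe <- list()
    all_tracks <- list()
    files <- c(customtrack = track_path)
    for (probe in probes) {
      stage <- paste0("probe ", probe, ": merge phenotype")
      profile <- expression_profile(expr, probe)
      merged <- merge_samples(ds, profile)
      log$add("probe %s: merged n=%d (dropped %d genotyped, %d expression)",
              probe, length(merged$phenotype), merged$n_dropped_genotypes,
              merged$n_dropped_expression)

      stage <- paste0("probe ", probe, ": association")
      results <- run_association(merged$genotypes, merged$phenotype,
                                 model = config$model)
      degen <- sum(is.na(results$p))
      if (degen)
        log$add("probe %s: %d degenerate SNP(s) reported with NA p",
                probe, degen)
      log$add("probe %s: min p = %s at %s", probe,
              format_num(min(results$p, na.rm = TRUE), scientific = TRUE),
              results$snp_id[which.min(results$p)])

      stage <- paste0("probe ", probe, ": adjustment")
      adjusted <- adjust_all(results$p)

      stage <- paste0("probe ", probe, ": write outputs")
      p_assoc <- file.path(config$out_dir,
                           sprintf("pvalues%s.linear.assoc.txt", probe))
      p_adj <- file.path(config$out_dir,
                         sprintf("pvalues%s.linear.assoc.adjusted.txt",
                                 probe))
      p_means <- file.path(config$out_dir,
                           sprintf("%s.qassoc.means.txt", probe))
      p_ped <- file.path(config$out_dir,
                         sprintf("extracted_snps_with_expression_values%s.ped",
                                 probe))
      write_assoc_table(results, note(p_assoc),
                        overwrite = config$overwrite)
      write_adjusted_table(results, adjusted, note(p_adj),
                           overwrite = config$overwrite)
      write_means_table(results, note(p_means),
                        overwrite = config$overwrite)
      write_ped_with_phenotype(merged$genotypes, merged$phenotype,
                               note(p_ped), overwrite = config$overwrite)
      note(sub("\\.ped$", ".map", p_ped))
      tracks <- make_tracks(results, adjusted, probe,
                            adjustments = config$adjustments,
                            cap = config$cap)
      write_custom_track(tracks, track_path, append = TRUE)
      all_tracks[[probe]] <- tracks
      files[paste0(probe, c("_assoc", "_adjusted", "_means", "_ped"))] <-
        c(p_assoc, p_adj, p_means, p_ped)
      per_probe[[probe]] <- list(results = results, adjusted = adjusted,
                                 n = length(merged$phenotype))
    }

    stage <- "write log"
    log_path <- file.path(config$out_dir, "run.log")
    check_overwrite(log_path, config$overwrite)
    write_log(log, note(log_path))
    files["log"] <- log_path
    invisible(list(probes = per_probe, tracks = all_tracks, files = files,
                   log_lines = log$entries()))
  }, error = on_fail)
}
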