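stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline run configuration
#'
#' A run config is a plain list (readable from YAML via
#' [read_run_config()]) with a `seed`, either a `simulation` block
#' (arguments of [simulation_config()]) or paths to an existing `eqtl`
#' table + sample sheet, and optional `selection` (arguments of
#' [selection_config()]), `min_gc`, `scoring` (arguments of
#' [scoring_config()]), `pwm_file` + `match` cutoffs, and `annotations`
#' path. Referenced files must exist at validation time.
#'
#' @param config list.
#' @return the config, invisibly; errors describe the first problem found.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed)) stop("run config needs a `seed`")
  if (is.null(config$simulation) && is.null(config$eqtl))
    stop("run config needs a `simulation` block or an `eqtl` table path")
  for (f in c("eqtl", "pwm_file", "annotations", "sample_sheet"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("run config references missing file `", f, "`: ", config[[f]])
  invisible(config)
}

#' Read a pipeline run configuration from YAML
#' @param path YAML file.
#' @return config list, validated.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the SNPs-seq pipeline end to end
#'
#' Orchestrates select -> design -> simulate -> count -> score (and
#' optionally match -> prioritize) and writes all stage outputs plus a run
#' manifest into `outdir`. Reruns with the same config and seed reproduce
#' byte-identical TSVs; result files carry no timestamps. On a stage
#' failure the partial outputs written so far are renamed with a
#' `.partial` suffix and the failing stage is named in the error.
#'
#' @param config run config list, see [validate_run_config()].
#' @param outdir output directory.
#' @return list with the principal in-memory results (`candidates`,
#'   `library`, `sim`, `counts`, `bab`, optional `motif`, `funnel`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  written <- character(0)
  out <- function(name) file.path(outdir, name)
  emit <- function(df, name) {
    write_tsv(df, out(name)); written <<- c(written, out(name))
  }
  current_stage <- "validate"
  res <- list()
  tryCatch({
    current_stage <- "simulate_snps"
    if (!is.null(config$simulation)) {
      simcfg <- do.call(simulation_config,
                        c(config$simulation, list(seed = config$seed)))
      snps <- simulate_snps(simcfg)
      effects <- attr(snps, "true_effects")
      stage_log(current_stage, "%d synthetic SNPs", nrow(snps))
    } else {
      snps <- load_eqtl_table(config$eqtl)
      effects <- NULL
      stage_log("load_eqtl", "%d records from %s", nrow(snps), config$eqtl)
    }

    current_stage <- "select"
    selcfg <- do.call(selection_config,
                      if (is.null(config$selection)) list()
                      else config$selection)
    candidates <- select_candidates(snps, selcfg)
    stage_log(current_stage, "%d of %d SNPs selected",
              nrow(candidates), nrow(snps))
    manifest$stages$select <- list(n_in = nrow(snps),
                                   n_selected = nrow(candidates))
    emit(candidates, "candidates.tsv")
    emit(attr(candidates, "region_summary"), "region_summary.tsv")

    current_stage <- "design"
    min_gc <- if (is.null(config$min_gc)) 0.33 else config$min_gc
    gc <- filter_low_gc(candidates, min_gc)
    lib <- design_library(gc$kept)
    stage_log(current_stage, "%d SNPs kept (min_gc %.2f), %d templates",
              nrow(gc$kept), min_gc, nrow(lib))
    manifest$stages$design <- list(n_kept = nrow(gc$kept),
                                   n_excluded_gc = nrow(gc$excluded),
                                   n_templates = nrow(lib),
                                   n_unique = attr(lib, "n_unique"))
    write_library(lib, out("library.fasta"))
    written <- c(written, out("library.fasta"))
    emit(as.data.frame(lib), "library_manifest.tsv")

    current_stage <- "simulate_reads"
    if (!is.null(config$simulation)) {
      sim <- simulate_reads(simcfg, lib, effects = effects,
                            outdir = file.path(outdir, "fastq"))
      samples <- sim$samples
      emit(samples, "samples.tsv")
      res$sim <- sim
      stage_log(current_stage, "%d samples at depth %d",
                nrow(samples), simcfg$depth)
    } else {
      samples <- read.delim(config$sample_sheet, stringsAsFactors = FALSE)
    }

    current_stage <- "count"
    index <- build_index(lib)
    counts <- count_reads(samples, index)
    stage_log(current_stage, "mappable rates: %s",
              paste(sprintf("%s %.2f", counts$qc$sample_id,
                            counts$qc$mappable_rate), collapse = ", "))
    manifest$stages$count <- list(
      mappable_rate = as.list(setNames(counts$qc$mappable_rate,
                                       counts$qc$sample_id)))
    write_counts(counts, out("counts.tsv"))
    written <- c(written, out("counts.tsv"))
    emit(counts$qc, "qc.tsv")

    current_stage <- "score"
    scocfg <- do.call(scoring_config,
                      if (is.null(config$scoring)) list()
                      else config$scoring)
    bab <- score_bab(counts, lib, scocfg)
    ov <- attr(bab, "overlap_counts")
    stage_log(current_stage, "%d SNPs scored", nrow(bab))
    manifest$stages$score <- list(n_snps = nrow(bab),
                                  overlap = as.list(ov))
    emit(as.data.frame(bab), "bab.tsv")
    if (!is.null(ov))
      emit(data.frame(class = names(ov), n = as.integer(ov),
                      percent = round(100 * as.integer(ov) / nrow(bab), 1)),
           "overlap_summary.tsv")

    current_stage <- "match"
    if (!is.null(config$pwm_file)) {
      pwms <- load_transfac(config$pwm_file)
      cc <- if (is.null(config$match$core_cutoff)) 0.75
            else config$match$core_cutoff
      mc <- if (is.null(config$match$matrix_cutoff)) 0.80
            else config$match$matrix_cutoff
      sig_ids <- bab$snp_id[rowSums(
        as.data.frame(bab)[, grep("^significant_", names(bab)),
                           drop = FALSE]) > 0]
      calls <- lapply(sig_ids, function(id) {
        pair <- lib[lib$snp_id == id, ]
        r <- pair$sequence[pair$allele_role == "reference"]
        a <- pair$sequence[pair$allele_role == "variant"]
        cbind(snp_id = id, compare_alleles(r, a, pwms, cc, mc))
      })
      motif <- if (length(calls)) do.call(rbind, calls)
               else data.frame(snp_id = character(), pwm = character(),
                               status = character())
      manifest$stages$match <- list(
        n_scanned = length(sig_ids),
        n_changed = length(unique(motif$snp_id[motif$status != "no_change"])))
      emit(motif, "motif_calls.tsv")
      res$motif <- motif
      stage_log(current_stage, "%d significant SNPs scanned against %d PWMs",
                length(sig_ids), length(pwms))
    }

    current_stage <- "prioritize"
    if (!is.null(config$annotations)) {
      ann <- load_annotations(config$annotations)
      if (!is.null(res$motif)) ann <- join_motif_calls(ann, res$motif)
      sig_ids <- if (!is.null(bab$overlap_class))
        bab$snp_id[bab$overlap_class == "shared"]
      else bab$snp_id[bab[[grep("^significant_", names(bab), value = TRUE)[1]]]]
      funnel <- apply_funnel(sig_ids, ann)
      manifest$stages$prioritize <- as.list(
        setNames(funnel$summary$n, funnel$summary$stage))
      emit(funnel$summary, "funnel_summary.tsv")
      res$funnel <- funnel
      stage_log(current_stage, "funnel: %s",
                paste(funnel$summary$n, collapse = " -> "))
    }

    current_stage <- "manifest"
    cfg_path <- out("config.yaml")
    yaml::write_yaml(config, cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    yaml::write_yaml(manifest, out("manifest.yaml"))
    res$candidates <- candidates
    res$library <- lib
    res$counts <- counts
    res$bab <- bab
    res$manifest <- manifest
    res
  }, error = function(e) {
    for (f in written)
      if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    stop(sprintf("pipeline failed at stage '%s': %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
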