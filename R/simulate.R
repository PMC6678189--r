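ADAPTER_5P <- "CGACGCTCTTCC"
ADAPTER_3P <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACGTA"

#' Configuration of the synthetic SNPs-seq experiment
#'
#' Defines the generative model used for validation: each SNP contributes a
#' reference and a variant 21-nt template. Per-template input abundances
#' are `2^N(0, input_log2_sd^2)` around balance; with the default sd 0.5
#' the input library is near-balanced (~95% of templates within 2-fold of
#' the mean, a typical synthesis-pool imbalance that also reproduces input
#' replicate correlations R^2 around 0.98 at the default depth). In a test
#' sample the variant template's weight is
#' multiplied by `2^beta`, where beta is the SNP's true log2 binding fold
#' change, so the BAB statistic is an unbiased estimator of beta. Reads are
#' adapter-prefix + template (random orientation) + adapter-suffix,
#' truncated to `read_length`; counts are multinomial at the sample depth;
#' a fraction of reads (nuclear-DNA background) is random sequence and
#' unmappable, and substitution errors occur per base at `error_rate`.
#'
#' When `true_effects` is NULL, each SNP has a nonzero effect with
#' probability 0.45, drawn uniformly on \[-5, 4\] (the realistic span of
#' observed allelic-binding effects); the remainder are exactly 0.
#'
#' @param n_snps number of biallelic SNP sites.
#' @param read_length single-end read length (>= 21; default 50).
#' @param depth reads per sample; default gives input mappable counts per
#'   template averaging about 1000.
#' @param true_effects optional numeric vector (length `n_snps`) of true
#'   log2 effects beta.
#' @param input_log2_sd sd of per-template log2 input abundance noise.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param replicates technical replicates per condition (default 2).
#' @param conditions test treatment labels (default DHT and ETH; the same
#'   beta drives both).
#' @param test_background,input_background fraction of unmappable
#'   background reads per test / input sample (defaults emulate ~76% and
#'   ~93% mappable rates).
#' @param adapter_5p,adapter_3p adapter sequence flanking the template in
#'   a read.
#' @param seed integer seed driving all randomness.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps, read_length = 50L, depth = NULL,
                              true_effects = NULL, input_log2_sd = 0.5,
                              error_rate = 0, replicates = 2L,
                              conditions = c("DHT", "ETH"),
                              test_background = 0.24,
                              input_background = 0.07,
                              adapter_5p = ADAPTER_5P,
                              adapter_3p = ADAPTER_3P,
                              seed = 1L) {
  stopifnot(n_snps >= 1, read_length >= TEMPLATE_LEN,
            error_rate >= 0, error_rate < 1, replicates >= 1,
            test_background >= 0, test_background < 1,
            input_background >= 0, input_background < 1,
            input_log2_sd >= 0)
  if (is.null(depth)) depth <- ceiling(1000 * 2 * n_snps / 0.93)
  stopifnot(depth > 0)
  if (!is.null(true_effects) && length(true_effects) != n_snps)
    stop("true_effects must have length n_snps")
  if (nchar(adapter_5p) > read_length - TEMPLATE_LEN)
    stop("adapter_5p too long: template would be truncated out of the read")
  structure(list(n_snps = as.integer(n_snps),
                 read_length = as.integer(read_length),
                 depth = as.integer(depth), true_effects = true_effects,
                 input_log2_sd = input_log2_sd, error_rate = error_rate,
                 replicates = as.integer(replicates), conditions = conditions,
                 test_background = test_background,
                 input_background = input_background,
                 adapter_5p = adapter_5p, adapter_3p = adapter_3p,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

random_seq <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate a candidate SNP table with flanks and known effects
#'
#' Generates `n_snps` biallelic SNPs with random distinct 10-nt flank
#' pairs, synthetic coordinates, eQTL p-values / LD r^2 and region labels,
#' plus the true log2 binding effects used downstream by
#' [simulate_reads()]. Deterministic for a fixed `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return candidate data.frame (columns of the eQTL table plus
#'   `left_flank`/`right_flank`); attribute `true_effects` is the named
#'   beta vector.
#' @export
simulate_snps <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_snps
  left <- random_seq(n, FLANK_LEN)
  right <- random_seq(n, FLANK_LEN)
  for (try in 1:100) {
    dup <- duplicated(paste(left, right))
    if (!any(dup)) break
    left[dup] <- random_seq(sum(dup), FLANK_LEN)
    right[dup] <- random_seq(sum(dup), FLANK_LEN)
  }
  if (any(duplicated(paste(left, right))))
    stop("could not generate distinct flank pairs after 100 retries")
  ref <- sample(DNA_BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  beta <- config$true_effects
  if (is.null(beta)) {
    beta <- numeric(n)
    nz <- runif(n) < 0.45
    beta[nz] <- runif(sum(nz), -5, 4)
  }
  n_regions <- max(1L, ceiling(n / 35))
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(n)),
    chrom = paste0("chr", rep_len(c(1:22, "X"), n)),
    pos = 1000000L + 1000L * seq_len(n),
    ref_allele = ref, alt_allele = unname(alt),
    gene = sprintf("GENE%03d", rep_len(seq_len(n_regions), n)),
    eqtl_p = 10^(-runif(n, 7.6, 52)),
    ld_r2 = runif(n, 0.05, 1),
    region_id = sprintf("region%02d", rep_len(seq_len(n_regions), n)),
    left_flank = left, right_flank = right,
    stringsAsFactors = FALSE
  )
  names(beta) <- snps$snp_id
  attr(snps, "true_effects") <- beta
  snps
}

mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  len <- nchar(reads)
  nerr <- rbinom(length(reads), len, error_rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(len[i], nerr[i])
    ch <- strsplit(reads[i], "")[[1]]
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

write_fastq <- function(reads, ids, path) {
  qual <- strrep("I", nchar(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), con)
  invisible(path)
}

#' Simulate sequencing reads for a template library
#'
#' Draws per-template read counts from the allele-biased binding model of
#' [simulation_config()] and writes one FASTQ per sample (input and each
#' test condition, `replicates` technical replicates each) into `outdir`.
#' The truth table records the realized per-template counts, the expected
#' proportions and the true effects, so pipeline estimates can be compared
#' with the generative truth.
#'
#' @param config a [simulation_config()].
#' @param library a `template_library` (see [design_library()]).
#' @param effects named beta vector per `snp_id`; defaults to
#'   `config$true_effects` or the `true_effects` attribute carried by
#'   [simulate_snps()] output must then be passed explicitly.
#' @param outdir output directory for FASTQ files (created if needed).
#' @return object of class `snpsseq_sim`: list with `samples` (sample
#'   sheet with FASTQ paths), `truth` (list: `counts` template x sample
#'   matrix, `proportions`, `effects`) and `config`.
#' @export
simulate_reads <- function(config, library, effects = NULL,
                           outdir = tempfile("snpsseq_sim")) {
  stopifnot(inherits(config, "simulation_config"))
  lib <- as.data.frame(library)
  if (is.null(effects)) effects <- config$true_effects
  if (is.null(effects)) stop("`effects` (true beta per snp_id) is required")
  snp_ids <- unique(lib$snp_id)
  if (is.null(names(effects)) && length(effects) == length(snp_ids))
    names(effects) <- snp_ids
  if (!all(snp_ids %in% names(effects)))
    stop("effects missing for some library SNPs")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)

  tpl <- lib$template_id
  is_var <- lib$allele_role == "variant"
  base_w <- 2^rnorm(length(tpl), 0, config$input_log2_sd)
  test_w <- base_w
  test_w[is_var] <- test_w[is_var] * 2^effects[lib$snp_id[is_var]]

  sample_specs <- rbind(
    expand.grid(role = "test", treatment = config$conditions,
                replicate = seq_len(config$replicates),
                stringsAsFactors = FALSE),
    expand.grid(role = "input", treatment = "none",
                replicate = seq_len(config$replicates),
                stringsAsFactors = FALSE))
  sample_specs$sample_id <- ifelse(
    sample_specs$role == "input",
    paste0("input_rep", sample_specs$replicate),
    paste0(tolower(sample_specs$treatment), "_rep", sample_specs$replicate))

  counts <- matrix(0L, nrow = length(tpl), ncol = nrow(sample_specs),
                   dimnames = list(tpl, sample_specs$sample_id))
  props <- matrix(0, nrow = length(tpl), ncol = nrow(sample_specs),
                  dimnames = list(tpl, sample_specs$sample_id))
  fastq <- character(nrow(sample_specs))

  for (i in seq_len(nrow(sample_specs))) {
    spec <- sample_specs[i, ]
    w <- if (spec$role == "input") base_w else test_w
    p <- w / sum(w)
    props[, i] <- p
    bg_frac <- if (spec$role == "input") config$input_background
               else config$test_background
    n_bg <- rbinom(1L, config$depth, bg_frac)
    ct <- as.integer(rmultinom(1L, config$depth - n_bg, p))
    counts[, i] <- ct

    fwd <- paste0(config$adapter_5p, lib$sequence, config$adapter_3p)
    rev <- paste0(config$adapter_5p, revcomp(lib$sequence), config$adapter_3p)
    n_fwd <- rbinom(length(ct), ct, 0.5)
    reads <- c(rep(substr(fwd, 1L, config$read_length), n_fwd),
               rep(substr(rev, 1L, config$read_length), ct - n_fwd),
               random_seq(n_bg, config$read_length))
    reads <- mutate_reads(reads, config$error_rate)
    reads <- reads[sample.int(length(reads))]
    path <- file.path(outdir, paste0(spec$sample_id, ".fastq"))
    write_fastq(reads, paste0(spec$sample_id, ":", seq_along(reads)), path)
    fastq[i] <- path
  }

  samples <- data.frame(sample_id = sample_specs$sample_id,
                        role = sample_specs$role,
                        treatment = sample_specs$treatment,
                        replicate = sample_specs$replicate,
                        fastq = fastq, stringsAsFactors = FALSE)
  structure(list(samples = samples,
                 truth = list(counts = counts, proportions = props,
                              effects = effects[snp_ids]),
                 config = config, outdir = outdir),
            class = "snpsseq_sim")
}

#' @export
print.snpsseq_sim <- function(x, ...) {
  cat(sprintf("snpsseq_sim: %d templates x %d samples, depth %d, seed %d\n",
              nrow(x$truth$counts), nrow(x$samples), x$config$depth,
              x$config$seed))
  invisible(x)
}
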