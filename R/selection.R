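#' Selection thresholds for the candidate-SNP funnel
#'
#' Thresholds of the eQTL/LD selection funnel. Defaults are the study-wide
#' values: regions must contain an eQTL signal with p < 1.97e-7; individual
#' SNPs are retained with LD r^2 with the region's lead risk SNP strictly
#' greater than 0.5 and eQTL p strictly below 3.02e-8. `window_bp` is the
#' half-window around a gene used by the optional positional filter.
#'
#' Per-region selection policies handle regions treated specially:
#' `"ld_filter"` (default) applies the LD and p-value filters;
#' `"all"` keeps every eQTL-significant SNP of the region (regions where the
#' LD filter would leave too few candidates); `"external_evidence"`
#' additionally requires a TRUE in the logical `chip_seq` column (regions
#' where only SNPs with ChIP-seq support were carried forward).
#'
#' @param region_p_threshold region-level eQTL p-value ceiling.
#' @param snp_p_threshold per-SNP eQTL p-value ceiling (strict).
#' @param ld_threshold LD r^2 floor (strict).
#' @param window_bp half-window in bp for the optional positional filter.
#' @param region_policies optional named character vector mapping
#'   `region_id` to a policy; unnamed regions use `"ld_filter"`.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(region_p_threshold = 1.97e-7,
                             snp_p_threshold = 3.02e-8,
                             ld_threshold = 0.5,
                             window_bp = 2200000L,
                             region_policies = NULL) {
  stopifnot(region_p_threshold > 0, snp_p_threshold > 0,
            ld_threshold >= 0, window_bp > 0)
  if (!is.null(region_policies)) {
    bad <- setdiff(region_policies, c("ld_filter", "all", "external_evidence"))
    if (length(bad)) stop("unknown region policy: ", paste(bad, collapse = ", "))
    if (is.null(names(region_policies))) stop("region_policies must be named by region_id")
  }
  structure(list(region_p_threshold = region_p_threshold,
                 snp_p_threshold = snp_p_threshold,
                 ld_threshold = ld_threshold,
                 window_bp = as.integer(window_bp),
                 region_policies = region_policies),
            class = "selection_config")
}

EQTL_CANONICAL <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele",
                    "eqtl_p", "ld_r2")
EQTL_OPTIONAL <- c("gene", "region_id", "chip_seq")

#' Load an eQTL SNP table
#'
#' Reads a TSV with header. `dialect` maps canonical field names to the
#' file's column names (e.g. `c(snp_id = "rsid")`); columns not mentioned
#' are looked up under their canonical names: `snp_id`, `chrom`, `pos`
#' (1-based), `ref_allele`, `alt_allele`, `eqtl_p`, `ld_r2`, and optionally
#' `gene`, `region_id`, `chip_seq`.
#'
#' Rows violating the record invariants (pos >= 1, distinct single-base
#' A/C/G/T alleles, 0 < p <= 1, 0 <= r^2 <= 1) are dropped with a
#' row-numbered warning and listed in the `rejected` attribute. A value
#' that cannot be parsed as a number at all is an error naming row and
#' column.
#'
#' @param path TSV file path.
#' @param dialect optional named character vector, canonical -> file column.
#' @return data.frame of eQTL records with canonical column names;
#'   attribute `rejected` is a data.frame of dropped row numbers + reasons.
#' @export
load_eqtl_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  cols <- setNames(c(EQTL_CANONICAL, EQTL_OPTIONAL),
                   c(EQTL_CANONICAL, EQTL_OPTIONAL))
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  miss <- setdiff(cols[EQTL_CANONICAL], names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    snp_id = raw[[cols["snp_id"]]],
                    chrom = raw[[cols["chrom"]]],
                    pos = raw[[cols["pos"]]],
                    ref_allele = toupper(raw[[cols["ref_allele"]]]),
                    alt_allele = toupper(raw[[cols["alt_allele"]]]),
                    eqtl_p = raw[[cols["eqtl_p"]]],
                    ld_r2 = raw[[cols["ld_r2"]]])
  for (opt in EQTL_OPTIONAL)
    if (cols[opt] %in% names(raw)) out[[opt]] <- raw[[cols[opt]]]

  for (num in c("pos", "eqtl_p", "ld_r2")) {
    parsed <- suppressWarnings(as.numeric(out[[num]]))
    bad <- is.na(parsed) & !is.na(out[[num]]) & nzchar(out[[num]])
    if (any(bad))
      stop(sprintf("unparseable numeric in column '%s', row %d: '%s'",
                   cols[num], which(bad)[1L], out[[num]][which(bad)[1L]]))
    out[[num]] <- parsed
  }
  out$pos <- as.integer(out$pos)
  if ("chip_seq" %in% names(out)) out$chip_seq <- as.logical(out$chip_seq)

  reasons <- character(nrow(out))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & !nzchar(reasons)] <<- why
  }
  flag(out$pos < 1, "pos < 1")
  flag(!(out$ref_allele %in% c("A", "C", "G", "T")) |
       !(out$alt_allele %in% c("A", "C", "G", "T")), "allele not in {A,C,G,T}")
  flag(out$ref_allele == out$alt_allele, "identical alleles")
  flag(out$eqtl_p <= 0 | out$eqtl_p > 1, "eqtl_p outside (0,1]")
  flag(out$ld_r2 < 0 | out$ld_r2 > 1, "ld_r2 outside [0,1]")
  bad <- nzchar(reasons)
  if (any(bad))
    warning(sprintf("rejected %d row(s): %s", sum(bad),
                    paste(sprintf("row %d (%s)", which(bad), reasons[bad]),
                          collapse = "; ")))
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejected") <- data.frame(row = which(bad), reason = reasons[bad],
                                      stringsAsFactors = FALSE)
  res
}

# natural chromosome order: 1..22, X, Y, MT, then anything else alphabetically
chrom_rank <- function(chrom) {
  c <- sub("^chr", "", chrom, ignore.case = TRUE)
  r <- suppressWarnings(as.numeric(c))
  r[toupper(c) == "X"] <- 23
  r[toupper(c) == "Y"] <- 24
  r[toupper(c) %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26 + match(c[is.na(r)], sort(unique(c[is.na(r)])))
  r
}

#' Select candidate SNPs by the eQTL/LD funnel
#'
#' Keeps regions whose minimum eQTL p-value beats the region threshold,
#' then applies the per-region policy (see [selection_config()]); under the
#' default `ld_filter` policy a SNP is retained iff `ld_r2 >
#' ld_threshold` and `eqtl_p < snp_p_threshold`, both strict. Output is
#' sorted by (chrom, pos).
#'
#' @param records eQTL record data.frame from [load_eqtl_table()].
#' @param config a [selection_config()].
#' @return data.frame of selected records in coordinate order; attribute
#'   `region_summary` reports per-region input / LD-passing / selected
#'   counts.
#' @export
select_candidates <- function(records, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  if (nrow(records) == 0L) stop("`records` is empty")
  region <- if ("region_id" %in% names(records)) records$region_id
            else rep("all", nrow(records))

  region_min_p <- tapply(records$eqtl_p, region, min)
  live <- names(region_min_p)[region_min_p < config$region_p_threshold]

  policy <- setNames(rep("ld_filter", length(live)), live)
  if (!is.null(config$region_policies)) {
    known <- intersect(names(config$region_policies), live)
    policy[known] <- config$region_policies[known]
  }
  need_ev <- policy[region] %in% "external_evidence"
  if (any(need_ev, na.rm = TRUE) && !"chip_seq" %in% names(records))
    stop("policy 'external_evidence' needs a logical `chip_seq` column")

  in_live <- region %in% live
  pass_ld <- records$ld_r2 > config$ld_threshold &
             records$eqtl_p < config$snp_p_threshold
  keep <- in_live & ifelse(policy[region] %in% "all", TRUE,
                    ifelse(policy[region] %in% "external_evidence",
                           pass_ld & records$chip_seq %in% TRUE,
                           pass_ld))
  keep[is.na(keep)] <- FALSE

  out <- records[keep, , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL

  regs <- sort(unique(region))
  attr(out, "region_summary") <- data.frame(
    region = regs,
    policy = ifelse(regs %in% live, policy[regs], "dropped"),
    n_eqtl = as.vector(table(factor(region, regs))),
    n_ld_filtered = as.vector(table(factor(region[pass_ld & in_live], regs))),
    n_selected = as.vector(table(factor(region[keep], regs))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Restrict records to a window around a gene TSS
#'
#' Optional positional helper: keeps records with |pos - tss| <= window_bp
#' on the given chromosome. The main funnel assumes this windowing was done
#' upstream of the input table.
#'
#' @param records eQTL record data.frame.
#' @param chrom,tss gene chromosome and transcription start site (1-based).
#' @param window_bp half-window in bp.
#' @return filtered data.frame.
#' @export
filter_window <- function(records, chrom, tss, window_bp = 2200000L) {
  records[records$chrom == chrom &
          abs(records$pos - tss) <= window_bp, , drop = FALSE]
}

#' Write candidates as BED (0-based half-open)
#'
#' Converts the package's 1-based inclusive coordinates to BED at write
#' time: start = pos - 1, end = pos.
#'
#' @param candidates candidate data.frame with `chrom`, `pos`, `snp_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(candidates, path) {
  bed <- data.frame(candidates$chrom, candidates$pos - 1L, candidates$pos,
                    candidates$snp_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
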