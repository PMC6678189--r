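#' Scoring configuration for biased allelic binding
#'
#' @param cutoff significance cutoff on |BAB| in log2 units; the default
#'   0.58 = log2(1.5) to two decimals, i.e. a 1.5-fold allelic difference.
#' @param pseudocount value added to all four read counts before forming
#'   ratios; default 0.5 (symmetric, preserves allele-swap antisymmetry).
#'   With pseudocount 0, any zero count is an error.
#' @param replicate_policy how technical replicates combine:
#'   `"pool_counts"` (default) sums counts across replicates of a condition
#'   before the ratio; `"mean_bab"` scores each replicate pair and averages
#'   the BAB values.
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(cutoff = 0.58, pseudocount = 0.5,
                           replicate_policy = c("pool_counts", "mean_bab")) {
  stopifnot(cutoff >= 0, pseudocount >= 0)
  structure(list(cutoff = cutoff, pseudocount = pseudocount,
                 replicate_policy = match.arg(replicate_policy)),
            class = "scoring_config")
}

#' Biased allelic binding (BAB) score
#'
#' The allele-specific binding statistic
#' `BAB = log2( (test_var/test_ref) / (input_var/input_ref) )`,
#' the log2 of the test sample's variant/reference read-count ratio
#' normalised by the same ratio in the input (pre-binding) pool. A
#' pseudocount is added to all four counts; with pseudocount 0, all counts
#' must be positive. Vectorised over equal-length count vectors.
#'
#' @param test_var,test_ref,input_var,input_ref non-negative read counts of
#'   the variant/reference templates in the test and input samples.
#' @param config a [scoring_config()] (only `pseudocount` is used here).
#' @return numeric vector of BAB scores in log2 units.
#' @examples
#' compute_bab(150, 100, 100, 100,
#'             config = scoring_config(pseudocount = 0))  # log2(1.5)
#' @export
compute_bab <- function(test_var, test_ref, input_var, input_ref,
                        config = scoring_config()) {
  counts <- cbind(test_var, test_ref, input_var, input_ref)
  if (any(counts < 0)) stop("read counts must be non-negative")
  c0 <- config$pseudocount
  if (c0 == 0 && any(counts == 0))
    stop("BAB undefined: zero count with pseudocount 0")
  log2((test_var + c0) / (test_ref + c0)) -
    log2((input_var + c0) / (input_ref + c0))
}

#' Significance of a BAB score
#'
#' Inclusive cutoff on the absolute score: |BAB| >= cutoff. The default
#' cutoff 0.58 corresponds to a 1.5-fold allelic binding difference in
#' either direction.
#'
#' @param bab finite numeric vector of BAB scores.
#' @param cutoff non-negative cutoff in log2 units.
#' @return logical vector.
#' @export
classify_significance <- function(bab, cutoff = 0.58) {
  if (any(!is.finite(bab))) stop("BAB scores must be finite")
  stopifnot(cutoff >= 0)
  abs(bab) >= cutoff
}

#' Fold change implied by a BAB score
#' @param bab finite numeric vector (log2 units).
#' @return `2^bab`, a positive fold change.
#' @export
fold_change <- function(bab) {
  if (any(!is.finite(bab))) stop("BAB scores must be finite")
  2^bab
}

#' Classify SNPs by treatment-condition overlap
#'
#' Partitions SNPs by which treatment conditions reached significance:
#' `shared` (both), `dht_only`, `eth_only`, or `nonsignificant`.
#'
#' @param dht,eth named logical significance flags over the same SNP set.
#' @return list with `classes` (named character vector per SNP) and
#'   `counts` (named integer vector over the four classes; sums to the
#'   number of SNPs).
#' @export
treatment_overlap <- function(dht, eth) {
  if (is.null(names(dht)) || is.null(names(eth)))
    stop("flags must be named by snp_id")
  extra <- c(setdiff(names(dht), names(eth)), setdiff(names(eth), names(dht)))
  if (length(extra))
    stop("SNP sets differ between conditions: ", paste(extra, collapse = ", "))
  eth <- eth[names(dht)]
  classes <- ifelse(dht & eth, "shared",
             ifelse(dht, "dht_only",
             ifelse(eth, "eth_only", "nonsignificant")))
  names(classes) <- names(dht)
  lv <- c("shared", "dht_only", "eth_only", "nonsignificant")
  counts <- table(factor(classes, levels = lv))
  list(classes = classes, counts = setNames(as.integer(counts), lv))
}

#' Score biased allelic binding for every SNP in a count table
#'
#' Aggregates a [count_reads()] table to per-SNP BAB scores per test
#' treatment condition, normalising by the pooled input samples. Under the
#' default `pool_counts` policy, counts are summed across technical
#' replicates of each condition (and across input replicates) before the
#' ratio; under `mean_bab`, the i-th test replicate is scored against the
#' i-th input replicate and the scores averaged.
#'
#' @param table a `read_count_table`.
#' @param library the `template_library` mapping templates to SNPs/alleles.
#' @param config a [scoring_config()].
#' @return data.frame of class `bab_result`: one row per SNP with read
#'   counts, `bab_<cond>`, `fold_change_<cond>` and `significant_<cond>`
#'   per condition, and `overlap_class` when both DHT and ETH are present.
#' @export
score_bab <- function(table, library, config = scoring_config()) {
  stopifnot(inherits(table, "read_count_table"))
  samples <- table$samples
  input_ids <- samples$sample_id[samples$role == "input"]
  if (!length(input_ids)) stop("no input samples in sample sheet")
  conds <- sort(unique(samples$treatment[samples$role == "test"]))
  if (!length(conds)) stop("no test samples in sample sheet")

  lib <- as.data.frame(library)
  var_tpl <- lib$template_id[lib$allele_role == "variant"]
  ref_tpl <- lib$template_id[lib$allele_role == "reference"]
  snp_ids <- lib$snp_id[lib$allele_role == "variant"]
  stopifnot(identical(snp_ids, lib$snp_id[lib$allele_role == "reference"]))

  cnt <- function(ids) {
    m <- table$counts[, ids, drop = FALSE]
    rowSums(m)
  }
  input_var <- cnt(input_ids)[var_tpl]
  input_ref <- cnt(input_ids)[ref_tpl]

  out <- data.frame(snp_id = snp_ids, input_var = unname(input_var),
                    input_ref = unname(input_ref), stringsAsFactors = FALSE)
  sig <- list()
  for (cond in conds) {
    tids <- samples$sample_id[samples$role == "test" &
                              samples$treatment == cond]
    if (config$replicate_policy == "pool_counts") {
      tv <- cnt(tids)[var_tpl]; tr <- cnt(tids)[ref_tpl]
      bab <- compute_bab(tv, tr, input_var, input_ref, config)
    } else {
      reps <- samples$replicate[match(tids, samples$sample_id)]
      ireps <- samples$replicate[match(input_ids, samples$sample_id)]
      per <- vapply(seq_along(tids), function(i) {
        iid <- input_ids[match(reps[i], ireps)]
        if (is.na(iid)) iid <- input_ids[1L]
        compute_bab(table$counts[var_tpl, tids[i]],
                    table$counts[ref_tpl, tids[i]],
                    table$counts[var_tpl, iid],
                    table$counts[ref_tpl, iid], config)
      }, numeric(length(var_tpl)))
      bab <- rowMeans(matrix(per, nrow = length(var_tpl)))
      tv <- cnt(tids)[var_tpl]; tr <- cnt(tids)[ref_tpl]
    }
    tag <- tolower(cond)
    out[[paste0("test_var_", tag)]] <- unname(tv)
    out[[paste0("test_ref_", tag)]] <- unname(tr)
    out[[paste0("bab_", tag)]] <- unname(bab)
    out[[paste0("fold_change_", tag)]] <- unname(fold_change(bab))
    out[[paste0("significant_", tag)]] <- unname(
      classify_significance(bab, config$cutoff))
    sig[[tag]] <- setNames(classify_significance(bab, config$cutoff), snp_ids)
  }
  if (all(c("dht", "eth") %in% names(sig))) {
    ov <- treatment_overlap(sig$dht, sig$eth)
    out$overlap_class <- unname(ov$classes[out$snp_id])
    attr(out, "overlap_counts") <- ov$counts
  }
  attr(out, "config") <- config
  class(out) <- c("bab_result", class(out))
  out
}

#' @export
print.bab_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("bab_result: %d SNPs (cutoff |BAB| >= %.2f, pseudocount %g, %s)\n",
              nrow(x), cfg$cutoff, cfg$pseudocount, cfg$replicate_policy))
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more SNPs\n", sep = "")
  invisible(x)
}

#' @export
summary.bab_result <- function(object, ...) {
  cfg <- attr(object, "config")
  cat(sprintf("BAB scoring of %d SNPs; significance at |BAB| >= %.2f (%.2f-fold)\n",
              nrow(object), cfg$cutoff, 2^cfg$cutoff))
  for (tag in c("dht", "eth")) {
    col <- paste0("bab_", tag)
    if (!col %in% names(object)) next
    b <- object[[col]]
    cat(sprintf("  %s: BAB range [%.2f, %.2f], %d/%d significant (%.0f%%)\n",
                toupper(tag), min(b), max(b),
                sum(object[[paste0("significant_", tag)]]), nrow(object),
                100 * mean(object[[paste0("significant_", tag)]])))
  }
  oc <- attr(object, "overlap_counts")
  if (!is.null(oc))
    cat(sprintf("  overlap: %d shared, %d DHT-only, %d ETH-only, %d nonsignificant\n",
                oc["shared"], oc["dht_only"], oc["eth_only"],
                oc["nonsignificant"]))
  invisible(object)
}

#' Allele ratio from EMSA band intensities
#'
#' Densitometry-based validation statistic: for each allele the
#' bound/unbound band-intensity quotient, and the cross-allele ratio of
#' those quotients (allele a over allele b), conventionally reported to 3
#' decimals.
#'
#' @param a,b lists (or one-row data.frames) with fields `allele`, `bound`,
#'   `unbound` (non-negative densitometry intensities).
#' @return list with `quotients` (named per allele), `ratio` and
#'   `ratio_3dp`.
#' @examples
#' emsa_allele_ratio(list(allele = "C", bound = 0.012, unbound = 1),
#'                   list(allele = "T", bound = 0.023, unbound = 1))
#' @export
emsa_allele_ratio <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  for (m in list(a, b)) {
    stopifnot(all(c("allele", "bound", "unbound") %in% names(m)))
    if (m$bound < 0 || m$unbound < 0) stop("intensities must be non-negative")
    if (m$unbound == 0) stop("unbound intensity of allele ", m$allele,
                             " is zero; quotient undefined")
  }
  qa <- a$bound / a$unbound
  qb <- b$bound / b$unbound
  if (qb == 0) stop("bound/unbound quotient of allele ", b$allele,
                    " is zero; ratio undefined")
  list(quotients = setNames(c(qa, qb), c(a$allele, b$allele)),
       ratio = qa / qb, ratio_3dp = round(qa / qb, 3))
}
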