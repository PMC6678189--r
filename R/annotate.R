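#' Controlled vocabulary of annotation marks
#'
#' Mark labels accepted in annotation tables and funnel rules: promoter /
#' enhancer histone marks, DNase hypersensitivity, bound transcription
#' factors, motif change, eQTL support, predicted modifier impact, and
#' ChIP-seq / protein-binding evidence.
#' @export
ANNOTATION_MARKS <- c("promoter_histone", "enhancer_histone", "dnase",
                      "tf_bound", "motif_change", "eqtl", "impact_modifier",
                      "chip_seq", "protein_binding")

parse_rank <- function(rank) {
  ok <- grepl("^[1-7][a-f]?$", rank)
  if (any(!ok)) stop("invalid RegulomeDB-style rank: ",
                     paste(unique(rank[!ok]), collapse = ", "))
  as.integer(substr(rank, 1, 1))
}

#' Load a local annotation table
#'
#' Reads a TSV snapshot with columns `snp_id`, `regulome_rank` (categorical
#' 1a..7; lower class = more regulatory evidence) and `marks` (semicolon-
#' separated labels from [ANNOTATION_MARKS]; empty for none). Records with
#' marks outside the controlled vocabulary are rejected with a diagnostic;
#' duplicated SNP ids are an error.
#'
#' @param path TSV path.
#' @return data.frame keyed by `snp_id` with `regulome_rank`,
#'   `regulome_class` (numeric 1..7) and `marks`; attribute `rejected`
#'   lists dropped rows.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("snp_id", "regulome_rank", "marks")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(raw$snp_id[duplicated(raw$snp_id)]), collapse = ", "))
  mk <- as.character(raw$marks)
  mk[is.na(mk)] <- ""
  marks <- strsplit(mk, ";", fixed = TRUE)
  marks <- lapply(marks, function(m) m[nzchar(trimws(m))])
  unknown <- vapply(marks, function(m) any(!m %in% ANNOTATION_MARKS), logical(1))
  if (any(unknown)) {
    bad <- unique(unlist(lapply(marks[unknown],
                                function(m) m[!m %in% ANNOTATION_MARKS])))
    warning(sprintf("rejected %d row(s) with unknown mark(s): %s",
                    sum(unknown), paste(bad, collapse = ", ")))
  }
  out <- raw[!unknown, need, drop = FALSE]
  out$regulome_class <- parse_rank(out$regulome_rank)
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(row = which(unknown),
                                      snp_id = raw$snp_id[unknown],
                                      stringsAsFactors = FALSE)
  out
}

has_marks <- function(marks_str, required, match) {
  marks_str <- as.character(marks_str)
  marks_str[is.na(marks_str)] <- ""
  got <- strsplit(marks_str, ";", fixed = TRUE)
  vapply(got, function(m) {
    m <- trimws(m)
    if (match == "all") all(required %in% m) else any(required %in% m)
  }, logical(1))
}

#' Define one funnel stage
#'
#' A stage keeps a SNP iff it passes the rank comparator (when `max_rank`
#' is set) and carries the required marks. `rank_direction = "leq"`
#' (default) reads "class <= max_rank", the RegulomeDB convention in which
#' LOWER classes carry MORE evidence; `"geq"` inverts the comparator for
#' tables scored the other way around.
#'
#' @param name stage label.
#' @param max_rank numeric rank bound (1..7), or NULL for no rank test.
#' @param required_marks character vector from [ANNOTATION_MARKS], or NULL.
#' @param match `"any"` (default) or `"all"` of the required marks.
#' @param rank_direction `"leq"` (default) or `"geq"`.
#' @return list of class `funnel_rule`.
#' @export
funnel_rule <- function(name, max_rank = NULL, required_marks = NULL,
                        match = c("any", "all"),
                        rank_direction = c("leq", "geq")) {
  match <- match.arg(match)
  rank_direction <- match.arg(rank_direction)
  if (!is.null(required_marks)) {
    bad <- setdiff(required_marks, ANNOTATION_MARKS)
    if (length(bad)) stop("unknown mark(s) in rule '", name, "': ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(max_rank)) stopifnot(max_rank >= 1, max_rank <= 7)
  structure(list(name = name, max_rank = max_rank,
                 required_marks = required_marks, match = match,
                 rank_direction = rank_direction),
            class = "funnel_rule")
}

#' Default prioritization funnel
#'
#' The standard three-stage funnel applied to significant SNPs: (1)
#' regulatory-evidence rank at class 4 or better, (2) modifier impact plus
#' motif change plus at least one histone/TF mark, (3) allele-dependent
#' motif disruption from the PWM comparison joined in as the
#' `motif_change` + `tf_bound` pair.
#'
#' @param rank_direction comparator direction, see [funnel_rule()].
#' @return list of `funnel_rule`s.
#' @export
default_funnel_rules <- function(rank_direction = "leq") {
  list(
    funnel_rule("regulome_rank", max_rank = 4, rank_direction = rank_direction),
    funnel_rule("functional_marks",
                required_marks = c("impact_modifier", "motif_change",
                                   "promoter_histone", "enhancer_histone",
                                   "tf_bound"),
                match = "any", rank_direction = rank_direction),
    funnel_rule("motif_disruption",
                required_marks = c("motif_change", "tf_bound"),
                match = "all", rank_direction = rank_direction)
  )
}

#' Apply a prioritization funnel to significant SNPs
#'
#' Stages are applied in order; stage k filters the survivors of stage
#' k-1, so survivor sets are nested. SNPs missing from the annotation
#' table fail every stage with a rank or mark requirement.
#'
#' @param snp_ids character vector of significant SNP ids (stage 0).
#' @param annotations annotation data.frame from [load_annotations()].
#' @param rules ordered list of [funnel_rule()]s.
#' @return object of class `funnel_result`: list with `stages` (named list
#'   of surviving id vectors, including `input`) and `summary` (per-stage
#'   counts).
#' @export
apply_funnel <- function(snp_ids, annotations,
                         rules = default_funnel_rules()) {
  if (!length(rules)) stop("`rules` must contain at least one stage")
  if (inherits(rules, "funnel_rule")) rules <- list(rules)
  stages <- list(input = unique(snp_ids))
  current <- stages$input
  for (rule in rules) {
    stopifnot(inherits(rule, "funnel_rule"))
    idx <- match(current, annotations$snp_id)
    ok <- !is.na(idx)
    pass <- ok
    if (!is.null(rule$max_rank)) {
      cls <- annotations$regulome_class[idx]
      cmp <- if (rule$rank_direction == "leq") cls <= rule$max_rank
             else cls >= rule$max_rank
      pass <- pass & ok & cmp %in% TRUE
    }
    if (!is.null(rule$required_marks)) {
      hm <- has_marks(annotations$marks[idx], rule$required_marks, rule$match)
      pass <- pass & ok & hm %in% TRUE
    }
    current <- current[pass %in% TRUE]
    stages[[rule$name]] <- current
  }
  summary <- data.frame(stage = names(stages),
                        n = lengths(stages), row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(stages = stages, summary = summary),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("prioritization funnel:\n")
  cat(paste(sprintf("  %-20s %d", x$summary$stage, x$summary$n),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Join motif gain/loss calls into an annotation table
#'
#' Adds `motif_change` and `tf_bound` marks to SNPs whose
#' [compare_alleles()] status is `gain` or `loss`, so the PWM comparison
#' can feed the funnel's motif-disruption stage.
#'
#' @param annotations annotation data.frame.
#' @param motif_calls data.frame with `snp_id` and `status` columns.
#' @return updated annotation data.frame.
#' @export
join_motif_calls <- function(annotations, motif_calls) {
  changed <- unique(motif_calls$snp_id[motif_calls$status %in%
                                       c("gain", "loss")])
  idx <- match(changed, annotations$snp_id)
  for (i in seq_along(changed)) {
    if (is.na(idx[i])) next
    m <- annotations$marks[idx[i]]
    add <- setdiff(c("motif_change", "tf_bound"),
                   trimws(strsplit(m, ";", fixed = TRUE)[[1]]))
    if (length(add))
      annotations$marks[idx[i]] <-
        paste(c(if (nzchar(m)) m, add), collapse = ";")
  }
  annotations
}
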