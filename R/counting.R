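#' Build an exact-match template index
#'
#' Maps every 21-nt template sequence and its reverse complement to the
#' owning template, so that read matching is orientation-free. Construction
#' fails if two different templates collide on a sequence or on a reverse
#' complement; palindromic templates (sequence equal to its own reverse
#' complement) contribute a single key and are reported.
#'
#' @param lib a `template_library` (see [design_library()]).
#' @return object of class `template_index` with the key/template lookup.
#' @export
build_index <- function(lib) {
  if (any(nchar(lib$sequence) != TEMPLATE_LEN))
    stop("all template sequences must be ", TEMPLATE_LEN, " nt")
  rc <- revcomp(lib$sequence)
  keys <- c(lib$sequence, rc)
  ids <- rep(lib$template_id, 2L)
  pal <- lib$sequence == rc
  if (any(pal)) {
    message("palindromic template(s): ",
            paste(lib$template_id[pal], collapse = ", "))
    dedup <- !(duplicated(keys) & ids %in% lib$template_id[pal])
    keys <- keys[dedup]; ids <- ids[dedup]
  }
  clash <- keys[duplicated(keys)]
  if (length(clash)) {
    who <- unique(ids[keys %in% clash])
    stop("template sequences collide (directly or by reverse complement): ",
         paste(who, collapse = ", "))
  }
  structure(list(keys = keys, ids = ids, k = TEMPLATE_LEN,
                 template_ids = lib$template_id),
            class = "template_index")
}

# vectorised matcher: for each read, the set of distinct templates whose
# 21-mer (either orientation) occurs in it. Returns template_id, "ambiguous"
# (>1 distinct) or NA (none).
match_reads_vec <- function(reads, index) {
  n <- length(reads)
  hit <- rep(NA_character_, n)
  ambig <- logical(n)
  if (n == 0L) return(character(0))
  k <- index$k
  max_off <- max(nchar(reads)) - k + 1L
  if (max_off >= 1L) for (j in seq_len(max_off)) {
    km <- substr(reads, j, j + k - 1L)
    id <- index$ids[match(km, index$keys)]
    got <- !is.na(id)
    new <- got & is.na(hit)
    hit[new] <- id[new]
    ambig <- ambig | (got & !is.na(hit) & hit != id)
  }
  hit[ambig] <- "ambiguous"
  hit
}

#' Match one read against the template index
#'
#' Scans every 21-mer of the read (perfect match only, both orientations
#' via the index). Exactly one distinct template hit gives that template;
#' none gives `"unmatched"`; hits to more than one distinct template give
#' `"ambiguous"` (the read is discarded from counting, not multi-counted).
#' A read containing the same template more than once still counts once.
#'
#' @param read a single read sequence.
#' @param index a `template_index` from [build_index()].
#' @return a `template_id`, `"unmatched"`, or `"ambiguous"`.
#' @export
match_read <- function(read, index) {
  stopifnot(is.character(read), length(read) == 1L)
  if (nchar(read) < index$k) {
    warning("read shorter than template length (", index$k, " nt)")
    return("unmatched")
  }
  r <- match_reads_vec(read, index)
  if (is.na(r)) "unmatched" else r
}

read_fastq_chars <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  as.character(seqs)
}

#' Count exactly-matching reads per template
#'
#' For each sample in the sample sheet, reads its FASTQ and assigns each
#' read by perfect 21-mer containment (either orientation) to at most one
#' template. Per-sample QC reports raw, matched, ambiguous and unmatched
#' read totals and the mappable rate (matched / raw; NA for an empty
#' sample).
#'
#' @param samples sample sheet data.frame with columns `sample_id`, `role`
#'   ("test"/"input"), `treatment` ("DHT"/"ETH"/"none"), `replicate`,
#'   `fastq` (file path). Input samples must have treatment "none".
#' @param index a `template_index` from [build_index()].
#' @return object of class `read_count_table`: list with `counts` (integer
#'   matrix, templates x samples), `qc` (per-sample totals and
#'   mappable_rate) and `samples` (the sheet).
#' @export
count_reads <- function(samples, index) {
  need <- c("sample_id", "role", "treatment", "replicate", "fastq")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet misses column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  bad <- samples$role == "input" & samples$treatment != "none"
  if (any(bad)) stop("input samples must have treatment 'none': ",
                     paste(samples$sample_id[bad], collapse = ", "))
  tpl <- index$template_ids
  counts <- matrix(0L, nrow = length(tpl), ncol = nrow(samples),
                   dimnames = list(tpl, samples$sample_id))
  qc <- data.frame(sample_id = samples$sample_id, raw = 0L, matched = 0L,
                   ambiguous = 0L, unmatched = 0L, mappable_rate = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(samples))) {
    reads <- read_fastq_chars(samples$fastq[i])
    r <- match_reads_vec(reads, index)
    tab <- table(factor(r, levels = tpl))
    counts[, i] <- as.integer(tab)
    qc$raw[i] <- length(reads)
    qc$ambiguous[i] <- sum(r %in% "ambiguous")
    qc$matched[i] <- sum(!is.na(r)) - qc$ambiguous[i]
    qc$unmatched[i] <- sum(is.na(r))
    qc$mappable_rate[i] <- if (length(reads)) qc$matched[i] / length(reads)
                           else NA_real_
  }
  structure(list(counts = counts, qc = qc, samples = samples),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("read_count_table: %d templates x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$qc, row.names = FALSE)
  invisible(x)
}

#' Squared correlation between technical replicates
#'
#' Squared Pearson correlation of log2(RC + 1) across all templates; the
#' standard replicate-QC statistic for count reproducibility.
#'
#' @param table a `read_count_table`.
#' @param sample_a,sample_b sample ids sharing the template universe.
#' @return R^2 in \[0, 1\].
#' @export
replicate_correlation <- function(table, sample_a, sample_b) {
  stopifnot(inherits(table, "read_count_table"))
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(table$counts)) stop("unknown sample: ", s)
  a <- log2(table$counts[, sample_a] + 1)
  b <- log2(table$counts[, sample_b] + 1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in counts of ", sample_a, " or ", sample_b)
  cor(a, b)^2
}

#' Write / read a count table as TSV (templates x samples)
#' @param table a `read_count_table`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  df <- data.frame(template_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
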