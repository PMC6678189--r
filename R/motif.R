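DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix for MATCH-style scoring
#'
#' Converts per-position base counts (or frequencies) into relative
#' frequencies f(i,b), the per-position information vector
#' I(i) = sum_b f(i,b) * ln(4 f(i,b)) (natural log, with 0*ln 0 := 0), and
#' the core: the 5 consecutive positions with maximal summed information,
#' ties broken leftmost. An optional pseudocount regularises zero
#' frequencies as f = (count + 0.25*pc) / (total + pc); the default pc = 0
#' scores raw frequencies.
#'
#' @param counts 4 x L numeric matrix, rows A, C, G, T, columns positions;
#'   non-negative, each column with a positive total.
#' @param name matrix identifier.
#' @param pseudocount regularisation total pc >= 0 (default 0).
#' @return object of class `pwm`: list with `name`, `freqs` (4 x L),
#'   `info` (length L), `core` (5 positions, or NULL when L < 5).
#' @export
pwm <- function(counts, name = "pwm", pseudocount = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every position needs a positive count total")
  freqs <- sweep(counts + 0.25 * pseudocount, 2, tot + pseudocount, "/")
  info <- apply(freqs, 2, function(f) {
    terms <- ifelse(f > 0, f * log(4 * f), 0)
    sum(terms)
  })
  L <- ncol(freqs)
  core <- NULL
  if (L >= 5L) {
    sums <- vapply(seq_len(L - 4L), function(i) sum(info[i:(i + 4L)]),
                   numeric(1))
    s <- which.max(sums)  # leftmost maximum
    core <- s:(s + 4L)
  }
  structure(list(name = name, freqs = freqs, info = info, core = core),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, core %s\n", x$name, ncol(x$freqs),
              if (is.null(x$core)) "undefined (L < 5)"
              else paste(range(x$core), collapse = "-")))
  print(round(x$freqs, 3))
  invisible(x)
}

#' Consensus sequence of a PWM (maximal-frequency base per position)
#' @param pwm a `pwm`.
#' @return character scalar of length L.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freqs, 2, which.max)], collapse = "")
}

#' Reverse complement a PWM
#' @param pwm a `pwm`.
#' @return a `pwm` scoring the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  f <- pwm$freqs[rev(DNA_BASES), rev(seq_len(ncol(pwm$freqs))), drop = FALSE]
  rownames(f) <- DNA_BASES
  pwm(f, name = paste0(pwm$name, "_rc"))
}

#' Load TRANSFAC-style matrices
#'
#' Parses matrix text in the TRANSFAC layout: `ID`/`NA`/`DE` identifier
#' lines, a `P0`/`PO` header giving the base column order, numbered
#' per-position count rows, `//` separators. Counts are converted to
#' frequencies and the information vector/core computed per [pwm()].
#' Matrices shorter than 5 positions are an error (the core is undefined).
#'
#' @param path matrix text file.
#' @param pseudocount passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
load_transfac <- function(path, pseudocount = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  pwms <- list()
  name <- NULL; order <- NULL; rows <- list()
  flush <- function() {
    if (!length(rows)) return()
    m <- do.call(rbind, rows)
    counts <- t(m)[match(DNA_BASES, order), , drop = FALSE]
    rownames(counts) <- DNA_BASES
    if (ncol(counts) < 5L)
      stop("matrix '", name, "' has fewer than 5 positions")
    pwms[[name]] <<- pwm(counts, name = name, pseudocount = pseudocount)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^//", ln)) { flush(); name <- NULL; order <- NULL; rows <- list(); next }
    tag <- sub("^(\\S+).*", "\\1", ln)
    if (tag %in% c("ID", "NA", "DE") && is.null(order)) {
      if (is.null(name)) name <- sub("^\\S+\\s+", "", ln)
    } else if (toupper(tag) %in% c("P0", "PO")) {
      order <- toupper(strsplit(sub("^\\S+\\s+", "", ln), "\\s+")[[1]])[1:4]
      if (!setequal(order, DNA_BASES))
        stop("P0 header must list the four bases, got: ", ln)
    } else if (grepl("^[0-9]+$", tag)) {
      if (is.null(order)) stop("count row before P0 header: ", ln)
      vals <- strsplit(sub("^\\S+\\s+", "", ln), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(vals[1:4]))
      if (any(is.na(num))) stop("unparseable count row: ", ln)
      if (is.null(name)) name <- paste0("matrix", length(pwms) + 1L)
      rows[[length(rows) + 1L]] <- num
    }
  }
  flush()
  if (!length(pwms)) stop("no matrices found in ", path)
  pwms
}

#' MATCH matrix similarity score of one window
#'
#' The information-weighted similarity
#' `(Current - Min) / (Max - Min)` with
#' `Current = sum_{i in positions} I(i) f(i, b_i)` and Min/Max the scores
#' of the per-position worst/best bases over the same positions. 1.0 when
#' every scored position carries its maximal-frequency base, 0.0 when every
#' position carries a minimal-frequency base. A degenerate window set with
#' Max = Min scores 1.0 by convention (with a warning).
#'
#' @param pwm a `pwm`.
#' @param window sequence of length L (the PWM width).
#' @param positions positions to score (subset of 1..L); defaults to all.
#' @return score in \[0, 1\].
#' @export
mss <- function(pwm, window, positions = seq_len(ncol(pwm$freqs))) {
  L <- ncol(pwm$freqs)
  if (nchar(window) != L)
    stop(sprintf("window length %d != PWM width %d", nchar(window), L))
  stopifnot(all(positions %in% seq_len(L)))
  b <- strsplit(window, "")[[1]][positions]
  bi <- match(b, DNA_BASES)
  if (any(is.na(bi))) stop("window must be over {A,C,G,T}")
  f <- pwm$freqs[, positions, drop = FALSE]
  I <- pwm$info[positions]
  cur <- sum(I * f[cbind(bi, seq_along(positions))])
  mn <- sum(I * apply(f, 2, min))
  mx <- sum(I * apply(f, 2, max))
  if (mx - mn <= 0) {
    warning("degenerate PWM positions (Max = Min); score 1.0 by convention")
    return(1.0)
  }
  (cur - mn) / (mx - mn)
}

# score all windows of seq on one strand; returns data.frame
scan_strand <- function(seq, pwm, strand) {
  L <- ncol(pwm$freqs)
  s <- if (strand == "+") seq else revcomp(seq)
  n <- nchar(s)
  offs <- seq_len(n - L + 1L)
  core <- vapply(offs, function(o)
    mss(pwm, substr(s, o, o + L - 1L), pwm$core), numeric(1))
  mat <- vapply(offs, function(o)
    mss(pwm, substr(s, o, o + L - 1L)), numeric(1))
  # map minus-strand offsets back to plus-strand coordinates
  off_plus <- if (strand == "+") offs else n - (offs + L - 1L) + 1L
  data.frame(pwm = pwm$name, offset = off_plus, strand = strand,
             core_score = core, matrix_score = mat, stringsAsFactors = FALSE)
}

#' Scan a sequence for MATCH-style motif hits
#'
#' Slides the PWM over every window of both strands and reports windows
#' whose core similarity (scored on the 5-position core) and matrix
#' similarity (scored on all L positions) both reach their cutoffs.
#' Offsets are 1-based on the supplied (plus) strand.
#'
#' @param seq nucleotide string, length >= PWM width.
#' @param pwm a `pwm` with a defined core (L >= 5).
#' @param core_cutoff,matrix_cutoff cutoffs in \[0, 1\].
#' @return data.frame of hits (possibly empty): `pwm`, `offset`, `strand`,
#'   `core_score`, `matrix_score`.
#' @export
scan_pwm <- function(seq, pwm, core_cutoff = 0.75, matrix_cutoff = 0.80) {
  stopifnot(core_cutoff >= 0, core_cutoff <= 1,
            matrix_cutoff >= 0, matrix_cutoff <= 1)
  if (is.null(pwm$core)) stop("PWM '", pwm$name, "' has no core (L < 5)")
  if (nchar(seq) < ncol(pwm$freqs))
    stop("sequence shorter than PWM width")
  hits <- rbind(scan_strand(seq, pwm, "+"), scan_strand(seq, pwm, "-"))
  hits <- hits[hits$core_score >= core_cutoff &
               hits$matrix_score >= matrix_cutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Allele-dependent motif creation or disruption
#'
#' Scans the reference- and variant-allele oligos (differing at exactly one
#' position) with each PWM and classifies the SNP's effect on the motif:
#' `gain` (hit for the variant oligo only), `loss` (reference only), or
#' `no_change`. Best core/matrix scores per allele (over all windows and
#' strands, before cutoffs) are reported alongside.
#'
#' @param ref_oligo,alt_oligo equal-length sequences differing at exactly
#'   one position (typically the 21-nt allele oligos).
#' @param pwms a `pwm` or list of `pwm`s.
#' @param core_cutoff,matrix_cutoff hit cutoffs, as in [scan_pwm()].
#' @return data.frame, one row per PWM: `pwm`, `status`, hit counts and
#'   best core/matrix scores for each allele.
#' @export
compare_alleles <- function(ref_oligo, alt_oligo, pwms,
                            core_cutoff = 0.75, matrix_cutoff = 0.80) {
  if (nchar(ref_oligo) != nchar(alt_oligo))
    stop("allele oligos must have equal length")
  ndiff <- sum(strsplit(ref_oligo, "")[[1]] != strsplit(alt_oligo, "")[[1]])
  if (ndiff != 1L)
    stop("allele oligos must differ at exactly one position (got ", ndiff, ")")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  rows <- lapply(pwms, function(p) {
    hr <- scan_pwm(ref_oligo, p, core_cutoff, matrix_cutoff)
    ha <- scan_pwm(alt_oligo, p, core_cutoff, matrix_cutoff)
    best <- function(seq) {
      all <- rbind(scan_strand(seq, p, "+"), scan_strand(seq, p, "-"))
      c(core = max(all$core_score), matrix = max(all$matrix_score))
    }
    br <- best(ref_oligo); ba <- best(alt_oligo)
    status <- if (nrow(ha) > 0 && nrow(hr) == 0) "gain"
              else if (nrow(hr) > 0 && nrow(ha) == 0) "loss"
              else "no_change"
    data.frame(pwm = p$name, status = status,
               ref_hits = nrow(hr), alt_hits = nrow(ha),
               ref_best_core = br["core"], ref_best_matrix = br["matrix"],
               alt_best_core = ba["core"], alt_best_matrix = ba["matrix"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
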