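#' Reverse complement of a DNA sequence
#'
#' Strict reverse complement over the alphabet A/C/G/T. Vectorised over
#' `seq`. Any other character (including IUPAC ambiguity codes and lower
#' case) is an error naming the offending position, since oligo templates
#' and simulated reads are required to be unambiguous.
#'
#' @param seq character vector of upper-case A/C/G/T sequences.
#' @return character vector of reverse complements, same length as `seq`.
#' @examples
#' revcomp("AACG")  # "CGTT"
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be a character vector")
  bad <- regexpr("[^ACGT]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-ACGT character at position %d of sequence %d",
                 bad[i], i))
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' GC fraction of a sequence
#'
#' @param seq character vector of non-empty A/C/G/T sequences.
#' @return numeric vector, (#G + #C) / length, in \[0, 1\].
#' @examples
#' gc_fraction("GGGCCC")  # 1
#' @export
gc_fraction <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be a character vector")
  if (any(!nzchar(seq))) stop("empty sequence has no GC fraction")
  if (any(grepl("[^ACGT]", seq))) stop("sequences must be over {A,C,G,T}")
  nchar(gsub("[AT]", "", seq)) / nchar(seq)
}

validate_candidate_snp <- function(snp) {
  need <- c("snp_id", "ref_allele", "alt_allele", "left_flank", "right_flank")
  miss <- setdiff(need, names(snp))
  if (length(miss))
    stop("candidate SNP is missing field(s): ", paste(miss, collapse = ", "))
  if (nchar(snp$left_flank) != FLANK_LEN || nchar(snp$right_flank) != FLANK_LEN)
    stop(sprintf("flanks of %s must be exactly %d nt (got %d/%d)",
                 snp$snp_id, FLANK_LEN,
                 nchar(snp$left_flank), nchar(snp$right_flank)))
  if (grepl("[^ACGT]", snp$left_flank) || grepl("[^ACGT]", snp$right_flank))
    stop("flanks of ", snp$snp_id, " must be over {A,C,G,T}")
  if (!snp$ref_allele %in% c("A", "C", "G", "T") ||
      !snp$alt_allele %in% c("A", "C", "G", "T"))
    stop("alleles of ", snp$snp_id, " must be single A/C/G/T bases")
  if (snp$ref_allele == snp$alt_allele)
    stop("alleles of ", snp$snp_id, " must differ")
  invisible(snp)
}

#' Design the four single-strand oligo templates for one SNP
#'
#' Builds the allele-pair duplex design: for each allele (reference and
#' variant) the plus-strand template is `left_flank + allele + right_flank`
#' (21 nt, SNP at position 11) and the minus strand is its reverse
#' complement. GC fraction is computed on the plus strand.
#'
#' @param snp a one-row data.frame or list with `snp_id`, `ref_allele`,
#'   `alt_allele`, and 10-nt `left_flank` / `right_flank` (plus strand).
#' @return data.frame with one row per oligo (2 alleles x 2 strands):
#'   `snp_id`, `allele_role` ("reference"/"variant"), `allele`, `strand`,
#'   `sequence`, `gc_fraction`.
#' @export
design_templates <- function(snp) {
  snp <- as.list(snp)
  validate_candidate_snp(snp)
  alleles <- c(reference = snp$ref_allele, variant = snp$alt_allele)
  plus <- paste0(snp$left_flank, alleles, snp$right_flank)
  gc <- gc_fraction(plus)
  data.frame(
    snp_id = snp$snp_id,
    allele_role = rep(names(alleles), each = 2L),
    allele = rep(unname(alleles), each = 2L),
    strand = rep(c("+", "-"), 2L),
    sequence = as.vector(rbind(plus, revcomp(plus))),
    gc_fraction = rep(gc, each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Build the plus-strand template library for a set of candidate SNPs
#'
#' Only plus-strand sequences enter the library (the minus strand is the
#' same duplex); read matching handles orientation. With all-distinct flank
#' pairs a library of n SNPs has exactly 2n unique sequences; duplicated
#' sequences across templates are reported.
#'
#' @param candidates data.frame of candidate SNPs (see [design_templates()]
#'   for required columns).
#' @return data.frame of class `template_library` with one row per
#'   plus-strand template: `template_id` (`snp_id|allele_role`), `snp_id`,
#'   `allele_role`, `allele`, `sequence`, `gc_fraction`; attribute
#'   `n_unique` holds the number of distinct sequences.
#' @export
design_library <- function(candidates) {
  if (nrow(candidates) == 0L) stop("no candidate SNPs supplied")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    tpl <- design_templates(candidates[i, , drop = FALSE])
    tpl[tpl$strand == "+", c("snp_id", "allele_role", "allele",
                             "sequence", "gc_fraction")]
  })
  lib <- do.call(rbind, rows)
  lib <- cbind(template_id = paste(lib$snp_id, lib$allele_role, sep = "|"),
               lib, stringsAsFactors = FALSE)
  rownames(lib) <- NULL
  dup <- duplicated(lib$sequence) | duplicated(lib$sequence, fromLast = TRUE)
  if (any(dup))
    warning("duplicated template sequences: ",
            paste(lib$template_id[dup], collapse = ", "))
  attr(lib, "n_unique") <- length(unique(lib$sequence))
  class(lib) <- c("template_library", class(lib))
  lib
}

#' Exclude SNPs whose oligos have low GC content
#'
#' A SNP is kept iff the larger of its two plus-strand allele-oligo GC
#' fractions is at least `min_gc`. GC-poor duplexes capture poorly in the
#' binding/purification protocol, so they are removed before synthesis.
#'
#' @param candidates candidate SNP data.frame (with flanks and alleles).
#' @param min_gc minimum GC fraction in \[0, 1\]; default 0.33 (7 of 21
#'   bases), a configurable placeholder for "low GC".
#' @return list with data.frames `kept` and `excluded` (disjoint, union =
#'   input).
#' @export
filter_low_gc <- function(candidates, min_gc = 0.33) {
  stopifnot(is.numeric(min_gc), length(min_gc) == 1L, min_gc >= 0, min_gc <= 1)
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, excluded = candidates))
  gc_max <- vapply(seq_len(nrow(candidates)), function(i) {
    s <- candidates[i, ]
    max(gc_fraction(paste0(s$left_flank, c(s$ref_allele, s$alt_allele),
                           s$right_flank)))
  }, numeric(1))
  keep <- gc_max >= min_gc
  list(kept = candidates[keep, , drop = FALSE],
       excluded = candidates[!keep, , drop = FALSE])
}

#' Write a template library to FASTA
#'
#' One record per plus-strand template, header `snp_id|allele_role|allele`.
#' Round-trips through [read_library()].
#'
#' @param lib a `template_library` from [design_library()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(lib$sequence)
  names(seqs) <- paste(lib$snp_id, lib$allele_role, lib$allele, sep = "|")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a template library from FASTA written by [write_library()]
#'
#' @param path FASTA path.
#' @return a `template_library` data.frame.
#' @export
read_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    lib <- data.frame(template_id = character(), snp_id = character(),
                      allele_role = character(), allele = character(),
                      sequence = character(), gc_fraction = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop("library FASTA headers must be snp_id|allele_role|allele")
    lib <- data.frame(
      template_id = paste(vapply(parts, `[`, "", 1L),
                          vapply(parts, `[`, "", 2L), sep = "|"),
      snp_id = vapply(parts, `[`, "", 1L),
      allele_role = vapply(parts, `[`, "", 2L),
      allele = vapply(parts, `[`, "", 3L),
      sequence = as.character(seqs),
      gc_fraction = gc_fraction(unname(as.character(seqs))),
      stringsAsFactors = FALSE
    )
    rownames(lib) <- NULL
  }
  attr(lib, "n_unique") <- length(unique(lib$sequence))
  class(lib) <- c("template_library", class(lib))
  lib
}
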