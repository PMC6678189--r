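# shared in-code fixtures

# deterministic candidate SNP table with fixed flanks
toy_candidates <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 50L),
    ref_allele = c("C", "A", "G"),
    alt_allele = c("T", "G", "A"),
    left_flank = c("ACGTACGTAC", "GGGGGCCCCC", "ATATATATAT"),
    right_flank = c("ACGTACGTAC", "CCCCCGGGGG", "TATATATATA"),
    stringsAsFactors = FALSE
  )
}

# write an eQTL TSV from a data.frame (possibly with text cells)
write_eqtl_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_eqtl_records <- function(n) {
  data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_allele = "N",  # fixed below
    eqtl_p = 10^-runif(n, 4, 12),
    ld_r2 = runif(n),
    region_id = sample(c("rA", "rB", "rC"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ) -> df
  df$alt_allele <- vapply(df$ref_allele, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  df
}

# TRANSFAC-style matrix text for a toy matrix; counts: list of per-position
# numeric(4) in A C G T order
write_transfac <- function(counts, name = "TOY",
                           path = tempfile(fileext = ".dat")) {
  lines <- c(paste("ID", name), "P0      A      C      G      T")
  for (i in seq_along(counts))
    lines <- c(lines, paste(sprintf("%02d", i),
                            paste(counts[[i]], collapse = " ")))
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}

# a 6-position PWM with an unambiguous consensus GATTAC and informative core
toy_pwm_counts <- function() {
  list(c(1, 2, 16, 1), c(16, 1, 2, 1), c(1, 1, 1, 17), c(0, 0, 2, 18),
       c(14, 2, 2, 2), c(3, 12, 3, 2))
}

# brute-force (Current - Min) / (Max - Min) score, independent of mss()
brute_mss <- function(freqs, info, window, positions) {
  bases <- c("A", "C", "G", "T")
  b <- strsplit(window, "")[[1]]
  cur <- 0; mn <- 0; mx <- 0
  for (i in positions) {
    cur <- cur + info[i] * freqs[match(b[i], bases), i]
    mn <- mn + info[i] * min(freqs[, i])
    mx <- mx + info[i] * max(freqs[, i])
  }
  unname((cur - mn) / (mx - mn))
}

all_windows <- function(L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                              stringsAsFactors = FALSE))
}

# minimal simulated experiment for counting/scoring tests
small_sim <- function(n_snps = 6, depth = 6000, seed = 11, effects = NULL,
                      ...) {
  cfg <- simulation_config(n_snps = n_snps, depth = depth, seed = seed,
                           true_effects = effects, ...)
  snps <- simulate_snps(cfg)
  lib <- design_library(snps)
  sim <- simulate_reads(cfg, lib, attr(snps, "true_effects"))
  list(cfg = cfg, snps = snps, lib = lib, sim = sim)
}
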