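test_that("PWM construction: frequencies, information vector, core", {
  # uniform column -> I = 0; single-base column -> I = ln 4
  counts <- cbind(c(5, 5, 5, 5), c(8, 0, 0, 0), c(0, 12, 0, 0),
                  c(1, 1, 1, 17), c(2, 2, 14, 2), c(3, 3, 3, 11))
  p <- pwm(counts)
  expect_equal(colSums(p$freqs), rep(1, 6))
  expect_equal(p$info[1], 0)
  expect_equal(p$info[2], log(4))
  expect_equal(p$info[3], log(4))
  expect_true(all(p$info >= 0))
  # core = 5 consecutive positions with maximal summed information: here
  # positions 2..6 beat 1..5 because position 1 carries none
  expect_equal(p$core, 2:6)
  expect_identical(pwm_consensus(p), "AACTGT")
  # frequency normalization: scaling a column's counts changes nothing
  counts2 <- counts; counts2[, 4] <- counts2[, 4] * 10
  expect_equal(pwm(counts2)$freqs, p$freqs)
  expect_error(pwm(counts[1:3, ]), "4 rows")
  expect_error(pwm(cbind(c(0, 0, 0, 0))), "positive count")
})

test_that("core ties break leftmost", {
  # two flat-information stretches of equal weight
  col_info <- c(8, 0, 0, 0)   # ln 4 information
  flat <- c(1, 1, 1, 1)       # zero information
  counts <- cbind(col_info, flat, flat, flat, flat, flat, col_info)
  p <- pwm(counts)
  expect_equal(p$core, 1:5)
})

test_that("TRANSFAC-style matrices parse with base-order mapping", {
  path <- write_transfac(toy_pwm_counts(), name = "TOY1")
  pwms <- load_transfac(path)
  expect_named(pwms, "TOY1")
  expect_equal(ncol(pwms$TOY1$freqs), 6L)
  expect_identical(pwm_consensus(pwms$TOY1), "GATTAC")

  # column order other than A C G T is honoured
  lines <- c("ID SWAP", "P0 T G C A",
             "01 10 0 0 0",  # all T
             "02 0 10 0 0",  # all G
             "03 0 0 10 0", "04 0 0 0 10", "05 5 5 0 0")
  path2 <- tempfile(); writeLines(c(lines, "//"), path2)
  sw <- load_transfac(path2)$SWAP
  expect_identical(pwm_consensus(sw), "TGCAG")

  # two matrices in one file
  path3 <- tempfile()
  writeLines(c(readLines(path), readLines(path2), "//"), path3)
  expect_equal(length(load_transfac(path3)), 2L)

  short <- write_transfac(toy_pwm_counts()[1:4], name = "SHORT")
  expect_error(load_transfac(short), "fewer than 5")
  bad <- tempfile(); writeLines(c("ID X", "P0 A C G T", "01 1 x 1 1", "//"),
                                bad)
  expect_error(load_transfac(bad), "unparseable")
})

test_that("mss normalization: consensus scores 1, anti-consensus scores 0", {
  set.seed(13)
  for (i in 1:10) {
    L <- sample(5:9, 1)
    counts <- matrix(runif(4 * L, 0.1, 10), nrow = 4)
    p <- pwm(counts)
    consensus <- pwm_consensus(p)
    anti <- paste(c("A", "C", "G", "T")[apply(p$freqs, 2, which.min)],
                  collapse = "")
    expect_equal(mss(p, consensus), 1)
    expect_equal(mss(p, anti), 0)
    expect_equal(mss(p, consensus, p$core), 1)
  }
  p <- pwm(do.call(cbind, toy_pwm_counts()))
  expect_error(mss(p, "ACGT"), "length")
  expect_error(mss(p, "ACGTNN"), "A,C,G,T")
})

test_that("mss agrees with exhaustive brute force on a 4-position PWM", {
  counts <- cbind(c(7, 1, 1, 1), c(1, 1, 8, 0), c(2, 5, 2, 1), c(0, 0, 3, 7))
  p <- pwm(counts)
  wins <- all_windows(4)
  expect_equal(length(wins), 256L)
  ours <- vapply(wins, function(w) mss(p, w), numeric(1))
  oracle <- vapply(wins, function(w)
    brute_mss(p$freqs, p$info, w, 1:4), numeric(1))
  expect_equal(unname(ours), unname(oracle))
  expect_equal(max(ours), 1)
  expect_equal(min(ours), 0)
})

test_that("degenerate Max = Min scores 1 by convention, with a warning", {
  flat <- matrix(1, nrow = 4, ncol = 5)
  p <- pwm(flat)
  expect_warning(s <- mss(p, "ACGTA"), "degenerate")
  expect_equal(s, 1)
})

test_that("scan reports both strands and matches a per-window oracle", {
  p <- pwm(do.call(cbind, toy_pwm_counts()), name = "TOY")
  consensus <- pwm_consensus(p)  # GATTAC
  seq <- paste0("AAAAAAA", consensus, "AAAAAAA")
  hits <- scan_pwm(seq, p, core_cutoff = 1, matrix_cutoff = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 8L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matrix_score, 1)

  # the reverse-complemented sequence yields the mirrored hit
  hits_rc <- scan_pwm(revcomp(seq), p, 1, 1)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(nchar(seq) - (hits_rc$offset + 6 - 1) + 1, 8)

  # no consensus present + cutoffs 1 -> empty
  expect_equal(nrow(scan_pwm(strrep("A", 30), p, 1, 1)), 0L)

  # oracle: brute-force both strands of a random sequence at lower cutoffs
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  got <- scan_pwm(s, p, 0.6, 0.6)
  expected <- 0L
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else revcomp(s)
    for (o in 1:(21 - 6 + 1)) {
      w <- substr(str_seq, o, o + 5)
      if (brute_mss(p$freqs, p$info, w, p$core) >= 0.6 &&
          brute_mss(p$freqs, p$info, w, 1:6) >= 0.6)
        expected <- expected + 1L
    }
  }
  expect_equal(nrow(got), expected)
})

test_that("compare_alleles calls gain/loss at the SNP", {
  p <- pwm(do.call(cbind, toy_pwm_counts()), name = "TOY")
  consensus <- pwm_consensus(p)  # GATTAC, consensus base T at position 4
  # centre the motif's position 4 on the SNP at oligo position 11
  left <- paste0("AAAAAAA", substr(consensus, 1, 3))
  right <- paste0(substr(consensus, 5, 6), "AAAAAAAA")
  alt_oligo <- paste0(left, "T", right)   # carries the consensus
  ref_oligo <- paste0(left, "A", right)   # disrupts it (A is rare at pos 4)
  expect_equal(nchar(alt_oligo), 21L)
  res <- compare_alleles(ref_oligo, alt_oligo, p,
                         core_cutoff = 0.95, matrix_cutoff = 0.95)
  expect_identical(res$status, "gain")
  expect_gt(res$alt_best_matrix, res$ref_best_matrix)
  # a PWM matching neither allele reports no_change
  res2 <- compare_alleles(ref_oligo, alt_oligo, p, 1, 1)
  expect_identical(res2$status, if (res2$alt_hits > 0) "gain" else "no_change")
  # swapped roles give loss
  res3 <- compare_alleles(alt_oligo, ref_oligo, p, 0.95, 0.95)
  expect_identical(res3$status, "loss")
  expect_error(compare_alleles("AAA", "AAA", p), "exactly one")
  expect_error(compare_alleles("AAC", "CCA", p), "exactly one")
})
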