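make_index <- function() build_index(design_library(toy_candidates()))

test_that("the index maps both orientations and rejects collisions", {
  lib <- design_library(toy_candidates()[1, ])
  idx <- build_index(lib)
  expect_equal(length(idx$keys), 4L)  # 2 alleles x 2 orientations
  expect_setequal(idx$keys, c(lib$sequence, revcomp(lib$sequence)))

  # colliding templates -> error naming the culprits
  clash <- lib
  clash$sequence[2] <- clash$sequence[1]
  expect_error(build_index(clash), "collide")
  # reverse-complement collision is also a collision
  clash$sequence[2] <- revcomp(clash$sequence[1])
  expect_error(build_index(clash), "collide")
  expect_error(build_index(transform(lib, sequence = substr(sequence, 1, 20))),
               "21")
})

test_that("odd-length templates are never their own reverse complement", {
  # a reverse-complement palindrome needs a centre base equal to its own
  # complement, impossible for DNA, so at the enforced 21-nt template
  # length every template always contributes two distinct index keys
  s10 <- "ACGTACGTAC"
  near_pal <- paste0(s10, "T", revcomp(s10))
  expect_false(near_pal == revcomp(near_pal))
  lib <- data.frame(template_id = "p|reference", snp_id = "p",
                    allele_role = "reference", allele = "T",
                    sequence = near_pal, stringsAsFactors = FALSE)
  expect_equal(length(build_index(lib)$keys), 2L)
})

test_that("match_read implements perfect-match containment with ambiguity", {
  idx <- make_index()
  lib <- design_library(toy_candidates())
  t1 <- lib$sequence[1]
  read <- paste0("GGTTGGTTGGTTGG", t1, "TTGGTTGGTTGGTTG")
  expect_identical(match_read(read, idx), lib$template_id[1])
  # orientation symmetry
  expect_identical(match_read(revcomp(read), idx), lib$template_id[1])
  # no template present
  expect_identical(match_read(strrep("GT", 25), idx), "unmatched")
  # two distinct templates -> ambiguous
  both <- paste0(t1, lib$sequence[3])
  expect_identical(match_read(both, idx), "ambiguous")
  # same template twice is still a unique match
  twice <- paste0(t1, t1)
  expect_identical(match_read(twice, idx), lib$template_id[1])
  # short read warns and is unmatched
  expect_warning(r <- match_read("ACGT", idx), "shorter")
  expect_identical(r, "unmatched")
})

test_that("count_reads reproduces the simulator truth table at zero error", {
  x <- small_sim(n_snps = 6, depth = 4000, seed = 3,
                 test_background = 0.2, input_background = 0.05)
  tab <- count_reads(x$sim$samples, build_index(x$lib))
  expect_identical(tab$counts, x$sim$truth$counts)
  # per-sample accounting: matched + unmatched + ambiguous = raw
  expect_equal(tab$qc$matched + tab$qc$unmatched + tab$qc$ambiguous,
               tab$qc$raw)
  expect_equal(colSums(tab$counts), setNames(tab$qc$matched,
                                             tab$qc$sample_id))
  expect_equal(tab$qc$mappable_rate, tab$qc$matched / tab$qc$raw)
  # background fractions drive the mappable rates
  test_rows <- tab$qc$sample_id[x$sim$samples$role == "test"]
  expect_true(all(abs(tab$qc$mappable_rate[tab$qc$sample_id %in%
                                           test_rows] - 0.8) < 0.05))
})

test_that("counting is invariant under reverse-complementing every read", {
  x <- small_sim(n_snps = 4, depth = 1500, seed = 5)
  idx <- build_index(x$lib)
  samples <- x$sim$samples[1:2, ]
  tab <- count_reads(samples, idx)
  flipped <- samples
  for (i in seq_len(nrow(flipped))) {
    lines <- readLines(samples$fastq[i])
    seqs <- lines[seq(2, length(lines), by = 4)]
    lines[seq(2, length(lines), by = 4)] <- revcomp(seqs)
    path <- tempfile(fileext = ".fastq")
    writeLines(lines, path)
    flipped$fastq[i] <- path
  }
  tab2 <- count_reads(flipped, idx)
  expect_identical(tab$counts, tab2$counts)
})

test_that("sample sheet validation and degenerate FASTQ inputs", {
  idx <- make_index()
  empty_fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), empty_fq)
  sheet <- data.frame(sample_id = "s1", role = "input", treatment = "none",
                      replicate = 1L, fastq = empty_fq,
                      stringsAsFactors = FALSE)
  tab <- count_reads(sheet, idx)
  expect_true(all(tab$counts == 0L))
  expect_true(is.na(tab$qc$mappable_rate))

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("r1", "ACGT", "+", "IIII"), bad)  # missing @ header
  sheet$fastq <- bad
  expect_error(count_reads(sheet, idx), "malformed FASTQ")
  sheet$treatment <- "DHT"
  expect_error(count_reads(sheet, idx), "treatment 'none'")
  expect_error(count_reads(sheet[, -1], idx), "misses column")
})

test_that("replicate correlation is an R^2 on log2 counts", {
  x <- small_sim(n_snps = 50, depth = 100000, seed = 9, replicates = 2)
  tab <- count_reads(x$sim$samples, build_index(x$lib))
  # identical vectors give exactly 1; exact scaling is not exactly 1 on
  # log2(x+1) but a doubled library stays essentially perfectly correlated
  tab2 <- tab
  tab2$counts <- cbind(tab$counts, dbl = tab$counts[, "input_rep1"] * 2L)
  expect_equal(replicate_correlation(tab2, "input_rep1", "input_rep1"), 1)
  expect_gt(replicate_correlation(tab2, "input_rep1", "dbl"), 0.9999)
  # two technical replicates at assay-scale depth over 100 templates
  expect_gt(replicate_correlation(tab, "input_rep1", "input_rep2"), 0.97)
  expect_gt(replicate_correlation(tab, "dht_rep1", "dht_rep2"), 0.97)
  # zero variance errors
  tab2$counts <- cbind(tab2$counts, flat = rep(1L, nrow(tab2$counts)))
  expect_error(replicate_correlation(tab2, "input_rep1", "flat"),
               "zero variance")
})
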