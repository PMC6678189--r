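write_ann_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_annotations <- function() {
  data.frame(
    snp_id = sprintf("s%d", 1:10),
    regulome_rank = c("1a", "2b", "3a", "4", "5", "6", "7", "1f", "2a", "4"),
    marks = c("impact_modifier;motif_change;tf_bound",
              "impact_modifier;promoter_histone",
              "motif_change", "impact_modifier;motif_change;enhancer_histone",
              "eqtl", "", "tf_bound", "motif_change;tf_bound",
              "impact_modifier;motif_change;tf_bound;promoter_histone", ""),
    stringsAsFactors = FALSE)
}

test_that("annotation loading validates marks and ranks", {
  ann <- load_annotations(write_ann_tsv(toy_annotations()))
  expect_equal(nrow(ann), 10L)
  expect_equal(ann$regulome_class, c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 1L, 2L, 4L))
  # unknown mark -> rejected with diagnostic
  bad <- toy_annotations()
  bad$marks[3] <- "motif_change;super_mark"
  expect_warning(ann2 <- load_annotations(write_ann_tsv(bad)), "super_mark")
  expect_equal(nrow(ann2), 9L)
  expect_equal(attr(ann2, "rejected")$snp_id, "s3")
  # duplicate snp_id -> error
  dup <- rbind(toy_annotations(), toy_annotations()[1, ])
  expect_error(load_annotations(write_ann_tsv(dup)), "duplicate")
  # empty table -> empty map
  expect_equal(nrow(load_annotations(write_ann_tsv(toy_annotations()[0, ]))),
               0L)
  bad$marks[3] <- ""
  bad$regulome_rank[5] <- "8"
  expect_error(load_annotations(write_ann_tsv(bad)), "invalid")
})

test_that("funnel stages are nested and match hand-computed survivors", {
  ann <- load_annotations(write_ann_tsv(toy_annotations()))
  ids <- ann$snp_id
  res <- apply_funnel(ids, ann, default_funnel_rules())
  # stage 1: class <= 4 -> s1,s2,s3,s4,s8,s9,s10
  expect_setequal(res$stages$regulome_rank,
                  c("s1", "s2", "s3", "s4", "s8", "s9", "s10"))
  # stage 2: any functional mark -> drops s10 (no marks)
  expect_setequal(res$stages$functional_marks,
                  c("s1", "s2", "s3", "s4", "s8", "s9"))
  # stage 3: motif_change AND tf_bound -> s1, s8, s9
  expect_setequal(res$stages$motif_disruption, c("s1", "s8", "s9"))
  # monotone inclusion down the stages
  for (k in 2:length(res$stages))
    expect_true(all(res$stages[[k]] %in% res$stages[[k - 1]]))
  expect_equal(res$summary$n, c(10L, 7L, 6L, 3L))

  # permutation of input order does not change survivor sets
  res2 <- apply_funnel(rev(ids), ann, default_funnel_rules())
  for (k in seq_along(res$stages))
    expect_setequal(res2$stages[[k]], res$stages[[k]])

  # always-true stage leaves the input unchanged
  pass <- apply_funnel(ids, ann, list(funnel_rule("noop")))
  expect_setequal(pass$stages$noop, ids)
  # empty input survives as empty everywhere
  none <- apply_funnel(character(0), ann, default_funnel_rules())
  expect_true(all(lengths(none$stages) == 0L))
})

test_that("funnel agrees with a brute-force predicate oracle on random tables", {
  set.seed(99)
  for (rep in 1:3) {
    n <- 300
    ann <- data.frame(
      snp_id = sprintf("r%d", seq_len(n)),
      regulome_rank = sample(c("1a", "2b", "3a", "4", "5", "6", "7"), n, TRUE),
      marks = vapply(seq_len(n), function(i)
        paste(sample(ANNOTATION_MARKS, sample(0:4, 1)), collapse = ";"), ""),
      stringsAsFactors = FALSE)
    rules <- list(funnel_rule("rank", max_rank = 4),
                  funnel_rule("marks", required_marks = c("motif_change",
                                                          "tf_bound"),
                              match = "all"))
    res <- apply_funnel(ann$snp_id, load_annotations(write_ann_tsv(ann)),
                        rules)
    # oracle: row-by-row predicate evaluation
    cls <- as.integer(substr(ann$regulome_rank, 1, 1))
    m <- strsplit(ann$marks, ";")
    keep1 <- cls <= 4
    keep2 <- keep1 & vapply(m, function(x)
      all(c("motif_change", "tf_bound") %in% x), logical(1))
    expect_setequal(res$stages$rank, ann$snp_id[keep1])
    expect_setequal(res$stages$marks, ann$snp_id[keep2])
  }
})

test_that("rank comparator direction is configurable", {
  ann <- load_annotations(write_ann_tsv(toy_annotations()))
  geq <- apply_funnel(ann$snp_id, ann,
                      list(funnel_rule("rank", max_rank = 4,
                                       rank_direction = "geq")))
  expect_setequal(geq$stages$rank, c("s4", "s5", "s6", "s7", "s10"))
  expect_error(funnel_rule("bad", required_marks = "nonsense"), "unknown")
})

test_that("adding a positive mark never removes a SNP from a monotone stage", {
  ann <- load_annotations(write_ann_tsv(toy_annotations()))
  rules <- list(funnel_rule("marks", required_marks = c("eqtl", "tf_bound")))
  before <- apply_funnel(ann$snp_id, ann, rules)$stages$marks
  ann$marks[ann$snp_id == "s6"] <- "eqtl"
  after <- apply_funnel(ann$snp_id, ann, rules)$stages$marks
  expect_true(all(before %in% after))
})

test_that("motif gain/loss calls join as funnel marks", {
  ann <- load_annotations(write_ann_tsv(toy_annotations()))
  calls <- data.frame(snp_id = c("s5", "s6", "s7"),
                      status = c("gain", "no_change", "loss"),
                      stringsAsFactors = FALSE)
  ann2 <- join_motif_calls(ann, calls)
  has <- function(id, mark) grepl(mark, ann2$marks[ann2$snp_id == id])
  expect_true(has("s5", "motif_change") && has("s5", "tf_bound"))
  expect_false(grepl("motif_change", ann2$marks[ann2$snp_id == "s6"]))
  expect_true(has("s7", "motif_change"))
  expect_true(grepl("eqtl", ann2$marks[ann2$snp_id == "s5"]))  # kept
})
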