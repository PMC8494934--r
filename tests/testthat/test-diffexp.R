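test_that("layer threshold rules match the published cutoffs", {
  # transcripts: q < 0.05 and fold change beyond 1.25
  expect_true(deFlag(1.5, p = 0.2, q = 0.01, layer = "transcript"))
  expect_false(deFlag(1.2, p = 0.001, q = 0.001, layer = "transcript"))
  expect_true(deFlag(1 / 1.3, p = 0.2, q = 0.01, layer = "transcript"))
  # proteomics: raw p < 0.05 and fold change beyond 1.1
  expect_true(deFlag(1.15, p = 0.03, q = 0.9, layer = "phosphosite"))
  expect_true(deFlag(1.15, p = 0.03, q = 0.9, layer = "protein"))
  expect_false(deFlag(1.15, p = 0.06, q = 0.01, layer = "protein"))
  # no change is never DE, whatever the significance
  expect_false(deFlag(1.0, p = 1e-10, q = 1e-10, layer = "transcript"))
  expect_false(deFlag(1.0, p = 1e-10, q = 1e-10, layer = "protein"))
  expect_false(deFlag(Inf, p = 0.001, q = 0.001, layer = "protein"))
})

test_that("a constructed 12-feature proteomic table is called exactly", {
  si <- make_sample_info(n_per_group = 4L, timepoints = 15L)
  # features designed around the two parts of the rule: clean separation
  # (rank-sum p = 2/70) with FC beyond / inside the 1.1 band, and
  # non-separated features with any FC. Columns: 4 mock then 4 treated.
  mk_feat <- function(mock_vals, fc) rbind(c(mock_vals, mock_vals * fc))
  m <- rbind(
    mk_feat(c(100, 101, 99, 102), 2.0),    # f1  DE up
    mk_feat(c(100, 101, 99, 102), 0.5),    # f2  DE down
    mk_feat(c(100, 101, 99, 102), 1.05),   # f3  separated, FC in band
    mk_feat(c(100, 101, 99, 102), 1 / 1.05), # f4 separated, FC in band
    mk_feat(c(100, 101, 99, 102), 1.2),    # f5  DE up
    mk_feat(c(100, 101, 99, 102), 1 / 1.2), # f6 DE down
    rbind(c(100, 140, 90, 130, 95, 135, 99, 131)), # f7 interleaved: ns
    rbind(c(100, 120, 80, 110, 90, 125, 85, 115)), # f8 interleaved: ns
    mk_feat(c(50, 51, 49, 52), 1.5),       # f9  DE up
    mk_feat(c(50, 51, 49, 52), 3.0),       # f10 DE up
    rbind(c(200, 210, 190, 205, 198, 207, 195, 203)), # f11 mixed: ns
    mk_feat(c(10, 10.5, 9.5, 10.2), 1.08)  # f12 separated, FC in band
  )
  dimnames(m) <- list(sprintf("f%02d", 1:12), si$sample_id)
  de <- callDE(make_assay(m, layer = "protein", sampleInfo = si))
  expect_equal(de$feature_id[de$is_de],
               c("f01", "f02", "f05", "f06", "f09", "f10"))
  expect_equal(de$direction[de$is_de],
               c("up", "down", "up", "down", "up", "up"))
})

test_that("BH q-values match a direct step-up implementation", {
  set.seed(11)
  for (i in 1:5) {
    p <- stats::runif(50)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
  # and callDE uses exactly that correction within a timepoint
  si <- make_sample_info(n_per_group = 3L, timepoints = 15L)
  m <- matrix(stats::rlnorm(30 * 6, 5, 1), 30,
              dimnames = list(sprintf("f%02d", 1:30), si$sample_id))
  de <- callDE(make_assay(m, layer = "protein", sampleInfo = si))
  expect_equal(de$q, oracle_bh(de$p))
})

test_that("lowering the fold-change cutoff never shrinks the DE set", {
  set.seed(12)
  si <- make_sample_info(n_per_group = 4L, timepoints = c(15L, 30L))
  m <- matrix(stats::rlnorm(40 * nrow(si), 5, 0.6), 40,
              dimnames = list(sprintf("f%02d", 1:40), si$sample_id))
  a <- make_assay(m, layer = "protein", sampleInfo = si)
  loose <- callDE(a, thresholds = list(fc_cutoff = 1.05, alpha = 0.05,
                                       use_q = FALSE))
  tight <- callDE(a, thresholds = list(fc_cutoff = 1.3, alpha = 0.05,
                                       use_q = FALSE))
  expect_true(all(which(tight$is_de) %in% which(loose$is_de)))
})

test_that("the rank-sum default controls type I error on a synthetic null", {
  set.seed(13)
  si <- make_sample_info(n_per_group = 10L, timepoints = 15L)
  m <- matrix(stats::rlnorm(1000 * nrow(si), 6, 0.5), 1000,
              dimnames = list(sprintf("f%04d", 1:1000), si$sample_id))
  de <- callDE(make_assay(m, layer = "protein", sampleInfo = si))
  expect_gt(mean(de$p < 0.05), 0.03)
  expect_lt(mean(de$p < 0.05), 0.07)
})

test_that("missing-condition, heavy missingness and zero means are handled", {
  si <- make_sample_info(n_per_group = 3L, timepoints = 15L)
  m <- matrix(stats::rlnorm(12 * 6, 4, 0.3), 12,
              dimnames = list(sprintf("f%02d", 1:12), si$sample_id))
  mock_cols <- si$sample_id[si$treatment == "mock"]
  m["f01", mock_cols] <- 0                    # infinite fold change
  m["f02", mock_cols[1:2]] <- NA              # >50% of mock missing
  a <- make_assay(m, layer = "phosphosite", sampleInfo = si)
  expect_warning(de <- callDE(a), "infinite fold change")
  expect_equal(de$note[de$feature_id == "f01"], "infinite_fc")
  expect_false(de$is_de[de$feature_id == "f01"])
  expect_equal(de$note[de$feature_id == "f02"], "skipped_missing")
  # a timepoint lacking one condition entirely is an error
  si_bad <- si[si$treatment == "mock", ]
  expect_error(
    callDE(make_assay(m[, si_bad$sample_id], layer = "phosphosite",
                      sampleInfo = si_bad)),
    "lacks")
})

test_that("DE sets are partitioned by timepoint and direction", {
  de <- data.frame(
    feature_id = c("a", "b", "c", "a", "d"),
    timepoint_min = c(15L, 15L, 15L, 30L, 30L),
    fold_change = c(2, 3, 0.5, 2, 0.4),
    p = 0.01, q = 0.01,
    direction = c("up", "up", "down", "up", "down"),
    is_de = c(TRUE, TRUE, TRUE, TRUE, FALSE), note = "")
  sets <- deSetsByTimepoint(de)
  expect_equal(sets[["15"]]$up, c("a", "b"))
  expect_equal(sets[["15"]]$down, "c")
  expect_equal(sets[["30"]]$up, "a")  # DE at two timepoints -> both sets
  expect_length(deSetsByTimepoint(de[de$is_de == FALSE, ]), 0L)
})
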