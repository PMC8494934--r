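make_phospho <- function(values, si) make_assay(values, "phosphosite", si)

test_that("p-loop regulator selection applies interval and DE rules", {
  si <- make_sample_info(n_per_group = 2L, timepoints = c(15L, 30L))
  sites <- c("k1@S150", "k1@S139", "k2@S200", "k3@S50", "tfX@S10")
  an <- data.frame(feature_id = sites,
                   gene_id = c("k1", "k1", "k2", "k3", "tfX"),
                   layer = "phosphosite",
                   site_position = c(150L, 139L, 200L, 50L, 10L),
                   is_tf = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                   is_kinase = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  ploop <- data.frame(protein_id = c("k1", "k2"),
                      ploop_start = c(140L, 190L),
                      ploop_end = c(160L, 210L))
  m <- matrix(stats::rlnorm(5 * 8, 6, 0.3), 5,
              dimnames = list(sites, si$sample_id))
  de <- data.frame(feature_id = sites, timepoint_min = 15L,
                   fold_change = 2, p = 0.01, q = 0.01, direction = "up",
                   is_de = c(TRUE, TRUE, FALSE, TRUE, TRUE), note = "")
  expect_warning(
    regs <- selectPloopRegulators(de, make_phospho(m, si), an, ploop),
    "k3")
  # inside the interval and DE: selected; boundary-outside (139 < 140),
  # non-DE (k2 site) and non-kinase sites are excluded
  expect_equal(regs$feature_id, "k1@S150")
})

test_that("correlation thresholds keep the published OR rule", {
  si <- make_sample_info(n_per_group = 4L, timepoints = 15L)
  ids <- c("k1@S5", "a@S1", "b@S1", "c@S1")
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  m <- rbind(
    base,                                  # regulator
    base + c(0, .1, -.1, 0, .1, -.1, 0, .1),  # high pearson & spearman
    c(1, 2, 3, 4, 5, 6, 7, -20),          # monotone-ish spearman, low pearson
    c(8, 1, 6, 3, 2, 7, 4, 5))            # unrelated
  dimnames(m) <- list(ids, si$sample_id)
  # shift to positive intensities
  m <- m + 30
  an_cor <- stats::cor(t(designMatrix(make_phospho(m, si))))
  regs <- data.frame(feature_id = "k1@S5", gene_id = "k1",
                     site_position = 5L, site_label = "S5")
  de <- data.frame(feature_id = ids, timepoint_min = 15L, fold_change = 2,
                   p = 0.01, q = 0.01, direction = "up", is_de = TRUE,
                   note = "")
  net <- correlationEdges(regs, make_phospho(m, si), de)
  e <- edges(net)
  # kept iff pearson >= .5 OR spearman >= .6; self excluded
  sp <- stats::cor(t(designMatrix(make_phospho(m, si))),
                   method = "spearman")
  for (t1 in ids[-1]) {
    kept <- t1 %in% e$target
    expect_equal(kept, an_cor["k1@S5", t1] >= 0.5 |
                         sp["k1@S5", t1] >= 0.6)
  }
  expect_false("k1@S5" %in% e$target)
  expect_true(all(e$edge_type == "kinase"))
  expect_equal(e$weight,
               pmax(e$pearson, e$spearman))
})

test_that("a target identical to the regulator profile is kept with r = 1", {
  si <- make_sample_info(n_per_group = 4L, timepoints = 15L)
  m <- rbind(stats::rlnorm(8, 4, 0.5))
  m <- rbind(m, m)
  dimnames(m) <- list(c("k1@S5", "z@S9"), si$sample_id)
  regs <- data.frame(feature_id = "k1@S5", gene_id = "k1",
                     site_position = 5L, site_label = "S5")
  de <- data.frame(feature_id = rownames(m), timepoint_min = 15L,
                   fold_change = 2, p = 0.01, q = 0.01, direction = "up",
                   is_de = TRUE, note = "")
  e <- edges(correlationEdges(regs, make_phospho(m, si), de))
  expect_equal(e$target, "z@S9")
  expect_equal(e$weight, 1)
  # sites on the same protein are never linked
  rownames(m)[2] <- "k1@S99"
  de$feature_id <- rownames(m)
  e2 <- edges(correlationEdges(regs, make_phospho(m, si), de))
  expect_equal(nrow(e2), 0L)
})

test_that("the edge set equals brute-force recomputation and is anti-monotone", {
  set.seed(71)
  si <- make_sample_info(n_per_group = 2L, timepoints = c(15L, 30L, 60L))
  n_reg <- 10L; n_tgt <- 30L
  reg_ids <- sprintf("k%02d@S5", seq_len(n_reg))
  tgt_ids <- sprintf("t%02d@S1", seq_len(n_tgt))
  m <- matrix(stats::rlnorm((n_reg + n_tgt) * nrow(si), 5, 1),
              n_reg + n_tgt,
              dimnames = list(c(reg_ids, tgt_ids), si$sample_id))
  regs <- data.frame(feature_id = reg_ids,
                     gene_id = sprintf("k%02d", seq_len(n_reg)),
                     site_position = 5L, site_label = "S5")
  de <- data.frame(feature_id = rownames(m), timepoint_min = 15L,
                   fold_change = 2, p = 0.01, q = 0.01, direction = "up",
                   is_de = TRUE, note = "")
  ph <- make_phospho(m, si)
  net <- correlationEdges(regs, ph, de)
  kept <- paste(edges(net)$source, edges(net)$target)
  dm <- designMatrix(ph)
  expected <- character()
  for (r in reg_ids) for (t1 in rownames(m)) {
    if (nodeGene(r) == nodeGene(t1)) next
    rp <- stats::cor(dm[r, ], dm[t1, ])
    rs <- stats::cor(dm[r, ], dm[t1, ], method = "spearman")
    if (rp >= 0.5 || rs >= 0.6) expected <- c(expected, paste(r, t1))
  }
  expect_setequal(kept, expected)
  # raising either threshold never adds edges
  stricter <- correlationEdges(regs, ph, de, pearson_min = 0.7)
  expect_true(all(paste(edges(stricter)$source, edges(stricter)$target)
                  %in% kept))
  stricter2 <- correlationEdges(regs, ph, de, spearman_min = 0.8)
  expect_true(all(paste(edges(stricter2)$source, edges(stricter2)$target)
                  %in% kept))
})

test_that("activation-state diagnostics flag missing or short data", {
  si <- make_sample_info(n_per_group = 4L, timepoints = c(15L, 30L))
  prot <- matrix(stats::rlnorm(16, 6, 0.2), 1,
                 dimnames = list("k1", si$sample_id))
  site <- prot * 3  # proportional: correlation exactly 1
  rownames(site) <- "k1@S5"
  an <- data.frame(feature_id = c("k1", "k1@S5"), gene_id = "k1",
                   layer = c("protein", "phosphosite"),
                   site_position = c(NA, 5L), is_tf = FALSE,
                   is_kinase = TRUE)
  regs <- data.frame(feature_id = "k1@S5", gene_id = "k1",
                     site_position = 5L, site_label = "S5")
  rep1 <- activationStateReport(regs, make_assay(prot, "protein", si),
                                make_phospho(site, si), an)
  expect_equal(rep1$correlation, c(1, 1))
  # kinase absent from the abundance layer
  prot2 <- prot; rownames(prot2) <- "other"
  an2 <- an; an2$feature_id[1] <- "other"; an2$gene_id[1] <- "other"
  rep2 <- activationStateReport(regs, make_assay(prot2, "protein", si),
                                make_phospho(site, si),
                                an2)
  expect_true(all(rep2$note == "missing_abundance"))
})

test_that("independent profiles center the diagnostic near zero", {
  set.seed(72)
  si <- make_sample_info(n_per_group = 10L, timepoints = 15L)
  cors <- replicate(100, {
    a <- matrix(stats::rlnorm(20, 6, 0.5), 1,
                dimnames = list("k1", si$sample_id))
    s <- matrix(stats::rlnorm(20, 6, 0.5), 1,
                dimnames = list("k1@S5", si$sample_id))
    an <- data.frame(feature_id = c("k1", "k1@S5"), gene_id = "k1",
                     layer = c("protein", "phosphosite"),
                     site_position = c(NA, 5L), is_tf = FALSE,
                     is_kinase = TRUE)
    regs <- data.frame(feature_id = "k1@S5", gene_id = "k1",
                       site_position = 5L, site_label = "S5")
    activationStateReport(regs, make_assay(a, "protein", si),
                          make_phospho(s, si), an)$correlation
  })
  expect_lt(abs(mean(cors)), 0.1)
})
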