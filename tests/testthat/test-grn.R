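sim_keys <- design_keys(timepoints = c(15L, 30L, 60L), reps = 4L)

test_that("regulator matrix prefers protein and falls back to transcript", {
  si <- make_sample_info(n_per_group = 2L, timepoints = c(15L, 30L))
  an <- data.frame(
    feature_id = c("tf1", "tf2", "tf1", "tf2", "tf3", "g1"),
    gene_id = c("tf1", "tf2", "tf1", "tf2", "tf3", "g1"),
    layer = c("protein", "protein", "transcript", "transcript",
              "transcript", "transcript"),
    site_position = NA_integer_, is_tf = c(rep(TRUE, 5), FALSE),
    is_kinase = FALSE)
  prot <- matrix(stats::rlnorm(8), 1,
                 dimnames = list("tf1", si$sample_id))
  trans <- matrix(stats::rlnorm(4 * 8, 5, 1), 4,
                  dimnames = list(c("tf1", "tf2", "tf3", "g1"),
                                  si$sample_id))
  reg <- buildRegulatorMatrix(
    c("tf1", "tf2", "tf3"), transcript = make_assay(trans, "transcript", si),
    protein = make_assay(prot, "protein", si), annotation = an,
    mode = "abundance")
  info <- attr(reg, "info")
  expect_equal(info$source_layer[info$gene_id == "tf1"], "protein")
  expect_equal(info$source_layer[info$gene_id == "tf2"], "transcript")
  expect_equal(unname(reg["tf1", ]),
               unname(designMatrix(make_assay(prot, "protein",
                                              si))["tf1", ]))
  # a TF absent from every matrix is excluded with a warning naming it
  expect_warning(
    reg2 <- buildRegulatorMatrix(
      c("tf1", "tf9"), transcript = make_assay(trans, "transcript", si),
      annotation = an, mode = "abundance"),
    "tf9")
  expect_equal(rownames(reg2), "tf1")
})

test_that("phosphosite mode yields one regulator row per DE site", {
  si <- make_sample_info(n_per_group = 2L, timepoints = c(15L, 30L))
  sites <- c("tf1@S179", "tf1@S180", "tf2@S10")
  an <- data.frame(feature_id = sites, gene_id = c("tf1", "tf1", "tf2"),
                   layer = "phosphosite",
                   site_position = c(179L, 180L, 10L), is_tf = TRUE,
                   is_kinase = FALSE)
  ph <- matrix(stats::rlnorm(3 * 8, 6, 0.5), 3,
               dimnames = list(sites, si$sample_id))
  de <- data.frame(feature_id = c("tf1@S179", "tf1@S180", "tf2@S10"),
                   timepoint_min = 15L, fold_change = 2, p = 0.01,
                   q = 0.01, direction = "up",
                   is_de = c(TRUE, TRUE, FALSE), note = "")
  reg <- buildRegulatorMatrix("tf1", phospho = make_assay(ph, "phosphosite",
                                                          si),
                              annotation = an, mode = "phosphosite",
                              de_table = de)
  expect_setequal(rownames(reg), c("tf1@S179", "tf1@S180"))
  expect_equal(attr(reg, "info")$site_label, c("S179", "S180"))
})

test_that("importance concentrates on an informative regulator", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    target <- stats::rnorm(24)
    regs <- rbind(target, matrix(stats::rnorm(5 * 24), 5))
    rownames(regs) <- c("true", sprintf("noise%d", 1:5))
    w <- importanceScores(target, regs, nTrees = 500L, seed = s)
    if (names(which.max(w)) == "true") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("importance weights obey their contracts", {
  set.seed(31)
  target <- stats::rnorm(24)
  regs <- rbind(a = target + stats::rnorm(24, 0, 0.1),
                b = stats::rnorm(24), const = rep(2, 24))
  w <- importanceScores(target, regs, nTrees = 300L, seed = 1)
  expect_equal(sum(w), 1)
  expect_equal(unname(w["const"]), 0)
  # invariant to regulator row order
  w2 <- importanceScores(target, regs[c(3, 1, 2), ], nTrees = 300L,
                         seed = 1)
  expect_equal(w, w2[names(w)])
  # constant target: all-zero, flagged
  wz <- importanceScores(rep(1, 24), regs, nTrees = 100L, seed = 1)
  expect_true(all(wz == 0))
  expect_true(attr(wz, "flagged"))
  expect_error(importanceScores(stats::rnorm(6), regs[, 1:6]), "8 samples")
})

test_that("lag alignment pairs regulator samples one step earlier", {
  keys <- design_keys(timepoints = c(15L, 30L, 60L), reps = 2L)
  m <- matrix(seq_along(keys), 1, dimnames = list("r", keys))
  al <- lagAlign(m, m, lagSteps = 1L)
  expect_equal(ncol(al$regulators), ncol(al$targets))
  # every target column's regulator partner is the same condition and
  # replicate at the previous timepoint
  tkeys <- colnames(al$targets)
  rkeys <- keys[al$regulators[1, ]]
  expect_equal(sub("_t0*[0-9]+_", "_", rkeys),
               sub("_t0*[0-9]+_", "_", tkeys))
  tp_t <- as.integer(sub("^.*_t0*([0-9]+)_r.*$", "\\1", tkeys))
  tp_r <- as.integer(sub("^.*_t0*([0-9]+)_r.*$", "\\1", rkeys))
  expect_true(all(tp_r < tp_t))
  expect_false(any(tp_t == 15L))
  al0 <- lagAlign(m, m, lagSteps = 0L)
  expect_identical(al0$regulators, m)
})

test_that("subnetworks respect clusters, DE sets and self-exclusion", {
  set.seed(32)
  keys <- sim_keys
  reg <- matrix(stats::rlnorm(3 * length(keys), 6, 0.5), 3,
                dimnames = list(c("tfA", "tfB", "tfC"), keys))
  tgt <- matrix(stats::rlnorm(3 * length(keys), 6, 0.5), 3,
                dimnames = list(c("g1", "g2", "tfA"), keys))
  tgt["g1", ] <- reg["tfB", ]  # perfectly correlated, different cluster
  attr(reg, "mode") <- "abundance"
  attr(reg, "info") <- data.frame(row_id = rownames(reg),
                                  gene_id = rownames(reg),
                                  source_layer = "protein",
                                  site_label = NA_character_)
  reg_cl <- c(tfA = 1L, tfB = 2L, tfC = 1L)
  tgt_cl <- c(g1 = 1L, g2 = 1L, tfA = 1L)
  net <- suppressWarnings(inferSubnetwork(
    reg, tgt, reg_cl, tgt_cl,
    de_regulators = c("tfA", "tfB", "tfC"),
    de_targets = c("g1", "g2", "tfA"), timepoint = 15L,
    nTrees = 300L, seed = 1))
  e <- edges(net)
  # no edge from the out-of-cluster tfB, even at correlation 1
  expect_false(any(e$source == "tfB"))
  # no self-edges (tfA regulating tfA's transcript)
  expect_false(any(e$source == e$target))
  for (i in seq_len(nrow(e)))
    expect_equal(unname(reg_cl[e$source[i]]), unname(tgt_cl[e$target[i]]))
  # empty DE sets give an empty network with a warning
  expect_warning(
    empty <- inferSubnetwork(reg, tgt, reg_cl, tgt_cl, character(),
                             character(), 15L),
    "empty")
  expect_equal(nEdges(empty), 0L)
})

test_that("a planted two-regulator target dominates the importance ranking", {
  keys <- design_keys()
  top2 <- both_loose <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    reg <- matrix(stats::rlnorm(6 * length(keys), 6, 0.4), 6,
                  dimnames = list(sprintf("tf%d", 1:6), keys))
    y <- 2^(log2(reg["tf1", ]) * 0.5 + log2(reg["tf2", ]) * 0.5 +
              stats::rnorm(length(keys), 0, 0.1))
    tgt <- matrix(y, 1, dimnames = list("g1", keys))
    attr(reg, "mode") <- "abundance"
    attr(reg, "info") <- data.frame(row_id = rownames(reg),
                                    gene_id = rownames(reg),
                                    source_layer = "protein",
                                    site_label = NA_character_)
    cl1 <- stats::setNames(rep(1L, 6), rownames(reg))
    w <- importanceScores(log2(y + 1), log2(reg + 1), nTrees = 500L,
                          seed = s)
    if (setequal(names(sort(w, decreasing = TRUE))[1:2],
                 c("tf1", "tf2"))) top2 <- top2 + 1L
    # an above-mean retention rule keeps both planted regulators even
    # when the importance mass splits unevenly between them
    net <- inferSubnetwork(reg, tgt, cl1, c(g1 = 1L),
                           de_regulators = rownames(reg),
                           de_targets = "g1", timepoint = 15L,
                           nTrees = 500L, seed = s, thresholdSD = 0,
                           lagSteps = 0L)
    if (all(c("tf1", "tf2") %in% edges(net)$source))
      both_loose <- both_loose + 1L
  }
  expect_gte(top2, 8L)
  expect_gte(both_loose, 8L)
})

test_that("merging networks is a union that preserves timepoints", {
  n1 <- random_network(3, seed = 51)
  expect_equal(edges(mergeNetworks(n1)), edges(n1))
  # disjoint unions add up
  e2 <- edges(random_network(4, seed = 52, genes = sprintf("h%d", 1:9)))
  n2 <- GRNetwork(e2)
  expect_equal(nEdges(mergeNetworks(n1, n2)), 7L)
  # same pair at two timepoints: two records
  a <- GRNetwork(data.frame(source = "x", target = "y", weight = 0.5,
                            edge_type = "abundance", timepoint = 15L))
  b <- GRNetwork(data.frame(source = "x", target = "y", weight = 0.7,
                            edge_type = "abundance", timepoint = 30L))
  m <- mergeNetworks(a, b)
  expect_equal(nEdges(m), 2L)
  expect_setequal(edges(m)$timepoint, c(15L, 30L))
  # idempotent and order-invariant on random triples
  for (s in 1:5) {
    nets <- lapply(1:3, function(i) random_network(6, seed = 60 + 3 * s + i))
    m1 <- mergeNetworks(nets)
    expect_equal(edges(mergeNetworks(m1, m1)), edges(m1))
    expect_equal(edges(mergeNetworks(nets[c(3, 1, 2)])), edges(m1))
    keys <- unlist(lapply(nets, function(n) {
      e <- edges(n); paste(e$source, e$target, e$edge_type, e$timepoint)
    }))
    expect_equal(nEdges(m1), length(unique(keys)))
  }
})
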