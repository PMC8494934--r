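#' Configuration for the synthetic multi-omic time course
#'
#' Describes a two-condition (mock vs treated), multi-replicate time course
#' with a planted signaling cascade: kinase activation-loop phosphosites
#' follow smooth saturating activation curves, transcription-factor
#' phosphosites respond to their planted upstream kinase, and target
#' transcripts respond to their planted TF regulators with a delay of
#' `lag_steps` timepoints. Replicate noise is multiplicative log-normal.
#'
#' @param n_kinases,n_tfs,n_targets numbers of kinases, TFs and target
#'   transcripts (defaults 5, 10, 100).
#' @param regulators_per_target inclusive integer range of planted TF
#'   regulators per target (default `c(1, 3)`).
#' @param timepoints_min strictly increasing sampling times in minutes
#'   (default 15, 30, 60, 120, 240, 480).
#' @param replicates replicates per condition per timepoint (default 4).
#' @param noise_sd multiplicative replicate noise: sd of the log2-scale
#'   Gaussian noise term (default 0.2, roughly 15 percent CV).
#' @param lag_steps timepoint lag between TF activity and target transcript
#'   response (default 1).
#' @param n_bystanders flat (null) background features added to every
#'   layer (default 30). They are drawn at high abundance so that, as in
#'   real data, unchanged bulk signal dominates library/loading totals.
#' @param batch_sd log-scale sd of the per-batch multiplicative offset
#'   injected into the proteomic layers (default 0.3).
#' @param seed integer seed; all generator randomness flows from it.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(n_kinases = 5L, n_tfs = 10L, n_targets = 100L,
                      regulators_per_target = c(1L, 3L),
                      timepoints_min = c(15L, 30L, 60L, 120L, 240L, 480L),
                      replicates = 4L, noise_sd = 0.2, lag_steps = 1L,
                      n_bystanders = 30L, batch_sd = 0.3, seed = 1L) {
  stopifnot(n_kinases >= 1L, n_tfs >= 1L, n_targets >= 1L,
            replicates >= 1L, noise_sd >= 0, lag_steps >= 0L,
            n_bystanders >= 0L,
            length(regulators_per_target) == 2L,
            regulators_per_target[1L] >= 1L,
            regulators_per_target[1L] <= regulators_per_target[2L],
            all(diff(timepoints_min) > 0))
  structure(list(n_kinases = as.integer(n_kinases),
                 n_tfs = as.integer(n_tfs),
                 n_targets = as.integer(n_targets),
                 regulators_per_target = as.integer(regulators_per_target),
                 timepoints_min = as.integer(timepoints_min),
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, lag_steps = as.integer(lag_steps),
                 n_bystanders = as.integer(n_bystanders),
                 batch_sd = batch_sd, seed = as.integer(seed)),
            class = "SimConfig")
}

# activation pulse: log-time Gaussian bump, peak scaled to 1. tpk is the
# peak time (min), sw the width in log-time units: small sw gives a
# transient spike, large sw a sustained response. The diversity of onset
# times and widths across regulators is what makes them separable.
.pulse <- function(t, tpk, sw) {
  a <- exp(-(log(t) - log(tpk))^2 / (2 * sw^2))
  a / max(a)
}

#' Simulate a multi-omic time course with a planted cascade
#'
#' Generates transcript, protein and phosphosite assays for the design in
#' `config`, together with sample metadata, feature annotation, a p-loop
#' coordinate table, and the ground truth needed to score edge recovery.
#' The cascade is: each kinase's activation-loop site follows its own
#' activation pulse under treatment (mock stays flat); each TF's
#' phosphosite is a signed response to its planted kinase; each target
#' transcript is a signed linear response to its planted TF regulators,
#' delayed by `lag_steps` timepoints. A subset of TFs is also quantified
#' at the protein level (to exercise the protein-else-transcript regulator
#' rule); kinase protein abundance and `n_bystanders` transcripts are flat
#' nulls. Proteomic samples are split across replicate-wise isobaric
#' batches, each carrying two pooled reference channels and a
#' multiplicative batch offset, so the normalization steps are exercised.
#' Deterministic given `config$seed`.
#'
#' @param config a [simConfig()].
#' @return list: `transcript`, `protein`, `phosphosite`
#'   ([OmicsAssay-class]), `sampleInfo`, `annotation`, `ploop`, `truth`.
#'   `truth` holds the planted edge list, the feature id sets, and the
#'   noise-free per-timepoint log2 treated/mock ratios per layer.
#' @export
simulateMultiomics <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  tps <- config$timepoints_min
  nt <- length(tps)
  reps <- config$replicates
  kin <- sprintf("K%02d", seq_len(config$n_kinases))
  tfs <- sprintf("F%02d", seq_len(config$n_tfs))
  tgt <- sprintf("G%03d", seq_len(config$n_targets))
  bys <- if (config$n_bystanders)
    sprintf("N%03d", seq_len(config$n_bystanders)) else character()

  # kinase activation curves and activation-loop sites: kinases act early
  k_tpk <- exp(stats::runif(config$n_kinases, log(12), log(120)))
  k_sw <- stats::runif(config$n_kinases, 0.3, 0.6)
  k_amp <- stats::runif(config$n_kinases, 1.5, 2.5)
  k_act <- vapply(seq_along(kin),
                  function(i) .pulse(tps, k_tpk[i], k_sw[i]),
                  numeric(nt))
  k_pos <- sample(150:400, config$n_kinases, replace = TRUE)
  k_site <- sprintf("%s@S%d", kin, k_pos)
  k_null_pos <- k_pos + sample(c(-120L, 120L), config$n_kinases,
                               replace = TRUE)
  k_null_site <- sprintf("%s@S%d", kin, k_null_pos)

  # TFs: planted upstream kinase; activity pulses peak later than the
  # kinase, with onsets spread across the whole time course (the waves of
  # early and late regulators typical of hormone responses)
  tf_kin <- sample(seq_len(config$n_kinases), config$n_tfs,
                   replace = TRUE)
  qs <- (sample(config$n_tfs) - 0.5) / config$n_tfs
  tf_tpk <- pmax(exp(log(tps[1L]) +
                       qs * (log(tps[nt]) - log(tps[1L])) +
                       stats::runif(config$n_tfs, -0.15, 0.15)),
                 k_tpk[tf_kin] * 1.2)
  tf_sw <- stats::runif(config$n_tfs, 0.25, 0.55)
  tf_sign <- sample(c(-1, 1), config$n_tfs, replace = TRUE)
  tf_amp <- stats::runif(config$n_tfs, 1, 2)
  tf_act <- vapply(seq_along(tfs),
                   function(i) .pulse(tps, tf_tpk[i], tf_sw[i]),
                   numeric(nt))
  tf_pos <- sample(50:500, config$n_tfs, replace = TRUE)
  tf_site <- sprintf("%s@S%d", tfs, tf_pos)
  tf_has_protein <- seq_len(config$n_tfs) <=
    max(1L, floor(0.7 * config$n_tfs))

  # planted TF -> target wiring, delayed by lag_steps
  lag_act <- rbind(matrix(0, config$lag_steps, config$n_tfs),
                   tf_act)[seq_len(nt), , drop = FALSE]
  planted <- vector("list", config$n_targets)
  tgt_resp <- matrix(0, nt, config$n_targets)
  for (g in seq_len(config$n_targets)) {
    nr <- sample(seq(config$regulators_per_target[1L],
                     config$regulators_per_target[2L]), 1L)
    regs <- sample(seq_len(config$n_tfs), min(nr, config$n_tfs))
    sg <- sample(c(-1, 1), length(regs), replace = TRUE)
    w <- stats::runif(length(regs), 1, 2)
    planted[[g]] <- data.frame(source = tfs[regs], target = tgt[g],
                               sign = sg, weight = w)
    tgt_resp[, g] <- lag_act[, regs, drop = FALSE] %*% (sg * w)
  }

  # sample layout: transcripts on their own platform; proteomics in
  # replicate-wise isobaric batches with two pooled references each
  grid <- expand.grid(replicate = seq_len(reps), timepoint_min = tps,
                      treatment = c("mock", "treated"),
                      stringsAsFactors = FALSE)
  rna_ids <- sprintf("rna_%s_t%03d_r%d", grid$treatment,
                     grid$timepoint_min, grid$replicate)
  tmt_ids <- sprintf("tmt_%s_t%03d_r%d", grid$treatment,
                     grid$timepoint_min, grid$replicate)
  tmt_batch <- sprintf("tmt_run%d", grid$replicate)
  ref_grid <- expand.grid(ref = 1:2, replicate = seq_len(reps))
  ref_ids <- sprintf("tmt_ref_run%d_%d", ref_grid$replicate, ref_grid$ref)
  si <- rbind(
    data.frame(sample_id = rna_ids, treatment = grid$treatment,
               timepoint_min = grid$timepoint_min,
               replicate = grid$replicate, batch = "rnaseq",
               channel = as.character(seq_along(rna_ids)),
               is_reference = FALSE),
    data.frame(sample_id = tmt_ids, treatment = grid$treatment,
               timepoint_min = grid$timepoint_min,
               replicate = grid$replicate, batch = tmt_batch,
               channel = as.character(seq_along(tmt_ids)),
               is_reference = FALSE),
    data.frame(sample_id = ref_ids, treatment = NA_character_,
               timepoint_min = tps[1L], replicate = ref_grid$ref,
               batch = sprintf("tmt_run%d", ref_grid$replicate),
               channel = paste0("ref", ref_grid$ref),
               is_reference = TRUE))

  tp_idx <- match(grid$timepoint_min, tps)
  treated <- grid$treatment == "treated"
  noise <- function(n) 2^stats::rnorm(n, 0, config$noise_sd)

  # expand a (feature x timepoint) log2 mean surface into sample columns
  expand_layer <- function(base, resp) {
    mu <- matrix(rep(base, length(tp_idx)), nrow = length(base))
    mu <- mu + t(resp)[, tp_idx, drop = FALSE] %*%
      diag(as.numeric(treated), length(tp_idx))
    2^mu * matrix(noise(length(mu)), nrow = nrow(mu))
  }

  # --- transcript layer: TF transcripts + targets + bystanders ---
  # bystanders sit at high abundance so that library totals are dominated
  # by unchanged signal, as in real data
  tr_ids <- c(tfs, tgt, bys)
  tr_base <- c(stats::runif(length(tfs) + length(tgt), 7, 12),
               stats::runif(length(bys), 13, 16))
  tr_resp <- cbind(
    vapply(seq_along(tfs),
           function(i) 0.7 * tf_sign[i] * tf_amp[i] * tf_act[, i],
           numeric(nt)),
    tgt_resp,
    matrix(0, nt, length(bys)))
  tr <- expand_layer(tr_base, tr_resp)
  dimnames(tr) <- list(tr_ids, rna_ids)

  # --- proteomic layers share a true surface, then batches + refs ---
  batch_fac <- stats::setNames(exp(stats::rnorm(reps, 0,
                                                config$batch_sd)),
                               sprintf("tmt_run%d", seq_len(reps)))
  tmt_layer <- function(ids, base, resp) {
    m <- expand_layer(base, resp)
    dimnames(m) <- list(ids, tmt_ids)
    pooled <- exp(rowMeans(log(2^(base +
      t(resp)[, tp_idx, drop = FALSE] %*%
        diag(as.numeric(treated), length(tp_idx))))))
    refs <- matrix(rep(pooled, length(ref_ids)), nrow = length(ids)) *
      matrix(noise(length(ids) * length(ref_ids)), nrow = length(ids))
    colnames(refs) <- ref_ids
    m <- cbind(m, refs)
    for (b in names(batch_fac)) {
      cols <- si$sample_id[si$batch == b]
      m[, cols] <- m[, cols, drop = FALSE] * batch_fac[b]
    }
    m
  }

  bys_prot <- if (config$n_bystanders)
    sprintf("P%03d", seq_len(config$n_bystanders)) else character()
  pr_ids <- c(tfs[tf_has_protein], kin, bys_prot)
  pr_base <- c(stats::runif(sum(tf_has_protein) + config$n_kinases,
                            9, 13),
               stats::runif(length(bys_prot), 12, 15))
  pr_resp <- cbind(
    vapply(which(tf_has_protein),
           function(i) tf_sign[i] * tf_amp[i] * tf_act[, i],
           numeric(nt)),
    matrix(0, nt, config$n_kinases + length(bys_prot)))
  pr <- tmt_layer(pr_ids, pr_base, pr_resp)

  bys_site <- if (config$n_bystanders)
    sprintf("X%03d@S100", seq_len(config$n_bystanders)) else character()
  ph_ids <- c(k_site, k_null_site, tf_site, bys_site)
  ph_base <- c(stats::runif(2L * config$n_kinases + config$n_tfs, 9, 13),
               stats::runif(length(bys_site), 12, 15))
  ph_resp <- cbind(
    vapply(seq_along(kin), function(i) k_amp[i] * k_act[, i],
           numeric(nt)),
    matrix(0, nt, config$n_kinases),
    vapply(seq_along(tfs),
           function(i) tf_sign[i] * tf_amp[i] * tf_act[, i],
           numeric(nt)),
    matrix(0, nt, length(bys_site)))
  ph <- tmt_layer(ph_ids, ph_base, ph_resp)

  annotation <- rbind(
    data.frame(feature_id = tr_ids, gene_id = tr_ids,
               layer = "transcript", site_position = NA_integer_,
               is_tf = tr_ids %in% tfs, is_kinase = FALSE),
    data.frame(feature_id = pr_ids, gene_id = pr_ids, layer = "protein",
               site_position = NA_integer_, is_tf = pr_ids %in% tfs,
               is_kinase = pr_ids %in% kin),
    data.frame(feature_id = ph_ids,
               gene_id = nodeGene(ph_ids), layer = "phosphosite",
               site_position = as.integer(sub("^.*@S", "", ph_ids)),
               is_tf = nodeGene(ph_ids) %in% tfs,
               is_kinase = nodeGene(ph_ids) %in% kin))

  ploop <- data.frame(protein_id = kin, ploop_start = k_pos - 15L,
                      ploop_end = k_pos + 15L)

  truth_edges <- rbind(
    data.frame(source = k_site[tf_kin], target = tf_site,
               sign = tf_sign, weight = tf_amp, type = "kinase_tf"),
    cbind(do.call(rbind, planted), type = "tf_target"))
  truth <- list(
    edges = truth_edges, config = config,
    kinases = kin, tfs = tfs, targets = tgt, bystanders = bys,
    kinase_sites = k_site, tf_sites = tf_site,
    response = list(
      transcript = t(tr_resp) |>
        (\(m) { dimnames(m) <- list(tr_ids, tps); m })(),
      protein = t(pr_resp) |>
        (\(m) { dimnames(m) <- list(pr_ids, tps); m })(),
      phosphosite = t(ph_resp) |>
        (\(m) { dimnames(m) <- list(ph_ids, tps); m })()))

  list(transcript = OmicsAssay(tr, "transcript", si),
       protein = OmicsAssay(pr, "protein", si),
       phosphosite = OmicsAssay(ph, "phosphosite", si),
       sampleInfo = validateSampleInfo(si), annotation = annotation,
       ploop = ploop, truth = truth)
}

#' Score recovery of the planted edges
#'
#' Compares a ranked edge list with the planted truth over the full
#' candidate universe (every possible regulator-target gene pair of the
#' requested edge class; candidates absent from the ranking are treated as
#' tied at the bottom with weight 0). Precision-recall and ROC areas are
#' tie-aware (trapezoidal over tie groups / midrank U statistic).
#'
#' @param network a [GRNetwork-class] or data.frame with `source`,
#'   `target`, `weight`; source labels may carry `@site` suffixes, which
#'   are reduced to genes, keeping the best weight per gene pair.
#' @param truth truth component of [simulateMultiomics()].
#' @param type `"tf_target"` or `"kinase_tf"`: which planted edge class to
#'   score.
#' @return list: `aupr`, `auroc`, `prevalence`, `n_pairs`,
#'   `median_planted_rank`.
#' @export
evaluateRecovery <- function(network, truth, type = "tf_target") {
  e <- if (is(network, "GRNetwork")) edges(network) else network
  pos <- truth$edges[truth$edges$type == type, , drop = FALSE]
  if (!nrow(pos)) stop("truth contains no planted edges of type ", type)
  if (type == "tf_target") {
    srcs <- truth$tfs; tgts <- truth$targets
    pos_key <- paste(nodeGene(pos$source), pos$target)
  } else {
    srcs <- truth$kinases; tgts <- truth$tfs
    pos_key <- paste(nodeGene(pos$source), nodeGene(pos$target))
  }
  univ <- expand.grid(source = srcs, target = tgts,
                      stringsAsFactors = FALSE)
  univ <- univ[univ$source != univ$target, , drop = FALSE]
  key <- paste(univ$source, univ$target)
  w <- stats::setNames(rep(0, nrow(univ)), key)
  if (nrow(e)) {
    ek <- paste(nodeGene(e$source), nodeGene(e$target))
    for (i in order(e$weight)) w[ek[i]] <- max(w[ek[i]], e$weight[i],
                                               na.rm = TRUE)
    w <- w[key]; w[is.na(w)] <- 0
  }
  is_pos <- key %in% pos_key
  P <- sum(is_pos); N <- sum(!is_pos)
  if (!P) stop("no planted edge lies in the candidate universe")
  # tie-aware PR curve: walk decreasing weight groups
  o <- order(-w)
  ws <- w[o]; ps <- is_pos[o]
  bounds <- cumsum(rle(ws)$lengths)
  tp <- cumsum(ps)[bounds]
  fp <- cumsum(!ps)[bounds]
  rec <- c(0, tp / P)
  prec <- c(tp[1L] / (tp[1L] + fp[1L]), tp / (tp + fp))
  aupr <- sum(diff(rec) * (utils::head(prec, -1L) + prec[-1L]) / 2)
  r <- rank(w)  # midranks
  auroc <- (sum(r[is_pos]) - P * (P + 1) / 2) / (P * N)
  rank_desc <- rank(-w)
  list(aupr = aupr, auroc = auroc, prevalence = P / (P + N),
       n_pairs = P + N,
       median_planted_rank = stats::median(rank_desc[is_pos]))
}
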