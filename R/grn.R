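#' Feature-by-design matrix over the shared sample design
#'
#' Reference channels are dropped and columns are renamed to the design key
#' `treatment_t<minutes>_r<replicate>` and sorted, so that matrices from
#' different platforms (with platform-specific sample ids) can be aligned
#' column-for-column in a regression.
#'
#' @param x an [OmicsAssay-class].
#' @return numeric matrix, features x design keys.
#' @export
designMatrix <- function(x) {
  stopifnot(is(x, "OmicsAssay"))
  m <- assay(x)
  si <- sampleInfo(x)
  keep <- !si$is_reference
  m <- m[, keep, drop = FALSE]
  si <- si[keep, , drop = FALSE]
  key <- sprintf("%s_t%03d_r%d", si$treatment, si$timepoint_min,
                 si$replicate)
  o <- order(si$treatment, si$timepoint_min, si$replicate)
  m <- m[, o, drop = FALSE]
  colnames(m) <- key[o]
  m
}

#' Assemble the regulator matrix for network inference
#'
#' In `abundance` mode each transcription factor contributes one row: its
#' protein abundance when the cognate protein was quantified, otherwise its
#' transcript abundance; TFs absent from both layers are excluded with a
#' warning. In `phosphosite` mode each differentially expressed phosphosite
#' of a TF contributes one row, labeled `gene@site`, so that several sites
#' of one TF are separate candidate regulators.
#'
#' @param tf_genes character vector of TF gene ids.
#' @param transcript,protein,phospho [OmicsAssay-class] objects sharing the
#'   sample design (`protein`/`phospho` optional per mode).
#' @param annotation feature-annotation data.frame
#'   (see [validateFeatureAnnotation()]).
#' @param mode `"abundance"` or `"phosphosite"`.
#' @param de_table phosphosite DE table ([callDE()]); required in
#'   `phosphosite` mode (only sites DE at >= 1 timepoint become regulators).
#' @return numeric matrix (regulators x design keys) with attributes `mode`
#'   and `info` (data.frame: `row_id`, `gene_id`, `source_layer`,
#'   `site_label`).
#' @export
buildRegulatorMatrix <- function(tf_genes, transcript = NULL,
                                 protein = NULL, phospho = NULL,
                                 annotation, mode = c("abundance",
                                                      "phosphosite"),
                                 de_table = NULL) {
  mode <- match.arg(mode)
  if (!length(tf_genes)) stop("tf_genes must be non-empty")
  rows <- list(); info <- list()
  if (mode == "abundance") {
    dm_p <- if (!is.null(protein)) designMatrix(protein)
    dm_t <- if (!is.null(transcript)) designMatrix(transcript)
    if (!is.null(dm_p) && !is.null(dm_t) &&
        !identical(colnames(dm_p), colnames(dm_t)))
      stop("protein and transcript matrices do not share the sample design")
    missing_tfs <- character()
    for (tf in tf_genes) {
      pf <- .features_of(annotation, tf, "protein")
      tfeat <- .features_of(annotation, tf, "transcript")
      if (!is.null(dm_p) && length(pf) && pf[1L] %in% rownames(dm_p)) {
        rows[[tf]] <- dm_p[pf[1L], ]
        info[[tf]] <- c(tf, tf, "protein", NA)
      } else if (!is.null(dm_t) && length(tfeat) &&
                 tfeat[1L] %in% rownames(dm_t)) {
        rows[[tf]] <- dm_t[tfeat[1L], ]
        info[[tf]] <- c(tf, tf, "transcript", NA)
      } else missing_tfs <- c(missing_tfs, tf)
    }
    if (length(missing_tfs))
      warning("TF(s) quantified in no layer, excluded: ",
              paste(missing_tfs, collapse = ", "))
  } else {
    if (is.null(phospho) || is.null(de_table))
      stop("phosphosite mode needs the phospho assay and its DE table")
    dm <- designMatrix(phospho)
    de_sites <- unique(de_table$feature_id[de_table$is_de])
    an <- annotation[annotation$layer == "phosphosite" &
                     annotation$gene_id %in% tf_genes &
                     annotation$feature_id %in% de_sites &
                     annotation$feature_id %in% rownames(dm), ,
                     drop = FALSE]
    for (i in seq_len(nrow(an))) {
      fid <- an$feature_id[i]
      rid <- if (grepl("@", fid, fixed = TRUE)) fid
             else paste0(an$gene_id[i], "@", an$site_position[i])
      rows[[rid]] <- dm[fid, ]
      info[[rid]] <- c(rid, an$gene_id[i], "phosphosite",
                       sub("^.*@", "", rid))
    }
  }
  if (!length(rows)) stop("no usable regulators; regulator matrix is empty")
  out <- do.call(rbind, rows)
  rownames(out) <- names(rows)
  inf <- as.data.frame(do.call(rbind, info), stringsAsFactors = FALSE)
  colnames(inf) <- c("row_id", "gene_id", "source_layer", "site_label")
  rownames(inf) <- NULL
  attr(out, "mode") <- mode
  attr(out, "info") <- inf
  out
}

.features_of <- function(annotation, gene, layer) {
  annotation$feature_id[annotation$gene_id == gene &
                        annotation$layer == layer]
}

#' Tree-ensemble regulator importance for one target
#'
#' Regresses the target's expression profile on the candidate regulators'
#' profiles with an ensemble of Extra-Trees regression trees (randomized
#' split points, `mtry = ceiling(sqrt(p))` candidate predictors per split,
#' impurity importance) and returns each regulator's total
#' variance-reduction importance normalized to sum to one. Regulator rows
#' are sorted internally so the result does not depend on their input
#' order; a fixed seed makes it reproducible. A constant target yields
#' all-zero weights with attribute `flagged = TRUE`.
#'
#' @param target numeric profile over the samples (length >= 8).
#' @param regulators numeric matrix, candidate regulators x samples.
#' @param nTrees number of trees (default 1000).
#' @param seed integer seed.
#' @param mtry candidate predictors per split; default `ceiling(sqrt(p))`.
#' @return named numeric vector of importance weights (sums to 1 when any
#'   split occurred).
#' @export
importanceScores <- function(target, regulators, nTrees = 1000L,
                             seed = 42L, mtry = NULL) {
  if (is.null(dim(regulators)))
    regulators <- matrix(regulators, nrow = 1L,
                         dimnames = list("regulator", NULL))
  if (length(target) < 8L) stop("need at least 8 samples")
  if (ncol(regulators) != length(target))
    stop("regulators and target must share the sample set")
  if (!nrow(regulators)) stop("need at least one regulator")
  ord <- order(rownames(regulators))
  regulators <- regulators[ord, , drop = FALSE]
  zero <- stats::setNames(rep(0, nrow(regulators)), rownames(regulators))
  if (stats::sd(target) == 0) {
    attr(zero, "flagged") <- TRUE
    return(zero)
  }
  if (is.null(mtry)) mtry <- ceiling(sqrt(nrow(regulators)))
  df <- as.data.frame(t(regulators))
  colnames(df) <- paste0("r", seq_len(nrow(regulators)))
  fit <- ranger::ranger(x = df, y = target, num.trees = nTrees,
                        mtry = min(mtry, ncol(df)),
                        splitrule = "extratrees", num.random.splits = 1L,
                        importance = "impurity", seed = seed,
                        num.threads = 1L)
  imp <- pmax(fit$variable.importance, 0)
  names(imp) <- rownames(regulators)
  if (sum(imp) > 0) imp / sum(imp) else { attr(imp, "flagged") <- TRUE; imp }
}

#' Lag-align regulator and target sample columns
#'
#' In a temporal cascade, a regulator's abundance at one timepoint acts on
#' its targets' transcription at a later one. This helper pairs each
#' target sample at timepoint index `i` with the regulator sample of the
#' same condition and replicate at index `i - lagSteps`, dropping the
#' unmatched ends of the series. With `lagSteps = 0` both matrices are
#' returned unchanged.
#'
#' @param regulators,targets matrices over the shared design-key columns
#'   (see [designMatrix()]).
#' @param lagSteps non-negative integer timepoint lag.
#' @return list with the column-paired `regulators` and `targets`
#'   matrices (equal column counts; target column names).
#' @export
lagAlign <- function(regulators, targets, lagSteps = 1L) {
  stopifnot(identical(colnames(regulators), colnames(targets)))
  if (lagSteps == 0L)
    return(list(regulators = regulators, targets = targets))
  keys <- colnames(targets)
  tp <- as.integer(sub("^.*_t0*([0-9]+)_r.*$", "\\1", keys))
  rest <- sub("_t0*[0-9]+_", "_", keys)
  tps <- sort(unique(tp))
  idx <- match(tp, tps)
  src_idx <- idx - lagSteps
  ok <- src_idx >= 1L
  src_key <- keys[ok]
  # same condition and replicate, earlier timepoint
  want <- paste(rest[ok], tps[src_idx[ok]])
  have <- paste(rest, tp)
  m <- match(want, have)
  keep <- !is.na(m)
  list(regulators = regulators[, m[keep], drop = FALSE],
       targets = targets[, which(ok)[keep], drop = FALSE])
}

#' Rank every regulator-target pair by tree-ensemble importance
#'
#' Computes [importanceScores()] for each target against the full
#' regulator matrix (self excluded, sample columns lag-aligned by
#' [lagAlign()]) and returns the pooled edge ranking used for recovery
#' benchmarking — no DE restriction, clustering or thresholding is
#' applied. Regression operates on log2(x + 1) intensities.
#'
#' @param regulator_matrix result of [buildRegulatorMatrix()] (or any
#'   matrix over design-key columns).
#' @param target_matrix targets x design-key matrix.
#' @param lagSteps timepoint lag between regulator and target samples
#'   (default 1).
#' @param nTrees,seed forwarded to [importanceScores()] (per-target seeds
#'   are derived from `seed`).
#' @return data.frame `source`, `target`, `weight`, ordered by decreasing
#'   weight.
#' @export
importanceRanking <- function(regulator_matrix, target_matrix,
                              lagSteps = 1L, nTrees = 1000L, seed = 42L) {
  al <- lagAlign(log2(regulator_matrix + 1), log2(target_matrix + 1),
                 lagSteps)
  info <- attr(regulator_matrix, "info")
  out <- list()
  tgt_ids <- sort(rownames(al$targets))
  for (ti in seq_along(tgt_ids)) {
    t_id <- tgt_ids[ti]
    reg <- al$regulators
    if (!is.null(info)) {
      keep <- info$gene_id != t_id
      reg <- reg[info$row_id[keep], , drop = FALSE]
    } else reg <- reg[rownames(reg) != t_id, , drop = FALSE]
    if (!nrow(reg)) next
    w <- importanceScores(al$targets[t_id, ], reg, nTrees = nTrees,
                          seed = seed + ti)
    out[[t_id]] <- data.frame(source = names(w), target = t_id,
                              weight = unname(w))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-res$weight, res$source, res$target), ]
}

#' Map a clustering of the combined matrix back to regulators and targets
#'
#' @param assignment a [ClusterAssignment-class] computed on a
#'   [buildClusteringMatrix()] result.
#' @param clustering_matrix the matrix the assignment was computed on.
#' @return list of named integer vectors `regulator` and `target`, keyed by
#'   original feature id.
#' @export
clusterMaps <- function(assignment, clustering_matrix) {
  origin <- attr(clustering_matrix, "origin")
  a <- clusters(assignment)
  out <- list()
  for (role in c("regulator", "target")) {
    sub <- origin[origin$role == role, , drop = FALSE]
    out[[role]] <- stats::setNames(as.integer(a[sub$row_id]),
                                   sub$feature_id)
  }
  out
}

#' Infer one timepoint-specific subnetwork
#'
#' Regulators are restricted to those differentially expressed at the
#' timepoint and targets to transcripts DE at the timepoint; for each
#' target the candidate regulators are the same-cluster TFs (self
#' excluded). Importance is computed over the full time-course sample set
#' (all timepoints, both conditions; regulator samples lag-aligned one
#' step ahead of target samples by default, see [lagAlign()]) — only
#' gene-set membership is timepoint-specific. Per target, edges with
#' importance above
#' `mean + thresholdSD * sd` of that target's weights are retained
#' (`topN` keeps the N best instead); a target with a single candidate
#' keeps it when its weight is positive.
#'
#' @param regulator_matrix result of [buildRegulatorMatrix()].
#' @param target_matrix numeric matrix (targets x design keys), e.g.
#'   `designMatrix(transcript_assay)`.
#' @param regulator_clusters,target_clusters named integer cluster vectors
#'   (see [clusterMaps()]); regulators may be keyed by row id or gene id.
#' @param de_regulators,de_targets ids DE at this timepoint (row/gene ids
#'   for regulators, target feature ids for targets).
#' @param timepoint integer minute label carried on the edges.
#' @param nTrees,seed,thresholdSD,topN inference parameters.
#' @param lagSteps regulator-to-target timepoint lag (default 1; 0 for
#'   contemporaneous regression).
#' @return a [GRNetwork-class]; empty (with a warning) when no DE
#'   regulators or targets exist at the timepoint.
#' @export
inferSubnetwork <- function(regulator_matrix, target_matrix,
                            regulator_clusters, target_clusters,
                            de_regulators, de_targets, timepoint,
                            nTrees = 1000L, seed = 42L, thresholdSD = 1,
                            topN = NULL, lagSteps = 1L) {
  info <- attr(regulator_matrix, "info")
  mode <- attr(regulator_matrix, "mode")
  if (!identical(colnames(regulator_matrix), colnames(target_matrix)))
    stop("regulator and target matrices do not share the sample design")
  keep_reg <- info$row_id %in% de_regulators |
    info$gene_id %in% de_regulators
  keep_tgt <- rownames(target_matrix) %in% de_targets
  if (!any(keep_reg) || !any(keep_tgt)) {
    warning("no DE regulators or targets at ", timepoint,
            " min; empty subnetwork")
    return(GRNetwork())
  }
  info <- info[keep_reg, , drop = FALSE]
  # regression operates on log2 intensities, the field's analysis scale
  al <- lagAlign(log2(regulator_matrix + 1), log2(target_matrix + 1),
                 lagSteps)
  reg <- al$regulators[info$row_id, , drop = FALSE]
  tgt <- al$targets[keep_tgt, , drop = FALSE]
  cl_reg <- ifelse(info$row_id %in% names(regulator_clusters),
                   regulator_clusters[info$row_id],
                   regulator_clusters[info$gene_id])
  edges <- list()
  tgt_ids <- sort(rownames(tgt))
  for (ti in seq_along(tgt_ids)) {
    t_id <- tgt_ids[ti]
    t_cl <- target_clusters[t_id]
    cand <- which(!is.na(cl_reg) & cl_reg == t_cl & info$gene_id != t_id)
    if (!length(cand)) next
    w <- importanceScores(tgt[t_id, ], reg[cand, , drop = FALSE],
                          nTrees = nTrees, seed = seed + ti)
    if (isTRUE(attr(w, "flagged"))) next
    if (!is.null(topN)) {
      keep <- names(sort(w, decreasing = TRUE))[seq_len(min(topN,
                                                            length(w)))]
      keep <- keep[w[keep] > 0]
    } else if (length(w) == 1L) {
      keep <- names(w)[w > 0]
    } else {
      keep <- names(w)[w > mean(w) + thresholdSD * stats::sd(w)]
    }
    if (!length(keep)) next
    ii <- match(keep, info$row_id)
    edges[[t_id]] <- data.frame(
      source = keep, target = t_id, weight = unname(w[keep]),
      edge_type = mode, timepoint = as.integer(timepoint),
      site_label = info$site_label[ii])
  }
  if (!length(edges)) {
    warning("no edges retained at ", timepoint, " min")
    return(GRNetwork())
  }
  GRNetwork(do.call(rbind, edges))
}

#' Union-merge networks
#'
#' The merged edge set is the union of the input edge records: an edge
#' present at several timepoints keeps one record per timepoint (the
#' timepoint attribute is preserved) and duplicate records collapse to
#' one. Weights are untouched. Idempotent and order-invariant.
#'
#' @param ... [GRNetwork-class] objects, or a single list of them.
#' @return the merged [GRNetwork-class].
#' @export
mergeNetworks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && is.list(nets[[1L]]) &&
      !is(nets[[1L]], "GRNetwork"))
    nets <- nets[[1L]]
  tabs <- lapply(nets, edges)
  cols <- Reduce(union, lapply(tabs, colnames))
  tabs <- lapply(tabs, function(e) {
    for (cc in setdiff(cols, colnames(e))) e[[cc]] <- NA
    e[, cols, drop = FALSE]
  })
  all_e <- do.call(rbind, tabs)
  if (!nrow(all_e)) return(GRNetwork())
  key <- paste(all_e$source, all_e$target, all_e$edge_type,
               all_e$timepoint, sep = "\r")
  # conflicting records for one key keep the strongest weight, so the
  # union does not depend on input order
  o <- order(all_e$source, all_e$target, all_e$timepoint,
             all_e$edge_type, -all_e$weight, method = "radix")
  all_e <- all_e[o, , drop = FALSE]
  key <- key[o]
  GRNetwork(all_e[!duplicated(key), , drop = FALSE])
}
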