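#' Select activation-loop phosphosite regulators
#'
#' Kinase activity can be read out from phosphorylation of the activation
#' loop (p-loop): a kinase qualifies as a potential signaling regulator
#' when it carries a differentially expressed phosphosite whose amino-acid
#' position falls inside its p-loop interval (1-based, inclusive ends).
#' Non-kinase proteins are excluded; kinases absent from the coordinate
#' table are excluded with one warning naming them.
#'
#' @param de_table phosphosite DE table from [callDE()].
#' @param phospho phosphosite [OmicsAssay-class].
#' @param annotation feature annotation (needs `gene_id`, `site_position`,
#'   `is_kinase` for phosphosite features).
#' @param ploop p-loop coordinate table ([readPloopTable()]).
#' @return data.frame of regulators: `feature_id`, `gene_id`,
#'   `site_position`, `site_label`.
#' @export
selectPloopRegulators <- function(de_table, phospho, annotation, ploop) {
  de_sites <- unique(de_table$feature_id[de_table$is_de])
  an <- annotation[annotation$layer == "phosphosite" &
                   annotation$is_kinase &
                   annotation$feature_id %in% de_sites &
                   annotation$feature_id %in% rownames(assay(phospho)), ,
                   drop = FALSE]
  if (!nrow(an))
    return(data.frame(feature_id = character(), gene_id = character(),
                      site_position = integer(), site_label = character()))
  idx <- match(an$gene_id, ploop$protein_id)
  no_coord <- unique(an$gene_id[is.na(idx)])
  if (length(no_coord))
    warning("kinase(s) without p-loop coordinates, excluded: ",
            paste(no_coord, collapse = ", "))
  inside <- !is.na(idx) &
    an$site_position >= ploop$ploop_start[idx] &
    an$site_position <= ploop$ploop_end[idx]
  an <- an[inside, , drop = FALSE]
  data.frame(feature_id = an$feature_id, gene_id = an$gene_id,
             site_position = an$site_position,
             site_label = sub("^.*@", "", an$feature_id),
             row.names = NULL)
}

#' Correlation-thresholded kinase-signaling edges
#'
#' For every regulator (activation-loop DE phosphosite) and target (any DE
#' phosphosite), Pearson and Spearman correlations are computed over the
#' paired non-missing samples; an edge is kept when Pearson >=
#' `pearson_min` OR Spearman >= `spearman_min` (one-sided, positive
#' correlations; `absolute = TRUE` thresholds `|r|` instead). The edge
#' weight is the larger of the two coefficients, both are carried as extra
#' columns. Self-pairs and pairs of sites on the same protein are excluded,
#' as are pairs with fewer than `min_pairs` shared observations or a
#' constant profile (reported in the `skipped` attribute).
#'
#' @param regulators regulator selection from [selectPloopRegulators()].
#' @param phospho phosphosite [OmicsAssay-class] holding both regulator and
#'   target profiles.
#' @param de_table phosphosite DE table (targets = all DE phosphosites).
#' @param pearson_min,spearman_min retention thresholds (defaults 0.5, 0.6).
#' @param absolute threshold absolute correlations instead of signed.
#' @param min_pairs minimum shared observations per pair (default 3).
#' @return a [GRNetwork-class] of `kinase` edges (timepoint `NA`: computed
#'   over the whole series) with `pearson` and `spearman` columns.
#' @export
correlationEdges <- function(regulators, phospho, de_table,
                             pearson_min = 0.5, spearman_min = 0.6,
                             absolute = FALSE, min_pairs = 3L) {
  m <- designMatrix(phospho)
  de_sites <- unique(de_table$feature_id[de_table$is_de])
  tgt_ids <- intersect(rownames(m), de_sites)
  reg_ids <- regulators$feature_id
  if (!length(reg_ids) || !length(tgt_ids)) return(GRNetwork())
  rx <- t(m[reg_ids, , drop = FALSE])
  tx <- t(m[tgt_ids, , drop = FALSE])
  n_pairs <- crossprod(!is.na(rx), !is.na(tx))
  pear <- suppressWarnings(stats::cor(rx, tx,
                                      use = "pairwise.complete.obs"))
  spear <- suppressWarnings(stats::cor(rx, tx, method = "spearman",
                                       use = "pairwise.complete.obs"))
  reg_gene <- regulators$gene_id[match(reg_ids, regulators$feature_id)]
  tgt_gene <- nodeGene(tgt_ids)
  edges <- list()
  skipped <- list()
  for (i in seq_along(reg_ids)) {
    same <- tgt_gene == reg_gene[i]
    enough <- n_pairs[i, ] >= min_pairs
    undef <- !same & enough & (is.na(pear[i, ]) | is.na(spear[i, ]))
    if (any(undef))
      skipped[[reg_ids[i]]] <- tgt_ids[undef]
    rp <- pear[i, ]; rs <- spear[i, ]
    if (absolute) { rp <- abs(rp); rs <- abs(rs) }
    keep <- which(!same & enough & !undef &
                  (rp >= pearson_min | rs >= spearman_min))
    if (length(keep))
      edges[[reg_ids[i]]] <- data.frame(
        source = reg_ids[i], target = tgt_ids[keep],
        weight = pmax(rp[keep], rs[keep]), edge_type = "kinase",
        timepoint = NA_integer_,
        site_label = regulators$site_label[i],
        pearson = pear[i, keep], spearman = spear[i, keep])
  }
  net <- if (length(edges)) GRNetwork(do.call(rbind, edges))
         else GRNetwork()
  attr(net, "skipped") <- skipped
  net
}

#' Kinase activation-state diagnostic
#'
#' Per kinase and timepoint, the correlation between kinase protein
#' abundance and its activation-loop phosphosite intensity across the
#' samples of that timepoint (both conditions). Intended as a diagnostic
#' of whether abundance tracks activity; the kinase network deliberately
#' uses p-loop site intensities, not abundance. Entries with fewer than 3
#' paired samples, or kinases missing from the abundance layer, are
#' flagged rather than computed.
#'
#' @param regulators selection from [selectPloopRegulators()].
#' @param protein protein [OmicsAssay-class].
#' @param phospho phosphosite [OmicsAssay-class].
#' @param annotation feature annotation mapping protein features to genes.
#' @return data.frame: `gene_id`, `feature_id` (site), `timepoint_min`,
#'   `n`, `correlation`, `note`.
#' @export
activationStateReport <- function(regulators, protein, phospho,
                                  annotation) {
  dm_p <- designMatrix(protein)
  dm_s <- designMatrix(phospho)
  stopifnot(identical(colnames(dm_p), colnames(dm_s)))
  tps <- sort(unique(sampleInfo(phospho)$timepoint_min))
  keys <- colnames(dm_s)
  key_tp <- as.integer(sub("^.*_t0*([0-9]+)_r.*$", "\\1", keys))
  out <- list()
  for (i in seq_len(nrow(regulators))) {
    g <- regulators$gene_id[i]
    site <- regulators$feature_id[i]
    pfeat <- .features_of(annotation, g, "protein")
    pfeat <- pfeat[pfeat %in% rownames(dm_p)]
    for (tp in tps) {
      cols <- which(key_tp == tp)
      if (!length(pfeat)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, feature_id = site, timepoint_min = tp,
          n = 0L, correlation = NA_real_, note = "missing_abundance")
        next
      }
      a <- dm_p[pfeat[1L], cols]
      s <- dm_s[site, cols]
      ok <- !is.na(a) & !is.na(s)
      if (sum(ok) < 3L) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, feature_id = site, timepoint_min = tp,
          n = sum(ok), correlation = NA_real_, note = "not_computable")
      } else {
        r <- suppressWarnings(stats::cor(a[ok], s[ok]))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, feature_id = site, timepoint_min = tp,
          n = sum(ok), correlation = r,
          note = if (is.na(r)) "constant_profile" else "")
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), feature_id = character(),
                      timepoint_min = integer(), n = integer(),
                      correlation = numeric(), note = character()))
  do.call(rbind, out)
}
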