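#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.LAYERS <- c("transcript", "protein", "phosphosite")
.EDGE_TYPES <- c("abundance", "phosphosite", "kinase")

#' Single-layer omics assay
#'
#' A feature-by-sample matrix for one molecular layer (transcript counts,
#' protein-group reporter intensities, or phosphosite reporter intensities),
#' backed by a [SummarizedExperiment::SummarizedExperiment] whose `colData`
#' holds the per-sample design metadata (treatment, timepoint, replicate,
#' batch, channel, reference flag). Values are non-negative; missing
#' quantifications are `NA`, never zero.
#'
#' @slot layer character(1), one of `"transcript"`, `"protein"`,
#'   `"phosphosite"`.
#' @export
setClass("OmicsAssay",
  contains = "SummarizedExperiment",
  representation(layer = "character"))

setValidity("OmicsAssay", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("layer must be one of %s",
                          paste(.LAYERS, collapse = ", ")))
  v <- assay(object)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "values must be non-negative where present")
  cd <- colData(object)
  req <- c("sample_id", "treatment", "timepoint_min", "replicate",
           "batch", "channel", "is_reference")
  miss <- setdiff(req, colnames(cd))
  if (length(miss))
    msg <- c(msg, sprintf("colData lacks columns: %s",
                          paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsAssay
#'
#' @param values numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames). Non-negative; `NA` marks a missing
#'   quantification.
#' @param layer `"transcript"`, `"protein"` or `"phosphosite"`.
#' @param sampleInfo data.frame of sample metadata (see
#'   [validateSampleInfo()]); every column of `values` must match one
#'   `sample_id`.
#' @return An [OmicsAssay-class] object.
#' @examples
#' si <- data.frame(sample_id = c("s1", "s2"), treatment = "mock",
#'   timepoint_min = 15L, replicate = 1:2, batch = "b1",
#'   channel = c("126", "127"), is_reference = FALSE)
#' oa <- OmicsAssay(matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"),
#'   c("s1", "s2"))), "transcript", si)
#' @export
OmicsAssay <- function(values, layer, sampleInfo) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sampleInfo <- validateSampleInfo(sampleInfo)
  idx <- match(colnames(values), sampleInfo$sample_id)
  if (anyNA(idx))
    stop("samples absent from sampleInfo: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  sub <- sampleInfo[idx, , drop = FALSE]
  smp <- sub[!sub$is_reference, , drop = FALSE]
  if (anyDuplicated(paste(smp$treatment, smp$timepoint_min,
                          smp$replicate)))
    stop("(treatment, timepoint_min, replicate) not unique among the ",
         "assay's samples")
  cd <- DataFrame(sub)
  rownames(cd) <- colnames(values)
  new("OmicsAssay",
      SummarizedExperiment(assays = list(intensity = values), colData = cd),
      layer = layer)
}

#' Directed regulatory network
#'
#' An edge table of directed, weighted regulations. Edges are typed:
#' `abundance` (TF protein/transcript abundance predicting a target
#' transcript), `phosphosite` (TF phosphosite intensity predicting a target
#' transcript; `site_label` records the predictive site as `gene@residue`),
#' or `kinase` (activation-loop phosphosite correlated with a substrate
#' phosphosite). `timepoint` carries the minute label of the subnetwork an
#' edge was inferred in (`NA` for edges computed over the whole series).
#'
#' @slot edges data.frame with columns `source`, `target`, `weight`,
#'   `edge_type`, `timepoint`, `site_label`.
#' @export
setClass("GRNetwork", representation(edges = "data.frame"))

.edge_cols <- c("source", "target", "weight", "edge_type", "timepoint",
                "site_label")

#' Gene id underlying a node label (strips a `@site` suffix)
#' @param id character vector of node labels.
#' @return character vector of gene ids.
#' @export
nodeGene <- function(id) sub("@.*$", "", id)

setValidity("GRNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(.edge_cols %in% colnames(e)))
    return(sprintf("edges must have columns %s",
                   paste(.edge_cols, collapse = ", ")))
  if (nrow(e)) {
    if (any(nodeGene(e$source) == nodeGene(e$target)))
      msg <- c(msg, "self-edges (same source and target gene) are not allowed")
    if (any(!is.finite(e$weight)))
      msg <- c(msg, "edge weights must be finite")
    if (any(!e$edge_type %in% .EDGE_TYPES))
      msg <- c(msg, sprintf("edge_type must be one of %s",
                            paste(.EDGE_TYPES, collapse = ", ")))
    key <- paste(e$source, e$target, e$edge_type, e$timepoint, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "(source, target, edge_type, timepoint) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GRNetwork
#'
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `edge_type` and optionally `timepoint` (integer minutes, `NA` allowed)
#'   and `site_label`.
#' @return A [GRNetwork-class] object with deterministically ordered rows
#'   (source, target, timepoint).
#' @examples
#' net <- GRNetwork(data.frame(source = "TF1", target = "g1", weight = 0.9,
#'   edge_type = "abundance", timepoint = 15L))
#' @export
GRNetwork <- function(edges = data.frame()) {
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), edge_type = character(),
                        timepoint = integer(), site_label = character())
  } else {
    if (!"timepoint" %in% colnames(edges)) edges$timepoint <- NA_integer_
    if (!"site_label" %in% colnames(edges)) edges$site_label <- NA_character_
    extra <- setdiff(colnames(edges), .edge_cols)
    edges <- edges[, c(.edge_cols, extra)]
    edges$timepoint <- as.integer(edges$timepoint)
    o <- order(edges$source, edges$target, edges$timepoint, edges$edge_type,
               method = "radix")
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("GRNetwork", edges = edges)
}

#' Cluster assignment of temporal profiles
#'
#' @slot assignments named integer vector mapping feature id to cluster id
#'   (contiguous `1..k`, every cluster non-empty).
#' @slot k integer(1), number of clusters.
#' @slot method `"dtw"` or `"ica"`.
#' @export
setClass("ClusterAssignment",
  representation(assignments = "integer", k = "integer", method = "character"))

setValidity("ClusterAssignment", function(object) {
  a <- object@assignments
  msg <- character()
  if (is.null(names(a)) || anyDuplicated(names(a)))
    msg <- c(msg, "assignments must be uniquely named by feature id")
  if (length(a)) {
    if (!setequal(unique(a), seq_len(object@k)))
      msg <- c(msg, "cluster ids must be contiguous 1..k with no empty cluster")
  }
  if (!object@method %in% c("dtw", "ica"))
    msg <- c(msg, "method must be 'dtw' or 'ica'")
  if (length(msg)) msg else TRUE
})
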