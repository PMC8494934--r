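#' @importFrom utils read.delim write.table
NULL

# Auto-detect tab vs comma from the header line; output is always tab.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

.read_table <- function(path) {
  read.delim(path, sep = .detect_sep(path), header = TRUE,
             check.names = FALSE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""))
}

#' Read a feature-by-sample expression matrix
#'
#' Parses a delimited text table (tab or comma, auto-detected) whose first
#' column holds feature ids and remaining columns one sample each. Empty
#' cells become `NA` (missing quantification), never zero.
#'
#' @param path file path.
#' @param layer `"transcript"`, `"protein"` or `"phosphosite"`.
#' @param sampleInfo optional sample-metadata data.frame; when supplied the
#'   result is a validated [OmicsAssay-class], otherwise a bare matrix.
#' @return An [OmicsAssay-class] (with `sampleInfo`) or a numeric matrix.
#' @export
readExpression <- function(path, layer, sampleInfo = NULL) {
  df <- .read_table(path)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  if (is.null(sampleInfo)) m else OmicsAssay(m, layer, sampleInfo)
}

#' Validate a sample-metadata table
#'
#' Required columns: `sample_id`, `treatment` (`mock`/`treated`; may be `NA`
#' for pooled reference channels), `timepoint_min`, `replicate`, `batch`,
#' `channel`, `is_reference`. The design key
#' (treatment, timepoint, replicate) must be unique among non-reference
#' samples.
#'
#' @param sampleInfo data.frame.
#' @return the validated data.frame (types coerced).
#' @export
validateSampleInfo <- function(sampleInfo) {
  req <- c("sample_id", "treatment", "timepoint_min", "replicate",
           "batch", "channel", "is_reference")
  miss <- setdiff(req, colnames(sampleInfo))
  if (length(miss))
    stop("sampleInfo lacks columns: ", paste(miss, collapse = ", "))
  si <- as.data.frame(sampleInfo)
  si$sample_id <- as.character(si$sample_id)
  si$is_reference <- as.logical(si$is_reference)
  si$timepoint_min <- as.integer(si$timepoint_min)
  si$replicate <- as.integer(si$replicate)
  if (anyDuplicated(si$sample_id))
    stop("duplicate sample_id in sampleInfo")
  smp <- si[!si$is_reference, , drop = FALSE]
  if (!all(smp$treatment %in% c("mock", "treated")))
    stop("treatment must be 'mock' or 'treated' for non-reference samples")
  # a metadata table may span platforms (e.g. RNA-seq + TMT) that each
  # carry the full design; strict per-assay uniqueness is enforced when an
  # OmicsAssay picks its columns
  key <- paste(smp$treatment, smp$timepoint_min, smp$replicate, smp$batch)
  if (anyDuplicated(key))
    stop("(treatment, timepoint_min, replicate) not unique within a batch")
  si
}

#' Read a sample-metadata table
#' @param path delimited text file with the columns of [validateSampleInfo()].
#' @return validated data.frame.
#' @export
readSampleInfo <- function(path) validateSampleInfo(.read_table(path))

#' Read a feature-annotation table
#'
#' Columns: `feature_id`, `gene_id`, `layer`, `site_position` (1-based
#' amino-acid coordinate, phosphosite rows only), `is_tf`, `is_kinase`.
#'
#' @param path delimited text file.
#' @return validated data.frame.
#' @export
readFeatureAnnotation <- function(path) {
  an <- .read_table(path)
  validateFeatureAnnotation(an)
}

#' @rdname readFeatureAnnotation
#' @param annotation data.frame to validate in place of a file.
#' @export
validateFeatureAnnotation <- function(annotation) {
  req <- c("feature_id", "gene_id", "layer", "site_position", "is_tf",
           "is_kinase")
  miss <- setdiff(req, colnames(annotation))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  an <- as.data.frame(annotation)
  an$is_tf <- as.logical(an$is_tf)
  an$is_kinase <- as.logical(an$is_kinase)
  an$site_position <- as.integer(an$site_position)
  if (any(is.na(an$gene_id) | an$gene_id == ""))
    stop("gene_id must be non-empty for every feature")
  ph <- an$layer == "phosphosite"
  if (any(is.na(an$site_position[ph])))
    stop("phosphosite features must carry site_position")
  if (any(!is.na(an$site_position[!ph])))
    stop("site_position is only meaningful for phosphosite features")
  an
}

#' Read an activation-loop (p-loop) coordinate table
#'
#' Columns: `protein_id`, `ploop_start`, `ploop_end` (1-based inclusive
#' amino-acid coordinates, start <= end; one row per kinase).
#'
#' @param path delimited text file.
#' @return validated data.frame.
#' @export
readPloopTable <- function(path) {
  pl <- .read_table(path)
  req <- c("protein_id", "ploop_start", "ploop_end")
  miss <- setdiff(req, colnames(pl))
  if (length(miss))
    stop("p-loop table lacks columns: ", paste(miss, collapse = ", "))
  pl$ploop_start <- as.integer(pl$ploop_start)
  pl$ploop_end <- as.integer(pl$ploop_end)
  if (anyDuplicated(pl$protein_id))
    stop("duplicate protein_id in p-loop table")
  if (any(pl$ploop_start > pl$ploop_end))
    stop("ploop_start must be <= ploop_end")
  pl
}

#' Write a network as a Cytoscape-compatible edge table
#'
#' Tab-separated with header `source target weight edge_type timepoint
#' site_label`, one row per edge record, rows sorted by (source, target,
#' timepoint) so that repeated runs are byte-identical.
#'
#' @param network a [GRNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEdgeTable <- function(network, path) {
  stopifnot(is(network, "GRNetwork"))
  e <- edges(network)
  e$weight <- formatC(e$weight, format = "g", digits = 15)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read an edge table written by [writeEdgeTable()]
#' @param path tab-separated edge table.
#' @return a [GRNetwork-class].
#' @export
readEdgeTable <- function(path) {
  e <- .read_table(path)
  if (nrow(e) == 0L) return(GRNetwork())
  e$weight <- as.numeric(e$weight)
  e$site_label <- as.character(e$site_label)
  GRNetwork(e)
}
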