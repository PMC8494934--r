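#' @rdname OmicsAssay-class
#' @param x an object.
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))

#' @rdname OmicsAssay-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GRNetwork-class
#' @param x an object.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname GRNetwork-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname ClusterAssignment-class
#' @param x an object.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @describeIn OmicsAssay-class the molecular layer tag.
#' @export
setMethod("layerType", "OmicsAssay", function(x) x@layer)

#' @describeIn OmicsAssay-class sample metadata as a base data.frame.
#' @export
setMethod("sampleInfo", "OmicsAssay", function(x) {
  df <- as.data.frame(colData(x))
  rownames(df) <- NULL
  df
})

#' @describeIn GRNetwork-class the edge table (base data.frame).
#' @export
setMethod("edges", "GRNetwork", function(x) x@edges)

#' @describeIn GRNetwork-class number of edge records.
#' @export
setMethod("nEdges", "GRNetwork", function(x) nrow(x@edges))

#' @describeIn ClusterAssignment-class named integer vector of cluster ids.
#' @export
setMethod("clusters", "ClusterAssignment", function(x) x@assignments)

#' @describeIn ClusterAssignment-class the number of clusters.
#' @export
setMethod("nClusters", "ClusterAssignment", function(x) x@k)

setMethod("show", "OmicsAssay", function(object) {
  v <- assay(object)
  cat(sprintf("OmicsAssay [%s]: %d features x %d samples (%d batches)\n",
              object@layer, nrow(v), ncol(v),
              length(unique(colData(object)$batch))))
  invisible(NULL)
})

setMethod("show", "GRNetwork", function(object) {
  e <- object@edges
  cat(sprintf("GRNetwork: %d edge records (%d sources, %d targets)\n",
              nrow(e), length(unique(e$source)), length(unique(e$target))))
  if (nrow(e)) {
    tab <- table(e$edge_type)
    cat("  by type:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment [%s]: %d features in %d clusters\n",
              object@method, length(object@assignments), object@k))
  invisible(NULL)
})
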