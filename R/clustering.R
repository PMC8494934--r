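#' Per-feature temporal response profiles
#'
#' Summarizes a layer into one profile per feature: the log2 ratio of the
#' treated over the mock replicate mean at each timepoint, z-scored across
#' timepoints so that profile shape, not amplitude, drives clustering.
#' Constant or non-finite profiles become all-zero rows.
#'
#' @param x an [OmicsAssay-class].
#' @return numeric matrix, features x timepoints (column names are minutes).
#' @export
temporalProfiles <- function(x) {
  stopifnot(is(x, "OmicsAssay"))
  m <- assay(x)
  si <- sampleInfo(x)
  keep <- !si$is_reference
  m <- m[, keep, drop = FALSE]
  si <- si[keep, , drop = FALSE]
  tps <- sort(unique(si$timepoint_min))
  prof <- matrix(NA_real_, nrow(m), length(tps),
                 dimnames = list(rownames(m), tps))
  for (i in seq_along(tps)) {
    tcols <- si$timepoint_min == tps[i] & si$treatment == "treated"
    mcols <- si$timepoint_min == tps[i] & si$treatment == "mock"
    prof[, i] <- log2(rowMeans(m[, tcols, drop = FALSE], na.rm = TRUE) /
                      rowMeans(m[, mcols, drop = FALSE], na.rm = TRUE))
  }
  prof[!is.finite(prof)] <- 0
  .zscore_rows(prof)
}

# row-wise z-score; constant or degenerate rows become all-zero
.zscore_rows <- function(prof) {
  ctr <- prof - rowMeans(prof)
  s <- apply(prof, 1L, stats::sd)
  s[!is.finite(s) | s == 0] <- Inf
  ctr / s
}

# profiles from a designMatrix() result: columns are design keys
.design_profiles <- function(m) {
  keys <- colnames(m)
  tp <- as.integer(sub("^.*_t0*([0-9]+)_r.*$", "\\1", keys))
  treated <- startsWith(keys, "treated")
  tps <- sort(unique(tp))
  prof <- vapply(tps, function(t1)
    log2(rowMeans(m[, treated & tp == t1, drop = FALSE], na.rm = TRUE) /
         rowMeans(m[, !treated & tp == t1, drop = FALSE], na.rm = TRUE)),
    numeric(nrow(m)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = nrow(m))
  dimnames(prof) <- list(rownames(m), tps)
  prof[!is.finite(prof)] <- 0
  .zscore_rows(prof)
}

.any_profiles <- function(x) {
  if (is(x, "OmicsAssay")) temporalProfiles(x) else .design_profiles(x)
}

#' Combine regulator and target profiles into one clustering matrix
#'
#' Row-binds the regulator-layer profiles (TF protein or phosphosite) and
#' the target-layer profiles (transcripts) over a shared timepoint design,
#' so that regulators are clustered together with their potential targets.
#' A feature id present in both layers gets suffixed row ids.
#'
#' @param regulators,targets [OmicsAssay-class] objects, or
#'   feature-by-design matrices ([designMatrix()] /
#'   [buildRegulatorMatrix()] results), sharing the same treatments and
#'   timepoints.
#' @return matrix of z-scored log-ratio profiles with attribute `origin`, a
#'   data.frame mapping each row id to its `feature_id` and `role`
#'   (`regulator`/`target`).
#' @export
buildClusteringMatrix <- function(regulators, targets) {
  pr <- .any_profiles(regulators)
  pt <- .any_profiles(targets)
  if (!identical(colnames(pr), colnames(pt)))
    stop("regulator and target matrices do not share the timepoint design")
  ids_r <- rownames(pr); ids_t <- rownames(pt)
  clash <- intersect(ids_r, ids_t)
  if (length(clash)) {
    suf_r <- if (is(regulators, "OmicsAssay")) layerType(regulators)
             else "regulator"
    suf_t <- if (is(targets, "OmicsAssay")) layerType(targets)
             else "target"
    rownames(pr)[ids_r %in% clash] <-
      paste(ids_r[ids_r %in% clash], suf_r, sep = ".")
    rownames(pt)[ids_t %in% clash] <-
      paste(ids_t[ids_t %in% clash], suf_t, sep = ".")
  }
  out <- rbind(pr, pt)
  attr(out, "origin") <- data.frame(
    row_id = c(rownames(pr), rownames(pt)),
    feature_id = c(ids_r, ids_t),
    role = rep(c("regulator", "target"), c(nrow(pr), nrow(pt))))
  out
}

#' Dynamic time warping distance
#'
#' Classic DTW between two numeric series: absolute-difference local cost,
#' unconstrained warping window, boundary-matched path. Symmetric and zero
#' on identical series.
#'
#' @param x,y numeric series (length >= 1, no missing values).
#' @return non-negative warping distance.
#' @examples
#' dtwDistance(c(0, 1, 2), c(0, 0, 1, 2))
#' @export
dtwDistance <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty series")
  if (anyNA(x) || anyNA(y)) stop("series must not contain missing values")
  n <- length(x); m <- length(y)
  cost <- abs(outer(x, y, `-`))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1L, j + 1L] <- cost[i, j] +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
  D[n + 1L, m + 1L]
}

#' Pairwise DTW distances between profile rows
#' @param profiles numeric matrix, one series per row.
#' @return a [stats::dist] object.
#' @export
dtwDistanceMatrix <- function(profiles) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n))
        d[i, j] <- d[j, i] <- dtwDistance(profiles[i, ], profiles[j, ])
  stats::as.dist(d)
}

#' Temporally informed clustering by DTW + hierarchical agglomeration
#'
#' Computes all pairwise DTW distances, agglomerates with average linkage,
#' and cuts the tree into `k` clusters. With `k = NULL` the number of
#' clusters maximizes the mean silhouette width over
#' `k in 2..min(kmax, n - 1)`.
#'
#' @param profiles numeric matrix of temporal profiles (rows = features).
#' @param k number of clusters, or `NULL` for silhouette-based selection.
#' @param kmax upper bound for automatic selection (default 15).
#' @return a [ClusterAssignment-class] with `method = "dtw"`.
#' @export
dtwCluster <- function(profiles, k = NULL, kmax = 15L) {
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 profiles")
  if (!is.null(k) && k > n) stop("k cannot exceed the number of profiles")
  if (!is.null(k) && k == 1L) {
    a <- rep(1L, n); names(a) <- rownames(profiles)
    return(new("ClusterAssignment", assignments = a, k = 1L,
               method = "dtw"))
  }
  d <- dtwDistanceMatrix(profiles)
  hc <- stats::hclust(d, method = "average")
  if (is.null(k)) {
    ks <- seq.int(2L, min(kmax, n - 1L))
    sil <- vapply(ks, function(kk) {
      cut <- stats::cutree(hc, k = kk)
      mean(cluster::silhouette(cut, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  a <- stats::cutree(hc, k = k)
  new("ClusterAssignment", assignments = a, k = as.integer(k),
      method = "dtw")
}
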