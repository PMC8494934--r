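#' Sample-loading (within-batch) normalization
#'
#' Equalizes total reporter-ion signal across the channels of each isobaric
#' labeling run: within a batch, every column is scaled so that its total
#' intensity equals the mean column total of that batch. Relative values
#' within a column are unchanged; missing values stay missing and are
#' excluded from column totals.
#'
#' @param x an [OmicsAssay-class] (every sample assigned to a batch).
#' @return a list with elements `assay` (normalized [OmicsAssay-class]) and
#'   `report` (data.frame of per-sample batch, column sum and scaling
#'   factor).
#' @seealso [internalReferenceNormalize()] for the between-batch step.
#' @export
sampleLoadingNormalize <- function(x) {
  stopifnot(is(x, "OmicsAssay"))
  m <- assay(x)
  si <- sampleInfo(x)
  csum <- colSums(m, na.rm = TRUE)
  if (any(csum <= 0))
    stop("zero column sum for sample(s): ",
         paste(colnames(m)[csum <= 0], collapse = ", "))
  factors <- numeric(ncol(m))
  for (b in unique(si$batch)) {
    cols <- which(si$batch == b)
    factors[cols] <- mean(csum[cols]) / csum[cols]
  }
  m <- sweep(m, 2L, factors, `*`)
  report <- data.frame(sample_id = colnames(m), batch = si$batch,
                       column_sum = csum, scale_factor = factors)
  rownames(report) <- NULL
  list(assay = OmicsAssay(m, layerType(x), si), report = report)
}

#' Internal-reference (between-batch) scaling
#'
#' Puts features on a common scale across isobaric labeling runs using the
#' pooled reference channel(s) carried in every batch. For each feature the
#' per-batch reference value is the arithmetic mean over that batch's
#' reference columns; the batch factor is the geometric mean of those
#' per-batch reference values divided by the batch's own value, and every
#' measurement of the feature in the batch is multiplied by it. After
#' scaling, a retained feature's reference means agree across batches.
#' Features lacking reference quantification (or with a zero reference) in
#' any batch cannot be placed on the common scale; they are dropped and
#' listed in the report.
#'
#' @param x an [OmicsAssay-class], already sample-loading normalized; every
#'   batch must contain at least one reference column
#'   (`is_reference = TRUE`).
#' @return list with `assay` (normalized, possibly fewer features),
#'   `report` (data.frame of per-feature, per-batch reference means and
#'   scale factors for retained features) and `dropped` (character vector
#'   of dropped feature ids).
#' @export
internalReferenceNormalize <- function(x) {
  stopifnot(is(x, "OmicsAssay"))
  m <- assay(x)
  si <- sampleInfo(x)
  batches <- unique(si$batch)
  ref_means <- matrix(NA_real_, nrow(m), length(batches),
                      dimnames = list(rownames(m), batches))
  for (j in seq_along(batches)) {
    rcols <- which(si$batch == batches[j] & si$is_reference)
    if (!length(rcols))
      stop("batch '", batches[j], "' has no reference column")
    ref_means[, j] <- rowMeans(m[, rcols, drop = FALSE], na.rm = TRUE)
  }
  ok <- apply(ref_means, 1L, function(r) all(is.finite(r) & r > 0))
  dropped <- rownames(m)[!ok]
  m <- m[ok, , drop = FALSE]
  ref_means <- ref_means[ok, , drop = FALSE]
  # geometric mean across batches is the common reference center
  center <- exp(rowMeans(log(ref_means)))
  factors <- center / ref_means
  for (j in seq_along(batches)) {
    cols <- which(si$batch == batches[j])
    m[, cols] <- m[, cols, drop = FALSE] * factors[, j]
  }
  report <- data.frame(feature_id = rep(rownames(m), length(batches)),
                       batch = rep(batches, each = nrow(m)),
                       reference_mean = as.vector(ref_means),
                       scale_factor = as.vector(factors))
  list(assay = OmicsAssay(m, layerType(x), si), report = report,
       dropped = dropped)
}

#' Post-normalization quality-control summary
#'
#' Per-sample intensity quartiles, the sample-sample Pearson correlation
#' matrix, and 2-component principal-coordinate projections for plotting.
#' A constant matrix yields an all-zero projection rather than an error.
#'
#' @param x an [OmicsAssay-class].
#' @return list with `quartiles` (samples x 5 matrix: min, Q1, median, Q3,
#'   max), `correlation` (samples x samples), `projection` (samples x 2,
#'   principal components of the centered feature profiles).
#' @export
qcSummary <- function(x) {
  stopifnot(is(x, "OmicsAssay"))
  m <- assay(x)
  quart <- t(apply(m, 2L, stats::quantile,
                   probs = c(0, .25, .5, .75, 1), na.rm = TRUE))
  colnames(quart) <- c("min", "q1", "median", "q3", "max")
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  mm <- m
  mm[is.na(mm)] <- mean(mm, na.rm = TRUE)
  cm <- t(mm) - colMeans(mm)
  if (all(abs(cm) < .Machine$double.eps^0.5)) {
    proj <- matrix(0, ncol(m), 2L)
  } else {
    sv <- svd(cm, nu = 2L, nv = 0L)
    proj <- sv$u %*% diag(sv$d[1:2], 2L, 2L)
  }
  dimnames(proj) <- list(colnames(m), c("PC1", "PC2"))
  list(quartiles = quart, correlation = cc, projection = proj)
}
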