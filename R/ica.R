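# Symmetric FastICA with the logcosh contrast, operating on the rows of a
# feature-by-sample matrix (features are observations, samples variables).
# Returns the n_features x n_comp source matrix. Seeded deterministic init.
.fastica_sources <- function(x, n_comp, seed, max_iter = 200L,
                             tol = 1e-8) {
  n <- nrow(x)
  z <- sweep(x, 2L, colMeans(x))
  sv <- svd(z, nu = n_comp, nv = 0L)
  if (sv$d[n_comp] < .Machine$double.eps^0.5 * sv$d[1L])
    stop("matrix rank is below n_components; reduce n_components")
  # whitened data: unit-variance feature-space principal scores
  w0 <- sv$u * sqrt(n)
  rng <- local({
    set.seed(seed)
    matrix(stats::rnorm(n_comp * n_comp), n_comp, n_comp)
  })
  sym_decorrelate <- function(w) {
    e <- eigen(crossprod(w), symmetric = TRUE)
    w %*% (e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                              n_comp, n_comp) %*% t(e$vectors))
  }
  w <- sym_decorrelate(rng)
  for (it in seq_len(max_iter)) {
    g <- tanh(w0 %*% w)
    w_new <- crossprod(w0, g) / n -
      w %*% diag(colMeans(1 - g^2), n_comp, n_comp)
    w_new <- sym_decorrelate(w_new)
    conv <- max(abs(abs(colSums(w_new * w)) - 1))
    w <- w_new
    if (conv < tol) break
  }
  s <- w0 %*% w
  rownames(s) <- rownames(x)
  s
}

#' ICA-based clustering for non-temporal designs
#'
#' Decomposes the feature-by-sample matrix into independent components and
#' assigns each feature to the component on which its loading has maximum
#' absolute value (component signs are arbitrary, so the assignment is
#' sign-agnostic). Components that attract no feature are dropped and the
#' remaining cluster ids relabeled contiguously. A fixed seed makes the
#' assignment reproducible.
#'
#' @param x numeric matrix (features x samples) or an [OmicsAssay-class].
#' @param n_components number of independent components,
#'   `1 <= n_components <= min(n_features, n_samples)`.
#' @param seed integer seed for the ICA initialization.
#' @return a [ClusterAssignment-class] with `method = "ica"`.
#' @export
icaCluster <- function(x, n_components, seed = 1L) {
  if (is(x, "OmicsAssay")) x <- assay(x)
  if (n_components < 1L) stop("n_components must be >= 1")
  if (n_components > min(dim(x)))
    stop("n_components cannot exceed min(n_features, n_samples)")
  if (n_components == 1L) {
    a <- rep(1L, nrow(x)); names(a) <- rownames(x)
    return(new("ClusterAssignment", assignments = a, k = 1L,
               method = "ica"))
  }
  s <- .fastica_sources(x, as.integer(n_components), seed = seed)
  raw <- apply(abs(s), 1L, which.max)
  lev <- sort(unique(raw))
  a <- stats::setNames(as.integer(match(raw, lev)), rownames(x))
  new("ClusterAssignment", assignments = a,
      k = length(lev), method = "ica")
}
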