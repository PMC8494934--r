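#' Layer-specific differential-expression thresholds
#'
#' Transcripts are called at a q-value (Benjamini-Hochberg) cutoff of 0.05
#' with a fold-change cutoff of 1.25; proteins and phosphosites at a raw
#' p-value cutoff of 0.05 with a fold-change cutoff of 1.1. The asymmetry
#' (q for transcripts, p for proteomics) reflects the very different feature
#' counts and p-value distributions of the two platforms.
#'
#' @param layer `"transcript"`, `"protein"` or `"phosphosite"`.
#' @return list with `fc_cutoff`, `alpha`, `use_q`.
#' @export
deThresholds <- function(layer) {
  layer <- match.arg(layer, .LAYERS)
  if (layer == "transcript")
    list(fc_cutoff = 1.25, alpha = 0.05, use_q = TRUE)
  else
    list(fc_cutoff = 1.1, alpha = 0.05, use_q = FALSE)
}

#' Apply the layer threshold rule to precomputed statistics
#'
#' A feature is differentially expressed when its significance statistic
#' (q or p, per the layer rule) is below `alpha` and its fold change lies
#' outside `[1/fc_cutoff, fc_cutoff]`. A fold change of exactly 1, or a
#' non-finite fold change, is never DE.
#'
#' @param fold_change treated/mock ratio (> 0).
#' @param p,q significance statistics in `[0, 1]`.
#' @param layer molecular layer (chooses the default thresholds).
#' @param thresholds optional list overriding [deThresholds()].
#' @return logical vector of DE calls.
#' @export
deFlag <- function(fold_change, p, q, layer, thresholds = deThresholds(layer)) {
  stat <- if (isTRUE(thresholds$use_q)) q else p
  fc_ok <- is.finite(fold_change) &
    (fold_change > thresholds$fc_cutoff |
     fold_change < 1 / thresholds$fc_cutoff)
  !is.na(stat) & stat < thresholds$alpha & fc_ok
}

# exact two-sided rank-sum p-value; falls back to the normal approximation
# only when ties make the exact null unavailable
.ranksum_test <- function(a, b) {
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}

# Welch t on the log2 scale: the transcript default. A rank test cannot
# serve the transcript rule at few replicates: its discrete p-values are
# floored (2/70 at 4 vs 4), which a BH q-cutoff of 0.05 almost never
# clears, whereas intensities/counts are near log-normal so the t test is
# well calibrated and its p-values are continuous.
.welch_log_test <- function(a, b) {
  suppressWarnings(stats::t.test(log2(a + 0.5), log2(b + 0.5))$p.value)
}

#' Default two-sample test for a layer
#'
#' Transcripts (called on q-values) use a Welch t-test on log2
#' counts-per-million; proteins and phosphosites (called on raw p-values)
#' use the exact Wilcoxon rank-sum test.
#'
#' @param layer molecular layer.
#' @return function(treated, mock) returning a p-value.
#' @export
defaultDETest <- function(layer) {
  layer <- match.arg(layer, .LAYERS)
  if (layer == "transcript") .welch_log_test else .ranksum_test
}

#' Per-timepoint differential-expression calling
#'
#' For every feature and timepoint, compares treated against mock replicates
#' on the normalized scale: fold change is mean(treated)/mean(mock)
#' (transcript counts are first scaled to counts-per-million), the p-value
#' comes from a pluggable two-sample test (default per
#' [defaultDETest()]), and q-values are Benjamini-Hochberg within each
#' timepoint.
#' Reference channels are excluded. Features quantified in fewer than half
#' of a condition's replicates at a timepoint are skipped there
#' (`note = "skipped_missing"`); a zero mock mean yields an infinite fold
#' change that is excluded from DE calling (`note = "infinite_fc"`).
#'
#' @param x an [OmicsAssay-class] (normalized).
#' @param test function(treated, mock) returning a p-value; defaults to
#'   the layer's test from [defaultDETest()].
#' @param thresholds list overriding [deThresholds()] for this layer.
#' @return data.frame with columns `feature_id`, `timepoint_min`,
#'   `fold_change`, `p`, `q`, `direction` (`up` iff fold change > 1),
#'   `is_de`, `note`.
#' @export
callDE <- function(x, test = defaultDETest(layerType(x)),
                   thresholds = deThresholds(layerType(x))) {
  stopifnot(is(x, "OmicsAssay"))
  m <- assay(x)
  si <- sampleInfo(x)
  keep <- !si$is_reference
  m <- m[, keep, drop = FALSE]
  si <- si[keep, , drop = FALSE]
  if (layerType(x) == "transcript") {
    libsize <- colSums(m, na.rm = TRUE)
    m <- sweep(m, 2L, libsize / 1e6, `/`)
  }
  tps <- sort(unique(si$timepoint_min))
  out <- vector("list", length(tps))
  inf_warned <- FALSE
  for (i in seq_along(tps)) {
    tp <- tps[i]
    tcols <- which(si$timepoint_min == tp & si$treatment == "treated")
    mcols <- which(si$timepoint_min == tp & si$treatment == "mock")
    if (!length(tcols) || !length(mcols))
      stop("timepoint ", tp, " min lacks a treated or mock condition")
    tv <- m[, tcols, drop = FALSE]
    mv <- m[, mcols, drop = FALSE]
    n_t <- rowSums(!is.na(tv))
    n_m <- rowSums(!is.na(mv))
    skipped <- n_t < length(tcols) / 2 | n_m < length(mcols) / 2
    fc <- rowMeans(tv, na.rm = TRUE) / rowMeans(mv, na.rm = TRUE)
    p <- rep(NA_real_, nrow(m))
    testable <- which(!skipped & n_t >= 2L & n_m >= 2L)
    for (f in testable)
      p[f] <- test(tv[f, !is.na(tv[f, ])], mv[f, !is.na(mv[f, ])])
    q <- rep(NA_real_, nrow(m))
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    note <- rep("", nrow(m))
    note[skipped] <- "skipped_missing"
    infinite <- !skipped & !is.finite(fc)
    note[infinite] <- "infinite_fc"
    if (any(infinite) && !inf_warned) {
      warning("infinite fold change (zero mock mean) for ",
              sum(infinite), " feature/timepoint pair(s); excluded from DE")
      inf_warned <- TRUE
    }
    is_de <- deFlag(fc, p, q, layerType(x), thresholds)
    is_de[skipped | infinite] <- FALSE
    out[[i]] <- data.frame(
      feature_id = rownames(m), timepoint_min = tp, fold_change = fc,
      p = p, q = q,
      direction = ifelse(is.finite(fc) & fc > 1, "up", "down"),
      is_de = is_de, note = note)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split DE calls into per-timepoint up/down feature sets
#'
#' @param de_table result of [callDE()].
#' @return named list (one element per timepoint with at least one DE
#'   feature) of lists with character vectors `up` and `down`.
#' @export
deSetsByTimepoint <- function(de_table) {
  de <- de_table[de_table$is_de, , drop = FALSE]
  out <- list()
  for (tp in sort(unique(de$timepoint_min))) {
    sub <- de[de$timepoint_min == tp, , drop = FALSE]
    out[[as.character(tp)]] <- list(
      up = sub$feature_id[sub$direction == "up"],
      down = sub$feature_id[sub$direction == "down"])
  }
  out
}
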