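#' Per-gene network motif participation counts
#'
#' Collapses the network to distinct gene-level directed pairs (node labels
#' carrying a `@site` suffix are reduced to their gene) and counts, for
#' every gene, the number of distinct motif instances it participates in,
#' in any role:
#'
#' * feed-forward loop: distinct A, B, C with A->B, B->C, A->C;
#' * feedback loop: distinct A, B with A->B and B->A (the 2-node mutual
#'   cycle; longer cycles are not counted);
#' * diamond: distinct A, B, C, D with A->B, A->C, B->D, C->D (the
#'   intermediate pair \{B, C\} is unordered);
#' * bi-fan: distinct A, B, C, D with A->C, A->D, B->C, B->D (source pair
#'   \{A, B\} and target pair \{C, D\} unordered).
#'
#' Matching is not induced: extra edges among the participating nodes do
#' not disqualify an instance.
#'
#' @param network a [GRNetwork-class] (or an edge data.frame with `source`
#'   and `target` columns).
#' @return data.frame: `gene_id`, `ffl`, `feedback`, `diamond`, `bifan`.
#' @export
countMotifs <- function(network) {
  e <- if (is(network, "GRNetwork")) edges(network) else network
  src <- nodeGene(e$source); tgt <- nodeGene(e$target)
  keep <- src != tgt
  pairs <- unique(data.frame(src = src[keep], tgt = tgt[keep]))
  genes <- sort(unique(c(pairs$src, pairs$tgt)))
  n <- length(genes)
  zero <- numeric(n)
  counts <- data.frame(gene_id = genes, ffl = zero, feedback = zero,
                       diamond = zero, bifan = zero)
  if (n < 2L || !nrow(pairs)) return(counts)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  A[cbind(match(pairs$src, genes), match(pairs$tgt, genes))] <- 1
  # feedback: one instance per mutual pair, counted at both members
  mutual <- A * t(A)
  counts$feedback <- rowSums(mutual)
  # feed-forward: paths A->B->C closed by A->C; roles are asymmetric
  A2 <- A %*% A
  counts$ffl <- rowSums(A * A2) +            # as A
    rowSums(t(A) * (A %*% t(A))) +           # as middle B
    colSums(A * A2)                          # as C
  # diamond: choose 2 distinct intermediates between ordered apexes (a, d)
  P2 <- A2
  diag(P2) <- 0
  inst <- choose(P2, 2)
  diag(inst) <- 0
  B <- P2 - 1
  diag(B) <- 0
  asMid <- vapply(seq_len(n), function(x)
    sum(A[, x] * (B %*% A[x, ])), numeric(1))
  counts$diamond <- rowSums(inst) + colSums(inst) + asMid
  # bi-fan: unordered source pair x unordered target pair
  CT <- A %*% t(A)   # common targets of two sources
  CS <- t(A) %*% A   # common sources of two targets
  diag(CT) <- 0; diag(CS) <- 0
  counts$bifan <- rowSums(choose(CT, 2)) + rowSums(choose(CS, 2))
  counts
}

#' Network Motif Score and ranking
#'
#' Each motif-type count is normalized to `[0, 1]` by the maximum count of
#' that type over all genes (0 when the maximum is 0); the Network Motif
#' Score (NMS) is the sum of the four normalized scores, so it lies in
#' `[0, 4]`. Ranks are dense and descending by NMS; ties share a rank.
#'
#' @param counts result of [countMotifs()].
#' @return the input with columns `nms` and `rank` appended.
#' @export
nmsRank <- function(counts) {
  norm1 <- function(v) { mx <- max(v); if (mx > 0) v / mx else rep(0, length(v)) }
  nms <- norm1(counts$ffl) + norm1(counts$feedback) +
    norm1(counts$diamond) + norm1(counts$bifan)
  counts$nms <- nms
  counts$rank <- match(nms, sort(unique(nms), decreasing = TRUE))
  counts[order(counts$rank, counts$gene_id), , drop = FALSE]
}

#' Hypergeometric enrichment of a gene set among network regulators
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between the network's regulator set (distinct source genes) and a gene
#' set of interest, given a stated gene universe.
#'
#' @param network a [GRNetwork-class].
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of all considered genes.
#' @return list: `overlap`, `n_regulators`, `n_set`, `n_universe`, `p`.
#' @export
regulatorEnrichment <- function(network, gene_set, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  regulators <- unique(nodeGene(edges(network)$source))
  if (!all(gene_set %in% universe) || !all(regulators %in% universe))
    stop("gene_set and regulators must be subsets of the universe")
  ov <- length(intersect(regulators, gene_set))
  p <- stats::phyper(ov - 1L, length(gene_set),
                     length(universe) - length(gene_set),
                     length(regulators), lower.tail = FALSE)
  list(overlap = ov, n_regulators = length(regulators),
       n_set = length(gene_set), n_universe = length(universe), p = p)
}
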