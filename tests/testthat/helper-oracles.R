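# Independent oracles, deliberately written differently from the package
# implementations they check.

# DTW by top-down recursion over the cumulative-cost lattice
oracle_dtw <- function(x, y) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 1L && j == 1L) return(abs(x[1L] - y[1L]))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    memo[[key]] <- abs(x[i] - y[j]) + best
    memo[[key]]
  }
  rec(length(x), length(y))
}

# per-gene motif counts by exhaustive enumeration over node tuples
oracle_motifs <- function(edge_df) {
  genes <- sort(unique(c(edge_df$source, edge_df$target)))
  has <- function(a, b) any(edge_df$source == a & edge_df$target == b)
  cnt <- matrix(0, length(genes), 4,
                dimnames = list(genes, c("ffl", "feedback", "diamond",
                                         "bifan")))
  n <- length(genes)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    A <- genes[a]; B <- genes[b]
    if (a < b && has(A, B) && has(B, A))
      cnt[c(A, B), "feedback"] <- cnt[c(A, B), "feedback"] + 1
    for (cc in seq_len(n)) {
      if (cc == a || cc == b) next
      C <- genes[cc]
      if (has(A, B) && has(B, C) && has(A, C))
        cnt[c(A, B, C), "ffl"] <- cnt[c(A, B, C), "ffl"] + 1
    }
  }
  # diamond: ordered apexes (a, d), unordered intermediates {b, c}
  for (a in seq_len(n)) for (d in seq_len(n)) {
    if (a == d) next
    A <- genes[a]; D <- genes[d]
    for (b in seq_len(n)) for (cc in seq_len(n)) {
      if (b >= cc || b %in% c(a, d) || cc %in% c(a, d)) next
      B <- genes[b]; C <- genes[cc]
      if (has(A, B) && has(A, C) && has(B, D) && has(C, D))
        cnt[c(A, B, C, D), "diamond"] <- cnt[c(A, B, C, D), "diamond"] + 1
    }
  }
  # bi-fan: unordered sources {a, b}, unordered targets {c, d}
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    for (cc in seq_len(n)) for (d in seq_len(n)) {
      if (cc >= d) next
      if (length(unique(c(a, b, cc, d))) < 4L) next
      A <- genes[a]; B <- genes[b]; C <- genes[cc]; D <- genes[d]
      if (has(A, C) && has(A, D) && has(B, C) && has(B, D))
        cnt[c(A, B, C, D), "bifan"] <- cnt[c(A, B, C, D), "bifan"] + 1
    }
  }
  cnt
}

random_digraph <- function(n_nodes, density) {
  genes <- sprintf("g%d", seq_len(n_nodes))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
}

# BH step-up written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
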