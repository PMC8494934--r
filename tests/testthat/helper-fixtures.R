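# Small builders shared across test files.

make_sample_info <- function(n_per_group = 2L, timepoints = c(15L, 30L),
                             batches = "b1", refs_per_batch = 0L) {
  grid <- expand.grid(replicate = seq_len(n_per_group),
                      timepoint_min = timepoints,
                      treatment = c("mock", "treated"),
                      stringsAsFactors = FALSE)
  grid$batch <- rep(batches, length.out = nrow(grid))
  si <- data.frame(
    sample_id = sprintf("%s_t%03d_r%d_%s", grid$treatment,
                        grid$timepoint_min, grid$replicate, grid$batch),
    treatment = grid$treatment, timepoint_min = grid$timepoint_min,
    replicate = grid$replicate, batch = grid$batch,
    channel = as.character(seq_len(nrow(grid))), is_reference = FALSE)
  if (refs_per_batch > 0L) {
    refs <- expand.grid(batch = unique(grid$batch),
                        ref = seq_len(refs_per_batch),
                        stringsAsFactors = FALSE)
    si <- rbind(si, data.frame(
      sample_id = sprintf("ref_%s_%d", refs$batch, refs$ref),
      treatment = NA_character_, timepoint_min = timepoints[1L],
      replicate = refs$ref, batch = refs$batch,
      channel = paste0("ref", refs$ref), is_reference = TRUE))
  }
  si
}

make_assay <- function(values, layer = "protein", sampleInfo) {
  OmicsAssay(values, layer, sampleInfo)
}

# design-key column names for hand-built regulator/target matrices
design_keys <- function(timepoints = c(15L, 30L, 60L, 120L, 240L, 480L),
                        reps = 4L) {
  grid <- expand.grid(replicate = seq_len(reps),
                      timepoint_min = timepoints,
                      treatment = c("mock", "treated"),
                      stringsAsFactors = FALSE)
  o <- order(grid$treatment, grid$timepoint_min, grid$replicate)
  sprintf("%s_t%03d_r%d", grid$treatment[o], grid$timepoint_min[o],
          grid$replicate[o])
}

random_network <- function(n_edges, seed = NULL, genes = sprintf("g%d", 1:12),
                           timepoints = c(15L, 30L, 60L)) {
  if (!is.null(seed)) set.seed(seed)
  got <- 0L
  rows <- list()
  seen <- character()
  while (got < n_edges) {
    s <- sample(genes, 1L); t <- sample(genes, 1L)
    if (s == t) next
    tp <- sample(timepoints, 1L)
    et <- sample(c("abundance", "phosphosite", "kinase"), 1L)
    key <- paste(s, t, et, tp)
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    rows[[got]] <- data.frame(source = s, target = t,
                              weight = round(stats::runif(1), 4),
                              edge_type = et, timepoint = tp,
                              site_label = NA_character_)
  }
  GRNetwork(do.call(rbind, rows))
}
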