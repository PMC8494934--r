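#' Read a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with the
#' sections `inputs` (paths: `transcript`, `protein`, `phosphosite`,
#' `sample_info`, `annotation`, `ploop`) or `simulate` (arguments for
#' [simConfig()], used instead of input files), plus optional `params`
#' overriding inference defaults (`n_trees`, `threshold_sd`, `cluster_k`,
#' `pearson_min`, `spearman_min`, `seed`) and `out_dir`.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$inputs) && is.null(config$simulate))
    stop("config needs an 'inputs' or a 'simulate' section")
  defaults <- list(n_trees = 1000L, threshold_sd = 1, cluster_k = NULL,
                   pearson_min = 0.5, spearman_min = 0.6, seed = 1L)
  config$params <- utils::modifyList(defaults,
                                     as.list(config$params)[
                                       nzchar(names(as.list(config$params)))])
  if (config$params$n_trees < 1 || config$params$threshold_sd < 0)
    stop("inference parameters must be positive")
  config
}

.load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- do.call(simConfig, config$simulate)
    return(simulateMultiomics(sim))
  }
  paths <- config$inputs
  req <- c("transcript", "protein", "phosphosite", "sample_info",
           "annotation", "ploop")
  miss <- setdiff(req, names(paths))
  if (length(miss))
    stop("config is missing input path(s): ", paste(miss, collapse = ", "))
  gone <- !vapply(unlist(paths[req]), file.exists, logical(1))
  if (any(gone))
    stop("input file(s) not found: ",
         paste(unlist(paths[req])[gone], collapse = ", "))
  si <- readSampleInfo(paths$sample_info)
  list(transcript = readExpression(paths$transcript, "transcript", si),
       protein = readExpression(paths$protein, "protein", si),
       phosphosite = readExpression(paths$phosphosite, "phosphosite", si),
       sampleInfo = si,
       annotation = readFeatureAnnotation(paths$annotation),
       ploop = readPloopTable(paths$ploop), truth = NULL)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], formatC, format = "g", digits = 15)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

# DE regulator row ids at one timepoint, per the layer each row came from
.de_regulators_at <- function(info, de_tables, tp) {
  ok <- vapply(seq_len(nrow(info)), function(i) {
    de <- de_tables[[info$source_layer[i]]]
    fid <- if (info$source_layer[i] == "phosphosite") info$row_id[i]
           else info$gene_id[i]
    any(de$is_de & de$feature_id == fid & de$timepoint_min == tp)
  }, logical(1))
  info$row_id[ok]
}

#' Run the whole inference pipeline
#'
#' Executes, in order: TMT normalization (sample loading then internal
#' reference) of the proteomic layers, per-timepoint DE calling on all
#' three layers, regulator-matrix assembly (abundance and phosphosite
#' modes), DTW clustering of the combined regulator/target profiles,
#' per-timepoint cluster-restricted subnetwork inference for both modes,
#' union merging, the correlation-based kinase-signaling network, and
#' motif scoring of the merged abundance and phosphosite networks. All
#' artifacts are written as TSV into `out_dir` together with a YAML
#' manifest recording parameters and seeds. All randomness derives from
#' the single configured seed.
#'
#' @param config YAML path or list (see [readPipelineConfig()]).
#' @param out_dir output directory (created if absent); overrides
#'   `config$out_dir`.
#' @return invisibly, a list with the in-memory artifacts (`networks`,
#'   `de`, `clusters`, `nms`, `data`).
#' @export
runPipeline <- function(config, out_dir = NULL) {
  config <- readPipelineConfig(config)
  p <- config$params
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dat <- stage("load", .load_inputs(config))

  norm <- stage("normalize", {
    lapply(dat[c("protein", "phosphosite")], function(a) {
      sl <- sampleLoadingNormalize(a)
      internalReferenceNormalize(sl$assay)$assay
    })
  })
  dat$protein <- norm$protein
  dat$phosphosite <- norm$phosphosite
  for (l in names(norm))
    .write_tsv(data.frame(feature_id = rownames(assay(norm[[l]])),
                          as.data.frame(assay(norm[[l]])),
                          check.names = FALSE),
               file.path(out_dir, paste0("normalized_", l, ".tsv")))

  de <- stage("de", {
    lapply(dat[c("transcript", "protein", "phosphosite")], callDE)
  })
  for (l in names(de))
    .write_tsv(de[[l]], file.path(out_dir, paste0("de_", l, ".tsv")))

  tf_genes <- sort(unique(dat$annotation$gene_id[dat$annotation$is_tf]))
  tgt_matrix <- designMatrix(dat$transcript)
  tps <- sort(unique(sampleInfo(dat$transcript)$timepoint_min))
  de_tr <- de$transcript

  networks <- list()
  clus_out <- list()
  for (mode in c("abundance", "phosphosite")) {
    reg <- stage(paste0("regulators_", mode),
      buildRegulatorMatrix(tf_genes, transcript = dat$transcript,
                           protein = dat$protein,
                           phospho = dat$phosphosite,
                           annotation = dat$annotation, mode = mode,
                           de_table = de$phosphosite))
    cm <- stage(paste0("cluster_", mode), {
      cm <- buildClusteringMatrix(reg, tgt_matrix)
      asg <- dtwCluster(cm, k = p$cluster_k)
      list(matrix = cm, assignment = asg, maps = clusterMaps(asg, cm))
    })
    clus_out[[mode]] <- data.frame(
      row_id = names(clusters(cm$assignment)),
      cluster = unname(clusters(cm$assignment)))
    info <- attr(reg, "info")
    subnets <- list()
    for (ti in seq_along(tps)) {
      tp <- tps[ti]
      de_reg <- .de_regulators_at(info, de, tp)
      de_tgt <- de_tr$feature_id[de_tr$is_de & de_tr$timepoint_min == tp]
      de_tgt <- intersect(de_tgt, rownames(tgt_matrix))
      if (!length(de_reg) || !length(de_tgt)) next
      subnets[[as.character(tp)]] <- stage(
        sprintf("infer_%s_t%d", mode, tp),
        suppressWarnings(inferSubnetwork(
          reg, tgt_matrix, cm$maps$regulator, cm$maps$target,
          de_reg, de_tgt, tp, nTrees = p$n_trees,
          seed = p$seed + 1000L * ti, thresholdSD = p$threshold_sd)))
    }
    networks[[mode]] <- mergeNetworks(subnets)
    writeEdgeTable(networks[[mode]],
                   file.path(out_dir, paste0("network_", mode, ".tsv")))
    .write_tsv(clus_out[[mode]],
               file.path(out_dir, paste0("clusters_", mode, ".tsv")))
  }

  networks$kinase <- stage("kinase_net", {
    regs <- selectPloopRegulators(de$phosphosite, dat$phosphosite,
                                  dat$annotation, dat$ploop)
    correlationEdges(regs, dat$phosphosite, de$phosphosite,
                     pearson_min = p$pearson_min,
                     spearman_min = p$spearman_min)
  })
  writeEdgeTable(networks$kinase, file.path(out_dir, "network_kinase.tsv"))

  networks$merged <- mergeNetworks(networks$abundance,
                                   networks$phosphosite, networks$kinase)
  writeEdgeTable(networks$merged, file.path(out_dir, "network_merged.tsv"))

  nms <- stage("nms", {
    lapply(networks[c("abundance", "phosphosite")],
           function(n) nmsRank(countMotifs(n)))
  })
  for (l in names(nms))
    .write_tsv(nms[[l]], file.path(out_dir, paste0("nms_", l, ".tsv")))

  manifest <- list(
    package = as.character(utils::packageVersion("omicGRN")),
    seed = p$seed, params = p[setdiff(names(p), "cluster_k")],
    n_features = list(
      transcript = nrow(assay(dat$transcript)),
      protein = nrow(assay(dat$protein)),
      phosphosite = nrow(assay(dat$phosphosite))),
    n_edges = lapply(networks, nEdges))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(networks = networks, de = de, clusters = clus_out,
                 nms = nms, data = dat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
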