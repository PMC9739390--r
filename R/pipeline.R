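## deterministic per-stage sub-seed from the run's global seed
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, deg = 23L, cluster = 37L, infer = 53L,
               compare = 71L, subnet = 89L, demo = 97L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or a named list.  Recognized fields:
#' `paths` (matrix, metadata, tf_list, reference_network, output_dir) and
#' `parameters` (top_n, nu, contrast, k, iterations, restarts,
#' max_lag_prop, alpha, n_permutations, combine_mode, consensus_k,
#' min_score, seeds...); unknown fields are rejected.
#'
#' @param config a list or a YAML file path.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(top_n = 3000, nu = NULL, contrast = "diff", k = 12,
                   iterations = 2000, restarts = 10, max_lag_prop = 0.1,
                   alpha = 0.05, n_permutations = 200,
                   combine_mode = "union", consensus_k = 2,
                   null_mode = "pooled", min_score = 0.4, seed = 1)
  params <- utils::modifyList(defaults, config$parameters %||% list())
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  paths <- config$paths %||% list()
  structure(list(paths = paths, parameters = params,
                 stages = config$stages %||% list()),
            class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages: read inputs, PCA summary, time-course statistic and top-DEG
#' selection, wave clustering, per-line network inference, line merge,
#' reference comparison, and an optional seed-TF sub-network.  Each stage
#' writes its artifact under `output_dir` together with a JSON run
#' manifest recording parameters and derived seeds.  With `resume = TRUE`
#' a stage whose output file already exists is reloaded instead of
#' recomputed.
#'
#' @param config a `PipelineConfig`, list, or YAML path.
#' @param resume reload existing stage outputs instead of recomputing.
#' @return list with the in-memory stage results (`dataset`, `pca`,
#'   `deg_stats`, `top_deg`, `clustering`, `line_networks`, `network`,
#'   `stats`, `overlap`, `successive_fraction`, `subnetwork`, `manifest`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (!inherits(config, "PipelineConfig")) config <- pipeline_config(config)
  p <- config$parameters
  paths <- config$paths
  out_dir <- paths$output_dir %||% stop("config paths$output_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_file <- function(name) file.path(out_dir, name)
  log_stage <- function(...) message("[tfchronet] ", ...)

  run_stage <- function(name, ...) {
    tryCatch(..., error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  log_stage("read: ", paths$matrix)
  dataset <- run_stage("read",
    read_expression(paths$matrix, paths$metadata))
  tf_list <- run_stage("read", read_gene_list(paths$tf_list))
  log_stage("read: ", nrow(dataset$values), " genes x ",
            ncol(dataset$values), " samples; ", length(tf_list), " TFs")

  pca <- run_stage("pca", pca_summary(dataset))

  deg_path <- stage_file("deg_stats.tsv")
  if (resume && file.exists(deg_path)) {
    deg_stats <- utils::read.delim(deg_path, stringsAsFactors = FALSE)
    log_stage("deg: resumed from ", deg_path)
  } else {
    tensor <- run_stage("deg", build_replicate_tensor(dataset))
    deg_stats <- run_stage("deg",
      mb_statistic(tensor, nu = p$nu, contrast = p$contrast))
    utils::write.table(deg_stats, deg_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  top_deg <- select_top_deg(deg_stats, p$top_n)
  tfs <- intersect(top_deg, tf_list)
  log_stage("deg: ", length(top_deg), " top DEGs, ", length(tfs),
            " time-varying TFs")

  cluster_path <- stage_file("clusters.tsv")
  cluster_seed <- derive_seed(p$seed, "cluster")
  clustering <- run_stage("cluster",
    cluster_waves(dataset, top_deg, k = p$k, iterations = p$iterations,
                  restarts = p$restarts, seed = cluster_seed))
  utils::write.table(
    data.frame(gene = names(clustering$assignment),
               raw_cluster = unname(clustering$assignment),
               chrono_label = unname(clustering$label_of_gene)),
    cluster_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("cluster: k = ", p$k)

  infer_seed <- derive_seed(p$seed, "infer")
  lines <- unique(dataset$samples$line_id)
  net_path <- stage_file("network.tsv")
  if (resume && file.exists(net_path)) {
    network <- read_network(net_path, "edge_tsv")
    line_networks <- NULL
    log_stage("infer: resumed from ", net_path)
  } else {
    line_networks <- lapply(seq_along(lines), function(i) {
      prof <- average_line_profiles(dataset, lines[i])
      cfg <- mac_config(max_lag_prop = p$max_lag_prop, alpha = p$alpha,
                        n_permutations = p$n_permutations,
                        seed = infer_seed + i, null_mode = p$null_mode)
      net <- run_stage("infer", infer_line_network(prof, tfs, cfg))
      write_network(net, stage_file(sprintf("network_line_%s.tsv", lines[i])),
                    "edge_tsv")
      net
    })
    network <- run_stage("infer",
      combine_line_networks(line_networks, p$combine_mode, p$consensus_k))
    write_network(network, net_path, "edge_tsv")
  }
  log_stage("infer: ", nrow(network$edges), " merged edges from ",
            length(lines), " lines")

  stats <- if (length(network$nodes) >= 2L) network_stats(network) else NULL
  ov <- NULL; succ <- NA_real_; subnet <- NULL
  if (!is.null(paths$reference_network)) {
    reference <- run_stage("compare",
      read_reference_network(paths$reference_network, p$min_score))
    ov <- run_stage("compare", overlap(network, reference))
    succ <- run_stage("compare",
      successive_cluster_links(network, reference, clustering))
  }
  if (!is.null(paths$seeds)) {
    subnet <- run_stage("subnet",
      extract_subnetwork(network, paths$seeds, clustering,
                         target_labels = paths$target_labels %||%
                           sort(unique(clustering$chrono_label))))
    write_network(subnet, stage_file("subnetwork.tsv"), "edge_tsv")
  }

  manifest <- list(parameters = p,
                   seeds = list(cluster = cluster_seed, infer = infer_seed),
                   n_genes = nrow(dataset$values),
                   n_samples = ncol(dataset$values),
                   n_tfs = length(tfs),
                   package_version = as.character(utils::packageVersion("tfchronet")))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(dataset = dataset, pca = pca, deg_stats = deg_stats,
       top_deg = top_deg, clustering = clustering,
       line_networks = line_networks, network = network, stats = stats,
       overlap = ov, successive_fraction = succ, subnetwork = subnet,
       manifest = manifest)
}

#' One-command synthetic demonstration run with recovery report
#'
#' Generates a default synthetic truth model (36 TFs in 12 waves, 50
#' lagged signed edges, 200 background genes) and dataset under the
#' study design (3 lines x 3 replicates x 32 days), runs the full
#' pipeline, and scores the result against the known truth.
#'
#' @param seed integer seed controlling every random stage.
#' @param output_dir where stage artifacts are written (default a
#'   temporary directory).
#' @param n_tfs,n_edges,n_background,noise_sd generator settings.
#' @return list with `pipeline` (the [run_pipeline()] bundle), `truth`,
#'   and `recovery`: edge `precision`, `recall`, `sign_accuracy`,
#'   `mean_lag_error` (days, on recovered true edges) and `cluster_ari`
#'   (adjusted Rand index of recovered waves vs true waves).
#' @export
run_demo <- function(seed = 1, output_dir = tempfile("tfchronet_demo_"),
                     n_tfs = 36, n_edges = 50, n_background = 200,
                     noise_sd = 0.3) {
  sim_seed <- derive_seed(seed, "simulate")
  truth <- generate_truth(n_tfs = n_tfs, k_waves = 12, n_edges = n_edges,
                          max_lag = 3, seed = sim_seed,
                          n_background = n_background)
  sim <- simulate_expression(truth,
    simulation_config(noise_sd = noise_sd, seed = sim_seed + 1L))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  matrix_path <- file.path(output_dir, "expression.tsv")
  metadata_path <- file.path(output_dir, "metadata.tsv")
  tf_path <- file.path(output_dir, "tf_list.txt")
  write_expression(sim$dataset, matrix_path, metadata_path)
  writeLines(truth$tf_names, tf_path)
  write_truth(truth, output_dir)

  cfg <- pipeline_config(list(
    paths = list(matrix = matrix_path, metadata = metadata_path,
                 tf_list = tf_path, output_dir = output_dir),
    parameters = list(top_n = n_tfs + 20, seed = seed)))
  res <- run_pipeline(cfg)
  recovery <- recovery_report(res$network, truth, res$clustering)
  jsonlite::write_json(recovery, file.path(output_dir, "recovery.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(pipeline = res, truth = truth, recovery = recovery,
       output_dir = output_dir)
}

#' Score an inferred network and clustering against a truth model
#'
#' @param network a `DirectedNetwork`.
#' @param truth a `TruthModel`.
#' @param clustering optional `WaveClustering` over (at least) the TFs.
#' @return list with `precision`, `recall`, `sign_accuracy`,
#'   `mean_lag_error`, and `cluster_ari` (NA without a clustering).
#' @export
recovery_report <- function(network, truth, clustering = NULL) {
  stopifnot(inherits(network, "DirectedNetwork"),
            inherits(truth, "TruthModel"))
  true_key <- paste(truth$edges$source, truth$edges$target)
  got_key <- paste(network$edges$source, network$edges$target)
  tp <- intersect(true_key, got_key)
  precision <- if (length(got_key)) length(tp) / length(got_key) else NA_real_
  recall <- if (length(true_key)) length(tp) / length(true_key) else NA_real_
  if (length(tp)) {
    ti <- match(tp, true_key)
    gi <- match(tp, got_key)
    sign_ok <- (truth$edges$sign[ti] > 0) ==
      (network$edges$edge_type[gi] == "activation")
    sign_accuracy <- mean(sign_ok)
    mean_lag_error <- mean(abs(truth$edges$lag_days[ti] -
                                 network$edges$lag_days[gi]))
  } else {
    sign_accuracy <- NA_real_
    mean_lag_error <- NA_real_
  }
  cluster_ari <- NA_real_
  if (!is.null(clustering)) {
    labels <- gene_labels(clustering)
    common <- intersect(names(labels), truth$tf_names)
    if (length(common) >= 2L)
      cluster_ari <- mclust::adjustedRandIndex(labels[common],
                                               truth$wave_of[common])
  }
  list(precision = precision, recall = recall,
       sign_accuracy = sign_accuracy, mean_lag_error = mean_lag_error,
       cluster_ari = cluster_ari)
}
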