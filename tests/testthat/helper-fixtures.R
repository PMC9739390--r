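# shared in-code fixtures; everything is generated, nothing stored on disk

# tiny dataset: n_genes x (2 replicates x days -1..1), values settable
tiny_dataset <- function(values = NULL, n_genes = 4) {
  days <- -1:1
  meta <- expand.grid(day = days, replicate_id = c("R1", "R2"),
                      stringsAsFactors = FALSE)
  meta$line_id <- "L1"
  meta$sample_id <- sprintf("%s_%s_D%d", meta$line_id, meta$replicate_id,
                            meta$day)
  if (is.null(values)) {
    set.seed(99)
    values <- matrix(rnorm(n_genes * nrow(meta)), n_genes, nrow(meta))
  }
  dimnames(values) <- list(sprintf("G%d", seq_len(nrow(values))),
                           meta$sample_id)
  expression_dataset(values, meta[, c("sample_id", "line_id",
                                      "replicate_id", "day")])
}

# dataset from explicit per-day gene profiles, replicated with noise
profile_dataset <- function(profiles, days, n_lines = 1, n_reps = 2,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  meta <- expand.grid(day = days, replicate_id = sprintf("R%d", 1:n_reps),
                      line_id = sprintf("L%d", 1:n_lines),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_D%d", meta$line_id, meta$replicate_id,
                            meta$day)
  values <- sapply(seq_len(nrow(meta)), function(j) {
    profiles[, match(meta$day[j], days)] +
      rnorm(nrow(profiles), sd = noise_sd)
  })
  dimnames(values) <- list(rownames(profiles), meta$sample_id)
  expression_dataset(values, meta[, c("sample_id", "line_id",
                                      "replicate_id", "day")])
}

# small directed network from source/target/mac vectors
toy_network <- function(src, tgt, mac = rep(0.9, length(src)),
                        lag = rep(1, length(src)), nodes = NULL) {
  directed_network(data.frame(
    source = src, target = tgt, lag_days = lag, mac = mac,
    p_value = 0.01,
    edge_type = ifelse(mac > 0, "activation", "repression"),
    stringsAsFactors = FALSE), nodes = nodes)
}

# independent brute-force lagged-correlation oracle (kept deliberately
# naive: plain loops, stats::cor on explicit windows)
brute_force_mac <- function(x, y, max_lag) {
  best <- list(lag_star = 0L, mac = 0)
  for (l in 0:max_lag) {
    xs <- x[1:(length(x) - l)]
    ys <- y[(1 + l):length(y)]
    r <- if (sd(xs) == 0 || sd(ys) == 0) 0 else cor(xs, ys)
    if (abs(r) > abs(best$mac)) best <- list(lag_star = l, mac = r)
  }
  best
}

# run per-line inference + union merge on a simulated dataset
infer_from_sim <- function(sim, seed = 1, config_args = list()) {
  lines <- unique(sim$dataset$samples$line_id)
  nets <- lapply(seq_along(lines), function(i) {
    cfg <- do.call(mac_config, c(list(seed = seed + i), config_args))
    infer_line_network(average_line_profiles(sim$dataset, lines[i]),
                       sim$truth$tf_names, cfg)
  })
  combine_line_networks(nets, "union")
}
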