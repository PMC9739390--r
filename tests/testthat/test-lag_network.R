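test_that("line profiles average replicates per day in sorted order", {
  days <- -1:4
  prof <- matrix(seq_len(12), 2, 6,
                 dimnames = list(c("A", "B"), as.character(days)))
  ds <- profile_dataset(prof, days, n_lines = 2, n_reps = 3, noise_sd = 0)
  # perturb one line/day triplet to check the mean
  cols <- ds$samples$sample_id[ds$samples$line_id == "L1" &
                                 ds$samples$day == 2]
  ds$values["A", cols] <- c(1, 2, 3)
  avg <- average_line_profiles(ds, "L1")
  expect_equal(avg["A", "2"], 2.0)
  expect_equal(colnames(avg), as.character(days))
  expect_equal(ncol(avg), 6L)
  # single replicate: identity
  one <- ds$samples$line_id == "L2" & ds$samples$replicate_id == "R1"
  ds_one <- expression_dataset(ds$values[, one], ds$samples[one, ])
  expect_equal(average_line_profiles(ds_one, "L2"), ds_one$values,
               ignore_attr = "dimnames")
  expect_error(average_line_profiles(ds, "L9"), "unknown line")
})

test_that("mac_score finds the generating shift with its sign", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  y <- c(0, 0, 1, 3, 2, 5, 4, 7, 6, 9)
  ms <- mac_score(x, y, max_lag = 3)
  expect_equal(ms$lag_star, 2L)
  expect_equal(ms$mac, 1.0)
  ms_neg <- mac_score(x, -y, max_lag = 3)
  expect_equal(ms_neg$lag_star, 2L)
  expect_equal(ms_neg$mac, -1.0)
  expect_error(mac_score(x, y[-1], 3), "length mismatch")
})

test_that("mac_score matches the brute-force oracle on random fixtures", {
  set.seed(31)
  for (rep in 1:5) {
    prof <- matrix(rnorm(3 * 10), 3, 10,
                   dimnames = list(c("A", "B", "C"), NULL))
    all <- tfchronet:::mac_all_pairs(prof, 3)
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      oracle <- brute_force_mac(prof[i, ], prof[j, ], 3)
      got <- mac_score(prof[i, ], prof[j, ], 3)
      expect_equal(got$lag_star, oracle$lag_star)
      expect_equal(got$mac, oracle$mac)
      expect_equal(all$mac[i, j], oracle$mac)
      expect_equal(all$lag[i, j], oracle$lag_star)
    }
  }
})

test_that("lag-0 MAC is symmetric and ties resolve to the smallest lag", {
  set.seed(32)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(mac_score(x, y, 0)$mac, mac_score(y, x, 0)$mac)
  # period-2 profile equally correlated at lag 0 and lag 2 -> lag 0 wins
  p <- rep(c(0, 1), 6)
  expect_equal(mac_score(p, p, 3)$lag_star, 0L)
  # zero-variance window treated as correlation 0
  expect_equal(mac_score(rep(1, 10), rnorm(10), 2)$mac, 0)
})

test_that("MAC respects affine transforms, flipping with negative slope", {
  set.seed(33)
  x <- cumsum(rnorm(15)); y <- cumsum(rnorm(15))
  base <- mac_score(x, y, 3)
  up <- mac_score(2.5 * x + 7, 0.3 * y - 2, 3)
  expect_equal(up$mac, base$mac, tolerance = 1e-12)
  expect_equal(up$lag_star, base$lag_star)
  down <- mac_score(-1.5 * x + 4, y, 3)
  expect_equal(down$mac, -base$mac, tolerance = 1e-12)
})

test_that("permutation p-values are deterministic and floored at 1/(1+N)", {
  set.seed(34)
  prof <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(sprintf("G%d", 1:5), NULL))
  # plant one perfect lagged pair
  prof[2, ] <- c(0, 0, prof[1, 1:18])
  p1 <- permutation_pvalues(prof, max_lag = 2, n_permutations = 50, seed = 7)
  p2 <- permutation_pvalues(prof, max_lag = 2, n_permutations = 50, seed = 7)
  expect_identical(p1, p2)
  n_null <- 50 * 5 * 4
  expect_true(all(p1$p_value >= 1 / (1 + n_null)))
  planted <- p1[p1$source == "G1" & p1$target == "G2", ]
  expect_equal(planted$lag_star, 2L)
  expect_equal(planted$mac, 1.0)
  expect_equal(planted$p_value, 1 / (1 + n_null))  # above every null value
  # per-pair mode agrees on the planted pair's extremity
  pp <- permutation_pvalues(prof, max_lag = 2, n_permutations = 50, seed = 7,
                            null_mode = "per_pair")
  expect_equal(pp[pp$source == "G1" & pp$target == "G2", "p_value"],
               1 / 51)
})

test_that("a noiseless lagged edge is retained with its lag and type", {
  tm <- generate_truth(n_tfs = 2, k_waves = 2, n_edges = 1, max_lag = 3,
                       seed = 4, onsets = c(1, 3), wave_polarity = c(1, 1))
  sim <- simulate_expression(tm, simulation_config(noise_sd = 0,
                                                   line_offset_sd = 0,
                                                   seed = 5))
  prof <- average_line_profiles(sim$dataset, "L1")
  net <- infer_line_network(prof, tm$tf_names, mac_config(seed = 6))
  e <- net$edges[net$edges$source == tm$edges$source &
                   net$edges$target == tm$edges$target, ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$lag_days, 2)
  expect_equal(e$edge_type, "activation")
  # retained edges reproduce their stored (lag, mac) from the profiles
  for (i in seq_len(nrow(net$edges))) {
    ms <- mac_score(prof[net$edges$source[i], ],
                    prof[net$edges$target[i], ], 3)
    expect_equal(ms$lag_star, net$edges$lag_days[i])
    expect_equal(ms$mac, net$edges$mac[i])
  }
  # degenerate inputs
  expect_equal(nrow(infer_line_network(prof, character(0),
                                       mac_config())$edges), 0L)
  expect_error(infer_line_network(prof, c("TF001", "GHOST"), mac_config()),
               "GHOST")
})

test_that("inference is bit-reproducible for a fixed seed and config", {
  tm <- generate_truth(n_tfs = 8, k_waves = 4, n_edges = 8, seed = 41)
  sim <- simulate_expression(tm, simulation_config(noise_sd = 0.3, seed = 42))
  prof <- average_line_profiles(sim$dataset, "L2")
  n1 <- infer_line_network(prof, tm$tf_names, mac_config(seed = 43))
  n2 <- infer_line_network(prof, tm$tf_names, mac_config(seed = 43))
  expect_identical(n1, n2)
})

test_that("per-line networks merge by union/intersection/consensus rules", {
  netA <- toy_network(c("A", "B"), c("B", "C"), mac = c(0.9, -0.8),
                      lag = c(1, 2))
  # identical networks are a fixed point (modulo provenance columns)
  same <- combine_line_networks(list(netA, netA, netA), "intersection")
  expect_equal(same$edges[, names(netA$edges)], netA$edges)
  expect_true(all(same$edges$n_lines == 3))

  netB <- toy_network("A", "B", mac = 0.85, lag = 1)
  two_of_three <- combine_line_networks(list(netA, netA, netB), "consensus_k",
                                        k = 2)
  expect_true("B" %in% two_of_three$edges$source)      # edge B->C in 2 lines
  inter <- combine_line_networks(list(netA, netA, netB), "intersection")
  expect_equal(inter$edges$source, "A")                # only A->B in all 3
  expect_error(combine_line_networks(list(netA), "consensus_k", k = 2),
               "exceeds")

  # sign conflict: positive in 2 lines, negative in 1
  netC <- toy_network("A", "B", mac = -0.7, lag = 1)
  maj <- combine_line_networks(list(netA, netB, netC), "consensus_k", k = 2)
  eAB <- maj$edges[maj$edges$source == "A" & maj$edges$target == "B", ]
  expect_equal(eAB$edge_type, "activation")
  expect_true(eAB$sign_conflict)
  expect_equal(eAB$mac, mean(c(0.9, 0.85)))   # mean over majority-sign lines
  # under intersection the conflicted edge drops
  inter2 <- combine_line_networks(list(netA, netB, netC), "intersection")
  expect_false("A" %in% inter2$edges$source)
})

test_that("recovery degrades monotonically with noise on synthetic truth", {
  res <- sapply(c(0, 0.5, 1.5), function(ns) {
    tm <- generate_truth(n_tfs = 12, k_waves = 6, n_edges = 12, seed = 51)
    sim <- simulate_expression(tm, simulation_config(noise_sd = ns,
                                                     seed = 52))
    r <- recovery_report(infer_from_sim(sim, seed = 53), tm)
    c(r$precision, r$recall)
  })
  expect_true(all(diff(res[2, ]) <= 0.05))  # recall within MC slack
  expect_gte(res[2, 1], 0.99)               # noiseless recall
})
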