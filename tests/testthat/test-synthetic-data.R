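test_that("environment series respects the pH band, bran pulses and determinism", {
  des <- fermentation_design()
  env <- simulate_environment(des, seed = 11)
  expect_true(all(env$ph >= 9.37 & env$ph <= 11.5))
  expect_true(all(env$ph >= des$ph_floor)) # reset happens the day it would cross
  expect_true(all(c("labile", "dead_cells", "bran") %in% names(env)))
  expect_true(all(env$labile >= 0 & env$dead_cells >= 0 & env$bran >= 0))
  # byte-identical under the same seed; different under another
  expect_identical(env, simulate_environment(des, seed = 11))
  expect_false(identical(env, simulate_environment(des, seed = 12)))
  # pH never dwells below the floor for more than one step (never emitted below)
  expect_true(all(env$ph >= des$ph_floor - 1e-12))
})

test_that("bran pool jumps on bran days and decays exponentially", {
  des <- fermentation_design(
    batches = tibble::tibble(batch_id = "B1", pretreat_temp = 25, pretreat_ph = 10.5),
    bran_days = 5L, sampling_days = c(1:20)
  )
  env <- simulate_environment(des, params = env_dynamics_params(bran_decay_days = 30), seed = 1)
  expect_equal(env$bran[env$day < 5], rep(0, 4))
  expect_equal(env$bran[env$day == 5], des$bran_amount)
  late <- env$bran[env$day >= 5]
  expect_true(all(diff(late) < 0))
  # closed-form decay from the pulse
  expect_equal(env$bran[env$day == 15], exp(-10 / 30), tolerance = 1e-12)
})

test_that("zero acid production and no Ca(OH)2 events leave pH constant", {
  des <- fermentation_design(
    batches = tibble::tibble(batch_id = "B1", pretreat_temp = 25, pretreat_ph = 10.5),
    sampling_days = 1:10
  )
  p <- env_dynamics_params(acid_rate = 0, acid_noise_sd = 0)
  env <- simulate_environment(des, p, seed = 1)
  expect_equal(env$ph, rep(10.5, 10))
  expect_false(any(env$caoh2_added))
})

test_that("non-finite dynamics parameters are rejected by name", {
  expect_error(env_dynamics_params(orp_start = NaN), "orp_start")
  expect_error(
    simulate_environment(fermentation_design(),
                         params = structure(list(acid_rate = Inf), class = "env_dynamics_params")),
    "acid_rate"
  )
})

test_that("community update matches a step-by-step independent evaluation", {
  taxa <- two_taxon_catalog()
  des <- fermentation_design(
    batches = tibble::tibble(batch_id = "B1", pretreat_temp = 25, pretreat_ph = 10.2),
    sampling_days = 1:15
  )
  p <- env_dynamics_params(growth_noise_sd = 0, acid_rate = 0, acid_noise_sd = 0,
                           orp_noise_sd = 0, density_penalty = 1)
  env <- simulate_environment(des, p, seed = 2)
  traj <- simulate_community(taxa, env, params = p, seed = 2)
  # independent hand evaluation of the multiplicative update rule
  x <- c(0.5, 0.5)
  hand <- matrix(0, nrow(env), 2)
  for (t in seq_len(nrow(env))) {
    f <- vapply(1:2, function(i) {
      ph_k <- p$ph_gain * exp(-(env$ph[t] - taxa$ph_optimum[i])^2 / (2 * taxa$ph_width[i]^2))
      sgn <- if (taxa$orp_direction[i] == "prefers_high") 1 else -1
      orp_k <- p$orp_gain / (1 + exp(-sgn * (env$orp[t] - taxa$orp_midpoint[i]) / p$orp_halfwidth))
      sub <- p$substrate_gain * (0.5 * env$labile[t] + 0.5 * env$dead_cells[t] + 0.5 * env$bran[t])
      taxa$baseline_fitness[i] + ph_k + orp_k + sub - p$density_penalty * x[i]
    }, numeric(1))
    x <- x * exp(f)
    x <- x / sum(x)
    hand[t, ] <- x
  }
  expect_equal(as.matrix(traj[, c("A", "B")]), hand, ignore_attr = TRUE, tolerance = 1e-12)
  # anaerobe share non-decreasing after the ORP crossover under falling ORP
  cross <- which(env$orp < taxa$orp_midpoint[2])[1]
  expect_true(all(diff(traj$B[cross:nrow(traj)]) > -1e-12))
})

test_that("community symmetries: identical taxa stay identical, single taxon is 1", {
  taxa <- two_taxon_catalog(orp_directions = c("prefers_low", "prefers_low"))
  env <- simulate_environment(fermentation_design(
    batches = tibble::tibble(batch_id = "B1", pretreat_temp = 25, pretreat_ph = 10.2),
    sampling_days = 1:12
  ), seed = 3)
  p0 <- env_dynamics_params(growth_noise_sd = 0)
  traj <- simulate_community(taxa, env, params = p0, seed = 3)
  expect_equal(traj$A, traj$B, tolerance = 1e-12)
  single <- simulate_community(dplyr::slice(default_taxon_catalog(), 1:2), env,
                               params = p0, seed = 1, init = c(1, 0))
  expect_equal(single[[2]], rep(1, nrow(env)))
  expect_error(simulate_community(taxa, env, params = p0, seed = 1, init = c(0, 0)),
               "not all zero")
  m <- as.matrix(traj[, -1])
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("read sampling is multinomial at the requested depths", {
  traj <- tibble::tibble(day = 1:2, A = c(0.5, 1), B = c(0.5, 0))
  ft <- sample_reads(traj, depths = c(8825, 100), seed = 1)
  expect_equal(sum(ft$S1), 8825)
  expect_equal(ft$S2, c(100, 0))
  expect_identical(ft, sample_reads(traj, depths = c(8825, 100), seed = 1))
  expect_error(sample_reads(tibble::tibble(day = 1, A = 0.6, B = 0.3), 10),
               "sum to 1")
  # binomial oracle on the first coordinate over replicate draws
  draws <- vapply(1:10000, function(i) {
    sample_reads(tibble::tibble(day = 1, A = 0.7, B = 0.3), 100, seed = i)$S1[1]
  }, numeric(1))
  se <- sqrt(100 * 0.7 * 0.3) / sqrt(10000)
  expect_lt(abs(mean(draws) - 70), 3 * se)
})

test_that("genome content plants causal KOs in reducer taxa", {
  taxa <- default_taxon_catalog(n_taxa = 20, n_reducers = 8, seed = 5)
  cm <- causal_function_model()
  g <- assign_genome_content(taxa, n_kos = 300, causal = cm, seed = 5)
  m <- as.matrix(g[, -1])
  expect_equal(dim(m), c(20, 300))
  expect_true(all(m >= 0 & m == round(m)))
  expect_true(all(cm$causal_kos %in% colnames(m)))
  red <- taxa$indigo_reducer
  for (k in cm$causal_kos) {
    expect_gt(mean(m[red, k]), mean(m[!red, k]))
  }
  # empty causal set: no constraint, any catalog allowed
  g0 <- assign_genome_content(taxa, n_kos = 10,
                              causal = causal_function_model(causal_kos = character()),
                              seed = 1)
  expect_true(all(as.matrix(g0[, -1]) >= 0))
  # no reducer present while causal set non-empty
  norr <- dplyr::mutate(taxa, indigo_reducer = FALSE)
  expect_error(assign_genome_content(norr, 300, cm, seed = 1), "indigo_reducer")
})

test_that("dye series follows the logistic causal law and encodes intensity in Lab", {
  taxa <- default_taxon_catalog(seed = 2)
  cm <- causal_function_model(noise_sd = 0)
  g <- assign_genome_content(taxa, 300, cm, seed = 2)
  # zero causal abundance: all causal copies zeroed
  g0 <- g
  g0[, cm$causal_kos] <- 0
  traj <- tibble::tibble(day = 1:3)
  traj[taxa$taxon_id] <- matrix(1 / nrow(taxa), 3, nrow(taxa))
  d0 <- emit_dye_series(traj, g0, cm, seed = 1)
  expect_equal(d0$intensity,
               rep(cm$baseline + (cm$saturation - cm$baseline) * 0.5, 3))
  # norm of emitted Lab reproduces intensity; b* is negative (blue)
  d <- emit_dye_series(traj, g, cm, seed = 1)
  expect_equal(sqrt(d$L^2 + d$a^2 + d$b^2), d$intensity, tolerance = 1e-6)
  expect_true(all(d$b <= 0))
  # monotone causal signal gives non-decreasing noise-free intensity
  red <- taxa$taxon_id[taxa$indigo_reducer]
  ramp <- tibble::tibble(day = 1:5)
  shares <- seq(0.1, 0.9, length.out = 5)
  for (tx in taxa$taxon_id) {
    ramp[[tx]] <- if (tx %in% red) shares / length(red) else (1 - shares) / (nrow(taxa) - length(red))
  }
  dr <- emit_dye_series(ramp, g, cm, seed = 1)
  expect_true(all(diff(dr$causal_signal) > 0))
  expect_true(all(diff(dr$intensity) > 0))
})

test_that("simulated datasets are deterministic and internally consistent", {
  ds <- simulate_fermentation(seed = 21)
  expect_identical(unclass(ds)[names(ds) != "design"],
                   unclass(simulate_fermentation(seed = 21))[names(ds) != "design"])
  # every sample has metadata, environment and dye records
  samples <- setdiff(names(ds$feature_table), "taxon_id")
  expect_setequal(samples, ds$metadata$sample_id)
  expect_setequal(samples, ds$dye$sample_id)
  key <- paste(ds$metadata$batch_id, ds$metadata$day)
  expect_true(all(key %in% paste(ds$environment$batch_id, ds$environment$day)))
  # column sums equal the drawn depths; depths within the design range
  depths <- colSums(as.matrix(ds$feature_table[, -1]))
  expect_true(all(depths >= ds$design$read_depth_range[1] &
                    depths <= ds$design$read_depth_range[2]))
  # truth causal KOs exist in the genome content
  expect_true(all(ds$truth$causal_kos %in% names(ds$genome_content)))
  # adding a batch leaves existing batches' environments untouched
  des5 <- fermentation_design(batches = dplyr::bind_rows(
    fermentation_design()$batches,
    tibble::tibble(batch_id = "B5", pretreat_temp = 25, pretreat_ph = 10.0)
  ))
  e4 <- simulate_environment(fermentation_design(), seed = 7)
  e5 <- simulate_environment(des5, seed = 7)
  expect_identical(e4, dplyr::filter(e5, batch_id != "B5"))
})
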