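# Synthetic community succession, sequencing noise, genome content with
# planted causal gene families, and the dye phenotype they drive.

#' Default taxon catalog
#'
#' A seeded catalog of taxon ecological profiles spanning the succession the
#' fermentation selects for: early aerobes preferring moderate pH and
#' positive ORP, facultative anaerobes, and alkaliphilic obligate anaerobes
#' and lactic-acid-type taxa preferring high pH, deeply negative ORP, and
#' bran/dead-cell substrates. A subset of the anaerobic/facultative taxa are
#' flagged as indigo reducers.
#'
#' @param n_taxa Number of taxa, default 40.
#' @param n_reducers Number of indigo-reducing taxa, default 8.
#' @param seed Integer seed for the catalog draw.
#' @return A tibble with one row per taxon: `taxon_id`, `oxygen_class`,
#'   `ph_optimum`, `ph_width`, `orp_midpoint`, `orp_direction`,
#'   `affinity_labile`, `affinity_dead`, `affinity_bran`,
#'   `baseline_fitness`, `indigo_reducer`.
#' @export
default_taxon_catalog <- function(n_taxa = 40, n_reducers = 8, seed = 1) {
  assert_that(n_taxa >= 2, "need at least two taxa")
  assert_that(n_reducers >= 1 && n_reducers < n_taxa, "n_reducers must be in [1, n_taxa)")
  with_seed(derive_seed(seed, "catalog"), {
    n_aer <- round(0.3 * n_taxa)
    n_fac <- round(0.3 * n_taxa)
    n_ana <- n_taxa - n_aer - n_fac
    oxygen_class <- c(
      rep("aerobe", n_aer), rep("facultative", n_fac), rep("obligate_anaerobe", n_ana)
    )
    anaerobic <- oxygen_class != "aerobe"
    # reducers drawn from the anaerobic/facultative pool, as in the fermentation
    reducer_idx <- sample(which(anaerobic), n_reducers)
    tibble(
      taxon_id = sprintf("T%03d", seq_len(n_taxa)),
      oxygen_class = oxygen_class,
      ph_optimum = ifelse(anaerobic, runif(n_taxa, 9.9, 10.9), runif(n_taxa, 8.8, 9.9)),
      ph_width = runif(n_taxa, 0.4, 0.9),
      orp_midpoint = runif(n_taxa, -350, -50),
      orp_direction = ifelse(oxygen_class == "aerobe", "prefers_high",
        ifelse(oxygen_class == "facultative",
          sample(c("prefers_high", "prefers_low"), n_taxa, replace = TRUE),
          "prefers_low"
        )
      ),
      affinity_labile = ifelse(anaerobic, runif(n_taxa, 0, 0.5), runif(n_taxa, 0.5, 1)),
      affinity_dead = ifelse(anaerobic, runif(n_taxa, 0.3, 1), runif(n_taxa, 0, 0.4)),
      # reducers are the dedicated bran degraders; everyone else barely
      # touches it, so the pulsed bran pool selectively drives the reducers
      affinity_bran = ifelse(seq_len(n_taxa) %in% reducer_idx,
        runif(n_taxa, 0.85, 1), runif(n_taxa, 0, 0.3)
      ),
      baseline_fitness = rnorm(n_taxa, 0, 0.15),
      indigo_reducer = seq_len(n_taxa) %in% reducer_idx
    )
  })
}

validate_taxa <- function(taxa) {
  need <- c(
    "taxon_id", "oxygen_class", "ph_optimum", "ph_width", "orp_midpoint",
    "orp_direction", "affinity_labile", "affinity_dead", "affinity_bran",
    "baseline_fitness", "indigo_reducer"
  )
  assert_that(all(need %in% names(taxa)),
              paste("taxon catalog missing columns:", paste(setdiff(need, names(taxa)), collapse = ", ")))
  assert_that(!anyDuplicated(taxa$taxon_id), "taxon ids must be unique")
  assert_that(all(taxa$ph_width > 0), "ph_width must be positive")
  aff <- as.matrix(taxa[, c("affinity_labile", "affinity_dead", "affinity_bran")])
  assert_that(all(aff >= 0 & aff <= 1), "substrate affinities must lie in [0, 1]")
  invisible(taxa)
}

#' Simulate community succession under an environment series
#'
#' Discrete-time multiplicative (replicator-like) update. The log-fitness of
#' taxon i on day t is
#' `baseline + ph_gain * exp(-(ph_t - opt_i)^2 / (2 w_i^2))
#'  + orp_gain * logistic(+/-(orp_t - mid_i) / halfwidth)
#'  + substrate_gain * sum(affinity * pool) - density_penalty * x_i + noise`,
#' with the ORP logistic signed by the taxon's preference. Abundances are
#' multiplied by `exp(fitness)` and renormalised to sum 1 each day.
#'
#' @param taxa Taxon catalog (see [default_taxon_catalog()]).
#' @param env Environment series for one batch (tibble with `day`, `ph`,
#'   `orp`, `labile`, `dead_cells`, `bran`).
#' @param params An [env_dynamics_params()] holding the kernel coefficients.
#' @param seed Integer seed (set `growth_noise_sd = 0` in `params` for a
#'   noise-free run).
#' @param init Optional initial abundance vector (summing to anything
#'   positive); defaults to uniform.
#' @return A wide tibble: `day` column plus one relative-abundance column per
#'   taxon; every row sums to 1.
#' @export
simulate_community <- function(taxa, env, params = env_dynamics_params(), seed = 1,
                               init = NULL) {
  validate_taxa(taxa)
  assert_that(nrow(taxa) >= 2, "need at least two taxa")
  assert_that(nrow(env) >= 1, "environment series is empty")
  n <- nrow(taxa)
  x <- if (is.null(init)) rep(1 / n, n) else as.numeric(init)
  assert_that(all(x >= 0) && sum(x) > 0, "initial abundances must be non-negative, not all zero")
  x <- x / sum(x)
  sign_orp <- ifelse(taxa$orp_direction == "prefers_high", 1, -1)
  aff <- as.matrix(taxa[, c("affinity_labile", "affinity_dead", "affinity_bran")])
  with_seed(seed, {
    out <- matrix(0, nrow(env), n, dimnames = list(NULL, taxa$taxon_id))
    for (t in seq_len(nrow(env))) {
      ph_term <- params$ph_gain * exp(-(env$ph[t] - taxa$ph_optimum)^2 / (2 * taxa$ph_width^2))
      orp_term <- params$orp_gain /
        (1 + exp(-sign_orp * (env$orp[t] - taxa$orp_midpoint) / params$orp_halfwidth))
      sub_term <- params$substrate_gain *
        as.numeric(aff %*% c(env$labile[t], env$dead_cells[t], env$bran[t]))
      fitness <- taxa$baseline_fitness + ph_term + orp_term + sub_term -
        params$density_penalty * x +
        (if (params$growth_noise_sd > 0) rnorm(n, 0, params$growth_noise_sd) else 0)
      x <- x * exp(fitness)
      x <- x / sum(x)
      out[t, ] <- x
    }
    dplyr::bind_cols(tibble(day = env$day), as_tibble(out))
  })
}

trajectory_matrix <- function(trajectory) {
  assert_that("day" %in% names(trajectory), "trajectory must have a day column")
  m <- as.matrix(trajectory[, setdiff(names(trajectory), "day"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(trajectory$day)
  m
}

#' Draw sequencing reads from a relative-abundance trajectory
#'
#' Each sample's taxon counts are drawn from a multinomial at that sample's
#' read depth, the standard stand-in for amplicon sequencing noise.
#'
#' @param trajectory A wide trajectory tibble (`day` + one column per taxon)
#'   whose rows sum to 1.
#' @param depths Integer vector of read depths, one per trajectory row.
#' @param seed Integer seed.
#' @param sample_ids Optional sample names; default `S<day>`.
#' @return A feature table (tibble `taxon_id` + one count column per sample);
#'   every column sums exactly to its depth.
#' @export
sample_reads <- function(trajectory, depths, seed = 1, sample_ids = NULL) {
  m <- trajectory_matrix(trajectory)
  assert_that(all(m >= 0), "proportions must be non-negative")
  assert_that(all(abs(rowSums(m) - 1) < 1e-9), "trajectory rows must sum to 1")
  assert_that(length(depths) == nrow(m) && all(depths >= 1), "need one depth >= 1 per row")
  ids <- sample_ids %||% paste0("S", trajectory$day)
  with_seed(seed, {
    counts <- vapply(
      seq_len(nrow(m)),
      function(i) as.integer(rmultinom(1, depths[i], m[i, ])),
      integer(ncol(m))
    )
    dimnames(counts) <- list(colnames(m), ids)
    matrix_to_table(counts)
  })
}

#' Causal gene-to-phenotype model
#'
#' Declares which KO gene families causally drive dyeing intensity in the
#' synthetic system, and how: the per-sample causal signal `s` (summed
#' abundance-weighted copy number of the causal KOs) maps to intensity
#' through `baseline + (saturation - baseline) * logistic(slope * s)` plus
#' Gaussian noise.
#'
#' @param causal_kos Character vector of causal KO ids (`K#####`).
#' @param slope Logistic slope (per unit causal abundance). The default maps
#'   the causal signal of a reducer-dominated community near the saturation
#'   shoulder while an early aerobe-dominated community sits near the floor
#'   of the logistic's upper half.
#' @param baseline,saturation Intensity floor/ceiling (CIELAB norm units).
#' @param noise_sd SD of the intensity noise. The default `NULL` scales the
#'   noise to the emitted series itself: 10% of the dynamic range (max minus
#'   min) of the noise-free intensity signal.
#' @param enrichment Extra copies of each causal KO carried by reducer taxa.
#' @return A list of class `causal_function_model`.
#' @export
causal_function_model <- function(causal_kos = c("K08325", "K03778", "K18981", "K00324", "K00325"),
                                  slope = 0.05,
                                  baseline = 5,
                                  saturation = 85,
                                  noise_sd = NULL,
                                  enrichment = 10) {
  assert_that(is.null(noise_sd) || noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(saturation > baseline, "saturation must exceed baseline")
  assert_that(all(grepl("^K\\d{5}$", causal_kos)), "causal KO ids must match K#####")
  structure(
    list(
      causal_kos = causal_kos, slope = slope, baseline = baseline,
      saturation = saturation, noise_sd = noise_sd, enrichment = enrichment
    ),
    class = "causal_function_model"
  )
}

#' Assign genome content (taxon-by-KO copy numbers)
#'
#' Draws a sparse non-negative integer copy-number matrix: most gene families
#' are absent from most taxa (presence probability `presence_p`), present
#' families carry `1 + Poisson` copies. Causal KOs follow the biology of a
#' phenotype-causing gene family: every indigo-reducer taxon carries
#' `causal$enrichment` extra copies, while non-reducers carry the gene only
#' rarely (`causal_leak_p`), guaranteeing a strictly higher reducer mean for
#' causal columns.
#'
#' @param taxa Taxon catalog.
#' @param n_kos Total number of KO gene families (>= number of causal KOs).
#' @param causal A [causal_function_model()].
#' @param seed Integer seed.
#' @param presence_p Probability a given (taxon, KO) pair is non-zero.
#' @param causal_leak_p Probability a non-reducer taxon carries a causal KO.
#' @return A tibble: `taxon_id` plus one integer column per KO id. Causal KO
#'   ids come from `causal`; filler ids are drawn from the unused `K#####`
#'   space.
#' @export
assign_genome_content <- function(taxa, n_kos = 300, causal = causal_function_model(),
                                  seed = 1, presence_p = 0.1, causal_leak_p = 0.05) {
  validate_taxa(taxa)
  n_causal <- length(causal$causal_kos)
  assert_that(n_kos >= n_causal, "n_kos must cover the causal set")
  if (n_causal > 0 && !any(taxa$indigo_reducer)) {
    abort("causal KO set is non-empty but no taxon is flagged indigo_reducer")
  }
  filler_pool <- setdiff(sprintf("K%05d", seq_len(n_kos + n_causal)), causal$causal_kos)
  ko_ids <- c(causal$causal_kos, filler_pool[seq_len(n_kos - n_causal)])
  n <- nrow(taxa)
  with_seed(derive_seed(seed, "genome"), {
    present <- matrix(rbinom(n * n_kos, 1, presence_p), n, n_kos)
    copies <- present * (1 + matrix(rpois(n * n_kos, 1), n, n_kos))
    dimnames(copies) <- list(taxa$taxon_id, ko_ids)
    if (n_causal > 0) {
      red <- taxa$indigo_reducer
      for (k in causal$causal_kos) {
        leak <- rbinom(sum(!red), 1, causal_leak_p) * (1 + rpois(sum(!red), 1))
        copies[!red, k] <- leak
        copies[red, k] <- causal$enrichment + rpois(sum(red), 1)
        # enforce the strict reducer-mean contract even for tiny catalogs
        while (mean(copies[red, k]) <= mean(copies[!red, k])) {
          copies[red, k] <- copies[red, k] + max(1, causal$enrichment)
        }
      }
    }
    dplyr::bind_cols(tibble(taxon_id = taxa$taxon_id), as_tibble(copies))
  })
}

genome_matrix <- function(genome) {
  m <- as.matrix(genome[, setdiff(names(genome), "taxon_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genome$taxon_id
  assert_that(all(m >= 0), "copy numbers must be non-negative")
  m
}

logistic <- function(u) 1 / (1 + exp(-u))

#' Emit the dye-phenotype series implied by a community trajectory
#'
#' Per day, the causal signal is `s = sum over causal KOs, taxa of
#' abundance x copy number`; intensity follows the logistic law of the
#' causal model plus Gaussian noise (negative draws are clipped to 0 and
#' flagged). Each intensity is decomposed into an (L*, a*, b*) triple lying
#' along a fixed indigo-like direction with b* < 0, so that
#' `sqrt(L^2 + a^2 + b^2)` reproduces the intensity to within 1e-6.
#'
#' @param trajectory Wide relative-abundance trajectory (`day` + taxa).
#' @param genome Genome content tibble from [assign_genome_content()].
#' @param causal A [causal_function_model()].
#' @param seed Integer seed for the intensity noise.
#' @return A tibble: `day`, `causal_signal`, `intensity`, `L`, `a`, `b`,
#'   `clipped`.
#' @export
emit_dye_series <- function(trajectory, genome, causal, seed = 1) {
  assert_that(nrow(trajectory) >= 1, "trajectory has no days")
  m <- trajectory_matrix(trajectory)
  g <- genome_matrix(genome)
  assert_that(all(colnames(m) %in% rownames(g)), "trajectory taxa missing from genome")
  ck <- intersect(causal$causal_kos, colnames(g))
  s <- if (length(ck) > 0) {
    as.numeric(m %*% rowSums(g[colnames(m), ck, drop = FALSE]))
  } else {
    rep(0, nrow(m))
  }
  with_seed(derive_seed(seed, "dye"), {
    signal <- causal$baseline +
      (causal$saturation - causal$baseline) * logistic(causal$slope * s)
    noise_sd <- causal$noise_sd %||% (0.1 * diff(range(signal)))
    intensity <- signal +
      (if (noise_sd > 0) rnorm(length(s), 0, noise_sd) else 0)
    clipped <- intensity < 0
    intensity <- pmax(intensity, 0)
    # indigo-like direction: dark, slightly red, strongly blue (b* < 0)
    u <- c(L = 0.891, a = 0.05, b = -0.45)
    u <- u / sqrt(sum(u^2))
    tibble(
      day = trajectory$day, causal_signal = s, intensity = intensity,
      L = u[["L"]] * intensity, a = u[["a"]] * intensity, b = u[["b"]] * intensity,
      clipped = clipped
    )
  })
}

#' Render a synthetic dyed-swatch image
#'
#' Emulates a scanned dyed cloth: an interior of the requested CIELAB colour
#' (plus optional per-pixel Lab texture noise) framed by a fixed light border
#' standing in for the undyed margin. Colours outside the sRGB gamut are
#' mapped to the nearest in-gamut colour and flagged via the
#' `clamped_fraction` attribute.
#'
#' @param lab Target interior colour, `c(L, a, b)`.
#' @param size Image side length in pixels (>= 8); images are square.
#' @param texture_noise_sd Per-pixel Gaussian noise SD in Lab units.
#' @param seed Integer seed for the texture noise.
#' @param border_fraction Width of the light frame as a fraction of the side.
#' @return A `size x size x 3` integer array of sRGB values in `[0, 255]`,
#'   with attribute `clamped_fraction`.
#' @export
render_swatch <- function(lab, size = 48, texture_noise_sd = 0, seed = 1,
                          border_fraction = 0.125) {
  assert_that(size >= 8, "size must be at least 8 pixels")
  lab <- as.numeric(lab)
  with_seed(derive_seed(seed, "swatch"), {
    npix <- size * size
    labs <- matrix(rep(lab, each = npix), ncol = 3)
    if (texture_noise_sd > 0) {
      labs <- labs + matrix(rnorm(npix * 3, 0, texture_noise_sd), ncol = 3)
      labs[, 1] <- pmin(pmax(labs[, 1], 0), 100)
    }
    border <- !extract_swatch_mask(array(0, c(size, size, 3)), border_fraction)
    frame_lab <- c(92, 0, 4) # off-white undyed cotton
    idx <- which(border)
    labs[idx, ] <- matrix(rep(frame_lab, each = length(idx)), ncol = 3)
    rgb <- lab_to_srgb(labs)
    img <- array(0L, c(size, size, 3))
    img[, , 1] <- as.integer(rgb$r)
    img[, , 2] <- as.integer(rgb$g)
    img[, , 3] <- as.integer(rgb$b)
    interior <- !border
    attr(img, "clamped_fraction") <- mean(rgb$clamped[which(interior)])
    img
  })
}

#' Simulate a complete fermentation dataset
#'
#' End-to-end generator: environment per batch, community succession, read
#' sampling at the design's sampling days, genome content with planted
#' causal KOs, and the dye series the causal KOs drive. Each stage draws
#' from its own substream of the master seed.
#'
#' @param design A [fermentation_design()].
#' @param params An [env_dynamics_params()].
#' @param taxa Taxon catalog; default [default_taxon_catalog()] reseeded from
#'   `seed`.
#' @param causal A [causal_function_model()].
#' @param n_kos Number of KO gene families.
#' @param seed Master integer seed.
#' @return A list of class `indigo_dataset`: `feature_table`, `metadata`
#'   (sample_id, batch_id, day, ph, orp, dye_intensity), `environment`,
#'   `genome_content`, `dye`, `trajectories` (per-batch daily truth), and
#'   `truth` (causal KO ids, reducer taxa, seed).
#' @export
simulate_fermentation <- function(design = fermentation_design(),
                                  params = env_dynamics_params(),
                                  taxa = NULL,
                                  causal = causal_function_model(),
                                  n_kos = 300,
                                  seed = 1) {
  if (is.null(taxa)) taxa <- default_taxon_catalog(seed = derive_seed(seed, "taxa"))
  validate_taxa(taxa)
  env <- simulate_environment(design, params, seed = seed)
  genome <- assign_genome_content(taxa, n_kos = n_kos, causal = causal, seed = seed)
  # the sukumo inoculum is aerobically composted: aerobes dominate at day 0
  init <- c(aerobe = 3, facultative = 1, obligate_anaerobe = 0.3)[taxa$oxygen_class]
  per_batch <- purrr::map(design$batches$batch_id, function(bid) {
    benv <- dplyr::filter(env, .data$batch_id == bid)
    traj <- simulate_community(taxa, benv,
      params = params,
      seed = derive_seed(seed, "community", bid),
      init = init
    )
    samp <- dplyr::filter(traj, .data$day %in% design$sampling_days)
    depths <- with_seed(derive_seed(seed, "depths", bid), {
      as.integer(round(runif(
        nrow(samp), design$read_depth_range[1], design$read_depth_range[2]
      )))
    })
    ids <- sprintf("%s_D%d", bid, samp$day)
    ft <- sample_reads(samp, depths,
      seed = derive_seed(seed, "reads", bid),
      sample_ids = ids
    )
    dye <- emit_dye_series(samp, genome, causal, seed = derive_seed(seed, "dye", bid))
    list(
      batch_id = bid, trajectory = traj, feature_table = ft,
      dye = dplyr::bind_cols(tibble(sample_id = ids, batch_id = bid), dye),
      meta = dplyr::left_join(
        tibble(sample_id = ids, batch_id = bid, day = samp$day),
        dplyr::select(benv, "day", "ph", "orp"),
        by = "day"
      )
    )
  })
  feature_table <- purrr::reduce(
    purrr::map(per_batch, "feature_table"),
    dplyr::left_join,
    by = "taxon_id"
  )
  dye <- purrr::map_dfr(per_batch, "dye")
  metadata <- purrr::map_dfr(per_batch, "meta") %>%
    dplyr::left_join(dplyr::select(dye, "sample_id", dye_intensity = "intensity"),
      by = "sample_id"
    )
  structure(
    list(
      feature_table = feature_table,
      metadata = metadata,
      environment = env,
      genome_content = genome,
      dye = dye,
      trajectories = setNames(purrr::map(per_batch, "trajectory"), design$batches$batch_id),
      design = design,
      params = params,
      taxa = taxa,
      causal = causal,
      truth = list(
        causal_kos = causal$causal_kos,
        reducer_taxa = taxa$taxon_id[taxa$indigo_reducer],
        seed = seed
      )
    ),
    class = "indigo_dataset"
  )
}

#' @export
print.indigo_dataset <- function(x, ...) {
  cat(
    "<indigo_dataset>",
    sprintf(
      "  %d taxa x %d samples, %d batches, %d KO gene families",
      nrow(x$feature_table), ncol(x$feature_table) - 1,
      nrow(x$design$batches), ncol(x$genome_content) - 1
    ),
    sprintf(
      "  planted causal KOs: %s",
      paste(x$truth$causal_kos, collapse = ", ")
    ),
    sep = "\n"
  )
  invisible(x)
}
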