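# Synthetic fermentation environment: batch designs and day-by-day dynamics
# of pH (acidification vs Ca(OH)2 correction), redox potential, and the
# three substrate pools (labile sukumo-derived matter, dead microbial cells,
# pulsed wheat bran).

#' Fermentation experiment design
#'
#' Defaults reproduce the study layout: four batches differing in
#' pretreatment (tap water vs wood-ash extract, 25 vs 60 degrees C), pH held
#' between 9.67 and 11.2 with Ca(OH)2, 1 g wheat bran pulsed on days
#' 5/19/51/85/194, incubation at 26 degrees C, daily sampling on days 1-7
#' then a sparse grid to day 209, and MiSeq-like read depths of 1e4-1e5.
#'
#' @param batches Tibble with columns `batch_id`, `pretreat_temp` (deg C),
#'   `pretreat_ph`.
#' @param ph_floor,ph_ceiling pH maintenance band.
#' @param bran_days Integer days on which bran is added (ascending).
#' @param bran_amount Grams of bran per addition.
#' @param temperature Incubation temperature (deg C).
#' @param sampling_days Integer days sampled (ascending).
#' @param read_depth_range Length-2 integer range of per-sample read depths.
#' @return A list of class `fermentation_design`.
#' @export
fermentation_design <- function(batches = tibble(
                                  batch_id = c("B1", "B2", "B3", "B4"),
                                  pretreat_temp = c(60, 25, 25, 60),
                                  pretreat_ph = c(9.7, 9.8, 11.2, 11.1)
                                ),
                                ph_floor = 9.67,
                                ph_ceiling = 11.2,
                                bran_days = c(5L, 19L, 51L, 85L, 194L),
                                bran_amount = 1,
                                temperature = 26,
                                sampling_days = c(1:7, 10L, 16L, 29L, 49L, 75L, 209L),
                                read_depth_range = c(10000L, 100000L)) {
  assert_that(ph_floor < ph_ceiling, "ph_floor must be below ph_ceiling")
  assert_that(!is.unsorted(bran_days), "bran_days must be ascending")
  assert_that(!is.unsorted(sampling_days), "sampling_days must be ascending")
  assert_that(all(c("batch_id", "pretreat_temp", "pretreat_ph") %in% names(batches)),
              "batches needs batch_id, pretreat_temp, pretreat_ph")
  assert_that(!anyDuplicated(batches$batch_id), "batch ids must be unique")
  structure(
    list(
      batches = as_tibble(batches), ph_floor = ph_floor, ph_ceiling = ph_ceiling,
      bran_days = as.integer(bran_days), bran_amount = bran_amount,
      temperature = temperature, sampling_days = as.integer(sampling_days),
      read_depth_range = as.integer(read_depth_range)
    ),
    class = "fermentation_design"
  )
}

#' Environment and community dynamics parameters
#'
#' One configuration object holds every kernel shape and coefficient used by
#' the generator, with study-motivated defaults: bran decays with a ~30 day
#' time constant (it is consumed within about a month), ORP falls from a
#' small positive start to a deeply negative plateau with a sigmoid midpoint
#' early in fermentation, and daily microbial acid production pulls pH down
#' until a Ca(OH)2 correction resets it to the ceiling.
#'
#' @param acid_rate Mean daily pH drop from acid production (pH units/day).
#' @param acid_noise_sd SD of the daily pH drop.
#' @param orp_start,orp_plateau ORP start and plateau (mV).
#' @param orp_midpoint,orp_scale Sigmoid midpoint (day) and width (days) of
#'   the ORP decline.
#' @param orp_noise_sd SD of ORP measurement noise (mV).
#' @param bran_decay_days Exponential decay time constant of the bran pool.
#' @param labile_init,labile_decay_days Initial labile substrate pool (AU)
#'   and its decay constant.
#' @param dead_init,dead_decay_days Initial dead-cell pool (AU, produced by
#'   the pretreatment kill-off) and its decay constant.
#' @param ph_gain,orp_gain,substrate_gain,density_penalty Fitness-kernel
#'   coefficients of the community model (log-fitness units).
#' @param orp_halfwidth Logistic width of the ORP preference term (mV).
#' @param growth_noise_sd SD of the per-taxon per-day log-fitness noise.
#' @return A list of class `env_dynamics_params`.
#' @export
env_dynamics_params <- function(acid_rate = 0.3,
                                acid_noise_sd = 0.05,
                                orp_start = 100,
                                orp_plateau = -550,
                                orp_midpoint = 1.5,
                                orp_scale = 0.8,
                                orp_noise_sd = 5,
                                bran_decay_days = 30,
                                labile_init = 1,
                                labile_decay_days = 6,
                                dead_init = 0.6,
                                dead_decay_days = 12,
                                ph_gain = 1.2,
                                orp_gain = 1.5,
                                substrate_gain = 4,
                                density_penalty = 14,
                                orp_halfwidth = 120,
                                growth_noise_sd = 0.15) {
  params <- as.list(environment())
  assert_finite_params(params)
  assert_that(bran_decay_days > 0, "bran_decay_days must be positive")
  structure(params, class = "env_dynamics_params")
}

#' Simulate environment series for every batch
#'
#' Runs the daily environment dynamics from day 1 to the last sampling day of
#' `design`, independently per batch (one RNG substream per batch, derived
#' from the master seed by stable hashing of the batch id, so adding a batch
#' never perturbs the others). pH starts at the batch's pretreatment value
#' and declines through acid production; whenever it would cross the floor it
#' is reset to the ceiling and `caoh2_added` is flagged for that day. ORP
#' follows a sigmoid decline to its plateau (monotone up to measurement
#' noise). The bran pool jumps by `bran_amount` on each bran day and decays
#' exponentially; labile and dead-cell pools decay from their initial values.
#'
#' @param design A [fermentation_design()].
#' @param params An [env_dynamics_params()].
#' @param seed Master integer seed.
#' @return A tibble with columns `batch_id`, `day`, `ph`, `orp`, `labile`,
#'   `dead_cells`, `bran`, `caoh2_added`.
#' @export
simulate_environment <- function(design, params = env_dynamics_params(), seed = 1) {
  assert_that(inherits(design, "fermentation_design"), "design must be a fermentation_design")
  assert_finite_params(params)
  days <- seq_len(max(design$sampling_days))
  purrr::map_dfr(seq_len(nrow(design$batches)), function(i) {
    b <- design$batches[i, ]
    with_seed(derive_seed(seed, "environment", b$batch_id), {
      n <- length(days)
      ph <- numeric(n)
      caoh2 <- logical(n)
      cur <- b$pretreat_ph
      drops <- pmax(rnorm(n, params$acid_rate, params$acid_noise_sd), 0)
      for (t in seq_len(n)) {
        cur <- cur - drops[t]
        if (cur < design$ph_floor) {
          cur <- design$ph_ceiling
          caoh2[t] <- TRUE
        }
        ph[t] <- min(cur, design$ph_ceiling)
      }
      orp_mean <- params$orp_start +
        (params$orp_plateau - params$orp_start) /
          (1 + exp(-(days - params$orp_midpoint) / params$orp_scale))
      orp <- orp_mean + rnorm(n, 0, params$orp_noise_sd)
      bran <- numeric(n)
      level <- 0
      decay <- exp(-1 / params$bran_decay_days)
      for (t in seq_len(n)) {
        level <- level * decay
        if (days[t] %in% design$bran_days) level <- level + design$bran_amount
        bran[t] <- level
      }
      tibble(
        batch_id = b$batch_id, day = days, ph = ph, orp = orp,
        labile = params$labile_init * exp(-days / params$labile_decay_days),
        dead_cells = params$dead_init * exp(-days / params$dead_decay_days),
        bran = bran, caoh2_added = caoh2
      )
    })
  })
}
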