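# End-to-end orchestrator: dataset (synthetic or imported) -> dye scoring ->
# composition and "Others" -> alpha diversity -> RDA per window -> networks
# per window -> predicted metagenome -> subpathway screens -> KO-phenotype
# screen -> oxidoreductase filter -> contribution ratios.

#' Analysis thresholds
#'
#' The screening thresholds of the standard workflow: taxa retained when
#' reaching 4.1% in any sample, alpha diversity at a rarefaction depth of
#' 8,825 reads, network edges at rs > 0.6 and p < 0.05, the KO-phenotype
#' screen at r >= 0.69, and subpathway ratio screens at ratio > 1.05.
#'
#' @param others_cutoff Proportion for rare-taxon aggregation (`>=`).
#' @param rarefaction_depth Reads per sample for alpha diversity.
#' @param rarefaction_replicates Rarefaction draws to average.
#' @param rs_min Network correlation threshold (strict `>`).
#' @param alpha Network significance threshold (strict `<`).
#' @param ko_r_min KO screen threshold (inclusive `>=`).
#' @param pathway_ratio_min Subpathway ratio threshold (strict `>`).
#' @return A list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(others_cutoff = 0.041,
                                rarefaction_depth = 8825,
                                rarefaction_replicates = 10,
                                rs_min = 0.6,
                                alpha = 0.05,
                                ko_r_min = 0.69,
                                pathway_ratio_min = 1.05) {
  assert_that(others_cutoff > 0 && others_cutoff < 1, "others_cutoff must be in (0,1)")
  assert_that(rarefaction_depth >= 1, "rarefaction_depth must be >= 1")
  structure(as.list(environment()), class = "analysis_thresholds")
}

#' Synthetic KO-to-subpathway map
#'
#' Assigns each KO id to one or two subpathways drawn from a fixed panel of
#' carbohydrate/defense/cofactor subpathways. Causal KOs are routed to the
#' carbohydrate-uptake subpathways ("Phosphotransferase system (PTS)",
#' "Starch and sucrose metabolism") so that planted causality surfaces in
#' the subpathway screens the way it does in the fermentation.
#'
#' @param ko_ids Character vector of KO ids.
#' @param causal_kos KO ids to route to the carbohydrate subpathways.
#' @param seed Integer seed.
#' @return A tibble `ko_id`, `subpathway`.
#' @export
synthetic_pathway_map <- function(ko_ids, causal_kos = character(), seed = 1) {
  panel <- c(
    "Phosphotransferase system (PTS)", "Starch and sucrose metabolism",
    "Prokaryotic defense system", "Nicotinate and nicotinamide metabolism",
    "Pyruvate metabolism", "Glycolysis / Gluconeogenesis", "ABC transporters",
    "Amino acid metabolism", "Methane metabolism", "Fatty acid biosynthesis",
    "Purine metabolism", "Two-component system"
  )
  with_seed(derive_seed(seed, "pathway_map"), {
    purrr::map_dfr(ko_ids, function(k) {
      if (k %in% causal_kos) {
        tibble(ko_id = k, subpathway = sample(panel[1:2], 1))
      } else {
        tibble(ko_id = k, subpathway = sample(panel, sample(1:2, 1)))
      }
    })
  })
}

#' Run the full fermentation analysis pipeline
#'
#' Executes every stage on a dataset (a synthetic one is generated when
#' `dataset` is NULL) and returns all results in one report object.
#' Identical `(design, params, causal, thresholds, seed)` give identical
#' reports. When `out_dir` is given every tabular artifact is also written
#' as TSV along with a manifest.
#'
#' @param dataset An `indigo_dataset` (from [simulate_fermentation()]) or
#'   NULL to simulate one from `design`/`params`/`causal`.
#' @param design,params,causal Generator configuration used when `dataset`
#'   is NULL.
#' @param thresholds An [analysis_thresholds()].
#' @param windows Named list of day ranges defining the analysis windows.
#' @param pathway_map KO-to-subpathway map; defaults to a synthetic map over
#'   the dataset's KOs.
#' @param ratio_day Day used for the between-batch subpathway ratio screens.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return A list of class `indigo_report`; see Details in the vignette.
#' @export
run_pipeline <- function(dataset = NULL,
                         design = fermentation_design(),
                         params = env_dynamics_params(),
                         causal = causal_function_model(),
                         thresholds = analysis_thresholds(),
                         windows = list(early = c(1, 7), late = c(10, 209)),
                         pathway_map = NULL,
                         ratio_day = 3,
                         seed = 1,
                         out_dir = NULL) {
  if (is.null(dataset)) {
    dataset <- simulate_fermentation(
      design = design, params = params, causal = causal, seed = seed
    )
  }
  assert_that(inherits(dataset, "indigo_dataset"), "dataset must be an indigo_dataset")
  meta <- dataset$metadata
  rel <- relative_abundance(dataset$feature_table)

  window_samples <- function(range) {
    meta$sample_id[meta$day >= range[1] & meta$day <= range[2]]
  }
  subset_table <- function(tbl, ids) tbl[, c("taxon_id", intersect(names(tbl), ids))]

  # composition with "Others", RDA, and networks per analysis window
  composition <- purrr::map(windows, function(rng) {
    aggregate_others(subset_table(rel, window_samples(rng)), thresholds$others_cutoff)
  })

  rda <- purrr::map(windows, function(rng) {
    ids <- window_samples(rng)
    Y <- transform_community(subset_table(rel, ids), "hellinger")
    X <- encode_environment(
      dplyr::filter(meta, .data$sample_id %in% ids),
      bran_days = dataset$design$bran_days,
      bran_amount = dataset$design$bran_amount
    )
    fit_rda(Y, X)
  })

  networks <- purrr::map(windows, function(rng) {
    ids <- window_samples(rng)
    comp <- aggregate_others(subset_table(rel, ids), thresholds$others_cutoff)
    retained <- dplyr::filter(comp, .data$taxon_id != "Others")
    batches <- unique(meta$batch_id[meta$sample_id %in% ids])
    nets <- purrr::map(batches, function(bid) {
      bids <- meta$sample_id[meta$sample_id %in% ids & meta$batch_id == bid]
      if (length(bids) < 3) return(NULL)
      build_network(subset_table(retained, bids),
        rs_min = thresholds$rs_min, alpha = thresholds$alpha
      )
    })
    purrr::compact(setNames(nets, batches))
  })

  alpha <- suppressWarnings(alpha_diversity(
    dataset$feature_table,
    depth = thresholds$rarefaction_depth,
    replicates = thresholds$rarefaction_replicates,
    seed = derive_seed(seed, "alpha")
  )) %>% dplyr::left_join(meta, by = "sample_id")

  # predicted metagenome and downstream function screens
  pm <- predict_metagenome(rel, dataset$genome_content)
  if (is.null(pathway_map)) {
    pathway_map <- synthetic_pathway_map(
      pm$ko_table$ko_id,
      causal_kos = dataset$truth$causal_kos, seed = seed
    )
  }
  subpathways <- aggregate_subpathways(pm$ko_table, pathway_map)

  ratio_screens <- list()
  ratio_ids <- meta$sample_id[meta$day == ratio_day]
  if (length(ratio_ids) >= 2) {
    ref <- ratio_ids[which.max(meta$dye_intensity[match(ratio_ids, meta$sample_id)])]
    others <- setdiff(ratio_ids, ref)
    ratio_screens <- setNames(
      purrr::map(others, function(s) {
        pathway_ratio_screen(subpathways, ref, s, thresholds$pathway_ratio_min)
      }),
      sprintf("%s_vs_%s", ref, others)
    )
  }

  screen <- ko_phenotype_correlation(pm$ko_table, dataset$dye, min_r = thresholds$ko_r_min)
  oxidoreductases <- filter_oxidoreductases(dplyr::filter(screen, .data$hit))

  contribution_ratios <- purrr::map_dfr(
    dataset$truth$causal_kos,
    function(k) {
      pairs <- meta %>%
        dplyr::group_by(.data$batch_id) %>%
        dplyr::arrange(.data$day, .by_group = TRUE) %>%
        dplyr::filter(dplyr::row_number() <= 3) %>%
        dplyr::summarise(
          a = .data$sample_id[2], b = .data$sample_id[3], .groups = "drop"
        )
      purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
        top <- dplyr::filter(pm$contrib, .data$sample_id == pairs$b[i], .data$ko_id == k)
        if (nrow(top) == 0) return(NULL)
        taxon <- top$taxon_id[which.max(top$contributed_count)]
        dplyr::mutate(
          contribution_day_ratio(pm$contrib, k, taxon, pairs$a[i], pairs$b[i]),
          batch_id = pairs$batch_id[i], .before = 1
        )
      })
    }
  )

  report <- structure(
    list(
      dataset = dataset,
      composition = composition,
      alpha_diversity = alpha,
      rda = rda,
      networks = networks,
      ko_table = pm$ko_table,
      contrib = pm$contrib,
      pathway_map = pathway_map,
      subpathways = subpathways,
      ratio_screens = ratio_screens,
      ko_screen = screen,
      oxidoreductases = oxidoreductases,
      contribution_ratios = contribution_ratios,
      manifest = list(
        seed = seed,
        thresholds = unclass(thresholds),
        windows = windows,
        config_hash = rlang::hash(list(
          dataset$truth, unclass(thresholds), windows, ratio_day, seed
        ))
      )
    ),
    class = "indigo_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.indigo_report <- function(x, ...) {
  cat("<indigo_report>\n")
  cat(sprintf("  windows: %s\n", paste(names(x$composition), collapse = ", ")))
  cat(sprintf(
    "  KO screen: %d tested, %d hits at r >= %g\n",
    nrow(x$ko_screen), sum(x$ko_screen$hit), x$manifest$thresholds$ko_r_min
  ))
  cat(sprintf(
    "  NAD(P)-dependent oxidoreductase hits: %d\n",
    nrow(x$oxidoreductases$retained)
  ))
  invisible(x)
}

#' Write every tabular artifact of a report to a directory
#'
#' @param report An `indigo_report`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_feature_table(report$dataset$feature_table, p("feature_table.tsv"))
  readr::write_tsv(report$dataset$metadata, p("metadata.tsv"))
  readr::write_tsv(report$dataset$dye, p("dye_series.tsv"))
  readr::write_tsv(report$dataset$environment, p("environment.tsv"))
  for (w in names(report$composition)) {
    readr::write_tsv(report$composition[[w]], p(sprintf("composition_%s.tsv", w)))
    readr::write_tsv(tidy(report$rda[[w]]), p(sprintf("rda_eigenvalues_%s.tsv", w)))
    for (b in names(report$networks[[w]])) {
      export_network(report$networks[[w]][[b]], p(sprintf("network_%s_%s.tsv", w, b)))
    }
  }
  readr::write_tsv(report$alpha_diversity, p("alpha_diversity.tsv"))
  write_picrust2_unstrat(report$ko_table, p("pred_metagenome_unstrat.tsv"))
  write_picrust2_contrib(report$contrib, p("pred_metagenome_contrib.tsv"))
  readr::write_tsv(report$subpathways, p("subpathways.tsv"))
  readr::write_tsv(as_tibble(report$ko_screen), p("ko_screen.tsv"))
  readr::write_tsv(report$oxidoreductases$retained, p("oxidoreductase_hits.tsv"))
  readr::write_tsv(report$contribution_ratios, p("contribution_ratios.tsv"))
  writeLines(
    c(
      sprintf("seed\t%d", report$manifest$seed),
      sprintf("config_hash\t%s", report$manifest$config_hash),
      sprintf(
        "thresholds\t%s",
        paste(names(report$manifest$thresholds),
          unlist(report$manifest$thresholds),
          sep = "=", collapse = ";"
        )
      )
    ),
    p("manifest.tsv")
  )
  invisible(out_dir)
}
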