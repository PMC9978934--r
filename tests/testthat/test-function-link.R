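toy_genome <- function() {
  tibble::tibble(
    taxon_id = c("T1", "T2", "T3"),
    K00001 = c(2, 1, 0),
    K00002 = c(0, 3, 1)
  )
}

test_that("metagenome prediction is the abundance x copy-number product-sum", {
  rel <- toy_feature_table(matrix(c(0.5, 0.3, 0.2), ncol = 1), taxa = c("T1", "T2", "T3"))
  pm <- predict_metagenome(rel, toy_genome())
  expect_equal(pm$ko_table$S1[pm$ko_table$ko_id == "K00001"], 1.3)
  c1 <- dplyr::filter(pm$contrib, ko_id == "K00001")
  expect_equal(c1$contributed_count[match(c("T1", "T2"), c1$taxon_id)], c(1.0, 0.3))
  expect_false("T3" %in% c1$taxon_id) # zero contributions omitted
  # single taxon, abundance 1, copy 3
  rel1 <- toy_feature_table(matrix(1, ncol = 1), taxa = "T2")
  expect_equal(predict_metagenome(rel1, toy_genome())$ko_table$S1, c(3, 9) / 3)
  # all-zero copies give all-zero tables
  g0 <- dplyr::mutate(toy_genome(), K00001 = 0, K00002 = 0)
  expect_true(all(as.matrix(predict_metagenome(rel, g0)$ko_table[, -1]) == 0))
  # unknown taxon rejected by name
  relx <- toy_feature_table(matrix(c(0.5, 0.5), ncol = 1), taxa = c("T1", "TX"))
  expect_error(predict_metagenome(relx, toy_genome()), "TX")
})

test_that("KO table equals the taxon-sum of the contribution table", {
  ds <- simulate_fermentation(seed = 31)
  rel <- relative_abundance(ds$feature_table)
  pm <- predict_metagenome(rel, ds$genome_content)
  recon <- pm$contrib %>%
    dplyr::group_by(sample_id, ko_id) %>%
    dplyr::summarise(total = sum(contributed_count), .groups = "drop")
  km <- as.matrix(pm$ko_table[, -1])
  rownames(km) <- pm$ko_table$ko_id
  for (i in sample(nrow(recon), 200)) {
    expect_equal(recon$total[i], km[recon$ko_id[i], recon$sample_id[i]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # every contributed_count equals its product exactly
  expect_true(all(abs(pm$contrib$contributed_count -
                        pm$contrib$taxon_abundance * pm$contrib$copy_number) < 1e-12))
})

test_that("subpathway aggregation multi-maps fully and collects unclassified KOs", {
  kt <- tibble::tibble(ko_id = c("K00001", "K00002", "K00003", "K00004"),
                       S1 = c(5, 2, 1, 7), S2 = c(0, 1, 1, 1))
  map <- tibble::tibble(
    ko_id = c("K00001", "K00001", "K00002", "K00003"),
    subpathway = c("P1", "P2", "P1", "P2")
  )
  agg <- aggregate_subpathways(kt, map)
  expect_equal(agg$S1[agg$subpathway == "P1"], 7) # 5 + 2
  expect_equal(agg$S1[agg$subpathway == "P2"], 6) # 5 + 1 (K00001 counted in both)
  expect_equal(agg$S1[agg$subpathway == "unclassified"], 7)
  # identity aggregation for a single-KO map
  one <- aggregate_subpathways(kt[1, ], tibble::tibble(ko_id = "K00001", subpathway = "P"))
  expect_equal(one$S1, 5)
  expect_error(aggregate_subpathways(kt, map[0, ]), "empty")
})

test_that("pathway ratio screen keeps ratios strictly above the threshold", {
  sp <- tibble::tibble(
    subpathway = c("a", "b", "c", "d", "e"),
    X = c(2.0, 1.05, 1.051, 0.9, 3),
    Y = c(1, 1, 1, 1, 0)
  )
  out <- pathway_ratio_screen(sp, "X", "Y", min_ratio = 1.05)
  expect_equal(out$hits$subpathway, c("a", "c")) # sorted descending by ratio
  expect_equal(out$hits$ratio, c(2.0, 1.051))
  expect_equal(out$undefined, "e")
  # equal columns retain nothing; 1.05 exactly is excluded (strict >)
  same <- pathway_ratio_screen(dplyr::mutate(sp[1:4, ], Y = X), "X", "Y", 1.05)
  expect_equal(nrow(same$hits), 0)
  exact <- pathway_ratio_screen(
    tibble::tibble(subpathway = "p", X = 105, Y = 100), "X", "Y", 1.05
  )
  expect_equal(nrow(exact$hits), 0)
  just <- pathway_ratio_screen(
    tibble::tibble(subpathway = "p", X = 1.06, Y = 1), "X", "Y", 1.05
  )
  expect_equal(just$hits$ratio, 1.06)
})

test_that("taxon contribution shares are normalised fractions of the subpathway", {
  contrib <- tibble::tibble(
    sample_id = "S1",
    ko_id = c("K00001", "K00001", "K00002", "K00003"),
    taxon_id = c("T1", "T2", "T1", "T3"),
    taxon_abundance = 1, copy_number = 1,
    contributed_count = c(3, 1, 2, 10)
  )
  map <- tibble::tibble(ko_id = c("K00001", "K00002"), subpathway = "P")
  sh <- taxon_contribution_share(contrib, map, "P", "S1")
  expect_equal(sh$fraction[sh$taxon_id == "T1"], 5 / 6)
  expect_equal(sh$fraction[sh$taxon_id == "T2"], 1 / 6)
  expect_equal(sum(sh$fraction), 1, tolerance = 1e-9)
  # two-taxon 3:1 split and the single-taxon degenerate case
  two <- taxon_contribution_share(contrib[1:2, ], map, "P", "S1")
  expect_equal(two$fraction, c(0.75, 0.25))
  one <- taxon_contribution_share(contrib[4, ],
                                  tibble::tibble(ko_id = "K00003", subpathway = "Q"), "Q", "S1")
  expect_equal(one$fraction, 1)
  expect_error(taxon_contribution_share(contrib, map, "P", "S9"), "zero total")
})

test_that("KO-phenotype correlation screens on pooled within-batch differences", {
  # two batches, three samples each; one KO tracks intensity changes exactly
  dye <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    batch_id = rep(c("b1", "b2"), each = 3),
    day = rep(1:3, 2),
    intensity = c(10, 30, 20, 5, 25, 45)
  )
  base <- c(50, 50, 50, 50, 50, 50)
  kt <- tibble::tibble(
    ko_id = c("K11111", "K22222", "K33333"),
    !!!setNames(as.data.frame(rbind(
      base + 2 * dye$intensity, # diffs proportional to intensity diffs
      c(9, 3, 1, 8, 4, 2), # unrelated, decreasing
      rep(4, 6) # constant: zero variance, skipped
    )), dye$sample_id)
  )
  sc <- ko_phenotype_correlation(kt, dye, min_r = 0.69, normalize = FALSE)
  expect_equal(sc$r[sc$ko_id == "K11111"], 1, tolerance = 1e-12)
  expect_true(sc$hit[sc$ko_id == "K11111"])
  expect_false("K33333" %in% sc$ko_id) # constant KO skipped
  expect_equal(unique(sc$n_pairs), 4) # 2 consecutive-day pairs per batch
  # brute-force Pearson on hand-built difference pairs for the unrelated KO
  dk <- c(3 - 9, 1 - 3, 4 - 8, 2 - 4)
  di <- c(20, -10, 20, 20)
  expect_equal(sc$r[sc$ko_id == "K22222"], cor(dk, di), tolerance = 1e-12)
  # level mode correlates raw values
  scl <- ko_phenotype_correlation(kt, dye, mode = "level", normalize = FALSE)
  expect_equal(scl$r[scl$ko_id == "K11111"], 1, tolerance = 1e-12)
  expect_error(ko_phenotype_correlation(kt[, 1:3], dye[1:2, ], normalize = FALSE),
               "pairs")
})

test_that("lowering the screen threshold never removes a hit", {
  ds <- simulate_fermentation(seed = 8)
  pm <- predict_metagenome(relative_abundance(ds$feature_table), ds$genome_content)
  hi <- ko_phenotype_correlation(pm$ko_table, ds$dye, min_r = 0.95)
  lo <- ko_phenotype_correlation(pm$ko_table, ds$dye, min_r = 0.5)
  expect_true(all(hi$ko_id[hi$hit] %in% lo$ko_id[lo$hit]))
})

test_that("oxidoreductase filter keeps NAD(P)-dependent EC 1.* hits only", {
  ann <- ko_annotations()
  expect_equal(sum(ann$nadp_dependent), 7)
  hits <- tibble::tibble(ko_id = ann$ko_id, r = seq(0.99, 0.69, length.out = nrow(ann)))
  out <- filter_oxidoreductases(hits, ann)
  expect_setequal(out$retained$ko_id,
                  c("K00324", "K00325", "K11261", "K00198", "K08325", "K18981", "K03778"))
  expect_equal(nrow(out$unannotated), 0)
  # EC 2.* flagged rows and unflagged EC 1.* rows are both excluded
  toy <- tibble::tibble(
    ko_id = c("Ka", "Kb", "Kc", "Kd", "Ke"),
    ec_numbers = c("1.1.1.2", "2.7.1.199", "1.1.3.2", "1.2.7.4", NA),
    nadp_dependent = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    symbol = "s", description = "d"
  )
  res <- filter_oxidoreductases(tibble::tibble(ko_id = c("Ka", "Kb", "Kc", "Kd", "Kx")), toy)
  expect_setequal(res$retained$ko_id, c("Ka", "Kd"))
  # unannotated hits surface in their own bucket, never dropped silently
  expect_equal(res$unannotated$ko_id, "Kx")
  # order of hits preserved
  expect_equal(res$retained$ko_id, c("Ka", "Kd"))
})

test_that("contribution day ratios use sentinel statuses for zero baselines", {
  contrib <- tibble::tibble(
    sample_id = c("D2", "D3", "D2", "D3", "D3"),
    ko_id = "K00001",
    taxon_id = c("T1", "T1", "T2", "T2", "T3"),
    taxon_abundance = 1, copy_number = 1,
    contributed_count = c(10, 20, 7, 7, 5)
  )
  r1 <- contribution_day_ratio(contrib, "K00001", "T1", "D2", "D3")
  expect_equal(r1$ratio, 2)
  expect_equal(r1$status, "ratio")
  r2 <- contribution_day_ratio(contrib, "K00001", "T2", "D2", "D3")
  expect_equal(r2$ratio, 1)
  r3 <- contribution_day_ratio(contrib, "K00001", "T3", "D2", "D3")
  expect_equal(r3$status, "new appearance")
  expect_equal(r3$ratio, Inf)
  r4 <- contribution_day_ratio(contrib, "K00001", "T1", "D7", "D8")
  expect_equal(r4$status, "absent")
  expect_error(contribution_day_ratio(contrib, "K99999", "T1", "D2", "D3"), "unknown KO")
  expect_error(contribution_day_ratio(contrib, "K00001", "TZ", "D2", "D3"), "unknown taxon")
})

test_that("PICRUSt2 layouts round-trip bit-compatibly", {
  ds <- simulate_fermentation(
    design = fermentation_design(sampling_days = 1:3),
    seed = 12
  )
  pm <- predict_metagenome(relative_abundance(ds$feature_table), ds$genome_content)
  tmp1 <- withr::local_tempfile(fileext = ".tsv")
  write_picrust2_unstrat(pm$ko_table, tmp1)
  expect_equal(readLines(tmp1, n = 1),
               paste(c("function", names(pm$ko_table)[-1]), collapse = "\t"))
  back <- read_picrust2_unstrat(tmp1)
  expect_equal(as.data.frame(back), as.data.frame(pm$ko_table), tolerance = 1e-12)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_picrust2_contrib(pm$contrib, tmp2)
  cback <- read_picrust2_contrib(tmp2)
  expect_equal(as.data.frame(cback), as.data.frame(pm$contrib), tolerance = 1e-12)
})
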