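# Predicted-metagenome construction and the phenotype-attribution core:
# taxon x gene-copy decomposition, subpathway ratio screens, the
# gene-to-dyeing-intensity correlation screen, and taxon contribution ratios.

#' Predict the functional metagenome from community and genome content
#'
#' The contribution of taxon t to gene family k in sample s is
#' `abundance(t, s) * copy_number(t, k)`; summing over taxa gives the
#' per-sample KO table (the "unstratified" layout), while the per-taxon
#' records form the stratified contribution table. The two are exactly
#' conserved: the KO table equals the taxon-sum of the contribution table.
#'
#' @param rel Relative-abundance table (`taxon_id` + sample columns).
#' @param genome Genome content tibble (`taxon_id` + one column per KO).
#' @return A list with `ko_table` (tibble `ko_id` + sample columns) and
#'   `contrib` (long tibble `sample_id`, `ko_id`, `taxon_id`,
#'   `taxon_abundance`, `copy_number`, `contributed_count`; zero
#'   contributions are omitted).
#' @export
predict_metagenome <- function(rel, genome) {
  a <- feature_matrix(rel) # taxa x samples
  g <- genome_matrix(genome) # taxa x KOs
  missing <- setdiff(rownames(a), rownames(g))
  if (length(missing) > 0) {
    abort(paste("taxa missing from genome content:", paste(missing, collapse = ", ")))
  }
  g <- g[rownames(a), , drop = FALSE]
  ko <- t(g) %*% a # KOs x samples
  contrib <- purrr::map_dfr(colnames(a), function(s) {
    cc <- g * a[, s] # taxa x KOs contributions
    idx <- which(cc > 0, arr.ind = TRUE)
    tibble(
      sample_id = s,
      ko_id = colnames(g)[idx[, 2]],
      taxon_id = rownames(g)[idx[, 1]],
      taxon_abundance = a[idx[, 1], s],
      copy_number = g[idx],
      contributed_count = cc[idx]
    )
  })
  list(
    ko_table = dplyr::bind_cols(tibble(ko_id = rownames(ko)), as_tibble(ko)),
    contrib = contrib
  )
}

ko_matrix <- function(ko_table) {
  m <- as.matrix(ko_table[, setdiff(names(ko_table), "ko_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ko_table$ko_id
  assert_that(all(is.finite(m)) && all(m >= 0), "KO abundances must be finite, non-negative")
  m
}

#' Aggregate KO abundances into subpathways
#'
#' A KO mapped to k subpathways contributes its full abundance to each of
#' them; KOs absent from the map are collected under `"unclassified"`.
#'
#' @param ko_table Tibble `ko_id` + sample columns (from
#'   [predict_metagenome()]).
#' @param pathway_map Tibble with columns `ko_id`, `subpathway` (one row per
#'   mapping; a KO may appear several times).
#' @return A tibble `subpathway` + sample columns.
#' @export
aggregate_subpathways <- function(ko_table, pathway_map) {
  assert_that(all(c("ko_id", "subpathway") %in% names(pathway_map)),
              "pathway_map needs ko_id and subpathway columns")
  assert_that(nrow(pathway_map) > 0, "pathway_map is empty")
  m <- ko_matrix(ko_table)
  mapped <- dplyr::filter(pathway_map, .data$ko_id %in% rownames(m))
  unmapped <- setdiff(rownames(m), pathway_map$ko_id)
  groups <- split(mapped$ko_id, mapped$subpathway)
  if (length(unmapped) > 0) groups$unclassified <- c(groups$unclassified, unmapped)
  out <- t(vapply(
    groups,
    function(kos) colSums(m[kos, , drop = FALSE]),
    numeric(ncol(m))
  ))
  dplyr::bind_cols(tibble(subpathway = names(groups)), as_tibble(out))
}

#' Ratio screen between two subpathway profiles
#'
#' Computes `ratio = a / b` per subpathway between two samples (or sample
#' groups) and retains subpathways with `ratio > min_ratio` (strict), sorted
#' descending. Zero-denominator subpathways are reported separately as
#' undefined rather than retained.
#'
#' @param subpathways Tibble `subpathway` + sample columns.
#' @param numerator,denominator Names of the two sample columns to compare.
#' @param min_ratio Retention threshold, default 1.05 (strict `>`).
#' @return A list with `hits` (tibble `subpathway`, `ratio`, descending) and
#'   `undefined` (character vector of zero-denominator subpathways).
#' @export
pathway_ratio_screen <- function(subpathways, numerator, denominator, min_ratio = 1.05) {
  assert_that(all(c(numerator, denominator) %in% names(subpathways)),
              "numerator/denominator columns not found")
  a <- subpathways[[numerator]]
  b <- subpathways[[denominator]]
  undef <- subpathways$subpathway[b == 0]
  ok <- b > 0
  ratio <- a[ok] / b[ok]
  hits <- tibble(subpathway = subpathways$subpathway[ok], ratio = ratio) %>%
    dplyr::filter(.data$ratio > min_ratio) %>%
    dplyr::arrange(dplyr::desc(.data$ratio))
  list(hits = hits, undefined = undef)
}

#' Per-taxon contribution share of a subpathway in one sample
#'
#' The fraction of a subpathway's predicted abundance contributed by each
#' taxon: `sum over member KOs of contributed_count(taxon, ko)` divided by
#' the subpathway total in that sample. Fractions sum to 1.
#'
#' @param contrib Long contribution table from [predict_metagenome()].
#' @param pathway_map Tibble `ko_id`, `subpathway`.
#' @param subpathway Subpathway id to decompose.
#' @param sample Sample id.
#' @return A tibble `taxon_id`, `contributed`, `fraction`, descending by
#'   fraction.
#' @export
taxon_contribution_share <- function(contrib, pathway_map, subpathway, sample) {
  kos <- pathway_map$ko_id[pathway_map$subpathway == subpathway]
  rows <- dplyr::filter(contrib, .data$sample_id == sample, .data$ko_id %in% kos)
  total <- sum(rows$contributed_count)
  if (total <= 0) {
    abort(sprintf("subpathway '%s' has zero total contribution in sample '%s'", subpathway, sample))
  }
  rows %>%
    dplyr::group_by(.data$taxon_id) %>%
    dplyr::summarise(contributed = sum(.data$contributed_count), .groups = "drop") %>%
    dplyr::mutate(fraction = .data$contributed / total) %>%
    dplyr::arrange(dplyr::desc(.data$fraction))
}

#' Correlate gene-family abundance with dyeing intensity
#'
#' The phenotype-attribution screen. In the default `"diff"` mode, first
#' differences of dyeing intensity and of each KO's (per-sample-normalised)
#' abundance are formed between consecutive sampled days within each batch,
#' pooled across batches, and each KO's Pearson correlation with the
#' intensity changes is computed; `"level"` mode correlates raw values.
#' Hits are KOs with `r >= min_r` (inclusive). KOs with zero variance are
#' skipped. Set `method = "spearman"` to rank-transform both series first.
#'
#' @param ko_table Tibble `ko_id` + sample columns.
#' @param dye Per-sample phenotype tibble with `sample_id`, `batch_id`,
#'   `day`, `intensity`.
#' @param min_r Hit threshold on r, default 0.69 (inclusive `>=`).
#' @param mode `"diff"` (default) or `"level"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param normalize Divide each sample's KO column by its total so depth
#'   variation does not masquerade as change (default TRUE).
#' @return An object of class `indigo_ko_screen`: tibble of all testable KOs
#'   (`ko_id`, `r`, `n_pairs`, `hit`), ordered by decreasing r, with the
#'   screen settings as attributes.
#' @export
ko_phenotype_correlation <- function(ko_table, dye, min_r = 0.69,
                                     mode = c("diff", "level"),
                                     method = c("pearson", "spearman"),
                                     normalize = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  m <- ko_matrix(ko_table)
  assert_that(all(c("sample_id", "batch_id", "day", "intensity") %in% names(dye)),
              "dye needs sample_id, batch_id, day, intensity")
  dye <- dplyr::arrange(as_tibble(dye), .data$batch_id, .data$day)
  common <- intersect(dye$sample_id, colnames(m))
  dye <- dplyr::filter(dye, .data$sample_id %in% common)
  m <- m[, dye$sample_id, drop = FALSE]
  if (normalize) {
    totals <- colSums(m)
    totals[totals == 0] <- 1
    m <- sweep(m, 2, totals, "/")
  }
  if (mode == "diff") {
    batches <- split(seq_len(nrow(dye)), dye$batch_id)
    pair_cols <- function(idx) if (length(idx) >= 2) cbind(idx[-length(idx)], idx[-1]) else NULL
    pairs <- do.call(rbind, lapply(batches, pair_cols))
    assert_that(!is.null(pairs) && nrow(pairs) >= 3,
                "need at least 3 consecutive-day pairs after matching samples")
    y <- dye$intensity[pairs[, 2]] - dye$intensity[pairs[, 1]]
    xm <- m[, pairs[, 2], drop = FALSE] - m[, pairs[, 1], drop = FALSE]
  } else {
    assert_that(nrow(dye) >= 3, "need at least 3 paired observations")
    y <- dye$intensity
    xm <- m
  }
  if (method == "spearman") {
    y <- rank_avg(y)
    xm <- t(apply(xm, 1, rank_avg))
  }
  sds <- apply(xm, 1, sd)
  testable <- sds > 0 & sd(y) > 0
  r <- rep(NA_real_, nrow(xm))
  r[testable] <- as.numeric(cor(t(xm[testable, , drop = FALSE]), y))
  out <- tibble(
    ko_id = rownames(m), r = r, n_pairs = length(y),
    hit = !is.na(r) & r >= min_r
  ) %>%
    dplyr::filter(!is.na(.data$r)) %>%
    dplyr::arrange(dplyr::desc(.data$r))
  structure(out,
    class = c("indigo_ko_screen", class(out)),
    min_r = min_r, mode = mode, method = method
  )
}

#' Screen hits for NAD(P)-dependent oxidoreductases
#'
#' Retains hits whose annotation carries at least one EC number of
#' oxidoreductase class (starting `1.`) AND is flagged NAD(P)-dependent.
#' Hits with no annotation row are never silently dropped: they are returned
#' in a separate `unannotated` bucket.
#'
#' @param hits A tibble with a `ko_id` column (e.g. the hits of
#'   [ko_phenotype_correlation()]).
#' @param annotations Annotation tibble with columns `ko_id`, `symbol`,
#'   `description`, `ec_numbers` (space-separated), `nadp_dependent`
#'   (logical); see [ko_annotations()] for the packaged table.
#' @return A list with `retained` (annotated, order of `hits` preserved) and
#'   `unannotated` tibbles.
#' @export
filter_oxidoreductases <- function(hits, annotations = ko_annotations()) {
  assert_that("ko_id" %in% names(hits), "hits need a ko_id column")
  need <- c("ko_id", "ec_numbers", "nadp_dependent")
  assert_that(all(need %in% names(annotations)),
              "annotations need ko_id, ec_numbers, nadp_dependent")
  merged <- dplyr::left_join(as_tibble(hits), as_tibble(annotations), by = "ko_id")
  unannotated <- merged[is.na(merged$nadp_dependent), names(hits), drop = FALSE]
  annotated <- merged[!is.na(merged$nadp_dependent), , drop = FALSE]
  ecs <- as.character(annotated$ec_numbers)
  ecs[is.na(ecs)] <- ""
  is_oxidoreductase <- vapply(
    strsplit(ecs, "\\s+"),
    function(e) any(startsWith(e, "1.")),
    logical(1)
  )
  list(
    retained = annotated[is_oxidoreductase & annotated$nadp_dependent, , drop = FALSE],
    unannotated = as_tibble(unannotated)
  )
}

#' Packaged KO annotation table
#'
#' Curated annotations (symbol, description, EC numbers, NAD(P)-dependence
#' flag) for the KO gene families recurring in indigo-reduction screens.
#'
#' @return A tibble with columns `ko_id`, `symbol`, `description`,
#'   `ec_numbers`, `nadp_dependent`.
#' @export
ko_annotations <- function() {
  path <- system.file("extdata", "ko_oxidoreductase_annotations.tsv", package = "indigoferm")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    ko_id = "c", symbol = "c", description = "c",
                    ec_numbers = "c", nadp_dependent = "l"
                  ))
}

#' Day-to-day contribution ratio for one (KO, taxon)
#'
#' The ratio of a taxon's contributed count for a KO between two samples
#' (typically consecutive days around the initiation of indigo reduction):
#' `contributed(day_b) / contributed(day_a)`. A zero baseline with a later
#' positive count is reported as a `"new appearance"` (infinite ratio);
#' zero in both samples as `"absent"`.
#'
#' @param contrib Long contribution table from [predict_metagenome()].
#' @param ko,taxon KO and taxon ids.
#' @param sample_a,sample_b Baseline and comparison sample ids.
#' @return A one-row tibble: `ko_id`, `taxon_id`, `count_a`, `count_b`,
#'   `ratio`, `status` (`"ratio"`, `"new appearance"`, or `"absent"`).
#' @export
contribution_day_ratio <- function(contrib, ko, taxon, sample_a, sample_b) {
  known_ko <- ko %in% contrib$ko_id
  known_taxon <- taxon %in% contrib$taxon_id
  if (!known_ko || !known_taxon) {
    abort(sprintf("unknown %s: %s", if (!known_ko) "KO" else "taxon",
                  if (!known_ko) ko else taxon))
  }
  pick <- function(s) {
    v <- contrib$contributed_count[
      contrib$sample_id == s & contrib$ko_id == ko & contrib$taxon_id == taxon
    ]
    if (length(v) == 0) 0 else sum(v)
  }
  ca <- pick(sample_a)
  cb <- pick(sample_b)
  status <- if (ca == 0 && cb == 0) "absent" else if (ca == 0) "new appearance" else "ratio"
  tibble(
    ko_id = ko, taxon_id = taxon, count_a = ca, count_b = cb,
    ratio = if (status == "ratio") cb / ca else if (status == "new appearance") Inf else NA_real_,
    status = status
  )
}
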