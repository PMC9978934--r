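# Feature-table analytics: relative abundance, rare-taxon aggregation,
# rarefaction without replacement, observed features, Shannon diversity.
#
# Feature tables are tidyverse-friendly wide tibbles: a `taxon_id` column
# followed by one integer count column per sample. Sample metadata travels in
# a separate tibble keyed by `sample_id` (columns batch_id, day, ph, orp, and
# optionally dye_intensity).

feature_matrix <- function(table) {
  assert_that(is.data.frame(table) && names(table)[1] == "taxon_id",
              "feature table must have a leading taxon_id column")
  assert_that(!anyDuplicated(table$taxon_id), "duplicate taxon ids")
  m <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$taxon_id
  assert_that(!anyDuplicated(colnames(m)), "duplicate sample ids")
  assert_that(all(is.finite(m)) && all(m >= 0), "counts must be finite and non-negative")
  m
}

matrix_to_table <- function(m) {
  dplyr::bind_cols(tibble(taxon_id = rownames(m)), as_tibble(m))
}

#' Per-sample relative abundance
#'
#' Divides each sample column of a taxon-by-sample table by its column sum.
#'
#' @param table A feature table: tibble with `taxon_id` then one numeric
#'   column per sample.
#' @return A tibble of the same shape whose sample columns each sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- feature_matrix(table)
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero total counts: %s", paste(zero, collapse = ", ")))
  }
  matrix_to_table(sweep(m, 2, totals, "/"))
}

#' Aggregate rare taxa into an "Others" row
#'
#' A taxon is retained if and only if its maximum relative abundance over all
#' samples in the table is at least `cutoff` ("present at >= cutoff in any
#' sample"); all remaining taxa are summed into a single `Others` row, so
#' per-sample mass is conserved exactly. Applied separately per analysis
#' window when the study is split into early and late phases.
#'
#' @param rel A relative-abundance table (see [relative_abundance()]).
#' @param cutoff Retention threshold as a proportion, default 0.041 (4.1%).
#' @param others_label Name of the aggregate row.
#' @return A tibble with the retained taxa and a final `Others` row.
#' @export
aggregate_others <- function(rel, cutoff = 0.041, others_label = "Others") {
  assert_that(is.numeric(cutoff) && length(cutoff) == 1 && cutoff > 0 && cutoff < 1,
              "cutoff must be a proportion in (0, 1)")
  m <- feature_matrix(rel)
  keep <- apply(m, 1, max) >= cutoff
  kept <- m[keep, , drop = FALSE]
  others <- colSums(m[!keep, , drop = FALSE])
  out <- rbind(kept, matrix(others, nrow = 1, dimnames = list(others_label, colnames(m))))
  matrix_to_table(out)
}

#' Rarefy one sample's counts to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), the
#' standard depth-normalisation before comparing diversity across samples.
#'
#' @param counts Non-negative integer vector of per-taxon counts.
#' @param depth Number of reads to draw; must not exceed `sum(counts)`.
#' @param seed Optional integer seed for a reproducible draw.
#' @return An integer vector of the same length summing exactly to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  assert_that(is_count_vector(counts), "counts must be non-negative integers")
  total <- sum(counts)
  assert_that(depth >= 1 && depth <= total, "depth must lie in [1, sum(counts)]")
  with_seed(seed, {
    # sequential hypergeometric draws: taxon i receives Hyper(N_i, rest, d)
    out <- integer(length(counts))
    remaining <- total
    todraw <- depth
    for (i in seq_along(counts)) {
      if (todraw == 0) break
      ni <- counts[i]
      out[i] <- stats::rhyper(1, ni, remaining - ni, todraw)
      todraw <- todraw - out[i]
      remaining <- remaining - ni
    }
    out
  })
}

#' Number of taxa present
#'
#' @param counts Numeric vector of per-taxon counts.
#' @return Integer count of entries greater than zero.
#' @export
observed_features <- function(counts) {
  sum(counts > 0)
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i, base))` over taxa with nonzero counts. Base 2
#' (bits) by default, matching common amplicon-workflow output.
#'
#' @param counts Numeric vector of per-taxon counts (or proportions).
#' @param base Logarithm base, default 2.
#' @return The Shannon index, in `[0, log(S, base)]`.
#' @export
shannon <- function(counts, base = 2) {
  total <- sum(counts)
  assert_that(total > 0, "cannot compute Shannon index of an all-zero sample")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Expected richness under rarefaction
#'
#' Closed-form mean number of taxa observed when drawing `depth` reads
#' without replacement: `sum_i 1 - C(N - N_i, depth) / C(N, depth)`,
#' evaluated in log space. Serves as the analytic reference for the
#' Monte-Carlo rarefaction estimate.
#'
#' @inheritParams rarefy_counts
#' @return Expected number of observed taxa (numeric).
#' @export
expected_richness <- function(counts, depth) {
  assert_that(is_count_vector(counts), "counts must be non-negative integers")
  total <- sum(counts)
  assert_that(depth >= 0 && depth <= total, "depth must lie in [0, sum(counts)]")
  n <- counts[counts > 0]
  miss <- exp(lchoose(total - n, depth) - lchoose(total, depth))
  miss[total - n < depth] <- 0
  sum(1 - miss)
}

#' Rarefied alpha diversity for every sample
#'
#' For each sample with at least `depth` reads, averages observed features
#' and the Shannon index over `replicates` independent rarefactions at
#' `depth`. Shallower samples are excluded with a warning, mirroring
#' fixed-depth alpha-diversity practice. Per-sample substreams are derived
#' from the master seed and the sample id, so adding a sample never perturbs
#' the draws of another.
#'
#' @param table A feature table (counts).
#' @param depth Rarefaction depth in reads (study default 8825).
#' @param replicates Number of rarefaction draws to average, default 10.
#' @param seed Master seed.
#' @param base Logarithm base for the Shannon index.
#' @return A tibble: `sample_id`, `observed`, `shannon`, `depth`,
#'   `replicates`.
#' @export
alpha_diversity <- function(table, depth = 8825, replicates = 10, seed = 1, base = 2) {
  assert_that(replicates >= 1, "replicates must be >= 1")
  m <- feature_matrix(table)
  totals <- colSums(m)
  shallow <- colnames(m)[totals < depth]
  if (length(shallow) > 0) {
    warn(sprintf(
      "excluding %d sample(s) below depth %d: %s",
      length(shallow), depth, paste(shallow, collapse = ", ")
    ))
  }
  keep <- setdiff(colnames(m), shallow)
  purrr::map_dfr(keep, function(sid) {
    counts <- m[, sid]
    reps <- purrr::map(seq_len(replicates), function(r) {
      rarefy_counts(counts, depth, seed = derive_seed(seed, "rarefy", sid, r))
    })
    tibble(
      sample_id = sid,
      observed = mean(vapply(reps, observed_features, numeric(1))),
      shannon = mean(vapply(reps, shannon, numeric(1), base = base)),
      depth = depth,
      replicates = replicates
    )
  })
}

#' Mean reads per sample from a sequencing-yield summary
#'
#' Given total read counts and sample numbers per processing stage, returns
#' the per-sample average rounded to the nearest read, the form in which
#' sequencing yields are conventionally reported.
#'
#' @param data A data frame with columns `total_reads` and `n_samples`
#'   (one row per stage/period).
#' @return `data` with a `mean_reads_per_sample` column appended.
#' @export
read_yield_summary <- function(data) {
  assert_that(all(c("total_reads", "n_samples") %in% names(data)),
              "data must have columns total_reads and n_samples")
  dplyr::mutate(as_tibble(data),
                mean_reads_per_sample = round(.data$total_reads / .data$n_samples))
}
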