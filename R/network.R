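# Taxon co-occurrence networks from abundance trends: Spearman's rank
# correlation with exact permutation p-values at small n, edges kept at
# rs > 0.6 and p < 0.05.

rank_avg <- function(x) rank(x, ties.method = "average")

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' Undefined (NA, with a warning) when either series has zero rank variance.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return `rs` in `[-1, 1]`, or `NA` for constant input.
#' @export
spearman_rs <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  rx <- rank_avg(x)
  ry <- rank_avg(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("zero rank variance: Spearman rs undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}

# all permutations of 1..n (n <= 8 keeps this under 41k rows)
permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

.perm_cache <- new.env(parent = emptyenv())

cached_permutations <- function(n) {
  key <- as.character(n)
  if (is.null(.perm_cache[[key]])) .perm_cache[[key]] <- permutations(n)
  .perm_cache[[key]]
}

#' Two-sided p-value for Spearman's rs
#'
#' Exact by full enumeration of permutations of one rank vector for
#' `n <= exact_max` (default 8); otherwise the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` with `n - 2` df. Under the
#' t approximation, `|rs| = 1` falls back to enumeration.
#'
#' @param x,y The two series (ranks are recomputed internally so that tied
#'   patterns are enumerated correctly).
#' @param exact_max Largest n for exact enumeration.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
spearman_p <- function(x, y, exact_max = 8) {
  n <- length(x)
  assert_that(n == length(y) && n >= 3, "x and y must have equal length >= 3")
  rs <- spearman_rs(x, y)
  if (is.na(rs)) return(NA_real_)
  if (n <= exact_max || abs(rs) >= 1 - 1e-12) {
    rx <- rank_avg(x)
    ry <- rank_avg(y)
    if (n > exact_max) {
      # |rs| = 1 only arises from tie-free monotone patterns; enumeration at
      # this n is infeasible, so report the exact tie-free tail probability.
      return(min(1, 2 / factorial(min(n, 170))))
    }
    perms <- cached_permutations(n)
    # permuted rows of rx all share the same mean and sum of squares, so the
    # full null distribution reduces to one matrix product
    A <- matrix(rx[perms], nrow(perms), n)
    yc <- ry - mean(ry)
    ssx <- sum((rx - mean(rx))^2)
    null_rs <- as.numeric(A %*% yc) / sqrt(ssx * sum(yc^2))
    return(mean(abs(null_rs) >= abs(rs) - 1e-12))
  }
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Build a taxon co-occurrence network over a fermentation period
#'
#' Tests every unordered taxon pair in the table: an edge is kept iff
#' `|rs| > rs_min` AND `p < alpha` (both strict). Edge sign is the sign of
#' rs (positive/negative co-occurrence). Node weight is the taxon's
#' abundance accumulated (summed) over the period's samples. Taxa with
#' constant series are skipped rather than assigned rs = 0. Series are the
#' per-taxon relative-abundance trajectories over the period's sampled days;
#' set `mode = "diff"` to correlate day-to-day changes instead.
#'
#' @param rel Relative-abundance table restricted to one period's samples
#'   (`taxon_id` + sample columns, in day order).
#' @param rs_min Correlation threshold, default 0.6 (strict `>`).
#' @param alpha Significance threshold, default 0.05 (strict `<`).
#' @param mode `"level"` (default) or `"diff"` (first differences).
#' @param exact_max Passed to [spearman_p()].
#' @return A list of class `indigo_network`: `nodes` tibble (`taxon_id`,
#'   `accumulated_abundance`), `edges` tibble (`taxon_a`, `taxon_b`, `rs`,
#'   `p_value`, `sign`), and the thresholds used.
#' @export
build_network <- function(rel, rs_min = 0.6, alpha = 0.05,
                          mode = c("level", "diff"), exact_max = 8) {
  mode <- match.arg(mode)
  m <- feature_matrix(rel)
  assert_that(ncol(m) >= 3, "a period needs at least 3 samples")
  series <- if (mode == "diff") t(apply(m, 1, diff)) else m
  if (mode == "diff") assert_that(ncol(series) >= 3, "diff mode needs at least 4 samples")
  taxa <- rownames(m)
  nodes <- tibble(taxon_id = taxa, accumulated_abundance = unname(rowSums(m)))
  usable <- apply(series, 1, function(v) sd(rank_avg(v)) > 0)
  if (any(!usable)) {
    warn(sprintf("skipping %d constant taxon series", sum(!usable)))
  }
  idx <- which(usable)
  edges <- list()
  if (length(idx) >= 2) {
    pairs <- utils::combn(idx, 2)
    edges <- purrr::map(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]
      i2 <- pairs[2, j]
      rs <- spearman_rs(series[i1, ], series[i2, ])
      if (is.na(rs) || abs(rs) <= rs_min) return(NULL)
      p <- spearman_p(series[i1, ], series[i2, ], exact_max = exact_max)
      if (!is.finite(p) || p >= alpha) return(NULL)
      tibble(
        taxon_a = taxa[i1], taxon_b = taxa[i2], rs = rs, p_value = p,
        sign = if (rs > 0) "positive" else "negative"
      )
    })
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) {
    edges <- tibble(
      taxon_a = character(), taxon_b = character(), rs = numeric(),
      p_value = numeric(), sign = character()
    )
  }
  structure(
    list(nodes = nodes, edges = edges, rs_min = rs_min, alpha = alpha, mode = mode),
    class = "indigo_network"
  )
}

#' @export
print.indigo_network <- function(x, ...) {
  cat(sprintf(
    "<indigo_network> %d nodes, %d edges (|rs| > %g, p < %g, mode = %s)\n",
    nrow(x$nodes), nrow(x$edges), x$rs_min, x$alpha, x$mode
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x An `indigo_network`.
#' @param ... Unused.
#' @export
tidy.indigo_network <- function(x, ...) as_tibble(x$edges)

#' @rdname build_network
#' @export
glance.indigo_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "positive"),
    n_negative = sum(x$edges$sign == "negative"),
    rs_min = x$rs_min, alpha = x$alpha
  )
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
  g
}

#' @rdname build_network
#' @param object An `indigo_network`.
#' @export
autoplot.indigo_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1)
  layout <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = layout[, 1], y = layout[, 2])
  edges <- object$edges %>%
    dplyr::left_join(dplyr::select(nodes, taxon_a = "taxon_id", xa = "x", ya = "y"), by = "taxon_a") %>%
    dplyr::left_join(dplyr::select(nodes, taxon_b = "taxon_id", xb = "x", yb = "y"), by = "taxon_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        colour = .data$sign, linewidth = abs(.data$rs)
      )
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$accumulated_abundance),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$taxon_id),
      size = 2.6, vjust = -1
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "firebrick", negative = "steelblue")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(size = "accumulated abundance", colour = "correlation")
}

#' Export / import a co-occurrence network
#'
#' `export_network()` writes the edge list as TSV (`taxon_a`, `taxon_b`,
#' `rs`, `p_value`, `sign`; node weights to a sidecar `*.nodes.tsv`) or as
#' GraphML with the node weight attribute. `import_network_tsv()` reads the
#' TSV pair back losslessly.
#'
#' @param net An `indigo_network`.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges, path)
    readr::write_tsv(net$nodes, paste0(path, ".nodes.tsv"))
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @param rs_min,alpha,mode Threshold metadata to attach to the imported
#'   network.
#' @export
import_network_tsv <- function(path, rs_min = 0.6, alpha = 0.05, mode = "level") {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             taxon_a = "c", taxon_b = "c", rs = "d",
                             p_value = "d", sign = "c"
                           ))
  nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"), show_col_types = FALSE,
                           col_types = readr::cols(taxon_id = "c", accumulated_abundance = "d"))
  structure(
    list(nodes = nodes, edges = edges, rs_min = rs_min, alpha = alpha, mode = mode),
    class = "indigo_network"
  )
}
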