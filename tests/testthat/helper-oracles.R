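# Independent oracles and small fixture builders shared across tests.
# Every oracle here is coded from the published definition, separately from
# the package implementation it checks.

# --- colorimetry: second implementation of the sRGB (IEC 61966-2-1, D65,
# 2 deg) -> CIELAB transform, written from the published constants ----------
ref_srgb_to_lab <- function(rgb) {
  v <- rgb / 255
  lin <- vapply(v, function(u) {
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }, numeric(1))
  M <- rbind(
    c(0.4124564, 0.3575761, 0.1804375),
    c(0.2126729, 0.7151522, 0.0721750),
    c(0.0193339, 0.1191920, 0.9503041)
  )
  xyz <- as.numeric(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# --- RDA: explicit projection + eigendecomposition oracle ------------------
brute_rda_eig <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  P <- Xc %*% solve(t(Xc) %*% Xc) %*% t(Xc)
  Yhat <- P %*% Yc
  ev <- eigen(t(Yhat) %*% Yhat / (nrow(Y) - 1), symmetric = TRUE)$values
  sort(ev[ev > 1e-10], decreasing = TRUE)
}

# --- Spearman: brute-force rank + Pearson, and enumeration p ---------------
# permutations generated by filtering the full n^n grid: a deliberately
# different algorithm from the package's recursive generator
oracle_perms <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_spearman_p <- function(x, y) {
  rs <- oracle_spearman(x, y)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  perms <- oracle_perms(length(x))
  null_rs <- apply(perms, 1, function(p) oracle_spearman(rx[p], ry))
  mean(abs(null_rs) >= abs(rs) - 1e-12)
}

# --- small fixture builders ------------------------------------------------
toy_feature_table <- function(counts, taxa = NULL, samples = NULL) {
  taxa <- taxa %||% sprintf("T%02d", seq_len(nrow(counts)))
  samples <- samples %||% sprintf("S%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(taxa, samples)
  dplyr::bind_cols(tibble::tibble(taxon_id = taxa), tibble::as_tibble(counts))
}

two_taxon_catalog <- function(orp_directions = c("prefers_high", "prefers_low")) {
  tibble::tibble(
    taxon_id = c("A", "B"),
    oxygen_class = c("aerobe", "obligate_anaerobe"),
    ph_optimum = 10.2, ph_width = 0.6,
    orp_midpoint = -200, orp_direction = orp_directions,
    affinity_labile = 0.5, affinity_dead = 0.5, affinity_bran = 0.5,
    baseline_fitness = 0, indigo_reducer = c(FALSE, TRUE)
  )
}

acceptance_design <- function() {
  fermentation_design(
    batches = tibble::tibble(
      batch_id = c("B2", "B3", "B4"),
      pretreat_temp = c(25, 25, 60),
      pretreat_ph = c(9.8, 11.2, 11.1)
    ),
    sampling_days = c(1:7, 10L, 16L, 29L, 49L, 75L, 140L, 209L)
  )
}
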