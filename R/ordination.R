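# Constrained ordination: redundancy analysis of the (Hellinger-transformed)
# community matrix on environmental variables, implemented directly from the
# projection + eigendecomposition definition.

#' Encode environmental drivers as a numeric sample-by-variable matrix
#'
#' Joins per-sample pH and ORP from the metadata with a wheat-bran exposure
#' variable encoded as the sum of exponentially decaying pulses,
#' `sum_events exp(-(t - t_event)/tau) * 1[t >= t_event]` — bran acts as an
#' environmental factor that is consumed within about a month, so `tau`
#' defaults to 30 days. All variables are standardised to zero mean, unit
#' variance.
#'
#' @param metadata Sample metadata tibble (`sample_id`, `batch_id`, `day`,
#'   `ph`, `orp`, plus any extra numeric columns to carry through).
#' @param bran_days Days on which bran was added.
#' @param bran_amount Amount per addition (the pulse height).
#' @param bran_decay_days Decay time constant tau, in days.
#' @param variables Which columns (after adding `bran`) to keep.
#' @return A tibble: `sample_id` plus one standardised column per variable.
#' @export
encode_environment <- function(metadata, bran_days = c(5, 19, 51, 85, 194),
                               bran_amount = 1, bran_decay_days = 30,
                               variables = c("ph", "orp", "bran")) {
  assert_that(all(c("sample_id", "day") %in% names(metadata)),
              "metadata needs sample_id and day columns")
  bran_level <- function(t) {
    sum(bran_amount * exp(-(t - bran_days[bran_days <= t]) / bran_decay_days))
  }
  env <- dplyr::mutate(as_tibble(metadata),
                       bran = vapply(.data$day, bran_level, numeric(1)))
  missing <- setdiff(variables, names(env))
  assert_that(length(missing) == 0,
              paste("variables not resolvable:", paste(missing, collapse = ", ")))
  vals <- env[, variables, drop = FALSE]
  assert_that(all(vapply(vals, function(v) all(is.finite(v)), logical(1))),
              "environmental variables must be complete and finite")
  scaled <- purrr::map(vals, function(v) {
    s <- sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  })
  dplyr::bind_cols(tibble(sample_id = env$sample_id), as_tibble(scaled))
}

#' Pre-transform a community profile for linear ordination
#'
#' Hellinger transform (square root of relative abundance), the standard
#' pre-transform that makes Euclidean-space methods appropriate for
#' proportion data; `"none"` passes proportions through untouched.
#'
#' @param rel Relative-abundance table (`taxon_id` + sample columns).
#' @param method `"hellinger"` (default) or `"none"`.
#' @return A samples x taxa numeric matrix (not yet centred).
#' @export
transform_community <- function(rel, method = c("hellinger", "none")) {
  method <- match.arg(method)
  m <- t(feature_matrix(rel)) # samples x taxa
  if (method == "hellinger") sqrt(m) else m
}

#' Redundancy analysis
#'
#' Fits `Y ~ X` by least squares on column-centred matrices: the fitted
#' values `Yhat = X (X'X)^-1 X' Y` span the constrained subspace, whose
#' principal axes (eigenvectors of `Yhat' Yhat / (n - 1)`) are the RDA axes;
#' residual axes come from `Y - Yhat`. Collinear columns of `X` are dropped
#' with a warning. Scores follow the species-focused (scaling-2) convention,
#' with each axis's sign fixed so its largest-magnitude species loading is
#' positive.
#'
#' @param Y Response matrix, samples x species (e.g. from
#'   [transform_community()]); centred internally.
#' @param X Constraint matrix: a samples x variables numeric matrix, or a
#'   tibble from [encode_environment()] (its `sample_id` column is used to
#'   align rows with `Y`).
#' @return An object of class `indigo_rda`: eigenvalues, proportion
#'   explained, site/species/biplot scores, and the variance decomposition.
#' @export
fit_rda <- function(Y, X) {
  if (is.data.frame(X) && "sample_id" %in% names(X)) {
    assert_that(!is.null(rownames(Y)) && all(rownames(Y) %in% X$sample_id),
                "Y rows must be named by sample ids present in X")
    X <- as.matrix(X[match(rownames(Y), X$sample_id), setdiff(names(X), "sample_id")])
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(Y)
  assert_that(nrow(X) == n, "Y and X must have the same number of samples")
  assert_that(n > ncol(X), "need more samples than constraint variables")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qx$pivot[seq.int(qx$rank + 1, ncol(Xc))]]
    warn(paste("dropping collinear constraint column(s):", paste(dropped, collapse = ", ")))
    Xc <- Xc[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(Xc)
  }
  if (qx$rank == 0) abort("constraint matrix has rank 0 after pruning")
  Yhat <- qr.fitted(qx, Yc)
  Yres <- Yc - Yhat
  total_var <- sum(Yc^2) / (n - 1)

  decompose <- function(M) {
    sv <- svd(M)
    ev <- sv$d^2 / (n - 1)
    keep <- ev > max(ev[1], 0) * 1e-12 & ev > 1e-12
    list(eig = ev[keep], u = sv$u[, keep, drop = FALSE], v = sv$v[, keep, drop = FALSE],
         d = sv$d[keep])
  }
  con <- decompose(Yhat)
  res <- decompose(Yres)

  # scaling-2: species scores V * d / sqrt(n-1) = V * sqrt(eig); sites U * d
  fix_signs <- function(v, u) {
    for (j in seq_len(ncol(v))) {
      i <- which.max(abs(v[, j]))
      if (v[i, j] < 0) {
        v[, j] <- -v[, j]
        u[, j] <- -u[, j]
      }
    }
    list(v = v, u = u)
  }
  sgn <- fix_signs(con$v, con$u)
  label <- function(prefix, v) {
    if (length(v) == 0) character(0) else paste0(prefix, seq_along(v))
  }
  axis_names <- label("RDA", con$eig)
  species_scores <- sgn$v %*% diag(sqrt(con$eig), length(con$eig))
  site_scores <- sgn$u %*% diag(con$d, length(con$eig))
  dimnames(species_scores) <- list(colnames(Y), axis_names)
  dimnames(site_scores) <- list(rownames(Y), axis_names)
  # biplot arrows: correlations of constraints with the constrained site axes
  biplot_scores <- suppressWarnings(cor(Xc, site_scores))
  biplot_scores[!is.finite(biplot_scores)] <- 0

  structure(
    list(
      constrained_eig = setNames(con$eig, axis_names),
      unconstrained_eig = setNames(res$eig, label("PC", res$eig)),
      total_variance = total_var,
      constrained_variance = sum(con$eig),
      unconstrained_variance = sum(res$eig),
      axis_explained = setNames(100 * con$eig / total_var, axis_names),
      site_scores = site_scores,
      species_scores = species_scores,
      biplot_scores = biplot_scores,
      n = n
    ),
    class = "indigo_rda"
  )
}

#' @export
print.indigo_rda <- function(x, ...) {
  cat("<indigo_rda>\n")
  cat(sprintf(
    "  constrained: %.4f (%.1f%%)  residual: %.4f  total: %.4f\n",
    x$constrained_variance, 100 * x$constrained_variance / x$total_variance,
    x$unconstrained_variance, x$total_variance
  ))
  cat("  axis % explained:", paste(sprintf("%s %.1f%%", names(x$axis_explained), x$axis_explained),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' @rdname fit_rda
#' @param x An `indigo_rda` object.
#' @param ... Unused.
#' @export
tidy.indigo_rda <- function(x, ...) {
  tibble(
    axis = c(names(x$constrained_eig), names(x$unconstrained_eig)),
    component = rep(c("constrained", "unconstrained"),
      c(length(x$constrained_eig), length(x$unconstrained_eig))
    ),
    eigenvalue = c(x$constrained_eig, x$unconstrained_eig),
    prop_explained = c(x$constrained_eig, x$unconstrained_eig) / x$total_variance
  )
}

#' @rdname fit_rda
#' @export
glance.indigo_rda <- function(x, ...) {
  tibble(
    total_variance = x$total_variance,
    constrained_variance = x$constrained_variance,
    unconstrained_variance = x$unconstrained_variance,
    prop_constrained = x$constrained_variance / x$total_variance,
    n_axes = length(x$constrained_eig),
    n = x$n
  )
}

#' @rdname fit_rda
#' @param object An `indigo_rda` object.
#' @param arrow_scale Multiplier applied to biplot arrows for display.
#' @export
autoplot.indigo_rda <- function(object, arrow_scale = NULL, ...) {
  sites <- as_tibble(object$site_scores[, 1:2, drop = FALSE], rownames = "sample_id")
  names(sites)[2:3] <- c("x", "y")
  arrows <- as_tibble(object$biplot_scores[, 1:2, drop = FALSE], rownames = "variable")
  names(arrows)[2:3] <- c("x", "y")
  arrow_scale <- arrow_scale %||% (0.8 * max(abs(sites$x), abs(sites$y)))
  labs <- sprintf("%s (%.1f%%)", names(object$axis_explained)[1:2], object$axis_explained[1:2])
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
      size = 2.6, vjust = -0.8, colour = "steelblue4"
    ) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = 0, y = 0, xend = .data$x * arrow_scale, yend = .data$y * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "black"
    ) +
    ggplot2::geom_text(
      data = arrows,
      ggplot2::aes(x = .data$x * arrow_scale * 1.08, y = .data$y * arrow_scale * 1.08,
                   label = .data$variable),
      colour = "black", size = 3
    ) +
    ggplot2::labs(x = labs[1], y = labs[2], title = "Redundancy analysis") +
    ggplot2::theme_minimal()
}
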