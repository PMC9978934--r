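# TSV readers/writers for the pipeline's tabular formats, including the
# PICRUSt2 "pred_metagenome_unstrat" and legacy "contrib" layouts.

#' Read and validate a feature table
#'
#' Expects a TSV with taxa as rows (first column the taxon id, any header
#' name) and one sample column per remaining column. Counts must be
#' non-negative integers; violations are rejected with the offending cell
#' named. CRLF and trailing-newline dialects parse identically to LF.
#'
#' @param path Path to the counts TSV.
#' @param metadata_path Optional sidecar TSV keyed by `sample_id` with at
#'   least `batch_id` and `day` columns.
#' @return A feature table tibble (`taxon_id` + integer sample columns);
#'   with metadata, a list `(table, metadata)`.
#' @export
read_feature_table <- function(path, metadata_path = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  names(raw)[1] <- "taxon_id"
  assert_that(!anyDuplicated(raw$taxon_id), "duplicate taxon ids in feature table")
  for (col in setdiff(names(raw), "taxon_id")) {
    v <- raw[[col]]
    if (!is.numeric(v)) abort(sprintf("sample column '%s' is not numeric", col))
    bad <- which(!is.finite(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad) > 0) {
      abort(sprintf(
        "invalid count at taxon '%s', sample '%s': %s",
        raw$taxon_id[bad[1]], col, format(v[bad[1]])
      ))
    }
    raw[[col]] <- as.integer(round(v))
  }
  if (is.null(metadata_path)) return(raw)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, col_types = readr::cols())
  need <- c("sample_id", "batch_id", "day")
  assert_that(all(need %in% names(meta)), "metadata needs sample_id, batch_id, day")
  missing <- setdiff(setdiff(names(raw), "taxon_id"), meta$sample_id)
  assert_that(length(missing) == 0,
              paste("samples without metadata:", paste(missing, collapse = ", ")))
  list(table = raw, metadata = meta)
}

#' @rdname read_feature_table
#' @param table A feature table tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read/write the PICRUSt2 unstratified KO table layout
#'
#' `pred_metagenome_unstrat.tsv`: rows are function (KO) ids under a first
#' column headed `function`, remaining columns are samples.
#'
#' @param path File path.
#' @return A tibble `ko_id` + sample columns.
#' @export
read_picrust2_unstrat <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  names(raw)[1] <- "ko_id"
  raw
}

#' @rdname read_picrust2_unstrat
#' @param ko_table A tibble `ko_id` + sample columns.
#' @export
write_picrust2_unstrat <- function(ko_table, path) {
  out <- ko_table
  names(out)[1] <- "function"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read/write the PICRUSt2 legacy stratified contribution layout
#'
#' Columns: `sample`, `function`, `taxon`, `taxon_abun`, `taxon_rel_abun`,
#' `genome_function_count`, `taxon_function_abun`, `taxon_rel_function_abun`.
#' On read, the relative columns map onto the package's contribution table
#' (`taxon_abundance`, `copy_number`, `contributed_count`).
#'
#' @param path File path.
#' @return A contribution tibble as produced by [predict_metagenome()].
#' @export
read_picrust2_contrib <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  need <- c("sample", "function", "taxon", "taxon_rel_abun",
            "genome_function_count", "taxon_rel_function_abun")
  assert_that(all(need %in% names(raw)),
              paste("contrib file missing columns:", paste(setdiff(need, names(raw)), collapse = ", ")))
  tibble(
    sample_id = raw$sample,
    ko_id = raw[["function"]],
    taxon_id = raw$taxon,
    taxon_abundance = raw$taxon_rel_abun,
    copy_number = raw$genome_function_count,
    contributed_count = raw$taxon_rel_function_abun
  )
}

#' @rdname read_picrust2_contrib
#' @param contrib A contribution tibble.
#' @export
write_picrust2_contrib <- function(contrib, path) {
  out <- tibble(
    sample = contrib$sample_id,
    "function" = contrib$ko_id,
    taxon = contrib$taxon_id,
    taxon_abun = contrib$taxon_abundance,
    taxon_rel_abun = contrib$taxon_abundance,
    genome_function_count = contrib$copy_number,
    taxon_function_abun = contrib$contributed_count,
    taxon_rel_function_abun = contrib$contributed_count
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read/write a KO-to-subpathway map
#'
#' TSV with columns `ko_id`, `subpathway` (one row per mapping), optionally
#' `super_pathway` and `category`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_pathway_map <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  assert_that(all(c("ko_id", "subpathway") %in% names(raw)),
              "pathway map needs ko_id and subpathway columns")
  assert_that(all(grepl("^K\\d{5}$", raw$ko_id)), "KO ids must match K#####")
  raw
}

#' @rdname read_pathway_map
#' @param map A pathway-map tibble.
#' @export
write_pathway_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' Write/read a swatch image as PNG
#'
#' @param image An H x W x 3 integer sRGB array (e.g. from
#'   [render_swatch()]).
#' @param path File path.
#' @return `path` (write) or the image array (read).
#' @export
write_swatch_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG swatches")
  }
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_swatch_png
#' @export
read_swatch_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to read PNG swatches")
  }
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), c(dim(raw), 3))
  img <- array(as.integer(round(raw[, , 1:3] * 255)), c(dim(raw)[1:2], 3))
  img
}
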