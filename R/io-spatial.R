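#' Read a 10x-style spatial triplet (matrix.mtx + barcodes.tsv + features.tsv)
#'
#' The Matrix Market file stores genes x barcodes (10x convention);
#' `barcodes.tsv` holds one barcode per line and `features.tsv` one gene
#' symbol per line (first column used if multiple). Section tags may be
#' given in a second barcode column; otherwise all barcodes are assigned
#' section `"1"`.
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @returns A spatial sample tibble (`barcode`, `section`, one column per
#'   gene) suitable for [classify_barcodes()].
#' @export
read_spatial_10x <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f) > 0) {
    abort(sprintf("Missing triplet file(s): %s", paste(missing_f, collapse = ", ")))
  }
  m <- Matrix::readMM(paths[1])
  bc <- readr::read_tsv(paths[2], col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  ft <- readr::read_tsv(paths[3], col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(ft) != nrow(m) || nrow(bc) != ncol(m)) {
    abort("Triplet dimensions disagree (features x barcodes expected).")
  }
  dense <- t(as.matrix(m)) # barcodes x genes
  colnames(dense) <- ft[[1]]
  out <- bind_cols(
    tibble(
      barcode = bc[[1]],
      section = if (ncol(bc) >= 2) as.character(bc[[2]]) else "1"
    ),
    as_tibble(dense)
  )
  validate_spatial(out)
}

#' Write a spatial sample as a 10x-style triplet
#'
#' @param spatial A spatial sample tibble (`barcode`, `section`, gene
#'   columns).
#' @param dir Output directory (created if needed).
#' @returns `dir`, invisibly.
#' @export
write_spatial_10x <- function(spatial, dir) {
  spatial <- validate_spatial(spatial)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes <- setdiff(names(spatial), c("barcode", "section"))
  mat <- t(as.matrix(spatial[, genes, drop = FALSE])) # genes x barcodes
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(spatial$barcode, spatial$section),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(genes), file.path(dir, "features.tsv"),
                   col_names = FALSE)
  invisible(dir)
}

#' Read a dense barcode x gene TSV as a spatial sample
#'
#' Expects columns `barcode`, `section`, then one numeric column per gene.
#'
#' @param path Path to the TSV file.
#' @returns A spatial sample tibble.
#' @export
read_spatial_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out$section <- as.character(out$section)
  validate_spatial(out)
}
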