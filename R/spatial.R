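#' Positive-expression threshold for one gene
#'
#' The threshold is the 25th percentile (first quartile, linear
#' interpolation between closest order statistics) of the strictly positive
#' expression values of the gene. Zeros are excluded before the quantile is
#' taken: the rule asks where the *detected* signal sits, not how often the
#' gene drops out.
#'
#' @param values Numeric vector of scaled-and-normalised expression values.
#' @returns The threshold (a single number).
#' @examples
#' positive_threshold(c(0, 1, 2, 3, 4)) # 1.75
#' @export
positive_threshold <- function(values) {
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  if (length(pos) == 0) abort("gene not detected in sample")
  unname(stats::quantile(pos, probs = 0.25, type = 7))
}

#' Classify barcodes as positive for a gene
#'
#' A barcode is positive when its expression is strictly above the
#' [positive_threshold()] computed over all barcodes of the sample (both
#' serial sections pooled). A gene whose positive values are all equal
#' therefore yields an empty positive set; this is surfaced as a warning.
#'
#' @param spatial A spatial sample: a tibble with columns `barcode`,
#'   `section` and one numeric column per gene (see [simulate_spatial()] or
#'   [read_spatial_10x()]).
#' @param gene Gene symbol (must be a column of `spatial`).
#' @returns A tibble of class `barcode_classification` with columns
#'   `barcode`, `value`, `positive`, and attributes `gene` and `threshold`.
#' @export
classify_barcodes <- function(spatial, gene) {
  spatial <- validate_spatial(spatial)
  if (!gene %in% names(spatial)) {
    abort(sprintf("Gene %s not present in spatial sample.", gene))
  }
  v <- spatial[[gene]]
  thr <- positive_threshold(v)
  positive <- v > thr
  if (!any(positive) && any(v > 0)) {
    warn(sprintf(
      "All positive values of %s are equal; strict thresholding leaves no positive barcode.",
      gene))
  }
  out <- tibble(barcode = spatial$barcode, value = v, positive = positive)
  class(out) <- c("barcode_classification", class(out))
  attr(out, "gene") <- gene
  attr(out, "threshold") <- thr
  out
}

validate_spatial <- function(spatial) {
  spatial <- as_tibble(spatial)
  need <- c("barcode", "section")
  missing_cols <- setdiff(need, names(spatial))
  if (length(missing_cols) > 0) {
    abort(sprintf("Spatial sample is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(spatial$barcode)) abort("Barcode IDs must be unique.")
  spatial
}

pos_set <- function(spatial, gene) {
  cl <- classify_barcodes(spatial, gene)
  cl$barcode[cl$positive]
}

#' Marker co-expression ratio for one gene in one sample
#'
#' Let `D` be the set of barcodes positive for both exclusion markers
#' (double-identity spots, e.g. SCN10A+ and DCN+). The ratio is
#' `|pos(gene) n pos(marker) \\ D| / |pos(marker) \\ D|`: among the
#' single-identity marker-positive barcodes, the fraction also positive for
#' the gene of interest. The exclusion applies to numerator and denominator
#' alike, so the ratio stays a proportion in \[0, 1\].
#'
#' @inheritParams classify_barcodes
#' @param gene Gene of interest.
#' @param marker Marker gene defining the denominator population.
#' @param excl_marker_a,excl_marker_b The two cell-identity markers whose
#'   double-positive barcodes are excluded (defaults `"SCN10A"`, `"DCN"`).
#' @returns The ratio, or `NA` when no marker-positive barcode remains after
#'   exclusion (undefined, reported as missing).
#' @export
coexpression_ratio <- function(spatial, gene, marker,
                               excl_marker_a = "SCN10A",
                               excl_marker_b = "DCN") {
  spatial <- validate_spatial(spatial)
  pos_gene <- pos_set(spatial, gene)
  pos_marker <- pos_set(spatial, marker)
  D <- intersect(pos_set(spatial, excl_marker_a), pos_set(spatial, excl_marker_b))
  denom <- setdiff(pos_marker, D)
  if (length(denom) == 0) return(NA_real_)
  num <- intersect(setdiff(intersect(pos_gene, pos_marker), D), denom)
  length(num) / length(denom)
}

#' Paired co-expression ratios of one gene against two markers
#'
#' For every spatial sample, computes the co-expression ratio of `gene`
#' with `marker_a` and with `marker_b` (double-marker barcodes excluded
#' from both).
#'
#' @param samples A named list of spatial sample tibbles, or one tibble
#'   with a `sample_id` column.
#' @inheritParams coexpression_ratio
#' @param marker_a,marker_b The two markers (defaults `"SCN10A"`, `"DCN"`).
#' @returns A tibble with columns `sample_id`, `gene`, `ratio_a`, `ratio_b`
#'   (`NA` where undefined).
#' @export
coexpression_ratios <- function(samples, gene,
                                marker_a = "SCN10A", marker_b = "DCN") {
  samples <- as_sample_list(samples)
  purrr::imap_dfr(samples, function(sp, id) {
    tibble(
      sample_id = id,
      gene = gene,
      ratio_a = coexpression_ratio(sp, gene, marker_a, marker_a, marker_b),
      ratio_b = coexpression_ratio(sp, gene, marker_b, marker_a, marker_b)
    )
  })
}

as_sample_list <- function(samples) {
  if (is.data.frame(samples)) {
    if (!"sample_id" %in% names(samples)) {
      abort("A single spatial tibble must carry a `sample_id` column.")
    }
    samples <- split(dplyr::select(samples, -"sample_id"), samples$sample_id)
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  samples
}

#' Test marker preference of one gene across samples
#'
#' Combines the per-sample paired ratios with the exact Wilcoxon
#' matched-pairs signed-rank test and the reporting rule: a gene is
#' *reported* only when the larger of its two mean co-expression ratios
#' reaches `min_coexpr`; its *preference* is the marker with the greater
#' mean ratio (`"none"` on an exact tie); the significance flag is set when
#' the two-sided exact p is below `alpha`. Samples where either ratio is
#' undefined are dropped pairwise; fewer than 3 valid pairs makes the gene
#' unevaluable.
#'
#' @inheritParams coexpression_ratios
#' @param alpha Significance level for the Wilcoxon flag (default 0.05).
#' @param min_coexpr Minimum mean co-expression ratio for a gene to be
#'   reported (default 0.05, i.e. 5%).
#' @returns A one-row tibble: `gene`, `n_samples`, `mean_ratio_a`,
#'   `mean_ratio_b`, `max_coexpression`, `W`, `p_value`, `significant`,
#'   `preference` (marker symbol, `"none"`, or `"unevaluable"`), `reported`.
#' @export
coexpression_test <- function(samples, gene,
                              marker_a = "SCN10A", marker_b = "DCN",
                              alpha = 0.05, min_coexpr = 0.05) {
  ratios <- coexpression_ratios(samples, gene, marker_a, marker_b)
  classify_gene_preference(ratios, marker_a = marker_a, marker_b = marker_b,
                           alpha = alpha, min_coexpr = min_coexpr)
}

#' Apply the preference / reporting rule to paired ratios
#'
#' @param ratios A tibble with columns `gene`, `sample_id`, `ratio_a`,
#'   `ratio_b` for a single gene (as produced by [coexpression_ratios()]).
#' @inheritParams coexpression_test
#' @returns See [coexpression_test()].
#' @export
classify_gene_preference <- function(ratios,
                                     marker_a = "SCN10A", marker_b = "DCN",
                                     alpha = 0.05, min_coexpr = 0.05) {
  stopifnot(all(c("gene", "ratio_a", "ratio_b") %in% names(ratios)))
  gene <- unique(ratios$gene)
  if (length(gene) != 1) abort("`ratios` must describe a single gene.")
  ok <- !(is.na(ratios$ratio_a) | is.na(ratios$ratio_b))
  a <- ratios$ratio_a[ok]
  b <- ratios$ratio_b[ok]
  if (length(a) < 3) {
    return(tibble(gene = gene, n_samples = length(a),
                  mean_ratio_a = NA_real_, mean_ratio_b = NA_real_,
                  max_coexpression = NA_real_, W = NA_real_,
                  p_value = NA_real_, significant = NA,
                  preference = "unevaluable", reported = FALSE))
  }
  wt <- wilcoxon_signed_rank_exact(a, b)
  mean_a <- mean(a)
  mean_b <- mean(b)
  max_co <- max(mean_a, mean_b)
  preference <- if (mean_a > mean_b) marker_a else if (mean_b > mean_a) marker_b else "none"
  tibble(
    gene = gene, n_samples = length(a),
    mean_ratio_a = mean_a, mean_ratio_b = mean_b,
    max_coexpression = max_co,
    W = wt$W, p_value = wt$p_value,
    significant = wt$p_value < alpha,
    preference = preference,
    reported = max_co >= min_coexpr
  )
}

#' Run the co-expression analysis for a set of genes
#'
#' @inheritParams coexpression_test
#' @param genes Character vector of genes of interest.
#' @returns A tibble of class `coexpr_results`, one row per gene (columns as
#'   in [coexpression_test()]); the per-sample ratio table is attached as
#'   attribute `"ratios"`.
#' @export
run_coexpression <- function(samples, genes,
                             marker_a = "SCN10A", marker_b = "DCN",
                             alpha = 0.05, min_coexpr = 0.05) {
  samples <- as_sample_list(samples)
  ratio_tbl <- purrr::map_dfr(
    genes, function(g) coexpression_ratios(samples, g, marker_a, marker_b))
  out <- purrr::map_dfr(genes, function(g) {
    classify_gene_preference(ratio_tbl[ratio_tbl$gene == g, , drop = FALSE],
                             marker_a = marker_a, marker_b = marker_b,
                             alpha = alpha, min_coexpr = min_coexpr)
  })
  class(out) <- c("coexpr_results", class(out))
  attr(out, "ratios") <- ratio_tbl
  attr(out, "markers") <- c(marker_a, marker_b)
  out
}

#' @describeIn run_coexpression Per-sample paired ratio table of a result.
#' @param results A `coexpr_results` object.
#' @export
coexpr_ratio_table <- function(results) {
  stopifnot(inherits(results, "coexpr_results"))
  attr(results, "ratios")
}
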