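#' Intersect differential-expression lists with the matrisome catalog
#'
#' Each condition's upregulated-gene list is intersected with the catalog,
#' matching either the primary symbol or any listed alias. The study's four
#' conditions are upregulated in male pain (MP), female pain (FP), male
#' no-pain (MN) and female no-pain (FN) donors.
#'
#' @param deg A tibble with columns `condition` and `symbol` (one row per
#'   list entry), or a named list of symbol vectors.
#' @param catalog A [matrisome_catalog].
#' @param conditions Valid condition tags (default `MP`, `FP`, `MN`, `FN`);
#'   an unknown tag in `deg` is an error.
#' @param case_fold Ignore case when matching symbols (default `FALSE`).
#' @returns A list of class `matrisome_deg`: `genes` (tibble `condition`,
#'   `symbol` — the catalog primary symbol — and `matched_via`), `counts`
#'   (per-condition), `total_entries` (summed with multiplicity across
#'   lists), `n_unique`, and the `catalog` for downstream annotation.
#' @export
filter_matrisome <- function(deg, catalog,
                             conditions = c("MP", "FP", "MN", "FN"),
                             case_fold = FALSE) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  if (is.list(deg) && !is.data.frame(deg)) {
    deg <- purrr::imap_dfr(deg, ~ tibble(condition = .y, symbol = .x))
  }
  deg <- as_tibble(deg)
  if (!all(c("condition", "symbol") %in% names(deg))) {
    abort("`deg` needs columns `condition` and `symbol`.")
  }
  bad <- setdiff(unique(deg$condition), conditions)
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition tag(s): %s", paste(bad, collapse = ", ")))
  }
  key <- if (case_fold) tolower else identity
  # measured-symbol -> catalog primary symbol, aliases included
  alias_tbl <- tibble(
    measured = unlist(catalog$aliases),
    primary = rep(catalog$symbol, lengths(catalog$aliases)),
    via = "alias"
  )
  lookup <- bind_rows(
    tibble(measured = catalog$symbol, primary = catalog$symbol, via = "symbol"),
    alias_tbl
  )
  lookup <- lookup[!duplicated(key(lookup$measured)), ]
  idx <- match(key(deg$symbol), key(lookup$measured))
  genes <- tibble(
    condition = deg$condition[!is.na(idx)],
    symbol = lookup$primary[idx[!is.na(idx)]],
    matched_via = lookup$via[idx[!is.na(idx)]]
  ) |>
    distinct(.data$condition, .data$symbol, .keep_all = TRUE) |>
    arrange(match(.data$condition, conditions), .data$symbol)
  counts <- tibble(condition = conditions) |>
    left_join(count(genes, .data$condition, name = "n"), by = "condition") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  out <- list(
    genes = genes,
    counts = counts,
    total_entries = nrow(genes),
    n_unique = dplyr::n_distinct(genes$symbol),
    catalog = catalog
  )
  class(out) <- "matrisome_deg"
  out
}

#' @export
print.matrisome_deg <- function(x, ...) {
  cat("Matrisome DEG overlay:", x$total_entries, "entries across",
      nrow(x$counts), "conditions (", x$n_unique, "unique genes )\n")
  print(x$counts)
  invisible(x)
}

#' @describeIn filter_matrisome One-row summary: total entries (with
#'   multiplicity), unique genes, and genes upregulated in more than one
#'   condition.
#' @param x A `matrisome_deg` object.
#' @param ... Unused.
#' @export
glance.matrisome_deg <- function(x, ...) {
  tibble(
    total_entries = x$total_entries,
    n_unique = x$n_unique,
    n_multi_condition = nrow(multi_condition_genes(x))
  )
}

#' Genes upregulated in more than one condition
#'
#' @param deg_report A `matrisome_deg` from [filter_matrisome()], or a
#'   tibble with columns `condition` and `symbol`.
#' @returns A tibble sorted by symbol: `symbol`, `conditions`
#'   (comma-separated, in list order), `n_conditions` (always >= 2).
#' @export
multi_condition_genes <- function(deg_report) {
  genes <- if (inherits(deg_report, "matrisome_deg")) deg_report$genes else
    as_tibble(deg_report)
  if (dplyr::n_distinct(genes$condition) < 2) {
    abort("Need gene lists for at least 2 conditions.")
  }
  genes |>
    group_by(.data$symbol) |>
    summarise(conditions = paste(.data$condition, collapse = ","),
              n_conditions = dplyr::n(), .groups = "drop") |>
    filter(.data$n_conditions >= 2) |>
    arrange(.data$symbol)
}

#' Rebuild a Table 1-style matrisome DEG / co-expression report
#'
#' Rows are the matrisome differentially expressed genes that pass the
#' minimum co-expression filter, grouped by their preferred marker (first
#' the marker_a block, then marker_b), each annotated with division,
#' category, the conditions it was upregulated in, and pass-through
#' interaction partners from an external ligand-receptor table.
#'
#' @param deg_report A `matrisome_deg` from [filter_matrisome()].
#' @param coexpr A `coexpr_results` from [run_coexpression()] covering the
#'   matrisome DEGs; a gene missing from it is emitted with preference
#'   `"unevaluated"` and a warning.
#' @param partners Optional tibble `gene`, `partner` (many rows per gene);
#'   partners are concatenated comma-separated into the row.
#' @param min_coexpr Minimum mean co-expression ratio (default 0.05); genes
#'   below it (per the `reported` flag in `coexpr`) are omitted.
#' @returns A tibble: `division`, `category`, `symbol`, `up_in`,
#'   `preference`, `partners`, ordered by preference block then symbol.
#' @export
build_table1 <- function(deg_report, coexpr, partners = NULL,
                         min_coexpr = 0.05) {
  stopifnot(inherits(deg_report, "matrisome_deg"))
  stopifnot(inherits(coexpr, "coexpr_results"))
  markers <- attr(coexpr, "markers") %||% c("SCN10A", "DCN")
  up_in <- deg_report$genes |>
    group_by(.data$symbol) |>
    summarise(up_in = paste(.data$condition, collapse = ", "), .groups = "drop")
  catalog <- deg_report$catalog
  rows <- up_in |>
    left_join(as_tibble(catalog)[, c("symbol", "division", "category")],
              by = "symbol")
  miss <- setdiff(rows$symbol, coexpr$gene)
  if (length(miss) > 0) {
    warn(sprintf("No co-expression result for: %s (emitted as unevaluated)",
                 paste(miss, collapse = ", ")))
  }
  rows <- rows |>
    left_join(as_tibble(coexpr)[, c("gene", "preference", "reported",
                                    "max_coexpression", "p_value")],
              by = c("symbol" = "gene")) |>
    mutate(
      preference = ifelse(is.na(.data$preference), "unevaluated", .data$preference),
      reported = ifelse(is.na(.data$reported), TRUE, .data$reported)
    ) |>
    filter(.data$preference %in% c("unevaluated", "unevaluable") |
             (!is.na(.data$max_coexpression) &
                .data$max_coexpression >= min_coexpr)) |>
    select(-"reported")
  if (!is.null(partners)) {
    partners <- as_tibble(partners)
    stopifnot(all(c("gene", "partner") %in% names(partners)))
    ptab <- partners |>
      group_by(.data$gene) |>
      summarise(partners = paste(.data$partner, collapse = ", "),
                .groups = "drop")
    rows <- left_join(rows, ptab, by = c("symbol" = "gene"))
  } else {
    rows$partners <- NA_character_
  }
  block <- match(rows$preference, c(markers, "none", "unevaluated"))
  rows <- rows[order(block, rows$symbol), ]
  rows <- rows[, c("division", "category", "symbol", "up_in", "preference",
                   "max_coexpression", "p_value", "partners")]
  rows
}
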