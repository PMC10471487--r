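#' Build a matrisome catalog from a data frame
#'
#' A matrisome catalog is the gene universe of the analysis: every gene is
#' assigned to one of six categories (glycoproteins, collagens, proteoglycans,
#' ECM-affiliated, ECM-regulators, secreted-factors), and the category fixes
#' the division — the three structural categories form the core matrisome,
#' the other three the matrisome-associated division.
#'
#' @param data Data frame with columns `symbol`, `division`, `category` and
#'   optionally `aliases` (a list-column of character vectors, or a character
#'   column with pipe-separated aliases).
#' @param species `"mouse"` or `"human"`.
#' @returns A tibble of class `matrisome_catalog` with columns `symbol`,
#'   `division`, `category`, `aliases` (list-column) and a `species`
#'   attribute.
#' @examples
#' matrisome_catalog(
#'   data.frame(
#'     symbol = c("Col1a1", "Dcn"),
#'     division = c("core-matrisome", "core-matrisome"),
#'     category = c("collagens", "proteoglycans")
#'   ),
#'   species = "mouse"
#' )
#' @export
matrisome_catalog <- function(data, species = c("mouse", "human")) {
  species <- match.arg(species)
  data <- as_tibble(data)
  required <- c("symbol", "division", "category")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Catalog is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"aliases" %in% names(data)) data$aliases <- vector("list", nrow(data))
  if (is.character(data$aliases)) {
    data$aliases <- lapply(strsplit(ifelse(is.na(data$aliases), "", data$aliases),
                                    "|", fixed = TRUE),
                           function(a) a[nzchar(a)])
  }
  data$symbol <- as.character(data$symbol)
  if (any(!nzchar(data$symbol) | is.na(data$symbol))) {
    abort("Catalog symbols must be non-empty.")
  }
  dup <- unique(data$symbol[duplicated(data$symbol)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate catalog symbol(s): %s", paste(dup, collapse = ", ")))
  }
  data$category <- normalize_category(data$category)
  data$division <- normalize_division(data$division)
  implied <- unname(category_division[data$category])
  bad <- data$symbol[data$division != implied]
  if (length(bad) > 0) {
    abort(sprintf(
      "Category/division mismatch for: %s (category implies the other division)",
      paste(bad, collapse = ", ")))
  }
  alias_all <- unlist(data$aliases)
  clash <- intersect(alias_all, data$symbol)
  if (length(clash) > 0) {
    abort(sprintf("Alias equals another entry's primary symbol: %s",
                  paste(unique(clash), collapse = ", ")))
  }
  out <- data[, c("symbol", "division", "category", "aliases")]
  class(out) <- c("matrisome_catalog", class(out))
  attr(out, "species") <- species
  out
}

#' Read a matrisome catalog file
#'
#' Reads a CSV or TSV catalog (dialect auto-detected from the file extension)
#' with required columns `symbol`, `division`, `category` and an optional
#' `aliases` column holding pipe-separated alias symbols. Upstream resources
#' use varying header names; map them with `header_map`.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @inheritParams matrisome_catalog
#' @param header_map Optional named character vector mapping file column names
#'   to the canonical names, e.g. `c("Gene Symbol" = "symbol")`.
#' @returns A [matrisome_catalog] tibble.
#' @export
read_matrisome_catalog <- function(path, species = c("mouse", "human"),
                                   header_map = NULL) {
  species <- match.arg(species)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(header_map)) {
    hits <- intersect(names(header_map), names(data))
    names(data)[match(hits, names(data))] <- unname(header_map[hits])
  }
  matrisome_catalog(data, species = species)
}

#' Write a matrisome catalog file
#'
#' Inverse of [read_matrisome_catalog()]: aliases are serialised
#' pipe-separated, and the dialect follows the file extension.
#'
#' @param catalog A [matrisome_catalog].
#' @param path Output path (`.csv` or `.tsv`).
#' @returns `path`, invisibly.
#' @export
write_matrisome_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  out <- as_tibble(catalog)
  out$aliases <- vapply(out$aliases, paste, character(1), collapse = "|")
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv
  } else {
    readr::write_tsv
  }
  writer(out, path)
  invisible(path)
}

#' Count catalog genes per category and division
#'
#' @param catalog A [matrisome_catalog].
#' @returns A tibble with columns `level` (`"category"`, `"division"`,
#'   `"total"`), `group` and `n`. Division counts are the sums of their
#'   categories and the total is the sum of the divisions.
#' @examples
#' cat6 <- matrisome_catalog(data.frame(
#'   symbol = paste0("G", 1:6),
#'   category = c("glycoproteins", "collagens", "proteoglycans",
#'                "ECM-affiliated", "ECM-regulators", "secreted-factors"),
#'   division = c(rep("core-matrisome", 3), rep("matrisome-associated", 3))
#' ))
#' category_counts(cat6)
#' @export
category_counts <- function(catalog) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  cat_n <- vapply(matrisome_categories,
                  function(cc) sum(catalog$category == cc), integer(1))
  div_n <- vapply(matrisome_divisions,
                  function(dd) sum(catalog$division == dd), integer(1))
  bind_rows(
    tibble(level = "category", group = matrisome_categories, n = unname(cat_n)),
    tibble(level = "division", group = matrisome_divisions, n = unname(div_n)),
    tibble(level = "total", group = "total", n = nrow(catalog))
  )
}

#' Resolve measured gene symbols against a catalog
#'
#' Each catalog entry is classified exactly once: `matched` if its primary
#' symbol occurs among the measured symbols, otherwise `alias` if one of its
#' listed aliases does (the first listed alias present wins), otherwise
#' `unmatched`. Direct matches always take precedence over alias rescue.
#'
#' @param catalog A [matrisome_catalog].
#' @param measured_symbols Character vector of symbols present in the
#'   measured data set.
#' @param case_fold If `TRUE`, matching ignores case. Default `FALSE`:
#'   mouse and human symbol casing conventions differ and are informative.
#' @returns A tibble of class `resolution_report` with columns `symbol`,
#'   `status` (`matched`/`alias`/`unmatched`) and `matched_as` (the measured
#'   symbol used; `NA` when unmatched).
#' @export
resolve_symbols <- function(catalog, measured_symbols, case_fold = FALSE) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  measured_symbols <- as.character(measured_symbols)
  if (length(measured_symbols) == 0) abort("`measured_symbols` must be non-empty.")
  key <- if (case_fold) tolower else identity
  measured_key <- key(measured_symbols)
  # keep the first measured spelling for each key
  first_idx <- !duplicated(measured_key)
  lookup <- setNames(measured_symbols[first_idx], measured_key[first_idx])

  resolve_one <- function(symbol, aliases) {
    if (key(symbol) %in% names(lookup)) {
      return(c("matched", unname(lookup[key(symbol)])))
    }
    for (a in aliases) {
      if (key(a) %in% names(lookup)) {
        return(c("alias", unname(lookup[key(a)])))
      }
    }
    c("unmatched", NA_character_)
  }
  res <- mapply(resolve_one, catalog$symbol, catalog$aliases,
                SIMPLIFY = TRUE, USE.NAMES = FALSE)
  out <- tibble(
    symbol = catalog$symbol,
    status = res[1, ],
    matched_as = res[2, ]
  )
  class(out) <- c("resolution_report", class(out))
  attr(out, "case_fold") <- case_fold
  out
}

#' Read a two-column human-mouse ortholog map
#'
#' The file is a TSV with columns `human_symbol` and `mouse_symbol`
#' (header required); duplicated rows are dropped. The mapping may be
#' many-to-many.
#'
#' @param path Path to the TSV file.
#' @returns A tibble of class `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ortholog_map(data)
}

#' Build an ortholog map from a data frame
#'
#' @param data Data frame with character columns `human_symbol` and
#'   `mouse_symbol`; duplicated pairs are de-duplicated.
#' @returns A tibble of class `ortholog_map`.
#' @export
ortholog_map <- function(data) {
  data <- as_tibble(data)
  need <- c("human_symbol", "mouse_symbol")
  if (!all(need %in% names(data))) {
    abort("Ortholog map needs columns `human_symbol` and `mouse_symbol`.")
  }
  out <- distinct(data[, need])
  class(out) <- c("ortholog_map", class(out))
  out
}

#' Map gene symbols to their orthologs in the other species
#'
#' Lookup is symmetric: the same pair table answers queries in either
#' direction, and one-to-many relations are preserved. Symbols without any
#' ortholog map to an empty set.
#'
#' @param map An [ortholog_map].
#' @param symbols Character vector of query symbols.
#' @param direction `"human_to_mouse"` or `"mouse_to_human"`.
#' @returns A tibble with columns `symbol` and `orthologs` (list-column of
#'   character vectors, possibly empty).
#' @export
map_orthologs <- function(map, symbols,
                          direction = c("human_to_mouse", "mouse_to_human")) {
  stopifnot(inherits(map, "ortholog_map"))
  direction <- match.arg(direction)
  from <- if (direction == "human_to_mouse") map$human_symbol else map$mouse_symbol
  to   <- if (direction == "human_to_mouse") map$mouse_symbol else map$human_symbol
  orth <- lapply(symbols, function(s) sort(unique(to[from == s])))
  tibble(symbol = as.character(symbols), orthologs = orth)
}
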