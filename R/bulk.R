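#' Read a gene x sample TPM matrix
#'
#' TSV with the gene symbol in the first column and one numeric column per
#' sample. Row symbols must be unique and all values non-negative.
#'
#' @param path Path to the TSV file.
#' @returns A tibble whose first column is `symbol`, remaining columns are
#'   per-sample TPM.
#' @export
read_tpm_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(data)[1] <- "symbol"
  validate_tpm(data)
}

validate_tpm <- function(tpm) {
  tpm <- as_tibble(tpm)
  if (names(tpm)[1] != "symbol") {
    abort("TPM table must have `symbol` as its first column.")
  }
  if (ncol(tpm) < 2) abort("TPM table has no sample columns.")
  dup <- unique(tpm$symbol[duplicated(tpm$symbol)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene symbol(s) in TPM table: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  vals <- as.matrix(tpm[, -1])
  if (!is.numeric(vals)) abort("Sample columns must be numeric.")
  if (any(vals < 0, na.rm = TRUE)) abort("TPM values must be non-negative.")
  tpm
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `species`, `sex`, `pain_status`.
#'
#' @param path Path to the TSV file.
#' @returns A tibble.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "species", "sex", "pain_status")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Sample metadata is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(data$sample_id)) abort("`sample_id` must be unique.")
  data
}

#' Derive the data-adaptive TPM expression cutoff
#'
#' The cutoff is the mean of the single non-zero TPM values of all genes
#' detected (TPM > 0) in exactly one sample. Genes detected in one sample
#' only sit at the boundary between technical noise and genuine expression,
#' so their typical magnitude is used as the floor above which a gene is
#' considered expressed. The average is taken over the non-zero values only
#' (one per singleton gene); the zero cells carry no magnitude information.
#'
#' @param tpm A TPM tibble as returned by [read_tpm_matrix()].
#' @param restrict_to Optional character vector of gene symbols (typically
#'   the matrisome genes); only these rows inform the cutoff.
#' @returns A single positive number, the TPM cutoff.
#' @examples
#' tpm <- tibble::tibble(symbol = c("A", "B", "C"),
#'                       s1 = c(0, 0, 1), s2 = c(0, 3, 1), s3 = c(5, 0, 1))
#' derive_cutoff(tpm) # mean of 5 and 3
#' @export
derive_cutoff <- function(tpm, restrict_to = NULL) {
  tpm <- validate_tpm(tpm)
  if (ncol(tpm) < 3) abort("Need at least 2 samples to derive a cutoff.")
  if (!is.null(restrict_to)) {
    tpm <- tpm[tpm$symbol %in% restrict_to, , drop = FALSE]
  }
  vals <- as.matrix(tpm[, -1])
  detected <- vals > 0
  singleton <- rowSums(detected) == 1L
  if (!any(singleton)) {
    abort(paste0(
      "No gene is detected (TPM > 0) in exactly one sample; ",
      "the data-adaptive cutoff is undefined. Supply a cutoff manually."))
  }
  single_vals <- vals[singleton, , drop = FALSE]
  mean(single_vals[single_vals > 0])
}

#' Call genes expressed against a TPM cutoff
#'
#' In `per-sample` mode a gene is expressed in a sample when its TPM in that
#' sample strictly exceeds the cutoff. In `cohort-mean` mode a gene is
#' expressed when its mean TPM across all samples strictly exceeds the
#' cutoff. Equality is never expressed.
#'
#' @inheritParams derive_cutoff
#' @param cutoff Positive TPM threshold (e.g. from [derive_cutoff()]).
#' @param mode `"per-sample"` or `"cohort-mean"`.
#' @returns A tibble of class `expression_calls`: in per-sample mode,
#'   `symbol` plus one logical column per sample; in cohort-mean mode,
#'   columns `symbol`, `mean_tpm`, `expressed`. Attributes `cutoff` and
#'   `mode` record the call parameters.
#' @export
call_expressed <- function(tpm, cutoff, mode = c("per-sample", "cohort-mean")) {
  tpm <- validate_tpm(tpm)
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0) {
    abort("`cutoff` must be a single positive number.")
  }
  vals <- as.matrix(tpm[, -1])
  if (mode == "per-sample") {
    calls <- as_tibble(as.data.frame(vals > cutoff))
    out <- bind_cols(tibble(symbol = tpm$symbol), calls)
  } else {
    mean_tpm <- rowMeans(vals)
    out <- tibble(symbol = tpm$symbol, mean_tpm = mean_tpm,
                  expressed = mean_tpm > cutoff)
  }
  class(out) <- c("expression_calls", class(out))
  attr(out, "cutoff") <- cutoff
  attr(out, "mode") <- mode
  out
}

#' Expressed gene set from cohort-mean calls
#'
#' @param calls An `expression_calls` object in cohort-mean mode.
#' @returns Character vector of symbols called expressed.
#' @export
expressed_genes <- function(calls) {
  stopifnot(inherits(calls, "expression_calls"))
  if (attr(calls, "mode") != "cohort-mean") {
    abort("`expressed_genes()` needs cohort-mean calls.")
  }
  calls$symbol[calls$expressed]
}

#' Per-sample percentage of expressed genes per matrisome category
#'
#' For each sample and category, the percentage of that category's genes
#' called expressed; likewise per division and overall. Catalog genes not
#' found in the measured data (unmatched in the resolution report) stay in
#' the denominator as not expressed, so percentages refer to the full
#' published category sizes.
#'
#' @param calls Per-sample `expression_calls` from [call_expressed()].
#' @param catalog A [matrisome_catalog].
#' @param resolution Optional `resolution_report` from [resolve_symbols()];
#'   when supplied, catalog entries rescued by alias are looked up in the
#'   call matrix under their measured (alias) symbol.
#' @returns A tibble of class `category_profile` with columns `sample_id`,
#'   `level` (`category`/`division`/`overall`), `group`, `n_expressed`,
#'   `n_genes`, `pct`. Empty categories yield `pct = NA` (undefined, not 0).
#'   Use [tidy()] for the mean +/- SEM summary across samples.
#' @export
category_percentages <- function(calls, catalog, resolution = NULL) {
  stopifnot(inherits(calls, "expression_calls"))
  stopifnot(inherits(catalog, "matrisome_catalog"))
  if (attr(calls, "mode") != "per-sample") {
    abort("`category_percentages()` needs per-sample calls.")
  }
  sample_ids <- setdiff(names(calls), "symbol")
  # symbol under which each catalog entry appears in the call matrix
  measured_as <- catalog$symbol
  if (!is.null(resolution)) {
    stopifnot(inherits(resolution, "resolution_report"))
    idx <- match(catalog$symbol, resolution$symbol)
    ma <- resolution$matched_as[idx]
    measured_as <- ifelse(is.na(ma), catalog$symbol, ma)
  }
  row_idx <- match(measured_as, calls$symbol)
  call_mat <- as.matrix(calls[, sample_ids, drop = FALSE])
  # unmatched genes: a row of FALSE (in denominator, never expressed)
  gene_calls <- matrix(FALSE, nrow = nrow(catalog), ncol = length(sample_ids),
                       dimnames = list(catalog$symbol, sample_ids))
  found <- !is.na(row_idx)
  gene_calls[found, ] <- call_mat[row_idx[found], , drop = FALSE]

  groups <- list()
  for (cc in matrisome_categories) {
    groups[[cc]] <- list(level = "category", rows = catalog$category == cc)
  }
  for (dd in matrisome_divisions) {
    groups[[dd]] <- list(level = "division", rows = catalog$division == dd)
  }
  groups[["overall"]] <- list(level = "overall", rows = rep(TRUE, nrow(catalog)))

  out <- purrr::map_dfr(names(groups), function(g) {
    rows <- groups[[g]]$rows
    size <- sum(rows)
    n_expr <- if (size == 0) rep(NA_integer_, length(sample_ids)) else
      unname(colSums(gene_calls[rows, , drop = FALSE]))
    pct <- if (size == 0) rep(NA_real_, length(sample_ids)) else
      100 * n_expr / size
    tibble(
      sample_id = sample_ids,
      level = groups[[g]]$level,
      group = g,
      n_expressed = as.integer(n_expr),
      n_genes = size,
      pct = pct
    )
  })
  class(out) <- c("category_profile", class(out))
  attr(out, "cutoff") <- attr(calls, "cutoff")
  out
}

#' @describeIn category_percentages Summarise a profile: mean, SEM
#'   (sample SD / sqrt(n)) and n per group across samples.
#' @param x A `category_profile`.
#' @param ... Unused.
#' @export
tidy.category_profile <- function(x, ...) {
  x |>
    group_by(.data$level, .data$group) |>
    summarise(
      mean_pct = mean(.data$pct),
      sem_pct = sem(.data$pct),
      n_samples = dplyr::n(),
      n_genes = .data$n_genes[1],
      .groups = "drop"
    )
}

#' @describeIn category_percentages One-row overview: overall mean
#'   percentage, SEM, sample count and the cutoff used.
#' @export
glance.category_profile <- function(x, ...) {
  ov <- x[x$level == "overall", ]
  tibble(
    mean_overall_pct = mean(ov$pct),
    sem_overall_pct = sem(ov$pct),
    n_samples = nrow(ov),
    n_genes = ov$n_genes[1],
    cutoff = attr(x, "cutoff") %||% NA_real_
  )
}

#' Compare core vs matrisome-associated expression percentages
#'
#' Unpaired two-tailed Student t-test on the per-sample division
#' percentages (core matrisome vs matrisome-associated).
#'
#' @param profile A `category_profile` from [category_percentages()].
#' @param var_equal Passed to [stats::t.test()]; defaults to `TRUE`
#'   (classic Student test).
#' @returns A one-row tibble: `t`, `df`, `p_value`, `mean_core`,
#'   `mean_associated`, `degenerate`. When both division vectors are
#'   constant and equal the test is undefined; `t = 0`, `p = 1` are
#'   reported with `degenerate = TRUE`.
#' @export
compare_divisions <- function(profile, var_equal = TRUE) {
  stopifnot(inherits(profile, "category_profile"))
  core <- profile$pct[profile$level == "division" &
                        profile$group == "core-matrisome"]
  assoc <- profile$pct[profile$level == "division" &
                         profile$group == "matrisome-associated"]
  if (length(core) < 2 || length(assoc) < 2) {
    abort("Need at least 2 samples per division for the t-test.")
  }
  if (stats::sd(core) == 0 && stats::sd(assoc) == 0) {
    if (mean(core) == mean(assoc)) {
      return(tibble(t = 0, df = length(core) + length(assoc) - 2, p_value = 1,
                    mean_core = mean(core), mean_associated = mean(assoc),
                    degenerate = TRUE))
    }
    # constant but different: infinitely separated under the pooled model
    return(tibble(t = Inf * sign(mean(core) - mean(assoc)),
                  df = length(core) + length(assoc) - 2, p_value = 0,
                  mean_core = mean(core), mean_associated = mean(assoc),
                  degenerate = TRUE))
  }
  tt <- stats::t.test(core, assoc, var.equal = var_equal,
                      alternative = "two.sided")
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_core = mean(core), mean_associated = mean(assoc),
         degenerate = FALSE)
}

#' Rank genes by mean TPM and keep the top n
#'
#' Mean TPM is the arithmetic mean across all samples, zeros included.
#' Ties are broken by ascending symbol order so the ranking is
#' deterministic.
#'
#' @inheritParams derive_cutoff
#' @param gene_set Optional character vector restricting the ranking
#'   (typically the matrisome symbols present in the matrix).
#' @param n Number of top genes to return.
#' @returns A tibble of class `ranked_genes` with columns `rank`, `symbol`,
#'   `mean_tpm`.
#' @export
rank_top <- function(tpm, gene_set = NULL, n) {
  tpm <- validate_tpm(tpm)
  if (!is.null(gene_set)) tpm <- tpm[tpm$symbol %in% gene_set, , drop = FALSE]
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  if (n > nrow(tpm)) {
    abort(sprintf("Requested top %d genes but only %d are available.",
                  n, nrow(tpm)))
  }
  mean_tpm <- rowMeans(as.matrix(tpm[, -1]))
  ord <- order(-mean_tpm, tpm$symbol)
  out <- tibble(
    rank = seq_len(n),
    symbol = tpm$symbol[ord][seq_len(n)],
    mean_tpm = mean_tpm[ord][seq_len(n)]
  )
  class(out) <- c("ranked_genes", class(out))
  out
}

#' Cross-species overlap of expressed matrisome genes
#'
#' Starting from the human expressed set, counts how many genes have at
#' least one mouse ortholog (`n_with_ortholog`) and how many of those have
#' an ortholog that is itself expressed in mouse (`n_shared`). When two
#' ranked lists are supplied, additionally counts how many human top genes
#' have an ortholog among the mouse top genes.
#'
#' @param expressed_human Character vector of expressed human symbols.
#' @param expressed_mouse Character vector of expressed mouse symbols.
#' @param map An [ortholog_map].
#' @param top_human,top_mouse Optional `ranked_genes` tibbles (or plain
#'   symbol vectors) for the top-list overlap.
#' @returns A one-row tibble of class `overlap_report`: `n_human_expressed`,
#'   `n_with_ortholog`, `n_shared`, `shared_ratio`, and (when top lists are
#'   given) `top_n`, `top_overlap`, `top_overlap_pct`.
#' @export
cross_species_overlap <- function(expressed_human, expressed_mouse, map,
                                  top_human = NULL, top_mouse = NULL) {
  stopifnot(inherits(map, "ortholog_map"))
  orth <- map_orthologs(map, expressed_human, "human_to_mouse")
  has_orth <- lengths(orth$orthologs) > 0
  shared <- purrr::map_lgl(orth$orthologs,
                           ~ length(intersect(.x, expressed_mouse)) > 0)
  H <- sum(has_orth)
  S <- sum(shared & has_orth)
  out <- tibble(
    n_human_expressed = length(expressed_human),
    n_with_ortholog = H,
    n_shared = S,
    shared_ratio = if (H > 0) S / H else NA_real_
  )
  if (!is.null(top_human) && !is.null(top_mouse)) {
    th <- if (is.data.frame(top_human)) top_human$symbol else top_human
    tm <- if (is.data.frame(top_mouse)) top_mouse$symbol else top_mouse
    torth <- map_orthologs(map, th, "human_to_mouse")
    tshared <- purrr::map_lgl(torth$orthologs,
                              ~ length(intersect(.x, tm)) > 0)
    out$top_n <- length(th)
    out$top_overlap <- sum(tshared)
    out$top_overlap_pct <- 100 * sum(tshared) / length(th)
  }
  class(out) <- c("overlap_report", class(out))
  out
}
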