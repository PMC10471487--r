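#' Call per-cell expression from in situ hybridization dot counts
#'
#' A probe is positive in a cell when the cell shows at least `min_dots`
#' dots for that probe (each probe thresholded independently); the two
#' booleans yield the label `none`, `probe1-only`, `probe2-only` or
#' `double`.
#'
#' @param counts A tibble with columns `sample_id`, `image_id`, `cell_id`,
#'   `dots_probe1`, `dots_probe2` (non-negative integers; the
#'   sample/image/cell triple must be unique).
#' @param min_dots Minimum dot count for a positive call (default 2).
#' @returns The input tibble with an added factor column `label`.
#' @examples
#' call_cells(tibble::tibble(sample_id = "s1", image_id = "i1",
#'                           cell_id = 1:3,
#'                           dots_probe1 = c(2, 1, 5),
#'                           dots_probe2 = c(0, 1, 2)))
#' @export
call_cells <- function(counts, min_dots = 2) {
  counts <- as_tibble(counts)
  need <- c("sample_id", "image_id", "cell_id", "dots_probe1", "dots_probe2")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    abort(sprintf("Dot-count table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(min_dots) || min_dots < 1 || min_dots != round(min_dots)) {
    abort("`min_dots` must be an integer >= 1.")
  }
  for (col in c("dots_probe1", "dots_probe2")) {
    v <- counts[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      abort(sprintf("`%s` must contain non-negative integers.", col))
    }
  }
  if (anyDuplicated(counts[, c("sample_id", "image_id", "cell_id")])) {
    abort("(sample_id, image_id, cell_id) triples must be unique.")
  }
  p1 <- counts$dots_probe1 >= min_dots
  p2 <- counts$dots_probe2 >= min_dots
  lab <- dplyr::case_when(
    p1 & p2 ~ "double",
    p1 ~ "probe1-only",
    p2 ~ "probe2-only",
    TRUE ~ "none"
  )
  counts$label <- factor(lab, levels = cell_label_levels)
  counts
}

cell_label_levels <- c("none", "probe1-only", "probe2-only", "double")

#' Summarise per-cell co-expression labels
#'
#' Per image: the proportion of cells in each label class. Per sample: the
#' mean of its images' proportions. Cohort: mean and SEM (sample SD /
#' sqrt(n)) across samples — the headline variability is across donors, not
#' across images.
#'
#' @param called Output of [call_cells()] (a tibble with a `label` column).
#' @returns A list of class `cell_summary` with tibbles `per_image`
#'   (`sample_id`, `image_id`, `n_cells`, `label`, `prop`), `per_sample`
#'   (`sample_id`, `label`, `mean_prop`, `n_images`) and `cohort` (`label`,
#'   `mean_prop`, `sem_prop`, `n_samples`).
#' @export
summarize_cell_calls <- function(called) {
  called <- as_tibble(called)
  if (!"label" %in% names(called)) abort("Run `call_cells()` first.")
  per_image <- called |>
    count(.data$sample_id, .data$image_id, .data$label, name = "n_label") |>
    tidyr::complete(tidyr::nesting(sample_id, image_id), label,
                    fill = list(n_label = 0L)) |>
    group_by(.data$sample_id, .data$image_id) |>
    mutate(n_cells = sum(.data$n_label),
           prop = .data$n_label / .data$n_cells) |>
    ungroup() |>
    select("sample_id", "image_id", "n_cells", "label", "prop") |>
    arrange(.data$sample_id, .data$image_id, .data$label)
  per_sample <- per_image |>
    group_by(.data$sample_id, .data$label) |>
    summarise(mean_prop = mean(.data$prop), n_images = dplyr::n(),
              .groups = "drop")
  cohort <- per_sample |>
    group_by(.data$label) |>
    summarise(sem_prop = sem(.data$mean_prop),
              mean_prop = mean(.data$mean_prop),
              n_samples = dplyr::n(), .groups = "drop") |>
    select("label", "mean_prop", "sem_prop", "n_samples")
  out <- list(per_image = per_image, per_sample = per_sample, cohort = cohort)
  class(out) <- "cell_summary"
  out
}

#' @export
print.cell_summary <- function(x, ...) {
  cat("Per-cell co-expression summary over", max(x$cohort$n_samples),
      "sample(s):\n")
  print(x$cohort)
  invisible(x)
}

#' @describeIn summarize_cell_calls Cohort-level tidy summary (one row per
#'   label class).
#' @param x A `cell_summary` object.
#' @param ... Unused.
#' @export
tidy.cell_summary <- function(x, ...) {
  x$cohort
}
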