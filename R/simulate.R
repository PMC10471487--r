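#' Simulate a matrisome catalog with aliases and orthologs
#'
#' Generates a category-structured catalog whose default sizes are the
#' published murine matrisome v2.0 category counts (194 glycoproteins, 44
#' collagens, 36 proteoglycans, 165 ECM-affiliated, 304 ECM regulators, 367
#' secreted factors; 1,110 genes in total). A stated fraction of genes get
#' an alias, and a stated fraction get a cross-species ortholog; the
#' companion catalog for the other species uses the species' casing
#' convention (all-caps for human).
#'
#' @param category_sizes Named integer vector over the six categories.
#' @param species Species of the primary catalog (default `"mouse"`).
#' @param alias_fraction Fraction of genes given one alias (default 0.1).
#' @param ortholog_fraction Fraction of genes with a one-to-one ortholog in
#'   the other species (default 0.9).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @returns A list: `catalog` (a [matrisome_catalog]), `ortholog_map` (an
#'   [ortholog_map]), `alias_table` (tibble `symbol`, `alias`).
#' @export
simulate_catalog <- function(category_sizes = c(
                               "glycoproteins" = 194, "collagens" = 44,
                               "proteoglycans" = 36, "ECM-affiliated" = 165,
                               "ECM-regulators" = 304, "secreted-factors" = 367),
                             species = c("mouse", "human"),
                             alias_fraction = 0.1,
                             ortholog_fraction = 0.9,
                             seed = 1L) {
  species <- match.arg(species)
  stopifnot(all(names(category_sizes) %in% matrisome_categories),
            all(category_sizes >= 0))
  withr::local_seed(seed)
  style <- function(x) if (species == "human") toupper(x) else x
  other_style <- function(x) if (species == "human") {
    paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  } else toupper(x)
  prefix <- c("glycoproteins" = "Glyc", "collagens" = "Colx",
              "proteoglycans" = "Prtg", "ECM-affiliated" = "Ecaf",
              "ECM-regulators" = "Ecrg", "secreted-factors" = "Secf")
  entries <- purrr::map_dfr(names(category_sizes), function(cc) {
    n <- category_sizes[[cc]]
    if (n == 0) return(tibble())
    tibble(
      symbol = style(sprintf("%s%03d", prefix[[cc]], seq_len(n))),
      division = unname(category_division[cc]),
      category = cc
    )
  })
  n <- nrow(entries)
  has_alias <- runif(n) < alias_fraction
  alias_table <- tibble(
    symbol = entries$symbol[has_alias],
    alias = paste0(entries$symbol[has_alias], if (species == "human") "-AS" else "-as")
  )
  entries$aliases <- lapply(seq_len(n), function(i) {
    if (has_alias[i]) alias_table$alias[match(entries$symbol[i], alias_table$symbol)]
    else character()
  })
  catalog <- matrisome_catalog(entries, species = species)
  has_orth <- runif(n) < ortholog_fraction
  own <- entries$symbol[has_orth]
  other <- other_style(own)
  omap <- if (species == "mouse") {
    ortholog_map(tibble(human_symbol = other, mouse_symbol = own))
  } else {
    ortholog_map(tibble(human_symbol = own, mouse_symbol = other))
  }
  list(catalog = catalog, ortholog_map = omap, alias_table = alias_table)
}

#' Simulate a bulk TPM matrix with planted expression structure
#'
#' Genes are planted as `expressed` (log-normal TPM per sample with a small
#' per-cell dropout probability), `singleton` (non-zero in exactly one
#' sample, drawn log-normal around the detection floor — these genes define
#' the data-adaptive cutoff) or `silent` (all zero). Defaults mirror the
#' murine cohort shape: 11 samples (6 male, 5 female), expressed fraction
#' 0.8 per category, singleton values around TPM 0.1.
#'
#' @param catalog A [matrisome_catalog] providing the gene universe.
#' @param n_samples Number of samples (default 11).
#' @param n_male Number of male samples (default 6; the rest are female).
#' @param expressed_fraction Fraction of each category planted as expressed
#'   (default 0.8).
#' @param meanlog,sdlog Log-normal parameters for expressed-gene TPM
#'   (defaults 2 and 1, i.e. median TPM ~7.4).
#' @param dropout Per-gene-per-sample probability that an expressed gene's
#'   TPM is zero in that sample (default 0.01).
#' @param n_singleton Number of singleton genes, drawn from the
#'   non-expressed pool (default 30).
#' @param singleton_meanlog,singleton_sdlog Log-normal parameters of the
#'   singleton values (defaults `log(0.1)` and 0.25, centring the derived
#'   cutoff near TPM 0.1).
#' @param seed Integer seed.
#' @returns A list: `tpm` (tibble, first column `symbol`), `meta` (sample
#'   metadata tibble), `truth` (tibble `symbol`, `status`), and
#'   `expressed_symbols`.
#' @export
simulate_tpm <- function(catalog, n_samples = 11, n_male = 6,
                         expressed_fraction = 0.8,
                         meanlog = 2, sdlog = 1, dropout = 0.01,
                         n_singleton = 30,
                         singleton_meanlog = log(0.1), singleton_sdlog = 0.25,
                         seed = 1L) {
  stopifnot(inherits(catalog, "matrisome_catalog"), n_samples >= 2,
            n_singleton >= 1, expressed_fraction >= 0, expressed_fraction <= 1)
  withr::local_seed(seed)
  genes <- catalog$symbol
  n_genes <- length(genes)
  status <- rep("silent", n_genes)
  for (cc in matrisome_categories) {
    idx <- which(catalog$category == cc)
    if (length(idx) == 0) next
    n_expr <- round(expressed_fraction * length(idx))
    status[sample(idx, n_expr)] <- "expressed"
  }
  pool <- which(status == "silent")
  if (length(pool) < n_singleton) {
    abort("Not enough non-expressed genes to plant singletons.")
  }
  status[sample(pool, n_singleton)] <- "singleton"

  vals <- matrix(0, nrow = n_genes, ncol = n_samples)
  expr_idx <- which(status == "expressed")
  n_expr_cells <- length(expr_idx) * n_samples
  ev <- rlnorm(n_expr_cells, meanlog = meanlog, sdlog = sdlog)
  ev[runif(n_expr_cells) < dropout] <- 0
  vals[expr_idx, ] <- ev
  single_idx <- which(status == "singleton")
  which_sample <- sample.int(n_samples, length(single_idx), replace = TRUE)
  vals[cbind(single_idx, which_sample)] <-
    rlnorm(length(single_idx), singleton_meanlog, singleton_sdlog)

  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  colnames(vals) <- sample_ids
  tpm <- bind_cols(tibble(symbol = genes), as_tibble(vals))
  meta <- tibble(
    sample_id = sample_ids,
    species = attr(catalog, "species"),
    sex = c(rep("male", min(n_male, n_samples)),
            rep("female", max(0, n_samples - n_male))),
    pain_status = "no-pain"
  )
  list(tpm = tpm, meta = meta,
       truth = tibble(symbol = genes, status = status),
       expressed_symbols = genes[status == "expressed"])
}

#' Simulate spatial samples with planted cell populations
#'
#' Emulates H&E-selected Visium barcodes from a cohort of DRG sections: 9
#' samples by default, two serial sections each. Barcodes are planted as
#' fibroblast-like (DCN-high), nociceptor-like (SCN10A-high), double
#' identity (both markers high; these exercise the exclusion rule) or other.
#' A gene of interest is "on" in a barcode with probability `base_rate`,
#' raised by `delta` in its enriched population (collagen-like genes in
#' fibroblast-like barcodes, receptor-like genes in nociceptor-like
#' barcodes); "on" values are gamma-distributed, mimicking
#' scaled-and-normalised expression.
#'
#' @param n_samples Number of samples (default 9, 4 male / 5 female).
#' @param barcodes_per_section Barcodes retained per section (default 250).
#' @param prop_fibroblast,prop_nociceptor,prop_double Population
#'   proportions (defaults 0.3, 0.3, 0.05; the remainder is "other").
#' @param fibro_genes,noci_genes Genes enriched in the fibroblast-like and
#'   nociceptor-like populations (defaults: collagen symbols and receptor
#'   symbols from the collagen signalling axis).
#' @param neutral_genes Genes with no enrichment anywhere (default
#'   `"NTRL1"`), useful for null calibration.
#' @param delta Planted enrichment: added probability of being "on" in the
#'   enriched population (default 0.25; 0 gives the null).
#' @param base_rate Baseline "on" probability everywhere (default 0.2).
#' @param neutral_rate "On" probability of the neutral genes (defaults to
#'   `base_rate`; set low to emulate genes with negligible co-expression).
#' @param marker_rate Probability that a population's own marker is "on" in
#'   its barcodes (default 0.9).
#' @param off_marker_rate Probability that a marker is "on" outside its
#'   population (default 0.05).
#' @param shape,rate Gamma parameters of "on" expression values (defaults
#'   4 and 2).
#' @param marker_shape Gamma shape of a marker in its own population
#'   (default 12; same `rate`), separating true marker signal from stray
#'   background.
#' @param seed Integer seed.
#' @returns A list: `samples` (named list of spatial tibbles with columns
#'   `barcode`, `section`, then genes), `truth` (tibble `sample_id`,
#'   `barcode`, `population`), `meta` (tibble `sample_id`, `sex`).
#' @export
simulate_spatial <- function(n_samples = 9, barcodes_per_section = 250,
                             prop_fibroblast = 0.3, prop_nociceptor = 0.3,
                             prop_double = 0.05,
                             fibro_genes = c("COL1A1", "COL1A2", "COL6A1"),
                             noci_genes = c("CD44", "ITGB1"),
                             neutral_genes = "NTRL1",
                             delta = 0.25, base_rate = 0.2,
                             neutral_rate = base_rate,
                             marker_rate = 0.9, off_marker_rate = 0.05,
                             shape = 4, rate = 2, marker_shape = 12,
                             seed = 1L) {
  stopifnot(prop_fibroblast + prop_nociceptor + prop_double <= 1,
            delta >= 0, delta <= 1, base_rate + delta <= 1)
  withr::local_seed(seed)
  pops <- c("fibroblast", "nociceptor", "double", "other")
  probs <- c(prop_fibroblast, prop_nociceptor, prop_double,
             1 - prop_fibroblast - prop_nociceptor - prop_double)
  genes <- c("SCN10A", "DCN", fibro_genes, noci_genes, neutral_genes)
  sample_ids <- sprintf("D%02d", seq_len(n_samples))
  n_bc <- 2 * barcodes_per_section

  draw_values <- function(on, shp) {
    v <- numeric(length(on))
    v[on] <- rgamma(sum(on), shape = shp, rate = rate)
    v
  }

  truth <- list()
  samples <- lapply(seq_len(n_samples), function(i) {
    population <- sample(pops, n_bc, replace = TRUE, prob = probs)
    barcode <- sprintf("%s-BC%04d", sample_ids[i], seq_len(n_bc))
    section <- rep(c("1", "2"), each = barcodes_per_section)
    cols <- list(barcode = barcode, section = section)
    for (g in genes) {
      if (g == "DCN") {
        own <- population %in% c("fibroblast", "double")
        on <- ifelse(own, runif(n_bc) < marker_rate, runif(n_bc) < off_marker_rate)
        v <- numeric(n_bc)
        v[on & own] <- rgamma(sum(on & own), shape = marker_shape, rate = rate)
        v[on & !own] <- rgamma(sum(on & !own), shape = shape, rate = rate)
      } else if (g == "SCN10A") {
        own <- population %in% c("nociceptor", "double")
        on <- ifelse(own, runif(n_bc) < marker_rate, runif(n_bc) < off_marker_rate)
        v <- numeric(n_bc)
        v[on & own] <- rgamma(sum(on & own), shape = marker_shape, rate = rate)
        v[on & !own] <- rgamma(sum(on & !own), shape = shape, rate = rate)
      } else {
        p_on <- rep(if (g %in% neutral_genes) neutral_rate else base_rate, n_bc)
        if (g %in% fibro_genes) {
          p_on[population %in% c("fibroblast", "double")] <- base_rate + delta
        } else if (g %in% noci_genes) {
          p_on[population %in% c("nociceptor", "double")] <- base_rate + delta
        }
        on <- runif(n_bc) < p_on
        v <- draw_values(on, shape)
      }
      cols[[g]] <- v
    }
    truth[[i]] <<- tibble(sample_id = sample_ids[i], barcode = barcode,
                          population = population)
    as_tibble(cols)
  })
  names(samples) <- sample_ids
  meta <- tibble(
    sample_id = sample_ids,
    sex = rep(c("male", "female"), length.out = n_samples)
  )
  list(samples = samples, truth = bind_rows(truth), meta = meta)
}

#' Simulate per-condition differential-expression gene lists
#'
#' Draws matrisome genes for the four condition lists with planted
#' multi-condition genes, plus optional non-matrisome filler symbols, so the
#' DEG overlay's bookkeeping (per-condition counts, total with
#' multiplicity, multi-condition detection) is exercised end to end.
#' Defaults plant the study shape: list sizes 37/29/4/22 and six
#' multi-condition genes (three shared MP+FP, one FP+MN, two MP+FN).
#'
#' @param catalog A [matrisome_catalog] to draw matrisome genes from.
#' @param n_per_condition Named vector of matrisome genes per condition.
#' @param multi Named list mapping `"cond1+cond2"` to the number of genes
#'   shared by exactly that pair.
#' @param n_nonmatrisome Non-matrisome filler symbols added to every list
#'   (default 10).
#' @param seed Integer seed.
#' @returns A tibble with columns `condition`, `symbol`.
#' @export
simulate_deg_lists <- function(catalog,
                               n_per_condition = c(MP = 37, FP = 29,
                                                   MN = 4, FN = 22),
                               multi = list("MP+FP" = 3, "FP+MN" = 1,
                                            "MP+FN" = 2),
                               n_nonmatrisome = 10,
                               seed = 1L) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  withr::local_seed(seed)
  conditions <- names(n_per_condition)
  shared_need <- setNames(rep(0L, length(conditions)), conditions)
  shared_genes <- list()
  pool <- sample(catalog$symbol)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  assign_multi <- purrr::imap(multi, function(k, pair) {
    conds <- strsplit(pair, "+", fixed = TRUE)[[1]]
    stopifnot(all(conds %in% conditions))
    genes <- take(k)
    for (cn in conds) shared_need[cn] <<- shared_need[cn] + k
    tibble(condition = rep(conds, each = k), symbol = rep(genes, 2))
  })
  own <- purrr::map_dfr(conditions, function(cn) {
    k <- n_per_condition[[cn]] - shared_need[[cn]]
    stopifnot(k >= 0)
    tibble(condition = cn, symbol = take(k))
  })
  deg <- bind_rows(bind_rows(assign_multi), own)
  if (n_nonmatrisome > 0) {
    filler <- purrr::map_dfr(conditions, function(cn) {
      tibble(condition = cn,
             symbol = sprintf("NONMAT_%s_%02d", cn, seq_len(n_nonmatrisome)))
    })
    deg <- bind_rows(deg, filler)
  }
  arrange(deg, match(.data$condition, conditions), .data$symbol)
}

#' Simulate per-cell dot-count tables
#'
#' Cells get a planted label class; dot counts per probe are Poisson with a
#' class-dependent rate (`lambda_pos` where the probe is truly expressed,
#' `lambda_neg` where not). Defaults mirror the study's imaging design: 2
#' donors, 10 images each, and a planted double-positive fraction of 22%.
#'
#' @param n_samples Number of donors (default 2).
#' @param images_per_sample Images per donor (default 10).
#' @param cells_per_image Cells per image (default 30).
#' @param class_probs Named probabilities of the planted classes `none`,
#'   `probe1-only`, `probe2-only`, `double` (default
#'   `c(0.40, 0.23, 0.15, 0.22)`).
#' @param lambda_pos,lambda_neg Poisson dot rates for expressed and
#'   non-expressed probes (defaults 10 and 0.2).
#' @param seed Integer seed.
#' @returns A list: `counts` (tibble `sample_id`, `image_id`, `cell_id`,
#'   `dots_probe1`, `dots_probe2`), `truth` (same keys plus
#'   `true_label`).
#' @export
simulate_dot_counts <- function(n_samples = 2, images_per_sample = 10,
                                cells_per_image = 30,
                                class_probs = c("none" = 0.40,
                                                "probe1-only" = 0.23,
                                                "probe2-only" = 0.15,
                                                "double" = 0.22),
                                lambda_pos = 10, lambda_neg = 0.2,
                                seed = 1L) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8,
            all(names(class_probs) == cell_label_levels))
  withr::local_seed(seed)
  grid <- tidyr::expand_grid(
    sample_id = sprintf("donor%d", seq_len(n_samples)),
    image_id = sprintf("img%02d", seq_len(images_per_sample)),
    cell_id = seq_len(cells_per_image)
  )
  n <- nrow(grid)
  true_label <- sample(names(class_probs), n, replace = TRUE,
                       prob = class_probs)
  p1_pos <- true_label %in% c("probe1-only", "double")
  p2_pos <- true_label %in% c("probe2-only", "double")
  counts <- grid |>
    mutate(
      dots_probe1 = rpois(n, ifelse(p1_pos, lambda_pos, lambda_neg)),
      dots_probe2 = rpois(n, ifelse(p2_pos, lambda_pos, lambda_neg))
    )
  truth <- bind_cols(grid, tibble(true_label = true_label))
  list(counts = counts, truth = truth)
}

#' Analytic per-cell label accuracy under the Poisson dot model
#'
#' With per-probe thresholding at `min_dots`, a truly expressed probe is
#' called positive with probability `P(Pois(lambda_pos) >= min_dots)` and a
#' truly silent probe with `P(Pois(lambda_neg) >= min_dots)`; a cell is
#' labelled correctly iff both probes are called correctly. Returns the
#' class-prob-weighted expected accuracy, the closed-form benchmark for the
#' Monte-Carlo recovery checks.
#'
#' @inheritParams simulate_dot_counts
#' @param min_dots Dot threshold (default 2).
#' @returns A single number in \[0, 1\].
#' @export
dot_label_accuracy <- function(lambda_pos = 10, lambda_neg = 0.2,
                               min_dots = 2,
                               class_probs = c("none" = 0.40,
                                               "probe1-only" = 0.23,
                                               "probe2-only" = 0.15,
                                               "double" = 0.22)) {
  p_pos <- stats::ppois(min_dots - 1, lambda_pos, lower.tail = FALSE)
  p_neg <- stats::ppois(min_dots - 1, lambda_neg, lower.tail = FALSE)
  correct <- c(
    "none" = (1 - p_neg)^2,
    "probe1-only" = p_pos * (1 - p_neg),
    "probe2-only" = p_pos * (1 - p_neg),
    "double" = p_pos^2
  )
  sum(class_probs * correct[names(class_probs)])
}
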