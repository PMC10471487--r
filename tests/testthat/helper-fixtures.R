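# Fixture builders and independent oracles shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# one gene per category, optional aliases
tiny_catalog <- function(species = "mouse", aliases = NULL) {
  cats <- c("glycoproteins", "collagens", "proteoglycans",
            "ECM-affiliated", "ECM-regulators", "secreted-factors")
  df <- data.frame(
    symbol = paste0("G", seq_along(cats)),
    category = cats,
    division = c(rep("core-matrisome", 3), rep("matrisome-associated", 3)),
    stringsAsFactors = FALSE
  )
  if (!is.null(aliases)) df$aliases <- aliases
  matrisome_catalog(df, species = species)
}

tiny_tpm <- function(values, symbols = NULL) {
  # values: gene x sample matrix (list of rows or matrix)
  m <- if (is.matrix(values)) values else do.call(rbind, values)
  symbols <- symbols %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(symbol = symbols),
                   tibble::as_tibble(m))
}

# spatial sample from explicit per-gene value vectors
tiny_spatial <- function(..., section = NULL) {
  genes <- list(...)
  n <- length(genes[[1]])
  section <- section %||% rep(c("1", "2"), length.out = n)
  out <- tibble::tibble(
    barcode = sprintf("BC%03d", seq_len(n)),
    section = as.character(section)
  )
  for (g in names(genes)) out[[g]] <- genes[[g]]
  out
}

# Type-7 quartile by hand: sort, h = 0.25*(n-1)+1, interpolate neighbours.
oracle_q25_positive <- function(values) {
  pos <- sort(values[values > 0])
  n <- length(pos)
  stopifnot(n > 0)
  h <- 0.25 * (n - 1) + 1
  lo <- floor(h); hi <- ceiling(h)
  pos[lo] + (h - lo) * (pos[hi] - pos[lo])
}

# Full 2^m sign-assignment enumeration of the signed-rank test.
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  W_all <- as.vector(signs %*% r)
  p <- mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
  list(W = W_obs, p = p)
}

# set-arithmetic oracle for the co-expression ratio
oracle_ratio <- function(pos_gene, pos_marker, pos_a, pos_b) {
  D <- intersect(pos_a, pos_b)
  denom <- setdiff(pos_marker, D)
  if (length(denom) == 0) return(NA_real_)
  length(setdiff(intersect(pos_gene, pos_marker), D)) / length(denom)
}
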