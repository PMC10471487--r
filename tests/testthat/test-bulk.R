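test_that("cutoff is the mean of singleton-detected gene values", {
  tpm <- tiny_tpm(list(c(0, 0, 5), c(0, 3, 0), c(1, 1, 1)),
                  symbols = c("A", "B", "C"))
  expect_equal(derive_cutoff(tpm), 4.0)
  # restriction excludes gene A -> only B's singleton value remains
  expect_equal(derive_cutoff(tpm, restrict_to = c("B", "C")), 3.0)
  # no singleton gene -> explicit error
  alltwo <- tiny_tpm(list(c(1, 2, 0), c(3, 0, 4)))
  expect_error(derive_cutoff(alltwo), "cutoff manually")
  expect_error(derive_cutoff(tiny_tpm(list(c(5)))), "at least 2 samples")
})

test_that("cutoff is scale-equivariant and calls are monotone in the cutoff", {
  withr::local_seed(7)
  for (i in 1:100) {
    n_genes <- sample(5:30, 1)
    n_samp <- sample(3:8, 1)
    m <- matrix(rlnorm(n_genes * n_samp), n_genes)
    m[runif(length(m)) < 0.4] <- 0
    # guarantee one singleton gene
    m[1, ] <- 0; m[1, 1] <- runif(1, 0.5, 2)
    tpm <- tiny_tpm(m)
    cut <- derive_cutoff(tpm)
    cc <- runif(1, 0.1, 10)
    scaled <- tpm
    scaled[, -1] <- scaled[, -1] * cc
    expect_equal(derive_cutoff(scaled), cc * cut, tolerance = 1e-12)

    # monotonicity: higher cutoff never increases expressed counts
    lo <- call_expressed(tpm, cut, "per-sample")
    hi <- call_expressed(tpm, cut * 2, "per-sample")
    expect_true(all(colSums(as.matrix(hi[, -1])) <=
                      colSums(as.matrix(lo[, -1]))))
  }
})

test_that("expression calls use strict inequality in both modes", {
  tpm <- tiny_tpm(list(c(0.15, 0.15, 0.15), c(0.1, 0.1, 0.1), c(0, 0, 3)),
                  symbols = c("A", "B", "C"))
  ps <- call_expressed(tpm, 0.1, "per-sample")
  expect_true(all(as.logical(ps[ps$symbol == "A", -1])))
  expect_false(any(as.logical(ps[ps$symbol == "B", -1]))) # equality: not expressed
  cm <- call_expressed(tpm, 0.9, "cohort-mean")
  expect_true(cm$expressed[cm$symbol == "C"]) # mean 1.0 > 0.9
  expect_equal(cm$mean_tpm[cm$symbol == "C"], 1.0)
  expect_false(call_expressed(tpm, 0.15, "cohort-mean")$expressed[1]) # mean == cutoff
  expect_setequal(expressed_genes(cm), c("C"))
  expect_error(call_expressed(tpm, -1), "positive")
})

test_that("category percentages match hand counts, keep unmatched in denominators", {
  cc <- matrisome_catalog(data.frame(
    symbol = c("g1", "g2", "g3", "g4", "r1", "r2"),
    category = c(rep("glycoproteins", 4), rep("ECM-regulators", 2)),
    division = c(rep("core-matrisome", 4), rep("matrisome-associated", 2))))
  # g4 and r2 absent from the measured matrix
  tpm <- tiny_tpm(list(c(5, 5), c(5, 0), c(5, 5), c(5, 5)),
                  symbols = c("g1", "g2", "g3", "r1"))
  calls <- call_expressed(tpm, 0.1, "per-sample")
  prof <- category_percentages(calls, cc)
  glyc <- prof[prof$group == "glycoproteins", ]
  expect_equal(glyc$pct, c(75, 50)) # 3/4 then 2/4, absent g4 in denominator
  expect_equal(prof$pct[prof$group == "ECM-regulators"], c(50, 50))
  # conservation: sum of category expressed = division expressed = overall
  for (s in c("s1", "s2")) {
    p <- prof[prof$sample_id == s, ]
    expect_equal(sum(p$n_expressed[p$level == "category"], na.rm = TRUE),
                 p$n_expressed[p$level == "overall"])
    expect_equal(sum(p$n_expressed[p$level == "division"], na.rm = TRUE),
                 p$n_expressed[p$level == "overall"])
  }
  # empty categories are undefined, not zero
  expect_true(all(is.na(prof$pct[prof$group == "collagens"])))

  # summary: mean and SEM across samples (closed form for n = 2)
  td <- tidy(prof)
  g <- td[td$group == "glycoproteins", ]
  expect_equal(g$mean_pct, 62.5)
  expect_equal(g$sem_pct, 12.5) # for n = 2, SEM = |x1 - x2| / 2
})

test_that("alias-rescued genes are looked up under their measured symbol", {
  cc <- matrisome_catalog(data.frame(
    symbol = "A", category = "collagens", division = "core-matrisome",
    aliases = "B"))
  tpm <- tiny_tpm(list(c(9, 9)), symbols = "B")
  calls <- call_expressed(tpm, 0.1, "per-sample")
  res <- resolve_symbols(cc, "B")
  prof_no <- category_percentages(calls, cc)
  prof_yes <- category_percentages(calls, cc, res)
  expect_equal(prof_no$pct[prof_no$group == "collagens"], c(0, 0))
  expect_equal(prof_yes$pct[prof_yes$group == "collagens"], c(100, 100))
})

test_that("division comparison reproduces a textbook t-test", {
  mkprof <- function(core, assoc) {
    # minimal category_profile with just the division rows
    out <- tibble::tibble(
      sample_id = rep(paste0("s", seq_along(core)), 2),
      level = "division",
      group = rep(c("core-matrisome", "matrisome-associated"),
                  each = length(core)),
      n_expressed = NA_integer_, n_genes = NA_integer_,
      pct = c(core, assoc))
    class(out) <- c("category_profile", class(out))
    out
  }
  # identical vectors: degenerate, t = 0, p = 1
  d <- compare_divisions(mkprof(c(80, 80, 80), c(80, 80, 80)))
  expect_equal(d$t, 0)
  expect_equal(d$p_value, 1)
  expect_true(d$degenerate)

  # jittered separated fixture vs stats::t.test directly
  core <- c(83, 83, 83) + c(0.01, -0.02, 0.005)
  assoc <- c(59, 59, 59) + c(-0.01, 0.02, 0.015)
  res <- compare_divisions(mkprof(core, assoc))
  ref <- t.test(core, assoc, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_lt(res$p_value, 1e-4)
  expect_false(res$degenerate)

  expect_error(compare_divisions(mkprof(80, 70)), "at least 2 samples")
})

test_that("top-n ranking is deterministic and matches a full sort", {
  tpm <- tiny_tpm(list(c(5, 5), c(2, 2), c(9, 9)),
                  symbols = c("gene1", "gene2", "gene3"))
  top2 <- rank_top(tpm, n = 2)
  expect_equal(top2$symbol, c("gene3", "gene1"))
  expect_equal(top2$rank, 1:2)
  # ties broken by ascending symbol order
  tie <- tiny_tpm(list(c(4, 4), c(4, 4)), symbols = c("zz", "aa"))
  expect_equal(rank_top(tie, n = 2)$symbol, c("aa", "zz"))
  expect_error(rank_top(tpm, n = 4), "3")

  withr::local_seed(99)
  for (i in 1:100) {
    m <- matrix(round(rlnorm(100 * 4), 2), 100)
    tpm <- tiny_tpm(m, symbols = sprintf("g%03d", sample(1:999, 100)))
    got <- rank_top(tpm, n = 50)
    means <- rowMeans(m)
    ord <- order(-means, tpm$symbol) # independent full sort
    expect_equal(got$symbol, tpm$symbol[ord][1:50])
    expect_equal(got$mean_tpm, means[ord][1:50])
    expect_true(all(diff(got$mean_tpm) <= 0))
  }
})

test_that("cross-species overlap counts orthologs of expressed genes", {
  m <- ortholog_map(data.frame(
    human_symbol = c("H1", "H2", "H3", "H3"),
    mouse_symbol = c("m1", "m2", "m3a", "m3b")))
  # every expressed human gene has an expressed mouse ortholog
  full <- cross_species_overlap(c("H1", "H2"), c("m1", "m2"), m)
  expect_equal(full$n_with_ortholog, 2)
  expect_equal(full$n_shared, 2)
  expect_equal(full$shared_ratio, 1)
  # disjoint expressed sets: H computed, S = 0
  disj <- cross_species_overlap(c("H1", "H2", "HX"), c("m3a"), m)
  expect_equal(disj$n_with_ortholog, 2)
  expect_equal(disj$n_shared, 0)
  # one-to-many: any expressed ortholog counts
  multi <- cross_species_overlap("H3", "m3b", m)
  expect_equal(multi$n_shared, 1)
  # S <= H and ratio in [0,1] on random inputs
  withr::local_seed(3)
  for (i in 1:20) {
    hs <- paste0("H", sample(50, 25))
    ms <- paste0("m", sample(50, 25))
    pairs <- ortholog_map(data.frame(human_symbol = paste0("H", sample(50, 30, TRUE)),
                                     mouse_symbol = paste0("m", sample(50, 30, TRUE))))
    r <- cross_species_overlap(hs, ms, pairs)
    expect_lte(r$n_shared, r$n_with_ortholog)
    if (r$n_with_ortholog > 0) {
      expect_gte(r$shared_ratio, 0); expect_lte(r$shared_ratio, 1)
    }
  }
})

test_that("top-list overlap is reported when ranked lists are supplied", {
  m <- ortholog_map(data.frame(human_symbol = c("H1", "H2", "H3"),
                               mouse_symbol = c("m1", "m2", "m3")))
  th <- tibble::tibble(rank = 1:3, symbol = c("H1", "H2", "H3"),
                       mean_tpm = c(3, 2, 1))
  r <- cross_species_overlap(c("H1"), c("m1"), m,
                             top_human = th, top_mouse = c("m1", "m3", "mX"))
  expect_equal(r$top_n, 3)
  expect_equal(r$top_overlap, 2)
  expect_equal(r$top_overlap_pct, 200 / 3)
})
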