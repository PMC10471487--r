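test_that("catalog loads from file and validates the category partition", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(
    symbol = c("A", "B"),
    division = c("core-matrisome", "matrisome-associated"),
    category = c("collagens", "ECM-regulators"),
    aliases = c("A2|A3", "")
  ), f)
  cat2 <- read_matrisome_catalog(f, species = "mouse")
  expect_s3_class(cat2, "matrisome_catalog")
  expect_equal(nrow(cat2), 2)
  expect_equal(cat2$aliases[[1]], c("A2", "A3"))
  expect_equal(attr(cat2, "species"), "mouse")

  # category implies division: collagens cannot be matrisome-associated
  bad <- data.frame(symbol = "X", division = "matrisome-associated",
                    category = "collagens")
  expect_error(matrisome_catalog(bad), "mismatch")
  expect_error(matrisome_catalog(data.frame(symbol = "X", division = "core-matrisome")),
               "missing required")
  expect_error(
    matrisome_catalog(data.frame(
      symbol = c("A", "A"),
      division = rep("core-matrisome", 2),
      category = rep("collagens", 2))),
    "Duplicate.*A")
  # alias colliding with another primary symbol
  expect_error(
    matrisome_catalog(data.frame(
      symbol = c("A", "B"), division = rep("core-matrisome", 2),
      category = rep("collagens", 2), aliases = c("B", ""))),
    "Alias")
})

test_that("upstream header dialects are normalised", {
  df <- data.frame(symbol = "A", division = "Core matrisome",
                   category = "ECM Glycoproteins")
  cc <- matrisome_catalog(df)
  expect_equal(cc$category, "glycoproteins")
  expect_equal(cc$division, "core-matrisome")

  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(`Gene Symbol` = "A", Division = "core-matrisome",
                              Category = "collagens", check.names = FALSE), f)
  cc2 <- read_matrisome_catalog(
    f, header_map = c("Gene Symbol" = "symbol", "Division" = "division",
                      "Category" = "category"))
  expect_equal(cc2$symbol, "A")
})

test_that("category counts are conserved across levels", {
  cat6 <- tiny_catalog()
  counts <- category_counts(cat6)
  expect_equal(sum(counts$n[counts$level == "category"]),
               counts$n[counts$level == "total"])
  expect_equal(sum(counts$n[counts$level == "division"]),
               counts$n[counts$level == "total"])
  expect_equal(counts$n[counts$group == "core-matrisome"], 3L)

  empty <- matrisome_catalog(data.frame(symbol = character(),
                                        division = character(),
                                        category = character()))
  expect_true(all(category_counts(empty)$n == 0))

  # random catalogs: integer conservation holds
  for (seed in 1:5) {
    sim <- simulate_catalog(
      category_sizes = setNames(sample(0:40, 6),
                                c("glycoproteins", "collagens", "proteoglycans",
                                  "ECM-affiliated", "ECM-regulators",
                                  "secreted-factors")),
      seed = seed)
    cnt <- category_counts(sim$catalog)
    expect_equal(sum(cnt$n[cnt$level == "category"]),
                 cnt$n[cnt$level == "total"])
    expect_equal(sum(cnt$n[cnt$level == "division"]),
                 cnt$n[cnt$level == "total"])
  }
})

test_that("symbol resolution: direct match beats alias, first alias wins", {
  cc <- matrisome_catalog(data.frame(
    symbol = c("A", "D"), division = rep("core-matrisome", 2),
    category = rep("collagens", 2), aliases = c("B|C", "")))
  # direct match wins even when the alias is also measured
  r1 <- resolve_symbols(cc, c("A", "B"))
  expect_equal(r1$status[r1$symbol == "A"], "matched")
  expect_equal(r1$matched_as[r1$symbol == "A"], "A")
  # alias rescue, first listed alias present wins
  r2 <- resolve_symbols(cc, c("C", "B", "X"))
  expect_equal(r2$status[r2$symbol == "A"], "alias")
  expect_equal(r2$matched_as[r2$symbol == "A"], "B")
  # no alias, absent from measurements -> unmatched
  expect_equal(r2$status[r2$symbol == "D"], "unmatched")
  expect_true(is.na(r2$matched_as[r2$symbol == "D"]))

  # case sensitivity is the default; case-fold relaxes it
  r3 <- resolve_symbols(cc, c("a"))
  expect_equal(r3$status[r3$symbol == "A"], "unmatched")
  r4 <- resolve_symbols(cc, c("a"), case_fold = TRUE)
  expect_equal(r4$status[r4$symbol == "A"], "matched")
  expect_equal(r4$matched_as[r4$symbol == "A"], "a")

  expect_error(resolve_symbols(cc, character()), "non-empty")
})

test_that("resolution partitions the catalog and is idempotent", {
  withr::local_seed(42)
  for (i in 1:10) {
    sim <- simulate_catalog(
      category_sizes = c("glycoproteins" = 20, "collagens" = 10,
                         "proteoglycans" = 5, "ECM-affiliated" = 10,
                         "ECM-regulators" = 15, "secreted-factors" = 20),
      alias_fraction = 0.3, seed = i)
    measured <- sample(c(sim$catalog$symbol, sim$alias_table$alias,
                         paste0("OTHER", 1:20)),
                       size = 40)
    rep1 <- resolve_symbols(sim$catalog, measured)
    # every catalog symbol classified exactly once
    expect_setequal(rep1$symbol, sim$catalog$symbol)
    expect_false(anyDuplicated(rep1$symbol) > 0)
    expect_true(all(rep1$status %in% c("matched", "alias", "unmatched")))
    # idempotent
    rep2 <- resolve_symbols(sim$catalog, measured)
    expect_identical(rep1, rep2)
  }
})

test_that("catalog round-trips through write/read", {
  sim <- simulate_catalog(
    category_sizes = c("glycoproteins" = 8, "collagens" = 4,
                       "proteoglycans" = 2, "ECM-affiliated" = 5,
                       "ECM-regulators" = 5, "secreted-factors" = 6),
    alias_fraction = 0.5, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrisome_catalog(sim$catalog, f)
  back <- read_matrisome_catalog(f, species = "mouse")
  expect_equal(as.data.frame(back), as.data.frame(sim$catalog))
})

test_that("ortholog mapping preserves many-to-many pairs symmetrically", {
  m <- ortholog_map(data.frame(
    human_symbol = c("COL1A1", "H1", "H1", "H2", "H2"),
    mouse_symbol = c("Col1a1", "m1", "m2", "m1", "m1"))) # dup row dropped
  expect_equal(nrow(m), 4)
  r <- map_orthologs(m, c("COL1A1", "H1", "H9"), "human_to_mouse")
  expect_equal(r$orthologs[[1]], "Col1a1")
  expect_equal(r$orthologs[[2]], c("m1", "m2"))
  expect_equal(r$orthologs[[3]], character())
  # reverse direction is consistent with the same pairs
  rev <- map_orthologs(m, "m1", "mouse_to_human")
  expect_setequal(rev$orthologs[[1]], c("H1", "H2"))
  # empty map: everything maps to the empty set
  empty <- ortholog_map(data.frame(human_symbol = character(),
                                   mouse_symbol = character()))
  re <- map_orthologs(empty, c("A", "B"), "human_to_mouse")
  expect_true(all(lengths(re$orthologs) == 0))
})
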