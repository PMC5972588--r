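demo_cat <- function() {
  tiny_catalogue(tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g2", "g3"),
    source = c("GO-CC", "GO-CC", "GO-CC", "GO-CC", "GO-CC", "GO-MF"),
    term_id = c("GO:1", "GO:2", "GO:2", "GO:3", "GO:4", "GO:9")
  ))
}

test_that("pair features are the canonical per-source cross product", {
  cat <- tiny_catalogue(tibble::tibble(
    gene_id = c("g1", "g2"), source = "GO-CC",
    term_id = c("GO:X", "GO:Y")
  ))
  pairs <- tibble::tibble(gene_a = "g1", gene_b = "g2")
  pf <- pair_features(pairs, cat, "GO-CC")
  expect_equal(nrow(pf), 1)
  expect_equal(pf$term_lo, "GO:X")
  expect_equal(pf$term_hi, "GO:Y")
})

test_that("feature count is |T1| x |T2| minus canonical collisions", {
  pairs <- tibble::tibble(gene_a = "g1", gene_b = "g2")
  pf <- pair_features(pairs, demo_cat(), "GO-CC")
  # brute-force double loop
  t1 <- c("GO:1", "GO:2")
  t2 <- c("GO:2", "GO:3", "GO:4")
  brute <- unique(t(apply(expand.grid(t1, t2, stringsAsFactors = FALSE),
                          1, function(r) sort(r))))
  expect_equal(nrow(pf), nrow(brute))
  expect_lte(nrow(pf), length(t1) * length(t2))
})

test_that("feature count matches a brute-force double loop on random data", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      t1 <- sample(sprintf("GO:%d", 1:12), sample(1:6, 1))
      t2 <- sample(sprintf("GO:%d", 1:12), sample(1:6, 1))
      cat <- tiny_catalogue(tibble::tibble(
        gene_id = c(rep("g1", length(t1)), rep("g2", length(t2))),
        source = "GO-BP", term_id = c(t1, t2)
      ))
      pf <- pair_features(tibble::tibble(gene_a = "g1", gene_b = "g2"),
                          cat, "GO-BP")
      brute <- unique(apply(expand.grid(t1, t2), 1,
                            function(r) paste(sort(r), collapse = "|")))
      expect_setequal(paste(pf$term_lo, pf$term_hi, sep = "|"), brute)
    }
  })
})

test_that("pair features are symmetric and sources never mix", {
  pairs_ab <- tibble::tibble(gene_a = "g1", gene_b = "g2")
  pairs_ba <- tibble::tibble(gene_a = "g2", gene_b = "g1")
  cat <- demo_cat()
  pf1 <- pair_features(pairs_ab, cat, "GO-IP")
  pf2 <- pair_features(pairs_ba, cat, "GO-IP")
  expect_setequal(paste(pf1$source, pf1$term_lo, pf1$term_hi),
                  paste(pf2$source, pf2$term_lo, pf2$term_hi))
  # g1 has no GO-MF annotation, so the GO-MF side yields nothing
  expect_false("GO-MF" %in% pf1$source)
})

test_that("a shared term yields a single self-pair feature", {
  cat <- tiny_catalogue(tibble::tibble(
    gene_id = c("g1", "g2"), source = "IP", term_id = "IPR000001"
  ))
  pf <- pair_features(tibble::tibble(gene_a = "g1", gene_b = "g2"),
                      cat, "IP")
  expect_equal(nrow(pf), 1)
  expect_equal(pf$term_lo, pf$term_hi)
})

test_that("all-parents features contain the term-only features", {
  g <- read_obo(obo_chain())
  raw <- read_gaf(c(gaf_row("g1", "GO:0000003", aspect = "P"),
                    gaf_row("g2", "GO:0000002", aspect = "P")), g)
  closed <- close_catalogue(raw, g)
  pairs <- tibble::tibble(gene_a = "g1", gene_b = "g2")
  pf_raw <- pair_features(pairs, raw, "GO-BP")
  pf_closed <- pair_features(pairs, closed, "GO-BP")
  expect_true(all(paste(pf_raw$term_lo, pf_raw$term_hi) %in%
                    paste(pf_closed$term_lo, pf_closed$term_hi)))
})

test_that("root-root features appear in every covered pair under closure", {
  bundle <- generate_bundle(synthetic_preset("tiny", seed = 3))
  L <- load_bundle(bundle)
  root_bp <- "GO:1000001"
  pf <- pair_features(bundle$pairs, L$catalogue, "GO-BP")
  covered <- unique(pf$pair_id)
  rootfeat <- pf[pf$term_lo == root_bp & pf$term_hi == root_bp, ]
  expect_setequal(rootfeat$pair_id, covered)
})

test_that("the feature matrix is binary, aligned and deterministic", {
  bundle <- generate_bundle(synthetic_preset("tiny", seed = 3))
  L <- load_bundle(bundle)
  fm1 <- build_feature_matrix(bundle$pairs, L$catalogue, "GO-IP")
  fm2 <- build_feature_matrix(bundle$pairs, L$catalogue, "GO-IP")
  expect_identical(fm1$x, fm2$x)
  expect_identical(as.data.frame(fm1$space), as.data.frame(fm2$space))
  expect_true(all(fm1$x@x == 1))
  expect_equal(nrow(fm1$x), nrow(bundle$pairs))
})

test_that("two pairs sharing one feature share exactly one column", {
  cat <- tiny_catalogue(tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    source = "GO-CC",
    term_id = c("GO:1", "GO:1", "GO:1", "GO:2")
  ))
  pairs <- tibble::tibble(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"))
  fm <- build_feature_matrix(pairs, cat, "GO-CC")
  # features: (1,1) for pair one; (1,2) for pair two -> no shared column
  expect_equal(ncol(fm$x), 2)
  cat2 <- tiny_catalogue(tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    source = "GO-CC", term_id = "GO:1"
  ))
  fm2 <- build_feature_matrix(pairs, cat2, "GO-CC")
  expect_equal(ncol(fm2$x), 1)
  expect_equal(sum(fm2$x), 2)
})

test_that("a frozen space drops unseen features and flags all-zero rows", {
  cat <- demo_cat()
  train <- tibble::tibble(gene_a = "g1", gene_b = "g2")
  fm_train <- build_feature_matrix(train, cat, "GO-CC")
  unseen <- tibble::tibble(gene_a = "g1", gene_b = "g3")  # only GO-MF on g3
  fm_test <- build_feature_matrix(unseen, cat, "GO-CC",
                                  space = fm_train$space)
  expect_equal(ncol(fm_test$x), ncol(fm_train$x))
  expect_equal(sum(fm_test$x), 0)
  expect_equal(attr(fm_test, "zero_rows"), "g1|g3")
})

test_that("matrix round-trips through MatrixMarket export", {
  bundle <- generate_bundle(synthetic_preset("tiny", seed = 3))
  L <- load_bundle(bundle)
  fm <- build_feature_matrix(bundle$pairs, L$catalogue, "GO-CC")
  dir <- withr::local_tempdir()
  paths <- write_feature_matrix(fm, dir)
  m <- Matrix::readMM(paths[1])
  expect_equal(dim(m), dim(fm$x))
  expect_equal(Matrix::nnzero(m), Matrix::nnzero(fm$x))
  rows <- readr::read_tsv(paths[2], show_col_types = FALSE)
  expect_equal(nrow(rows), nrow(fm$x))
})
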