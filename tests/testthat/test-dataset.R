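test_that("matrix expansion enumerates within-complex pairs with provenance", {
  cx <- tibble::tibble(complex_id = "c1", gene_id = c("A", "B"))
  expect_equal(matrix_expand(cx)[, c("gene_a", "gene_b")],
               tibble::tibble(gene_a = "A", gene_b = "B"))

  cx3 <- tibble::tibble(complex_id = "c1", gene_id = c("A", "B", "C"))
  expect_equal(nrow(matrix_expand(cx3)), 3)

  overlap <- tibble::tibble(
    complex_id = rep(c("c1", "c2"), each = 3),
    gene_id = c("A", "B", "C", "B", "C", "D")
  )
  px <- matrix_expand(overlap)
  expect_equal(nrow(px), 5)
  expect_equal(px$complexes[px$gene_a == "B" & px$gene_b == "C"], "c1;c2")
})

test_that("matrix expansion count equals sum n(n-1)/2 for disjoint complexes", {
  sizes <- c(2, 3, 5, 8, 13)
  cx <- plant_complexes(sizes, seed = 4)
  expect_equal(nrow(matrix_expand(cx)), sum(sizes * (sizes - 1) / 2))
  summary <- complex_summary(cx)
  expect_equal(summary$n_complexes, length(sizes))
  expect_equal(summary$max_size, 13)
  expect_equal(summary$n_multi_complex_genes, 0)
})

test_that("a one-member complex is skipped with a warning", {
  cx <- tibble::tibble(complex_id = c("c1", "c2", "c2"),
                       gene_id = c("A", "B", "C"))
  expect_warning(px <- matrix_expand(cx), "<2 members")
  expect_equal(nrow(px), 1)
})

test_that("spoke expansion emits bait-prey pairs only and is nested in matrix", {
  cx <- tibble::tibble(complex_id = "c1", gene_id = c("A", "B", "C"))
  sp <- spoke_expand(cx, c(c1 = "A"))
  expect_setequal(paste(sp$gene_a, sp$gene_b), c("A B", "A C"))
  expect_equal(nrow(spoke_expand(
    tibble::tibble(complex_id = "c1", gene_id = c("A", "B")),
    c(c1 = "A")
  )), 1)
  expect_error(spoke_expand(cx, c(c1 = "Z")), "not a member")
  # spoke subset of matrix for every complex
  cx2 <- plant_complexes(c(3, 4, 6), seed = 8)
  baits <- cx2 |> dplyr::distinct(complex_id, .keep_all = TRUE)
  mx <- matrix_expand(cx2)
  sp2 <- spoke_expand(cx2, baits)
  expect_true(all(paste(sp2$gene_a, sp2$gene_b) %in%
                    paste(mx$gene_a, mx$gene_b)))
})

test_that("homology transfer is the canonical cross-product of homolog sets", {
  pairs <- tibble::tibble(gene_a = "A", gene_b = "B", label = "positive")
  hmap <- tibble::tibble(source_gene = c("A", "A", "B"),
                         target_gene = c("a1", "a2", "b1"))
  out <- transfer_by_homology(pairs, hmap)
  # brute-force oracle: all combinations of the homolog sets
  oracle <- expand.grid(a = c("a1", "a2"), b = "b1",
                        stringsAsFactors = FALSE)
  oracle_keys <- sort(paste(pmin(oracle$a, oracle$b),
                            pmax(oracle$a, oracle$b)))
  expect_equal(sort(paste(out$gene_a, out$gene_b)), oracle_keys)
  expect_equal(unique(out$source_pair), "A|B")
})

test_that("transfer drops unmapped pairs and self-pair collapses", {
  pairs <- tibble::tibble(gene_a = c("A", "C", "E"),
                          gene_b = c("B", "D", "F"),
                          label = "positive")
  hmap <- tibble::tibble(source_gene = c("A", "B", "C", "D"),
                         target_gene = c("X", "X", "c1", "d1"))
  out <- transfer_by_homology(pairs, hmap)
  # (A,B) -> (X,X) self-pair dropped; (E,F) unmapped; (C,D) survives
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_a, "c1")
  rep <- attr(out, "transfer_report")
  expect_equal(rep$n_unmapped, 1)
  expect_equal(rep$n_self_dropped, 1)
})

test_that("transfer then canonicalization is idempotent and self-pair free", {
  pairs <- tibble::tibble(gene_a = c("B", "A"), gene_b = c("A", "C"),
                          label = "positive") |> canonicalize_pairs()
  hmap <- tibble::tibble(source_gene = c("A", "B", "C"),
                         target_gene = c("z9", "z1", "z5"))
  out <- transfer_by_homology(pairs, hmap)
  expect_true(all(out$gene_a < out$gene_b))
  expect_equal(canonicalize_pairs(out), out, ignore_attr = TRUE)
})

test_that("negative sampling is constrained, seeded and fails when infeasible", {
  forced <- sample_negatives(2, c("A", "B", "C"),
                             exclude = tibble::tibble(gene_a = "A",
                                                      gene_b = "B"),
                             seed = 5)
  expect_setequal(paste(forced$gene_a, forced$gene_b), c("A C", "B C"))
  expect_error(
    sample_negatives(3, c("A", "B", "C"),
                     exclude = tibble::tibble(gene_a = "A", gene_b = "B")),
    "only 2 admissible"
  )
  again <- sample_negatives(2, c("A", "B", "C"),
                            exclude = tibble::tibble(gene_a = "A",
                                                     gene_b = "B"),
                            seed = 5)
  expect_equal(forced, again)
})

test_that("negative sampling is uniform over admissible pairs", {
  universe <- c("A", "B", "C", "D", "E")  # 10 unordered pairs
  counts <- integer(10)
  names(counts) <- apply(utils::combn(universe, 2), 2, paste,
                         collapse = " ")
  n_rep <- 400
  for (s in seq_len(n_rep)) {
    neg <- sample_negatives(3, universe, seed = s)
    k <- paste(neg$gene_a, neg$gene_b)
    counts[k] <- counts[k] + 1L
  }
  # chi-square against uniform inclusion 3/10 per draw
  expected <- rep(n_rep * 3 / 10, 10)
  chi <- sum((counts - expected)^2 / expected)
  expect_lt(chi, qchisq(0.999, df = 9))
})

test_that("gene-family exclusion drops pairs touching the blocklist", {
  pairs <- tibble::tibble(gene_a = c("H1", "A"), gene_b = c("A", "B"),
                          label = "positive")
  out <- exclude_gene_families(pairs, "H1")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_equal(nrow(exclude_gene_families(pairs, character(0))), 2)
  expect_warning(out2 <- exclude_gene_families(pairs, c("H1", "A", "B")),
                 "every pair")
  expect_equal(nrow(out2), 0)
})

test_that("subsampling is seeded, bounded and identity at full size", {
  pairs <- matrix_expand(plant_complexes(c(4, 5), seed = 2))
  expect_equal(subsample_pairs(pairs, nrow(pairs))[, 1:2], pairs[, 1:2])
  expect_equal(nrow(subsample_pairs(pairs, 0)), 0)
  expect_equal(subsample_pairs(pairs, 5, seed = 3),
               subsample_pairs(pairs, 5, seed = 3))
  expect_error(subsample_pairs(pairs, nrow(pairs) + 1), "cannot subsample")
})

test_that("CYC2008-format tables read into complex memberships", {
  tab <- c("ORF\tName\tComplex\tPubMed_id",
           "YAL001C\ta\tcomplex one\t1",
           "YAL002C\tb\tcomplex one\t1",
           "YBR001W\tc\tcomplex two\t2",
           "YBR002W\td\tcomplex two\t2",
           "YBR003W\te\tcomplex two\t2")
  path <- withr::local_tempfile(lines = tab, fileext = ".tab")
  cx <- read_cyc2008(path)
  expect_equal(nrow(cx), 5)
  expect_equal(nrow(matrix_expand(cx)), 1 + 3)
  expect_error(read_cyc2008(path, complex_col = "Missing"), "expected col")
})
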