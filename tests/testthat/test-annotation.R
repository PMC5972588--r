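go_cc_graph <- function() {
  read_obo(c("[Term]", "id: GO:0000001", "name: r",
             "namespace: cellular_component",
             "[Term]", "id: GO:0000002", "name: x",
             "namespace: cellular_component", "is_a: GO:0000001",
             "[Term]", "id: GO:0000003", "name: y",
             "namespace: cellular_component", "is_a: GO:0000002"))
}

test_that("GAF evidence and qualifier filtering follows the exclusion list", {
  g <- go_cc_graph()
  gaf <- c("!gaf-version: 2.1",
           gaf_row("gA", "GO:0000003", evidence = "IEA"),
           gaf_row("gA", "GO:0000003", evidence = "IDA"),
           gaf_row("gB", "GO:0000002", evidence = "NAS"),
           gaf_row("gB", "GO:0000002", evidence = "ND"),
           gaf_row("gB", "GO:0000002", evidence = "NR"),
           gaf_row("gC", "GO:0000002", evidence = "IDA",
                   qualifier = "NOT|contributes_to"),
           gaf_row("gC", "GO:0000003", evidence = "IPI",
                   qualifier = "contributes_to"))
  cat <- read_gaf(gaf, g)
  expect_equal(catalogue_mode(cat), "term_only")
  # gA keeps GO:0000003 only via IDA; gB fully excluded; gC keeps the
  # non-NOT row
  expect_setequal(cat$gene_id, c("gA", "gC"))
  expect_equal(cat$evidence[cat$gene_id == "gA"], "IDA")
  expect_equal(cat$term_id[cat$gene_id == "gC"], "GO:0000003")
})

test_that("duplicate evidence deduplicates to one row per gene/term", {
  g <- go_cc_graph()
  cat <- read_gaf(c(gaf_row("gA", "GO:0000002", "IDA"),
                    gaf_row("gA", "GO:0000002", "IPI")), g)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$evidence, "IDA,IPI")
})

test_that("malformed rows and unknown GO ids are skipped with warnings", {
  g <- go_cc_graph()
  expect_warning(cat <- read_gaf(c(gaf_row("gA", "GO:0000002"),
                                   "too\tshort"), g),
                 "malformed")
  expect_equal(nrow(cat), 1)
  expect_warning(cat2 <- read_gaf(gaf_row("gA", "GO:7777777"), g),
                 "unknown GO id")
  expect_equal(nrow(cat2), 0)
})

test_that("aspect routes GO terms to the right source", {
  obo <- c("[Term]", "id: GO:0000001", "name: b",
           "namespace: biological_process",
           "[Term]", "id: GO:0000002", "name: m",
           "namespace: molecular_function")
  g <- read_obo(obo)
  cat <- read_gaf(c(gaf_row("gA", "GO:0000001", aspect = "P"),
                    gaf_row("gA", "GO:0000002", aspect = "F")), g)
  expect_setequal(cat$source, c("GO-BP", "GO-MF"))
})

test_that("InterPro annotations load, deduplicate and tolerate orphans", {
  cat <- read_interpro_annotations(c("gA\tIPR000001", "gA\tIPR000001",
                                     "gB\tIPR000002"))
  expect_equal(nrow(cat), 2)
  expect_true(all(cat$source == "IP"))
  expect_equal(nrow(read_interpro_annotations(character(0))), 0)
  ip <- read_interpro_hierarchy("IPR000001::f::")
  expect_warning(read_interpro_annotations("gA\tIPR999999", ip),
                 "orphan")
})

test_that("closure fills ancestor terms and flips the mode", {
  g <- go_cc_graph()
  cat <- read_gaf(gaf_row("gA", "GO:0000003"), g)
  closed <- close_catalogue(cat, g)
  expect_equal(catalogue_mode(closed), "all_parents")
  expect_setequal(closed$term_id,
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  # already containing an ancestor does not duplicate it
  cat2 <- read_gaf(c(gaf_row("gA", "GO:0000002"),
                     gaf_row("gA", "GO:0000003")), g)
  closed2 <- close_catalogue(cat2, g)
  expect_equal(nrow(closed2), 3)
  expect_error(close_catalogue(closed, g), "already")
})

test_that("unannotated genes stay absent after closure", {
  g <- go_cc_graph()
  cat <- read_gaf(gaf_row("gA", "GO:0000002"), g)
  closed <- close_catalogue(cat, g)
  expect_false("gZ" %in% closed$gene_id)
})

test_that("a closed catalogue is a fixed point of closure", {
  dag <- random_dag_obo(80, seed = 5)
  g <- read_obo(dag$obo)
  terms <- withr::with_seed(6, sample(dag$ids, 12))
  cat <- read_gaf(vapply(terms, function(t) {
    gaf_row(sample(c("gA", "gB", "gC"), 1), t, aspect = "P")
  }, character(1)), g)
  closed <- close_catalogue(cat, g)
  for (gene in unique(closed$gene_id)) {
    ts <- closed$term_id[closed$gene_id == gene]
    expect_setequal(term_ancestors(g, ts), ts)
  }
})

test_that("evidence filtering commutes with closure", {
  # filter-then-close equals close-then-filter when evidence attaches to
  # the asserted term and ancestors inherit retained status
  g <- go_cc_graph()
  rows <- c(gaf_row("gA", "GO:0000003", "IDA"),
            gaf_row("gA", "GO:0000002", "IEA"),
            gaf_row("gB", "GO:0000003", "IEA"))
  filtered_then_closed <- close_catalogue(read_gaf(rows, g), g)
  # closing the unfiltered assertions, then keeping only ancestors that a
  # retained asserted term contributed
  retained <- read_gaf(rows, g)  # the filter is applied at load time
  manual <- unique(unlist(lapply(seq_len(nrow(retained)), function(i) {
    paste(retained$gene_id[i], term_ancestors(g, retained$term_id[i]))
  })))
  expect_setequal(paste(filtered_then_closed$gene_id,
                        filtered_then_closed$term_id), manual)
  expect_false("gB" %in% filtered_then_closed$gene_id)
})

test_that("annotation coverage counts pairs with a shared annotated source", {
  cat <- tiny_catalogue(tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    source = c("GO-CC", "GO-CC", "GO-MF"),
    term_id = c("GO:0000001", "GO:0000001", "GO:0000009")
  ))
  pairs <- tibble::tibble(gene_a = c("gA", "gA", "gB"),
                          gene_b = c("gB", "gC", "gC"),
                          label = c("positive", "positive", "negative"))
  cov <- annotation_coverage(cat, pairs)
  expect_equal(cov$coverage[cov$label == "positive"], 0.5)
  expect_equal(cov$coverage[cov$label == "negative"], 0)
  # empty pair set: not applicable
  cov0 <- annotation_coverage(cat, pairs[0, ])
  expect_equal(nrow(cov0), 0)
})

test_that("coverage is monotone when switching term_only to all_parents", {
  bundle <- generate_bundle(synthetic_preset("tiny", seed = 2))
  L_raw <- load_bundle(bundle, close_annotations = FALSE)
  L_closed <- load_bundle(bundle, close_annotations = TRUE)
  cov_raw <- annotation_coverage(L_raw$catalogue, bundle$pairs)
  cov_closed <- annotation_coverage(L_closed$catalogue, bundle$pairs)
  expect_true(all(cov_closed$coverage >= cov_raw$coverage))
})
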