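test_that("stratified splits preserve class proportions and are seeded", {
  labels <- rep(c("positive", "negative"), each = 500)
  plan <- make_splits(labels, n_runs = 10, seed = 7)
  for (r in 1:10) {
    te <- plan$test[[r]]
    expect_equal(length(plan$train[[r]]), 900)
    expect_equal(length(te), 100)
    expect_equal(sum(labels[te] == "positive"), 50)
    expect_setequal(c(plan$train[[r]], te), seq_along(labels))
  }
  plan2 <- make_splits(labels, n_runs = 10, seed = 7)
  expect_identical(plan$train, plan2$train)
  expect_error(make_splits(rep(c("positive", "negative"), c(5, 100))),
               "at least 10")
})

test_that("unbalanced stratification stays within one example per class", {
  labels <- rep(c("positive", "negative"), c(333, 667))
  plan <- make_splits(labels, n_runs = 5, train_frac = 0.9, seed = 1)
  for (r in 1:5) {
    tr <- plan$train[[r]]
    expect_equal(sum(labels[tr] == "positive"), round(0.9 * 333))
    expect_equal(sum(labels[tr] == "negative"), round(0.9 * 667))
  }
})

test_that("confusion metrics match direct formula evaluation", {
  # TP=45, FN=5, TN=40, FP=10 at threshold 0.5
  scores <- c(rep(0.9, 45), rep(0.1, 5), rep(0.2, 40), rep(0.8, 10))
  labels <- rep(c("positive", "negative"), c(50, 50))
  m <- compute_metrics(scores, labels)
  expect_equal(m$TP, 45)
  expect_equal(m$precision, 45 / 55)
  expect_equal(m$recall, 0.9)
  expect_equal(m$ACC, 85 / 100)
  mcc_oracle <- (45 * 40 - 10 * 5) /
    sqrt((45 + 10) * (45 + 5) * (40 + 10) * (40 + 5))
  expect_equal(m$MCC, mcc_oracle)
  expect_equal(m$F1, 2 * 45 / (2 * 45 + 10 + 5))
})

test_that("perfect and balanced-confusion cases hit the metric landmarks", {
  perfect <- compute_metrics(c(0.9, 0.8, 0.1, 0.2),
                             c("positive", "positive", "negative",
                               "negative"))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$AUC, 1)
  balanced <- compute_metrics(c(0.9, 0.1, 0.9, 0.1),
                              c("positive", "positive", "negative",
                                "negative"))
  expect_equal(balanced$MCC, 0)
  expect_equal(balanced$ACC, 0.5)
})

test_that("rank AUC equals trapezoidal ROC integration", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- sample(10:80, 1)
      labels <- ifelse(rbinom(n, 1, 0.5) == 1, "positive", "negative")
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties often
      roc <- roc_points(scores, labels)
      trap <- sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) +
                                     utils::tail(roc$TPR, -1)) / 2)
      expect_equal(rank_auc(scores, labels), trap, tolerance = 1e-12)
    }
  })
})

test_that("metrics are invariant to example order and AUC NA on one class", {
  withr::with_seed(11, {
    scores <- runif(60)
    labels <- ifelse(rbinom(60, 1, 0.4) == 1, "positive", "negative")
    perm <- sample(60)
  })
  expect_equal(compute_metrics(scores, labels),
               compute_metrics(scores[perm], labels[perm]))
  expect_true(is.na(rank_auc(runif(5), rep("positive", 5))))
})

test_that("system comparison uses the unpaired rank-sum test", {
  a <- tibble::tibble(run = 1:50, MCC = seq(0.8, 0.9, length.out = 50))
  b <- tibble::tibble(run = 1:50, MCC = seq(0.2, 0.3, length.out = 50))
  res <- compare_systems(a, b, "MCC")
  expect_lt(res$p_value, 1e-6)
  # identical vectors: no detectable difference
  expect_equal(compare_systems(a, a, "MCC")$p_value, 1)
  # unpaired: permuting run order changes nothing
  b_perm <- b[sample(50), ]
  expect_equal(compare_systems(a, b, "MCC")$p_value,
               compare_systems(a, b_perm, "MCC")$p_value)
  expect_error(compare_systems(a, b[1:10, ], "MCC"), "different run counts")
})

test_that("small-sample comparisons match exact rank-sum enumeration", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      a <- runif(6)
      b <- runif(6)
      res <- compare_systems(tibble::tibble(run = seq_along(a), MCC = a),
                             tibble::tibble(run = seq_along(b), MCC = b))
      expect_equal(res$p_value, ranksum_enum_p(a, b), tolerance = 1e-10)
    }
  })
})

test_that("the term audit separates pattern terms from the full vocabulary", {
  obo <- c("[Term]", "id: GO:0000001", "name: root",
           "namespace: cellular_component")
  for (i in 2:21) {
    nm <- if (i <= 6) paste("synthetic protein complex", i) else {
      paste("plain term", i)
    }
    obo <- c(obo, "[Term]", sprintf("id: GO:%07d", i),
             paste0("name: ", nm), "namespace: cellular_component",
             "is_a: GO:0000001")
  }
  g <- read_obo(obo)
  withr::with_seed(31, {
    genes <- sprintf("g%02d", 1:40)
    # pattern terms appear equally in both classes; the enriched plain
    # terms only annotate genes of positive pairs
    pos_pairs <- tibble::tibble(gene_a = genes[1:10],
                                gene_b = genes[11:20],
                                label = "positive")
    neg_pairs <- tibble::tibble(gene_a = genes[21:30],
                                gene_b = genes[31:40],
                                label = "negative")
    rows <- list()
    for (gset in list(1:20, 21:40)) {
      for (i in gset) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = genes[i], source = "GO-CC",
          term_id = sprintf("GO:%07d", sample(2:6, 2))
        )
      }
    }
    for (i in 1:20) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = genes[i], source = "GO-CC",
        term_id = sprintf("GO:%07d", sample(7:21, 4))
      )
    }
    cat <- tiny_catalogue(dplyr::bind_rows(rows))
  })
  audit <- complex_term_audit(cat, dplyr::bind_rows(pos_pairs, neg_pairs),
                              g, name_pattern = "complex")
  expect_gt(audit$p_pattern, 0.05)
  expect_lt(audit$p_all, 0.05)
  expect_equal(audit$n_pattern_terms_in_ontology, 5)
  expect_error(
    complex_term_audit(cat, pos_pairs, g),
    "both a positive and a negative"
  )
  expect_warning(
    complex_term_audit(cat, dplyr::bind_rows(pos_pairs, neg_pairs), g,
                       name_pattern = "no such name"),
    "matches no term"
  )
})

test_that("the protocol runner scores every system on every run", {
  bundle <- generate_bundle(synthetic_preset("tiny", seed = 5))
  L <- load_bundle(bundle)
  splits <- make_splits(bundle$pairs$label, n_runs = 3, seed = 2)
  rep <- evaluate_protocol(bundle$pairs, L$catalogue,
                           systems = c("maxent:GO-CC", "svm:GO-CC"),
                           splits = splits,
                           config = maxent_config(max_iter = 40))
  expect_equal(nrow(rep), 6)
  expect_setequal(rep$system, c("maxent:GO-CC", "svm:GO-CC"))
  expect_true(all(rep$AUC >= 0 & rep$AUC <= 1))
  expect_true(all(rep$MCC >= -1 & rep$MCC <= 1))
  g <- glance(rep)
  expect_setequal(unique(g$n_runs), 3)
  # score ordering invariant to input pair order
  perm <- withr::with_seed(9, sample(nrow(bundle$pairs)))
  rep_perm <- evaluate_protocol(
    bundle$pairs[perm, ], L$catalogue, systems = "maxent:GO-CC",
    splits = splits, config = maxent_config(max_iter = 40)
  )
  expect_equal(sort(unlist(rep_perm$scores[1])), sort(unlist(
    evaluate_protocol(bundle$pairs[perm, ], L$catalogue,
                      systems = "maxent:GO-CC", splits = splits,
                      config = maxent_config(max_iter = 40))$scores[1]
  )))
})
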