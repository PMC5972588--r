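# shared in-code fixtures and independent oracles

obo_chain <- function() {
  c("[Term]", "id: GO:0000001", "name: r",
    "namespace: biological_process",
    "[Term]", "id: GO:0000002", "name: x",
    "namespace: biological_process", "is_a: GO:0000001 ! r",
    "[Term]", "id: GO:0000003", "name: y",
    "namespace: biological_process", "is_a: GO:0000002 ! x")
}

obo_diamond <- function() {
  c("[Term]", "id: GO:0000001", "name: r",
    "namespace: biological_process",
    "[Term]", "id: GO:0000002", "name: x1",
    "namespace: biological_process", "is_a: GO:0000001",
    "[Term]", "id: GO:0000003", "name: x2",
    "namespace: biological_process", "is_a: GO:0000001",
    "[Term]", "id: GO:0000004", "name: y",
    "namespace: biological_process",
    "is_a: GO:0000002", "is_a: GO:0000003")
}

# random DAG: term i may attach to several earlier terms
random_dag_obo <- function(n, seed, max_parents = 3) {
  withr::with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n))
    stanzas <- c("[Term]", paste0("id: ", ids[1]), "name: t1",
                 "namespace: biological_process")
    edges <- list()
    for (i in 2:n) {
      k <- sample(min(i - 1, max_parents), 1)
      parents <- sample(i - 1, k)
      edges[[i]] <- cbind(ids[i], ids[parents])
      stanzas <- c(stanzas, "[Term]", paste0("id: ", ids[i]),
                   paste0("name: t", i), "namespace: biological_process",
                   paste0("is_a: ", ids[parents]))
    }
    list(obo = stanzas, edges = do.call(rbind, edges), ids = ids)
  })
}

# brute-force reachability: depth-first enumeration over the raw edge list
dfs_ancestors <- function(edges, id, include_self = TRUE) {
  out <- character(0)
  stack <- id
  while (length(stack) > 0) {
    cur <- stack[1]
    stack <- stack[-1]
    parents <- edges[edges[, 1] == cur, 2]
    new <- setdiff(parents, out)
    out <- c(out, new)
    stack <- c(stack, new)
  }
  if (include_self) unique(c(id, out)) else setdiff(unique(out), id)
}

gaf_row <- function(gene, go, evidence = "IDA", qualifier = "",
                    aspect = "C") {
  paste("SYN", gene, gene, qualifier, go, "REF:1", evidence, "", aspect,
        gene, "protein", "taxon:1", "20180101", "SYN", "", "", "",
        sep = "\t")
}

tiny_catalogue <- function(df) {
  df$evidence <- NA_character_
  structure(tibble::as_tibble(df), mode = "term_only",
            class = c("annotation_catalogue", class(tibble::tibble())))
}

# maximum-likelihood conditional maxent by a generic optimizer (BFGS on the
# exact conditional log-likelihood) -- the independent oracle for GIS
maxent_optim_oracle <- function(x, labels) {
  a <- cbind(as.matrix(x), 1)
  yi <- as.integer(factor(labels, levels = c("negative", "positive")))
  probs <- function(par) {
    s <- a %*% matrix(par, ncol = 2)
    m <- apply(s, 1, max)
    e <- exp(s - m)
    e / rowSums(e)
  }
  nll <- function(par) {
    p <- probs(par)
    -sum(log(pmax(p[cbind(seq_len(nrow(a)), yi)], 1e-300)))
  }
  opt <- stats::optim(rep(0, ncol(a) * 2), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  probs(opt$par)[, 2]
}

# non-separable random fixture: distinct binary rows observed in both
# classes, so the conditional MLE is finite and unique in probability
nonseparable_fixture <- function(seed, n_rows = 6, n_feat = 8,
                                 max_dup = 3) {
  withr::with_seed(seed, {
    proto <- unique(matrix(stats::rbinom(n_rows * n_feat, 1, 0.4),
                           nrow = n_rows))
    x <- NULL
    labels <- character(0)
    for (i in seq_len(nrow(proto))) {
      n_pos <- sample(seq_len(max_dup), 1)
      n_neg <- sample(seq_len(max_dup), 1)
      x <- rbind(x, proto[rep(i, n_pos + n_neg), , drop = FALSE])
      labels <- c(labels, rep("positive", n_pos), rep("negative", n_neg))
    }
    list(x = x, labels = labels)
  })
}

as_fm <- function(x, labels = NULL) {
  list(x = Matrix::Matrix(x, sparse = TRUE),
       labels = if (is.null(labels)) NULL else {
         factor(labels, levels = c("negative", "positive"))
       },
       space = NULL, sources = NULL)
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}

# two-sided exact rank-sum p-value by full enumeration of group
# assignments (tie-free inputs)
ranksum_enum_p <- function(a, b) {
  combined <- c(a, b)
  r <- rank(combined)
  m <- length(a)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  all_w <- apply(utils::combn(length(combined), m), 2, function(ix) {
    sum(r[ix]) - m * (m + 1) / 2
  })
  min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs)))
}
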