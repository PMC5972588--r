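#' Repeated stratified train/test splits
#'
#' The evaluation protocol: `n_runs` (default 50) independent stratified
#' partitions of the labelled pairs into a 90% training and a 10% test
#' partition. Stratification preserves the global class proportions in each
#' partition to within one example per class. Fully reproducible under the
#' master seed (run r uses derived seed `seed + r`).
#'
#' @param labels factor/character labels (`positive` / `negative`).
#' @param n_runs number of repeated splits.
#' @param train_frac training fraction.
#' @param seed master seed.
#' @return Tibble of class `split_plan` (`run`, `train`, `test` list
#'   columns of integer indices).
#' @export
make_splits <- function(labels, n_runs = 50L, train_frac = 0.9, seed = 1L) {
  labels <- factor(labels, levels = c("negative", "positive"))
  cls_n <- table(labels)
  if (any(cls_n < 10)) {
    stop("need at least 10 examples per class to stratify (have ",
         paste(cls_n, collapse = "/"), ")")
  }
  idx_by_class <- split(seq_along(labels), labels)
  plan <- purrr::map_dfr(seq_len(n_runs), function(r) {
    withr::with_seed(seed + r, {
      train <- sort(unlist(lapply(idx_by_class, function(ix) {
        sample(ix, round(train_frac * length(ix)))
      }), use.names = FALSE))
    })
    test <- setdiff(seq_along(labels), train)
    tibble::tibble(run = r, train = list(train), test = list(test))
  })
  attr(plan, "seed") <- seed
  attr(plan, "train_frac") <- train_frac
  attr(plan, "n") <- length(labels)
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the rank-sum statistic with
#' midranks for tied scores (equivalent to trapezoidal integration of the
#' ROC curve).
#' @param scores numeric scores, larger = more positive.
#' @param labels labels.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
rank_auc <- function(scores, labels) {
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a threshold
#'
#' Confusion-matrix metrics (accuracy, Matthews correlation coefficient,
#' F1, recall, precision) at the score threshold, plus threshold-free AUC
#' by the rank statistic. MCC with a zero denominator is reported as 0;
#' precision with no predicted positives as `NA`.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels labels aligned with `scores`.
#' @param threshold classification threshold on the score (default 0.5,
#'   suitable for probability scores).
#' @return One-row tibble: `ACC`, `MCC`, `F1`, `recall`, `precision`,
#'   `AUC`, plus the confusion counts.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- factor(labels, levels = c("negative", "positive"))
  pred_pos <- scores > threshold
  tp <- sum(pred_pos & labels == "positive")
  fp <- sum(pred_pos & labels == "negative")
  fn <- sum(!pred_pos & labels == "positive")
  tn <- sum(!pred_pos & labels == "negative")
  n <- tp + fp + fn + tn
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  tibble::tibble(
    ACC = (tp + tn) / n,
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    F1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    AUC = rank_auc(scores, labels),
    TP = tp, FP = fp, TN = tn, FN = fn
  )
}

#' ROC curve points
#' @param scores,labels as in [compute_metrics()].
#' @return Tibble (`threshold`, `FPR`, `TPR`) sweeping all score cutoffs.
#' @export
roc_points <- function(scores, labels) {
  labels <- factor(labels, levels = c("negative", "positive"))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- labels[ord] == "positive"
  tp <- cumsum(pos); fp <- cumsum(!pos)
  keep <- !duplicated(s, fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    FPR = c(0, fp[keep] / max(sum(!pos), 1)),
    TPR = c(0, tp[keep] / max(sum(pos), 1))
  )
}

#' Compare two systems over the repeated splits
#'
#' Two-sample (unpaired) Wilcoxon rank-sum test on the per-run values of a
#' metric, two-sided. The normal approximation with tie correction is used
#' at the protocol's 50 runs; exact enumeration when both samples are small
#' (<= 12) and tie-free.
#'
#' @param report_a,report_b metric reports from [evaluate_protocol()] (or
#'   any tibble with `run` and the metric column) computed on the same
#'   split plan.
#' @param metric metric column to compare (default `"MCC"`).
#' @return One-row tibble (`metric`, `statistic`, `p_value`).
#' @export
compare_systems <- function(report_a, report_b, metric = "MCC") {
  a <- report_a[[metric]]
  b <- report_b[[metric]]
  if (length(a) != length(b)) {
    stop("reports have different run counts (", length(a), " vs ",
         length(b), ")")
  }
  if (stats::sd(c(a, b)) == 0) {
    # all observations tied: no detectable difference
    return(tibble::tibble(metric = metric,
                          statistic = length(a) * length(b) / 2,
                          p_value = 1))
  }
  exact <- length(a) <= 12 && length(b) <= 12 &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)
  )
  tibble::tibble(metric = metric, statistic = unname(ht$statistic),
                 p_value = ht$p.value)
}

#' Audit term frequencies between classes
#'
#' Sanity check that the classifier is not just reading off an obvious
#' vocabulary: counts each term's occurrences among the genes of positive
#' versus negative pairs, then runs two unpaired Wilcoxon rank-sum tests —
#' one restricted to terms whose name matches `name_pattern` (by default
#' terms naming protein complexes), one over all terms present in the
#' training pairs. A non-significant pattern test alongside a significant
#' all-terms test indicates the classes differ in overall annotation
#' profile but not through giveaway "complex" terms.
#'
#' @param cat an [annotation_catalogue].
#' @param pairs labelled interaction tibble (both classes present).
#' @param graph `ontology_graph` supplying term names.
#' @param name_pattern regular expression matched (case-insensitively)
#'   against term names.
#' @return List of class `term_audit`: `term_counts` tibble (`term_id`,
#'   `name`, `matches_pattern`, `n_positive`, `n_negative`), `p_pattern`,
#'   `p_all`, `n_pattern_terms_in_ontology`, `n_pattern_terms_in_training`.
#' @export
complex_term_audit <- function(cat, pairs, graph, name_pattern = "complex") {
  if (!all(c("positive", "negative") %in% pairs$label)) {
    stop("term audit needs both a positive and a negative pair set")
  }
  genes_long <- pairs |>
    dplyr::select("gene_a", "gene_b", "label") |>
    tidyr::pivot_longer(c("gene_a", "gene_b"), values_to = "gene_id") |>
    dplyr::select("gene_id", "label")
  counts <- genes_long |>
    dplyr::inner_join(tibble::as_tibble(cat), by = "gene_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$term_id, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  if (!"n_positive" %in% names(counts)) counts$n_positive <- 0L
  if (!"n_negative" %in% names(counts)) counts$n_negative <- 0L
  counts$name <- graph$terms$name[match(counts$term_id, graph$terms$term_id)]
  counts$matches_pattern <- !is.na(counts$name) &
    stringr::str_detect(counts$name, stringr::regex(name_pattern,
                                                    ignore_case = TRUE))
  n_pattern_onto <- sum(stringr::str_detect(
    graph$terms$name, stringr::regex(name_pattern, ignore_case = TRUE)
  ))
  pat <- counts[counts$matches_pattern, ]
  if (nrow(pat) == 0) {
    warning("name pattern '", name_pattern, "' matches no term in the ",
            "training pairs")
    p_pattern <- NA_real_
  } else {
    p_pattern <- suppressWarnings(
      stats::wilcox.test(pat$n_positive, pat$n_negative)$p.value
    )
  }
  p_all <- suppressWarnings(
    stats::wilcox.test(counts$n_positive, counts$n_negative)$p.value
  )
  structure(
    list(term_counts = counts[, c("term_id", "name", "matches_pattern",
                                  "n_positive", "n_negative")],
         p_pattern = p_pattern, p_all = p_all,
         n_pattern_terms_in_ontology = n_pattern_onto,
         n_pattern_terms_in_training = nrow(pat)),
    class = "term_audit"
  )
}

#' @export
print.term_audit <- function(x, ...) {
  cat("<term_audit> ", x$n_pattern_terms_in_training, "/",
      x$n_pattern_terms_in_ontology,
      " pattern terms in training pairs; p(pattern)=",
      signif(x$p_pattern, 3), ", p(all terms)=", signif(x$p_all, 3), "\n",
      sep = "")
  invisible(x)
}

#' Run the repeated stratified evaluation protocol
#'
#' Trains and scores each requested system on every split of the plan and
#' collects per-run metrics. Systems are named `"maxent:<sources>"`,
#' `"svm:<sources>"` (where `<sources>` is `GO-BP`, `GO-CC`, `GO-MF`, `IP`,
#' `GO` or `GO-IP`), `"stacked"` or `"mkl"` (which always combine the four
#' base sources). Feature spaces and kernels are rebuilt from the training
#' partition of every run, so test pairs only ever map onto features seen
#' in training.
#'
#' @param pairs labelled interaction tibble.
#' @param cat an [annotation_catalogue] (typically all-parents mode).
#' @param systems character vector of system specifications.
#' @param splits a [make_splits()] plan for `nrow(pairs)` examples.
#' @param config [maxent_config()] for maxent bases.
#' @param cost SVM soft-margin parameter.
#' @param threshold score threshold for confusion metrics (probability
#'   systems; margin systems are thresholded at 0).
#' @param keep_scores retain per-run score vectors (for ROC curves).
#' @return Tibble of class `metric_report`: one row per run x system with
#'   metric columns, plus `scores`/`test_labels` list columns when
#'   `keep_scores`.
#' @export
evaluate_protocol <- function(pairs, cat, systems = c("maxent:GO-IP"),
                              splits = make_splits(pairs$label),
                              config = maxent_config(), cost = 1,
                              threshold = 0.5, keep_scores = TRUE) {
  stopifnot(attr(splits, "n") == nrow(pairs))
  labels <- factor(pairs$label, levels = c("negative", "positive"))
  pf <- pair_features(pairs, cat, "GO-IP")
  pair_ids <- paste(pairs$gene_a, pairs$gene_b, sep = "|")

  # integer-indexed view of the pair features: the per-run matrix builds
  # reduce to index arithmetic instead of repeated string matching
  global_space <- build_feature_space(pf)
  pf_gid <- match(space_key(pf), space_key(global_space))
  pf_row <- match(pf$pair_id, pair_ids)
  src_mask <- lapply(ALL_SOURCES, function(s) pf$source == s)
  names(src_mask) <- ALL_SOURCES

  fm_fast <- function(idx, sources, space = NULL) {
    srcs <- expand_sources(sources)
    mask <- Reduce(`|`, src_mask[srcs]) & (pf_row %in% idx)
    gid <- pf_gid[mask]
    rowv <- pf_row[mask]
    if (is.null(space)) {
      gids <- sort(unique(gid))
      space <- global_space[gids, , drop = FALSE]
      space$feature_id <- seq_along(gids)
      attr(space, "gids") <- gids
      attr(space, "frozen") <- TRUE
      class(space) <- c("pair_feature_space", class(space))
    } else {
      gids <- attr(space, "gids")
    }
    j <- match(gid, gids)
    keep <- !is.na(j)
    x <- Matrix::sparseMatrix(
      i = match(rowv[keep], idx), j = j[keep], x = 1,
      dims = c(length(idx), length(gids)),
      dimnames = list(pair_ids[idx], NULL)
    )
    if (length(x@x) > 0) x@x[] <- 1
    structure(
      list(x = x, space = space, pairs = pairs[idx, , drop = FALSE],
           labels = labels[idx], sources = srcs),
      class = "pair_feature_matrix",
      zero_rows = pair_ids[idx][Matrix::rowSums(x) == 0]
    )
  }

  # per-run cache: systems sharing a source representation (or a trained
  # per-source base model, or a training kernel) reuse it
  run_cache <- NULL
  cached <- function(key, value_fn) {
    if (is.null(run_cache[[key]])) run_cache[[key]] <<- value_fn()
    run_cache[[key]]
  }
  fm_pair_cached <- function(sources, tr, te) {
    cached(paste0("fm:", paste(sources, collapse = "+")), function() {
      fm_tr <- fm_fast(tr, sources)
      list(train = fm_tr, test = fm_fast(te, sources, space = fm_tr$space))
    })
  }
  maxent_cached <- function(src, tr, te) {
    cached(paste0("mx:", src), function() {
      maxent_train(fm_pair_cached(src, tr, te)$train, config)
    })
  }
  kernel_cached <- function(src, tr, te) {
    cached(paste0("k:", src), function() {
      fms <- fm_pair_cached(src, tr, te)
      list(train = tanimoto_kernel(fms$train),
           cross = tanimoto_kernel(fms$test, fms$train))
    })
  }
  score_system <- function(sys, tr, te) {
    if (startsWith(sys, "maxent:")) {
      src <- sub("^maxent:", "", sys)
      model <- maxent_cached(src, tr, te)
      list(scores = predict(model, fm_pair_cached(src, tr, te)$test),
           thr = threshold)
    } else if (startsWith(sys, "svm:")) {
      src <- sub("^svm:", "", sys)
      ks <- kernel_cached(src, tr, te)
      model <- svm_train(ks$train, labels[tr], cost = cost,
                         psd_check = FALSE)
      list(scores = predict(model, ks$cross, type = "prob"),
           thr = threshold)
    } else if (sys == "stacked") {
      per_src <- lapply(ALL_SOURCES, function(s) fm_pair_cached(s, tr, te))
      names(per_src) <- ALL_SOURCES
      bases <- lapply(ALL_SOURCES, function(s) maxent_cached(s, tr, te))
      names(bases) <- ALL_SOURCES
      model <- stacked_train(lapply(per_src, `[[`, "train"), config,
                             cost = cost, base_models = bases)
      list(scores = predict(model, lapply(per_src, `[[`, "test")), thr = 0)
    } else if (sys == "mkl") {
      ks <- lapply(ALL_SOURCES, function(s) kernel_cached(s, tr, te))
      names(ks) <- ALL_SOURCES
      model <- mkl_train(lapply(ks, `[[`, "train"), labels[tr],
                         cost = cost, psd_check = FALSE)
      list(scores = predict(model, lapply(ks, `[[`, "cross")), thr = 0,
           betas = model$betas)
    } else {
      stop("unknown system specification: ", sys)
    }
  }

  out <- purrr::map_dfr(seq_len(nrow(splits)), function(r) {
    tr <- splits$train[[r]]
    te <- splits$test[[r]]
    run_cache <<- new.env(parent = emptyenv())
    purrr::map_dfr(systems, function(sys) {
      res <- score_system(sys, tr, te)
      m <- compute_metrics(res$scores, labels[te], threshold = res$thr)
      m$run <- r
      m$system <- sys
      if (keep_scores) {
        m$scores <- list(res$scores)
        m$test_labels <- list(as.character(labels[te]))
      }
      if (!is.null(res$betas)) m$betas <- list(res$betas)
      m
    })
  })
  out <- dplyr::relocate(out, "run", "system")
  class(out) <- c("metric_report", class(out))
  out
}

#' Aggregate a metric report over runs
#'
#' Mean, standard deviation and median of every metric per system.
#' @param x a `metric_report`.
#' @param ... unused.
#' @return Tibble (`system`, `metric`, `mean`, `sd`, `median`, `n_runs`).
#' @export
glance.metric_report <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("run", "system", "ACC", "MCC", "F1", "recall",
                  "precision", "AUC") |>
    tidyr::pivot_longer(-c("run", "system"), names_to = "metric") |>
    dplyr::group_by(.data$system, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      n_runs = dplyr::n(), .groups = "drop"
    )
}

#' @export
tidy.metric_report <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("run", "system", "ACC", "MCC", "F1", "recall",
                  "precision", "AUC") |>
    tidyr::pivot_longer(-c("run", "system"), names_to = "metric")
}

#' Box plot of per-run metrics by system
#' @param object a `metric_report`.
#' @param metrics which metrics to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object,
                                   metrics = c("ACC", "MCC", "F1", "recall",
                                               "precision", "AUC"), ...) {
  df <- tidy.metric_report(object) |>
    dplyr::filter(.data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$system, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ROC curves pooled over runs
#' @param report a `metric_report` built with `keep_scores = TRUE`.
#' @param systems subset of systems to draw (default all).
#' @return A ggplot object.
#' @export
plot_roc <- function(report, systems = unique(report$system)) {
  if (!"scores" %in% names(report)) {
    stop("report was built with keep_scores = FALSE")
  }
  df <- report |>
    tibble::as_tibble() |>
    dplyr::filter(.data$system %in% systems) |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(
      pts = list(roc_points(unlist(.data$scores), unlist(.data$test_labels))),
      .groups = "drop"
    ) |>
    tidyr::unnest("pts")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$FPR, y = .data$TPR,
                                   colour = .data$system)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate")
}
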