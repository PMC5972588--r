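#' Stacked GIS-MaxEnt ensemble
#'
#' Trains one GIS-MaxEnt base model per annotation source and a linear SVM
#' decision layer on the base models' predicted positive-class
#' probabilities for the training examples. The layer is trained on
#' in-sample base predictions (the straightforward construction; an
#' out-of-fold mode is available via `out_of_fold` for a less optimistic
#' layer).
#'
#' @param fms named list of [pair_feature_matrix][build_feature_matrix]
#'   objects, one per source, with aligned rows and identical labels.
#' @param config a [maxent_config()] for the base models.
#' @param cost soft-margin parameter of the linear decision layer.
#' @param out_of_fold if `TRUE`, layer inputs are 5-fold out-of-fold base
#'   predictions (base models are still refit on all data for prediction).
#' @param seed seed for the out-of-fold split (unused otherwise).
#' @param base_models optional named list of already-trained per-source
#'   `maxent_model`s matching `fms` (skips refitting the bases).
#' @return An object of class `stacked_ensemble`.
#' @export
stacked_train <- function(fms, config = maxent_config(), cost = 1,
                          out_of_fold = FALSE, seed = 1L,
                          base_models = NULL) {
  labels <- fms[[1]]$labels
  stopifnot(!is.null(labels))
  for (fm in fms) stopifnot(identical(as.character(fm$labels),
                                      as.character(labels)))
  prior <- mean(labels == "positive")
  base <- base_models %||% lapply(fms, function(fm) {
    if (is.null(fm$x) || ncol(fm$x) == 0) NULL else maxent_train(fm, config)
  })
  score_col <- function(model, fm) {
    if (is.null(model)) rep(prior, nrow(fm$x)) else predict(model, fm)
  }
  if (out_of_fold) {
    n <- length(labels)
    folds <- withr::with_seed(seed, sample(rep_len(1:5, n)))
    z <- matrix(prior, n, length(fms))
    for (f in 1:5) {
      tr <- folds != f
      for (j in seq_along(fms)) {
        fm <- fms[[j]]
        if (is.null(fm$x) || ncol(fm$x) == 0) next
        sub <- list(x = fm$x[tr, , drop = FALSE], labels = labels[tr],
                    space = fm$space, sources = fm$sources)
        m <- maxent_train(sub, config)
        z[!tr, j] <- predict(m, fm$x[!tr, , drop = FALSE])
      }
    }
  } else {
    z <- vapply(seq_along(fms), function(j) score_col(base[[j]], fms[[j]]),
                numeric(nrow(fms[[1]]$x)))
  }
  colnames(z) <- names(fms)
  layer <- e1071::svm(z, labels, scale = FALSE, kernel = "linear",
                      cost = cost, fitted = FALSE)
  d <- as.numeric(attr(stats::predict(layer, z, decision.values = TRUE),
                       "decision.values"))
  sign_flip <- if (mean(d[labels == "positive"]) <
                   mean(d[labels == "negative"])) -1 else 1
  structure(
    list(base = base, layer = layer, sign_flip = sign_flip,
         sources = names(fms), prior = prior, train_scores = z),
    class = "stacked_ensemble"
  )
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat("<stacked_ensemble> bases: ", paste(x$sources, collapse = ", "),
      "; linear SVM decision layer\n", sep = "")
  invisible(x)
}

#' Score new pairs with a stacked ensemble
#' @param object a `stacked_ensemble`.
#' @param fms named list of feature matrices built on each base model's
#'   frozen space (same source order as at training).
#' @param ... unused.
#' @return Numeric decision scores (larger = more likely positive).
#' @export
predict.stacked_ensemble <- function(object, fms, ...) {
  n <- nrow(fms[[1]]$x)
  z <- matrix(vapply(seq_along(object$base), function(j) {
    m <- object$base[[j]]
    fm <- fms[[j]]
    if (is.null(m)) rep(object$prior, nrow(fm$x)) else predict(m, fm)
  }, numeric(n)), nrow = n)
  colnames(z) <- object$sources
  object$sign_flip * as.numeric(attr(
    stats::predict(object$layer, z, decision.values = TRUE),
    "decision.values"
  ))
}

#' l2-norm multiple kernel learning
#'
#' Learns a nonnegative weighted combination `K'' = sum_i beta_i K'_i` of
#' per-source Tanimoto kernels jointly with a C-SVM, with the l2 norm
#' constraint on beta. Alternating optimization: (1) solve the SVM on the
#' current combined kernel; (2) closed-form lp-norm update of beta from the
#' per-kernel margin contributions `||w_i||^2 = beta_i^2 a' K_i a` (a the
#' signed dual coefficients), normalized to unit l2 norm; iterate until the
#' largest beta change falls below `tol`.
#'
#' @param kernels named list of square, aligned, normalized kernel
#'   matrices (one per source).
#' @param labels factor/character labels.
#' @param cost SVM soft-margin parameter.
#' @param tol convergence tolerance on max |delta beta|.
#' @param max_outer maximum outer iterations.
#' @param damping step damping on the beta update in (0, 1]; 1 is the raw
#'   alternating update. Damping stabilizes the small oscillations induced
#'   by the discrete support-vector set changes of the inner solver.
#' @param patience the alternation plateaus at the inner solver's noise
#'   level well before `tol` on hard problems; when the beta change fails
#'   to improve on its running minimum for this many consecutive
#'   iterations, the weights are declared stalled and the best iterate is
#'   kept.
#' @param psd_check check base kernels for PSD once before optimizing.
#' @return An object of class `mkl_model` with fields `betas` (unit l2
#'   norm), `svm` (final `kernel_model`) and the iteration trace.
#' @export
mkl_train <- function(kernels, labels, cost = 1, tol = 1e-4,
                      max_outer = 50L, damping = 0.5, patience = 3L,
                      psd_check = TRUE) {
  labels <- factor(labels, levels = c("negative", "positive"))
  m <- length(kernels)
  if (psd_check) kernels <- lapply(kernels, check_psd)
  beta <- rep(1 / sqrt(m), m)
  trace <- list()
  best_delta <- Inf
  stalled <- 0L
  for (it in seq_len(max_outer)) {
    kc <- Reduce(`+`, Map(function(b, k) b * unclass(k), beta, kernels))
    svm <- svm_train(structure(kc, class = c("kernel_matrix", "matrix"),
                               normalized = TRUE),
                     labels, cost = cost, psd_check = FALSE,
                     calibrate = FALSE)
    a <- svm$dual  # alpha * y (zero off the support set)
    wnorm2 <- vapply(seq_len(m), function(i) {
      beta[i]^2 * drop(crossprod(a, unclass(kernels[[i]]) %*% a))
    }, numeric(1))
    wnorm2 <- pmax(wnorm2, 0)
    if (sum(wnorm2) == 0) break
    # lp-norm MKL update with p = 2: beta_i ~ ||w_i||^(2/(p+1)), l2-normed
    new_beta <- wnorm2^(1 / 3)
    new_beta <- new_beta / sqrt(sum(new_beta^2))
    new_beta <- (1 - damping) * beta + damping * new_beta
    new_beta <- new_beta / sqrt(sum(new_beta^2))
    delta <- max(abs(new_beta - beta))
    trace[[it]] <- c(iter = it, delta = delta)
    beta <- new_beta
    if (delta < tol) break
    if (delta < best_delta) {
      best_delta <- delta
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= patience) break
    }
  }
  # final SVM at the converged weights
  kc <- Reduce(`+`, Map(function(b, k) b * unclass(k), beta, kernels))
  svm <- svm_train(structure(kc, class = c("kernel_matrix", "matrix"),
                             normalized = TRUE),
                   labels, cost = cost, psd_check = FALSE, calibrate = FALSE)
  structure(
    list(betas = stats::setNames(beta, names(kernels)), svm = svm,
         n_outer = length(trace),
         trace = dplyr::bind_rows(lapply(trace, as.list)),
         sources = names(kernels)),
    class = "mkl_model"
  )
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("<mkl_model> beta = (",
      paste(sprintf("%s %.3f", names(x$betas), x$betas), collapse = ", "),
      "), ", x$n_outer, " outer iterations\n", sep = "")
  invisible(x)
}

#' Score new pairs with an MKL model
#' @param object an `mkl_model`.
#' @param cross_kernels named list of kernels between new examples (rows)
#'   and the training examples (columns), same order as at training.
#' @param ... unused.
#' @return Numeric decision scores.
#' @export
predict.mkl_model <- function(object, cross_kernels, ...) {
  kc <- Reduce(`+`, Map(function(b, k) b * unclass(k),
                        object$betas, cross_kernels))
  predict(object$svm, structure(kc, class = c("kernel_matrix", "matrix")))
}

#' Kernel weights of an MKL model
#' @param x an `mkl_model`.
#' @param ... unused.
#' @return Tibble (`source`, `beta`) plus the l2 norm as attribute.
#' @export
tidy.mkl_model <- function(x, ...) {
  tibble::tibble(source = names(x$betas), beta = as.numeric(x$betas))
}

#' @export
glance.mkl_model <- function(x, ...) {
  tibble::tibble(n_outer = x$n_outer,
                 beta_l2 = sqrt(sum(x$betas^2)),
                 n_sv = length(x$svm$sv_index))
}
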