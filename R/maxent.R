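#' Training configuration for GIS-MaxEnt
#'
#' @param max_iter maximum number of GIS iterations (default 100, the
#'   setting used throughout the package's evaluation protocol).
#' @param tol convergence tolerance on the change in mean conditional
#'   log-likelihood between iterations.
#' @param correction correction-constant mode. `"mean"` (default) uses the
#'   mean number of active features per training example as the GIS
#'   correction constant C; `"max"` is classic GIS, using the maximum count
#'   together with a slack feature that fills each example up to C. The
#'   mean constant takes larger steps; classic GIS's monotone-likelihood
#'   guarantee is not inherited, so training monitors for decreases.
#' @param gaussian_prior optional Gaussian prior variance on the weights
#'   (`Inf` = no smoothing, the default).
#' @return A list of class `maxent_config`.
#' @export
maxent_config <- function(max_iter = 100L, tol = 1e-9,
                          correction = c("mean", "max"),
                          gaussian_prior = Inf) {
  stopifnot(max_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 correction = match.arg(correction),
                 gaussian_prior = gaussian_prior),
            class = "maxent_config")
}

# augment X with intercept (and slack in max mode); returns list(a, C).
# mode mean: C is the mean number of active annotation features per
# example (the intercept is an implementation device, not an annotation);
# an all-empty matrix falls back to C = 1 so the intercept update stays
# bounded. mode max: classic GIS, C bounds the full active count
# (including the intercept) and a slack feature fills each example to C.
maxent_design <- function(x, correction, C = NULL) {
  n <- nrow(x)
  if (correction == "max") {
    counts <- Matrix::rowSums(x) + 1
    if (is.null(C)) C <- max(counts)
    slack <- pmax(C - counts, 0)
    a <- cbind(x, Matrix::Matrix(1, n, 1, sparse = TRUE),
               Matrix::Matrix(slack, n, 1, sparse = TRUE))
  } else {
    if (is.null(C)) {
      C <- mean(Matrix::rowSums(x))
      if (C == 0) C <- 1
    }
    a <- cbind(x, Matrix::Matrix(1, n, 1, sparse = TRUE))
  }
  list(a = methods::as(a, "CsparseMatrix"), C = C)
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Train a maximum-entropy pair classifier by Generalized Iterative Scaling
#'
#' Fits a conditional maximum-entropy model over the classes
#' positive/negative with binary pair features `f_i(x, y)` (feature i active
#' in x, class y), by the GIS fixed-point update
#' `lambda_i <- lambda_i + (1/C) * log(E_emp[f_i] / E_model[f_i])`.
#' The correction constant C is, by default, the mean number of active
#' features per training example rather than the classic maximum; see
#' [maxent_config()]. Features with zero empirical count for a class are
#' skipped (their weight stays 0) rather than epsilon-floored, which keeps
#' fixed points exact on small problems. An always-on intercept feature per
#' class absorbs the class prior, so an example with no active features is
#' scored at the prior.
#'
#' @param fm a [pair_feature_matrix][build_feature_matrix] with labels, or a
#'   list with elements `x` (binary matrix) and `labels`.
#' @param config a [maxent_config()].
#' @return An object of class `maxent_model`.
#' @export
maxent_train <- function(fm, config = maxent_config()) {
  x <- fm$x
  labels <- fm$labels
  if (is.null(labels)) stop("training requires labelled examples")
  labels <- factor(labels, levels = c("negative", "positive"))
  if (any(table(labels) == 0)) stop("need at least one example per class")
  if (is.null(x) || ncol(x) == 0) {
    # no pair features at all: the model is the class prior alone
    x <- Matrix::Matrix(0, length(labels), 0, sparse = TRUE)
  }
  n <- nrow(x)
  if (n == 0) stop("empty feature matrix")
  des <- maxent_design(x, config$correction)
  a <- des$a
  C <- des$C
  y_ind <- cbind(as.numeric(labels == "negative"),
                 as.numeric(labels == "positive"))
  e_emp <- as.matrix(Matrix::crossprod(a, y_ind))  # F' x 2 raw counts
  lambda <- matrix(0, ncol(a), 2)
  upd <- e_emp > 0
  loglik <- rep(NA_real_, config$max_iter)
  decreases <- 0L
  yi <- cbind(seq_len(n), as.integer(labels))
  for (it in seq_len(config$max_iter)) {
    s <- as.matrix(a %*% lambda)
    p <- softmax_rows(s)
    ll <- mean(log(pmax(p[yi], 1e-300)))
    if (is.finite(config$gaussian_prior)) {
      ll <- ll - sum(lambda^2) / (2 * config$gaussian_prior * n)
    }
    loglik[it] <- ll
    if (it > 1) {
      if (ll < loglik[it - 1] - 1e-12) decreases <- decreases + 1L
      if (abs(ll - loglik[it - 1]) < config$tol) {
        loglik <- loglik[seq_len(it)]
        break
      }
    }
    e_mod <- as.matrix(Matrix::crossprod(a, p))
    delta <- matrix(0, ncol(a), 2)
    delta[upd] <- log(e_emp[upd] / pmax(e_mod[upd], 1e-300)) / C
    if (is.finite(config$gaussian_prior)) {
      delta <- delta - lambda / (config$gaussian_prior * C)
    }
    lambda <- lambda + delta
  }
  loglik <- loglik[!is.na(loglik)]
  s <- as.matrix(a %*% lambda)
  p <- softmax_rows(s)
  e_mod <- as.matrix(Matrix::crossprod(a, p))
  structure(
    list(
      lambda = lambda, C = C, correction = config$correction,
      n_features = ncol(x), n_iter = length(loglik), loglik = loglik,
      moment_gap = max(abs(e_emp[upd] - e_mod[upd]) / n, 0),
      ll_decreases = decreases,
      class_prior = as.numeric(table(labels) / n),
      space = fm$space, sources = fm$sources
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model> ", x$n_features, " pair features, C=",
      signif(x$C, 4), " (", x$correction, "), ", x$n_iter,
      " iterations, loglik ", signif(utils::tail(x$loglik, 1), 6), "\n",
      sep = "")
  invisible(x)
}

#' Predict co-complex probabilities with a GIS-MaxEnt model
#'
#' @param object a `maxent_model`.
#' @param newdata a `pair_feature_matrix` built on the model's frozen space
#'   (or a binary matrix with the same columns).
#' @param type `"score"` returns p(positive); `"prob"` a two-column tibble.
#' @param ... unused.
#' @return Numeric scores or a tibble of class probabilities.
#' @export
predict.maxent_model <- function(object, newdata, type = c("score", "prob"),
                                 ...) {
  type <- match.arg(type)
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  if (ncol(x) != object$n_features) {
    stop("newdata has ", ncol(x), " features; model expects ",
         object$n_features, " (was the matrix built on the model's space?)")
  }
  a <- maxent_design(x, object$correction, C = object$C)$a
  p <- softmax_rows(as.matrix(a %*% object$lambda))
  if (type == "score") return(p[, 2])
  tibble::tibble(p_negative = p[, 1], p_positive = p[, 2])
}

#' Ranked pair-feature weights of a trained model
#'
#' The interpretability payoff of the maximum-entropy model: each pair
#' feature's weight difference `lambda_positive - lambda_negative`, ranked.
#' With an ontology graph supplied, term names are resolved.
#'
#' @param x a `maxent_model`.
#' @param graphs optional named list of `ontology_graph`s used to resolve
#'   term names (all graphs are searched).
#' @param ... unused.
#' @return Tibble (`feature_id`, `source`, `term_lo`, `term_hi`,
#'   `lambda_pos`, `lambda_neg`, `weight`), sorted by decreasing weight.
#' @export
tidy.maxent_model <- function(x, graphs = NULL, ...) {
  if (is.null(x$space)) {
    stop("model has no feature space attached")
  }
  out <- tibble::as_tibble(x$space)
  out$lambda_neg <- x$lambda[seq_len(x$n_features), 1]
  out$lambda_pos <- x$lambda[seq_len(x$n_features), 2]
  out$weight <- out$lambda_pos - out$lambda_neg
  if (!is.null(graphs)) {
    nm <- dplyr::bind_rows(lapply(graphs, function(g) {
      g$terms[, c("term_id", "name")]
    }))
    out$name_lo <- nm$name[match(out$term_lo, nm$term_id)]
    out$name_hi <- nm$name[match(out$term_hi, nm$term_id)]
  }
  dplyr::arrange(out, dplyr::desc(.data$weight))
}

#' One-row training summary of a GIS-MaxEnt model
#' @param x a `maxent_model`.
#' @param ... unused.
#' @return Tibble with feature count, correction constant, iterations,
#'   final log-likelihood, moment gap and likelihood-decrease count.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features, C = x$C, correction = x$correction,
    n_iter = x$n_iter, loglik = utils::tail(x$loglik, 1),
    moment_gap = x$moment_gap, ll_decreases = x$ll_decreases
  )
}

#' Persist / restore a GIS-MaxEnt model as JSON
#'
#' The JSON bundle carries the weights, correction constant, configuration
#' and a checksum of the feature space, so reloaded models reproduce
#' predictions bit-exactly.
#' @param model a `maxent_model`.
#' @param path output / input file path.
#' @return `write_maxent` the path invisibly; `read_maxent` the model.
#' @export
write_maxent <- function(model, path) {
  payload <- list(
    # 17 significant digits round-trip IEEE doubles exactly, so reloaded
    # models predict bit-identically
    lambda = sprintf("%.17g", model$lambda),
    C = sprintf("%.17g", model$C), correction = model$correction,
    n_features = model$n_features, n_iter = model$n_iter,
    loglik = model$loglik, moment_gap = model$moment_gap,
    ll_decreases = model$ll_decreases, class_prior = model$class_prior,
    sources = model$sources,
    space = if (is.null(model$space)) NULL else tibble::as_tibble(model$space),
    space_checksum = if (is.null(model$space)) NULL else {
      digest::digest(space_key(model$space))
    }
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- NULL
  if (!is.null(payload$space)) {
    space <- tibble::as_tibble(payload$space)
    attr(space, "frozen") <- TRUE
    class(space) <- c("pair_feature_space", class(space))
    if (!identical(digest::digest(space_key(space)), payload$space_checksum)) {
      stop("feature-space checksum mismatch in ", path)
    }
  }
  structure(
    list(
      lambda = matrix(as.numeric(payload$lambda), ncol = 2),
      C = as.numeric(payload$C),
      correction = payload$correction, n_features = payload$n_features,
      n_iter = payload$n_iter, loglik = payload$loglik,
      moment_gap = payload$moment_gap, ll_decreases = payload$ll_decreases,
      class_prior = payload$class_prior, space = space,
      sources = payload$sources
    ),
    class = "maxent_model"
  )
}
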