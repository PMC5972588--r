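#' Linear kernel between pair-feature matrices
#'
#' Inner products of sparse binary feature rows; for binary vectors the
#' entry is the size of the feature-set intersection. The degenerate case
#' (c = 0, d = 1) of the polynomial kernel.
#'
#' @param x a [pair_feature_matrix][build_feature_matrix] or binary matrix.
#' @param y optional second matrix on the same feature space (e.g. test
#'   pairs); defaults to `x`, giving the square training kernel.
#' @return A dense `kernel_matrix`: rows of `x` by rows of `y`, with
#'   attributes `diag_x` / `diag_y` (the self-kernels needed for Tanimoto
#'   normalization) and `normalized = FALSE`.
#' @export
linear_kernel <- function(x, y = NULL) {
  xs <- if (is.list(x) && !is.null(x$x)) x$x else x
  ys <- if (is.null(y)) xs else if (is.list(y) && !is.null(y$x)) y$x else y
  if (ncol(xs) != ncol(ys)) {
    stop("feature-space mismatch: ", ncol(xs), " vs ", ncol(ys), " columns")
  }
  k <- as.matrix(xs %*% Matrix::t(ys))
  structure(k, class = c("kernel_matrix", "matrix"),
            diag_x = Matrix::rowSums(xs^2),
            diag_y = Matrix::rowSums(ys^2),
            normalized = FALSE)
}

#' Tanimoto normalization of a kernel matrix
#'
#' `K'(x, x') = K(x, x') / (K(x, x) + K(x', x') - K(x, x'))`. For the linear
#' kernel on binary vectors this is exactly the Jaccard similarity of the
#' two feature sets, and the result is itself a valid (PSD) kernel. It
#' normalizes on the kernel matrix directly, so sparse feature matrices
#' never need densifying. Pairs with an empty feature set are defined to
#' have similarity 0 against everything (including themselves) rather than
#' NaN. Normalization is not idempotent; a guard attribute refuses double
#' application.
#'
#' @param k a `kernel_matrix` from [linear_kernel()] (square or
#'   rectangular; rectangular matrices use the stored self-kernels).
#' @return The normalized `kernel_matrix` (unit diagonal for nonempty rows).
#' @export
tanimoto_normalize <- function(k) {
  if (isTRUE(attr(k, "normalized"))) {
    stop("kernel matrix is already Tanimoto-normalized")
  }
  dx <- attr(k, "diag_x")
  dy <- attr(k, "diag_y")
  if (is.null(dx) || is.null(dy)) {
    if (nrow(k) != ncol(k)) {
      stop("rectangular kernel without stored self-kernels")
    }
    dx <- dy <- diag(k)
  }
  denom <- outer(dx, dy, "+") - k
  kn <- ifelse(denom > 0, k / denom, 0)
  structure(kn, class = c("kernel_matrix", "matrix"),
            diag_x = as.numeric(dx > 0), diag_y = as.numeric(dy > 0),
            normalized = TRUE)
}

#' Tanimoto kernel in one step
#' @inheritParams linear_kernel
#' @return Normalized `kernel_matrix`.
#' @export
tanimoto_kernel <- function(x, y = NULL) tanimoto_normalize(linear_kernel(x, y))

check_psd <- function(k, tol = 1e-9) {
  ev <- eigen(unclass(k), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    warning("kernel matrix not PSD (min eigenvalue ", signif(min(ev), 3),
            "); clipping negative eigenvalues")
    es <- eigen(unclass(k), symmetric = TRUE)
    kc <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
    k[] <- (kc + t(kc)) / 2
  }
  k
}

#' Train a kernel SVM on a precomputed kernel
#'
#' Soft-margin C-SVM on a (normalized) kernel matrix. The kernel is
#' eigen-decomposed into an exact finite-dimensional feature map (negative
#' eigenvalues, if any, are reported and clipped), the dual problem is
#' solved by libsvm on those features, and the model keeps the dual
#' coefficients so that new examples are scored directly from their
#' cross-kernel against the training set. Decision scores are oriented so
#' that larger means more likely positive; an optional Platt-style logistic
#' calibration of the decision values provides probability scores.
#'
#' @param k square training `kernel_matrix`.
#' @param labels factor/character labels (`positive` / `negative`).
#' @param cost soft-margin parameter C (default 1).
#' @param psd_check warn when the kernel has eigenvalues below the
#'   tolerance (they are clipped either way; Tanimoto-normalized binary
#'   kernels are PSD so the warning indicates a construction error).
#' @param calibrate fit the logistic calibration layer.
#' @param tol termination tolerance of the dual optimizer.
#' @return An object of class `kernel_model`.
#' @export
svm_train <- function(k, labels, cost = 1, psd_check = TRUE,
                      calibrate = TRUE, tol = 1e-3) {
  labels <- factor(labels, levels = c("negative", "positive"))
  if (dplyr::n_distinct(labels) < 2) stop("need both classes to train an SVM")
  km <- unclass(k)
  es <- eigen(km, symmetric = TRUE)
  if (psd_check && min(es$values) < -1e-9 * max(abs(es$values), 1)) {
    warning("kernel matrix not PSD (min eigenvalue ",
            signif(min(es$values), 3), "); clipping negative eigenvalues")
  }
  z <- t(t(es$vectors) * sqrt(pmax(es$values, 0)))
  fit <- e1071::svm(z, labels, scale = FALSE, kernel = "linear",
                    cost = cost, tolerance = tol, fitted = FALSE)
  dual <- numeric(nrow(km))
  dual[fit$index] <- fit$coefs
  d_train <- as.numeric(km %*% dual) - fit$rho
  sign_flip <- if (mean(d_train[labels == "positive"]) <
                   mean(d_train[labels == "negative"])) -1 else 1
  d_train <- sign_flip * d_train
  calib <- NULL
  if (calibrate) {
    df <- data.frame(y = as.numeric(labels == "positive"), d = d_train)
    calib <- tryCatch(
      stats::coef(suppressWarnings(
        stats::glm(y ~ d, data = df, family = stats::binomial())
      )),
      error = function(e) NULL
    )
  }
  structure(
    list(dual = dual, rho = fit$rho, sv_index = fit$index,
         sign_flip = sign_flip, cost = cost, n_train = nrow(km),
         calibration = calib, train_decision = d_train, labels = labels),
    class = "kernel_model"
  )
}

#' @export
print.kernel_model <- function(x, ...) {
  cat("<kernel_model> C-SVM, cost=", x$cost, ", ", length(x$sv_index),
      "/", x$n_train, " support vectors\n", sep = "")
  invisible(x)
}

#' Decision / probability scores of a kernel SVM
#'
#' @param object a `kernel_model`.
#' @param newk kernel matrix between the new examples (rows) and the full
#'   training set (columns), e.g. `tanimoto_kernel(test_fm, train_fm)`.
#'   Omit to score the training examples.
#' @param type `"decision"` for raw margins, `"prob"` for calibrated
#'   p(positive).
#' @param ... unused.
#' @return Numeric score vector.
#' @export
predict.kernel_model <- function(object, newk = NULL,
                                 type = c("decision", "prob"), ...) {
  type <- match.arg(type)
  d <- if (is.null(newk)) {
    object$train_decision
  } else {
    if (ncol(newk) != object$n_train) {
      stop("newk must have one column per training example")
    }
    object$sign_flip *
      (as.numeric(unclass(newk) %*% object$dual) - object$rho)
  }
  if (type == "decision") return(d)
  if (is.null(object$calibration)) {
    stop("model was trained without calibration")
  }
  stats::plogis(object$calibration[1] + object$calibration[2] * d)
}

#' One-row summary of a kernel SVM
#' @param x a `kernel_model`.
#' @param ... unused.
#' @return Tibble with cost, support-vector count and training error.
#' @export
glance.kernel_model <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, n_sv = length(x$sv_index), n_train = x$n_train,
    train_error = mean((x$train_decision > 0) !=
                         (x$labels == "positive"))
  )
}

#' Write a kernel matrix as MatrixMarket with an id sidecar
#' @param k a `kernel_matrix`.
#' @param dir output directory.
#' @param ids row/column example ids.
#' @return Invisibly, paths written.
#' @export
write_kernel_matrix <- function(k, dir, ids = rownames(k)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(unclass(k), sparse = TRUE),
                  file.path(dir, "kernel.mtx"))
  readr::write_tsv(tibble::tibble(id = ids %||% as.character(seq_len(nrow(k)))),
                   file.path(dir, "ids.tsv"), progress = FALSE)
  invisible(file.path(dir, c("kernel.mtx", "ids.tsv")))
}
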