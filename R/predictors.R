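#' Surrogate cell-type classifiers
#'
#' The attack is purely a data-level manipulation, so any classifier that can
#' be trained on a labelled matrix exercises it. Two desk-scale surrogates are
#' provided in place of GPU-scale foundation models:
#'
#' * `predictor_softmax()` — a linear soft-max (multinomial logistic)
#'   classifier over depth-normalized log1p features: the features are first
#'   projected onto their leading principal components (a fixed linear map
#'   estimated from the training matrix, as in standard single-cell
#'   annotation practice) and a ridge-penalized multinomial model is fit in
#'   that space via \pkg{glmnet}. The composite decision function is linear
#'   in the log1p features.
#' * `predictor_knn()` — a k-nearest-neighbour voter in the same
#'   depth-normalized log1p space.
#'
#' Both satisfy the trainable-predictor contract: `fit(predictor, m)` returns
#' a fitted object whose `predict(fitted, m)` yields one label per cell,
#' restricted to the classes seen at fit time, deterministically given the
#' predictor's seed.
#'
#' @param lambda ridge penalty of the soft-max fit (default 1e-3).
#' @param n_components number of principal components of the soft-max
#'   feature projection (default 50, capped at the feature/sample count).
#' @param k neighbourhood size of the kNN voter (default 15).
#' @param seed RNG seed consumed by any stochastic step (kNN tie-breaking;
#'   the soft-max fit is deterministic but accepts a seed for interface
#'   symmetry).
#' @return an object of class `sc_predictor`.
#' @examples
#' m <- simulate_cells(synthetic_spec(n_cells = 80, n_genes = 60, seed = 3))
#' fitted <- fit(predictor_softmax(), m)
#' head(predict(fitted, m))
#' @name surrogate-predictors
NULL

#' @rdname surrogate-predictors
#' @export
predictor_softmax <- function(lambda = 1e-3, n_components = 50, seed = 1) {
  structure(list(kind = "softmax", lambda = lambda,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "sc_predictor")
}

#' @rdname surrogate-predictors
#' @export
predictor_knn <- function(k = 15, seed = 1) {
  structure(list(kind = "knn", k = as.integer(k), seed = as.integer(seed)),
            class = "sc_predictor")
}

#' @export
print.sc_predictor <- function(x, ...) {
  cat("<sc_predictor> ", x$kind, "\n", sep = "")
  invisible(x)
}

# shared feature map: depth-normalize to 10k and log1p — the standard
# single-cell transform, and the space in which concealment and anomaly
# scores are also computed
.lognorm <- function(values, scale = 1e4) {
  v <- as.matrix(values)
  d <- rowSums(v)
  d[d == 0] <- 1
  log1p(v / d * scale)
}

#' @importFrom generics fit
#' @export
generics::fit

#' Fit a surrogate predictor
#'
#' @param object an `sc_predictor` from [predictor_softmax()] or
#'   [predictor_knn()].
#' @param m a [cell_matrix()] with >= 2 label classes.
#' @param ... ignored.
#' @return a fitted object of class `sc_predictor_fit` supporting
#'   `predict(fitted, m)`.
#' @export
fit.sc_predictor <- function(object, m, ...) {
  validate_cell_matrix(m)
  x <- .lognorm(m$values)
  y <- factor(m$labels)
  fitted <- withr::with_seed(object$seed, {
    if (object$kind == "softmax") {
      rank <- min(object$n_components, ncol(x), nrow(x) - 1)
      pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = rank)
      model <- glmnet::glmnet(pca$x, y, family = "multinomial",
                              lambda = object$lambda, alpha = 0,
                              standardize = FALSE)
      list(model = model, center = pca$center, rotation = pca$rotation)
    } else {
      list(train_x = x, train_y = y, k = object$k)
    }
  })
  structure(list(spec = object, model = fitted, classes = levels(y),
                 gene_ids = m$gene_ids),
            class = "sc_predictor_fit")
}

#' Predict cell-type labels
#'
#' @param object a fitted predictor from [fit.sc_predictor()].
#' @param newdata a [cell_matrix()] over the same gene universe.
#' @param ... ignored.
#' @return character vector of predicted labels, one per cell, each one of
#'   the classes seen at fit time.
#' @export
predict.sc_predictor_fit <- function(object, newdata, ...) {
  if (!identical(newdata$gene_ids, object$gene_ids)) {
    stop("newdata gene universe differs from the one seen at fit time",
         call. = FALSE)
  }
  x <- .lognorm(newdata$values)
  withr::with_seed(object$spec$seed, {
    if (object$spec$kind == "softmax") {
      pcs <- sweep(x, 2, object$model$center) %*% object$model$rotation
      as.character(predict(object$model$model, pcs, type = "class"))
    } else {
      as.character(class::knn(object$model$train_x, x, object$model$train_y,
                              k = object$model$k))
    }
  })
}
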