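# Linear-SVM feature ranking: one-vs-rest hyperplanes, importance =
# sum over classes of squared weights. Binary problems fit a single SVM.
svm_feature_importance <- function(X, y, cost = 1) {
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("feature ranking needs >= 2 classes")
  if (length(classes) == 2L) classes <- classes[1]
  imp <- rep(0, ncol(X))
  for (cl in classes) {
    yy <- factor(ifelse(as.character(y) == cl, cl, "rest"),
      levels = c(cl, "rest")
    )
    fit <- e1071::svm(X, yy,
      kernel = "linear", cost = cost,
      scale = FALSE, shrinking = TRUE
    )
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    imp <- imp + w^2
  }
  imp
}

#' Recursive feature elimination with a linear-SVM ranker
#'
#' Repeatedly fits a linear SVM on the surviving features (one-vs-rest for
#' multi-class labels), ranks features by the squared hyperplane weights,
#' and drops the lowest-ranked until `k` remain. Features are standardized
#' (zero mean, unit variance over the supplied rows) before ranking so that
#' weight magnitudes are comparable across features.
#'
#' By default each round removes 10% of the surviving features until the
#' count is within `2 k`, then one feature at a time — the schedule of
#' exact one-at-a-time elimination made affordable; set `step_frac = 0` to
#' force one-at-a-time throughout.
#'
#' @param X Numeric matrix, rows = patients, columns = features. Training
#'   rows only: selection must never see test data.
#' @param y Class labels aligned with rows (2 or 3 classes).
#' @param k Number of features to keep.
#' @param step_frac Fraction of surviving features removed per round in the
#'   coarse phase (default 0.1).
#' @param cost Linear-SVM regularization parameter C (default 1).
#' @return A `pcg_reduction` of kind `"rfe"` with `selected` — sorted
#'   original column indices of the `k` kept features.
#' @export
rfe_select <- function(X, y, k, step_frac = 0.1, cost = 1) {
  X <- as.matrix(X)
  if (k < 1L || k >= ncol(X)) {
    stop("'k' must satisfy 1 <= k < n_features (= ", ncol(X), ")")
  }
  if (length(unique(as.character(y))) < 2L) {
    stop("labels contain a single class; RFE needs at least two")
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)
  surviving <- seq_len(ncol(X))
  while (length(surviving) > k) {
    imp <- svm_feature_importance(Xs[, surviving, drop = FALSE], y, cost)
    n_cur <- length(surviving)
    n_drop <- if (step_frac > 0 && n_cur > 2L * k) {
      max(1L, as.integer(round(step_frac * n_cur)))
    } else {
      1L
    }
    n_drop <- min(n_drop, n_cur - k)
    drop_idx <- order(imp)[seq_len(n_drop)]
    surviving <- surviving[-drop_idx]
  }
  structure(
    list(kind = "rfe", selected = sort(surviving), k = k,
         n_features = ncol(X)),
    class = "pcg_reduction"
  )
}

#' Principal component analysis of a feature matrix
#'
#' Mean-centers the rows, eigendecomposes the covariance and keeps the top
#' `k` components by explained variance (via [stats::prcomp()]). Components
#' are orthonormal; explained variances are non-increasing.
#'
#' @param X Numeric matrix, rows = patients.
#' @param k Number of components, `k <= min(n_rows, n_features)`.
#' @return A `pcg_reduction` of kind `"pca"` with `components`
#'   (features x k), `center`, and `explained_variance`.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  if (k < 1L || k > min(dim(X))) {
    stop("'k' must satisfy 1 <= k <= min(n_rows, n_features) = ", min(dim(X)))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(
    list(
      kind = "pca",
      components = p$rotation[, seq_len(k), drop = FALSE],
      center = p$center,
      explained_variance = p$sdev[seq_len(k)]^2,
      k = k,
      n_features = ncol(X)
    ),
    class = "pcg_reduction"
  )
}

#' Project rows through a PCA model
#' @param model A `pcg_reduction` of kind `"pca"`.
#' @param X Matrix with the same number of columns as the fit data.
#' @return `nrow(X) x k` score matrix.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pcg_reduction"), model$kind == "pca")
  X <- as.matrix(X)
  sweep(X, 2L, model$center) %*% model$components
}

#' Apply a fitted reduction to new rows
#'
#' RFE models return the selected column subset; PCA models project onto
#' the retained components. Row count (including zero) is preserved.
#'
#' @param model A `pcg_reduction` from [rfe_select()] or [pca_fit()].
#' @param X Matrix whose column count matches the fit data.
#' @return Reduced matrix with `model$k` columns.
#' @export
reduce_apply <- function(model, X) {
  if (!inherits(model, "pcg_reduction")) {
    stop("'model' must come from rfe_select() or pca_fit()")
  }
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop(
      "X has ", ncol(X), " columns but the reduction was fitted on ",
      model$n_features
    )
  }
  switch(model$kind,
    rfe = X[, model$selected, drop = FALSE],
    pca = pca_transform(model, X),
    stop("unknown reduction kind: ", model$kind)
  )
}

#' Serialize a reduction model to JSON
#'
#' @param model A `pcg_reduction`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reduction <- function(model, path) {
  if (!inherits(model, "pcg_reduction")) stop("expected a 'pcg_reduction'")
  obj <- unclass(model)
  if (model$kind == "pca") obj$components <- as.data.frame(obj$components)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reduction
#' @export
read_reduction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "pca") obj$components <- as.matrix(obj$components)
  if (obj$kind == "rfe") obj$selected <- as.integer(obj$selected)
  structure(obj, class = "pcg_reduction")
}
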