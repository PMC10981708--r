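#' Class-rebalancing configuration
#'
#' Parameters for the combined strategy: random down-sampling of the
#' majority class followed by SMOTE up-sampling of each minority class.
#'
#' @param k_neighbors Number of same-class nearest neighbours SMOTE
#'   interpolates between (default 5).
#' @param target_ratio Desired minority:majority count ratio after
#'   balancing, in (0, 1\] (default 1: full balance).
#' @param majority_downsample_frac Fraction of the majority class retained
#'   (default 0.8).
#' @param seed Integer seed; balancing is deterministic given it.
#' @return A `pcg_balance_config` list.
#' @export
balance_config <- function(k_neighbors = 5L, target_ratio = 1.0,
                           majority_downsample_frac = 0.8, seed = 1L) {
  if (k_neighbors < 1L) stop("'k_neighbors' must be >= 1")
  if (target_ratio <= 0 || target_ratio > 1) {
    stop("'target_ratio' must be in (0, 1]")
  }
  if (majority_downsample_frac <= 0 || majority_downsample_frac > 1) {
    stop("'majority_downsample_frac' must be in (0, 1]")
  }
  structure(
    list(
      k_neighbors = as.integer(k_neighbors), target_ratio = target_ratio,
      majority_downsample_frac = majority_downsample_frac,
      seed = as.integer(seed)
    ),
    class = "pcg_balance_config"
  )
}

#' SMOTE with combined majority down-sampling
#'
#' Rebalances a training set: the majority class is randomly down-sampled
#' (without replacement) to `majority_downsample_frac` of its size, then
#' every other class is up-sampled with SMOTE until its count reaches
#' `target_ratio` times the retained majority count. Each synthetic point
#' is `x_i + u * (x_nn - x_i)` with `u ~ U(0, 1)` and `x_nn` one of the
#' `k_neighbors` nearest same-class neighbours of a randomly chosen minority
#' point `x_i`. Must only ever be applied to training rows.
#'
#' @param X Numeric matrix of training rows.
#' @param y Labels aligned with rows.
#' @param config A [balance_config()].
#' @return List with the rebalanced `X`, `y`, and a `summary` data.frame of
#'   per-class counts before/after.
#' @export
smote_balance <- function(X, y, config = balance_config()) {
  if (!inherits(config, "pcg_balance_config")) {
    stop("'config' must come from balance_config()")
  }
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  counts <- table(y)
  if (length(counts) < 2L) stop("balancing needs at least two classes")
  maj_class <- names(counts)[which.max(counts)]
  minority <- setdiff(names(counts), maj_class)
  too_small <- minority[counts[minority] <= config$k_neighbors]
  if (length(too_small) > 0) {
    stop(
      "class(es) ", paste(too_small, collapse = ", "), " have <= ",
      config$k_neighbors, " members; lower 'k_neighbors' in balance_config()",
      " or supply more training patients"
    )
  }
  with_local_seed(config$seed, {
    maj_idx <- which(y == maj_class)
    n_keep <- max(1L, as.integer(round(
      config$majority_downsample_frac * length(maj_idx)
    )))
    keep <- sort(sample(maj_idx, n_keep))
    target <- as.integer(round(config$target_ratio * n_keep))

    X_parts <- list(X[keep, , drop = FALSE])
    y_parts <- list(y[keep])
    for (cl in minority) {
      cl_idx <- which(y == cl)
      Xc <- X[cl_idx, , drop = FALSE]
      X_parts[[length(X_parts) + 1L]] <- Xc
      y_parts[[length(y_parts) + 1L]] <- y[cl_idx]
      n_new <- target - length(cl_idx)
      if (n_new > 0L) {
        D <- as.matrix(stats::dist(Xc))
        diag(D) <- Inf
        k_nn <- min(config$k_neighbors, nrow(Xc) - 1L)
        nn <- apply(D, 1L, function(d) order(d)[seq_len(k_nn)])
        nn <- matrix(nn, nrow = k_nn) # k_nn x n_c
        i <- sample.int(nrow(Xc), n_new, replace = TRUE)
        j <- vapply(i, function(ii) nn[sample.int(k_nn, 1L), ii], 1L)
        u <- stats::runif(n_new)
        synth <- Xc[i, , drop = FALSE] +
          u * (Xc[j, , drop = FALSE] - Xc[i, , drop = FALSE])
        X_parts[[length(X_parts) + 1L]] <- synth
        y_parts[[length(y_parts) + 1L]] <- rep(cl, n_new)
      }
    }
    Xb <- do.call(rbind, X_parts)
    yb <- unlist(y_parts, use.names = FALSE)
  })
  after <- table(yb)
  summary <- data.frame(
    class = names(counts),
    before = as.integer(counts),
    after = as.integer(after[names(counts)])
  )
  list(X = Xb, y = yb, summary = summary)
}
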