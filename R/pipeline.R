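#' Pipeline run configuration
#'
#' Bundles every stage's parameters for an end-to-end run. The defaults are
#' the pipeline's operating point: 12.5 s / 1000 Hz preprocessing, a
#' 20-350 Hz Stockwell band on a decimated voice/time grid, the "small"
#' seeded-random backbone, RFE down to 120 features, SMOTE balancing, and a
#' random-forest classifier with an 80/20 patient-level split.
#'
#' @param task `"murmur"` (3-class) or `"outcome"` (2-class).
#' @param classifier `"rf"`, `"svm_linear"` or `"gb"`.
#' @param reducer `"rfe"`, `"pca"` or `"none"`.
#' @param k_features Reduced dimension (default 120).
#' @param split_frac Fraction of patients used for training (default 0.8).
#' @param seed Master seed for split, backbone, balancing and classifier.
#' @param preprocess A [preprocess_config()].
#' @param band Stockwell band in Hz.
#' @param voice_step,time_step TFM decimation factors (see [stockwell()]).
#'   Defaults 18 and 10 give a ~230 x 1250 map from a 12.5 s, 1000 Hz
#'   record, ample for a 127- or 227-pixel image.
#' @param backbone A [backbone_spec()] (default the `"small"` preset).
#' @param balance A [balance_config()] or `NULL` to disable balancing.
#' @param rfe_step_frac RFE coarse elimination fraction.
#' @return A `pcg_run_config` list.
#' @export
run_config <- function(task = c("murmur", "outcome"),
                       classifier = c("rf", "svm_linear", "gb"),
                       reducer = c("rfe", "pca", "none"),
                       k_features = 120L, split_frac = 0.8, seed = 1L,
                       preprocess = preprocess_config(),
                       band = c(20, 350), voice_step = 18L, time_step = 10L,
                       backbone = backbone_spec("small"),
                       balance = balance_config(seed = seed),
                       rfe_step_frac = 0.1) {
  task <- match.arg(task)
  classifier <- match.arg(classifier)
  reducer <- match.arg(reducer)
  if (split_frac <= 0 || split_frac >= 1) stop("'split_frac' must be in (0,1)")
  if (k_features < 1L) stop("'k_features' must be >= 1")
  structure(
    list(
      task = task, classifier = classifier, reducer = reducer,
      k_features = as.integer(k_features), split_frac = split_frac,
      seed = as.integer(seed), preprocess = preprocess, band = band,
      voice_step = as.integer(voice_step), time_step = as.integer(time_step),
      backbone = backbone, balance = balance, rfe_step_frac = rfe_step_frac
    ),
    class = "pcg_run_config"
  )
}

task_labels <- function(cohort, task) {
  field <- if (task == "murmur") "murmur_label" else "outcome_label"
  setNames(
    vapply(cohort$patients, `[[`, "", field),
    vapply(cohort$patients, `[[`, "", "patient_id")
  )
}

#' Stratified patient-level train/test split
#'
#' Splits patient ids into disjoint train and test sets, stratified by the
#' task label so every class appears on both sides. Deterministic given
#' `seed`. Recordings of one patient never straddle the split.
#'
#' @param labels Named vector: patient id -> class label.
#' @param split_frac Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with `train` and `test` id character vectors.
#' @export
patient_split <- function(labels, split_frac = 0.8, seed = 1L) {
  if (split_frac <= 0 || split_frac >= 1) stop("'split_frac' must be in (0,1)")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop(
      "every class needs >= 2 patients to split; got ",
      paste(names(counts), as.integer(counts), sep = "=", collapse = ", ")
    )
  }
  with_local_seed(seed, {
    train <- character(0)
    for (cl in names(counts)) {
      ids <- names(labels)[labels == cl]
      n_tr <- min(length(ids) - 1L, max(1L, round(split_frac * length(ids))))
      train <- c(train, sample(ids, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = sort(setdiff(names(labels), train)))
}

#' Compute fused deep-feature vectors for a cohort
#'
#' Runs each recording through preprocessing, the Stockwell transform,
#' amplitude-map imaging and the backbone, then fuses per-location vectors
#' into one row per patient ([fuse_patient()]).
#'
#' @param cohort A `pcg_cohort` (from [simulate_cohort()] or
#'   [load_cohort()]).
#' @param config A [run_config()].
#' @param backbone_model Optional pre-initialized `pcg_backbone`; by default
#'   one is created with `backbone_init(config$backbone, config$seed)`.
#' @param verbose Print progress every 25 patients.
#' @return List with `X` (patients x `4 * backbone_dim` matrix, rownames =
#'   patient ids), `murmur` and `outcome` label vectors.
#' @export
compute_patient_features <- function(cohort, config = run_config(),
                                     backbone_model = NULL, verbose = FALSE) {
  if (!inherits(cohort, "pcg_cohort")) stop("expected a 'pcg_cohort'")
  if (is.null(backbone_model)) {
    backbone_model <- backbone_init(config$backbone, seed = config$seed)
  }
  dim <- backbone_dim(backbone_model$spec)
  size <- backbone_model$spec$input_size[1:2]
  n <- length(cohort$patients)
  X <- matrix(0, nrow = n, ncol = 4L * dim)
  ids <- character(n)
  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    per_loc <- list()
    for (loc in names(p$recordings)) {
      s <- preprocess_signal(p$recordings[[loc]], config$preprocess)
      tfm <- stockwell(s,
        band = config$band, voice_step = config$voice_step,
        time_step = config$time_step
      )
      img <- tfm_to_image(st_amplitude(tfm), size = size)
      per_loc[[loc]] <- extract_features(img, backbone_model)
    }
    X[i, ] <- fuse_patient(per_loc, dim = dim)
    ids[i] <- p$patient_id
    if (verbose && i %% 25L == 0L) {
      message("  features: ", i, "/", n, " patients")
    }
  }
  rownames(X) <- ids
  list(
    X = X,
    murmur = task_labels(cohort, "murmur"),
    outcome = task_labels(cohort, "outcome")
  )
}

fit_classifier <- function(X, y, classifier, seed, class_levels) {
  y <- factor(y, levels = class_levels)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (classifier == "rf") {
    fit <- ranger::ranger(
      x = X, y = y, probability = TRUE, num.trees = 500,
      seed = seed, num.threads = 1L
    )
    list(kind = "rf", fit = fit, levels = class_levels)
  } else if (classifier == "svm_linear") {
    fit <- e1071::svm(X, y, kernel = "linear", cost = 1, probability = TRUE,
                      scale = FALSE)
    list(kind = "svm_linear", fit = fit, levels = class_levels)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
    nc <- length(class_levels)
    params <- list(
      objective = if (nc > 2L) "multi:softprob" else "binary:logistic",
      max_depth = 3, eta = 0.3, nthread = 1
    )
    if (nc > 2L) params$num_class <- nc
    fit <- xgboost::xgb.train(params, dtrain, nrounds = 60, verbose = 0)
    list(kind = "gb", fit = fit, levels = class_levels)
  }
}

predict_classifier <- function(model, X) {
  lv <- model$levels
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (model$kind == "rf") {
    prob <- stats::predict(model$fit, data = X, num.threads = 1L)$predictions
    prob <- prob[, lv, drop = FALSE]
  } else if (model$kind == "svm_linear") {
    pr <- stats::predict(model$fit, X, probability = TRUE)
    prob <- attr(pr, "probabilities")[, lv, drop = FALSE]
  } else {
    p <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
    if (length(lv) > 2L) {
      prob <- matrix(p, ncol = length(lv), byrow = TRUE)
      colnames(prob) <- lv
    } else {
      prob <- cbind(p, 1 - p)
      colnames(prob) <- lv
    }
  }
  # deterministic tie-break: first class (lowest index) wins
  pred <- lv[apply(prob, 1L, which.max)]
  list(pred = pred, prob = prob)
}

#' Train the screening model on a feature matrix
#'
#' Standardizes the training rows (statistics frozen into the model),
#' rebalances them with SMOTE, fits the configured reducer on the balanced
#' rows and then the configured classifier on the reduced rows. Test rows
#' must never be passed in here.
#'
#' @param X Training feature matrix (rows = patients).
#' @param y Training labels for the configured task.
#' @param config A [run_config()].
#' @return A `pcg_model` bundling scaler statistics, the reduction, the
#'   classifier and a config snapshot.
#' @export
pcg_train <- function(X, y, config = run_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  class_levels <- if (config$task == "murmur") MURMUR_CLASSES else OUTCOME_CLASSES
  class_levels <- intersect(class_levels, unique(y))
  if (length(class_levels) < 2L) {
    stop("training labels contain fewer than two classes")
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)

  if (!is.null(config$balance)) {
    bal <- smote_balance(Xs, y, config$balance)
    Xb <- bal$X
    yb <- bal$y
  } else {
    Xb <- Xs
    yb <- y
    bal <- NULL
  }

  reduction <- switch(config$reducer,
    rfe = rfe_select(Xb, yb, k = config$k_features,
                     step_frac = config$rfe_step_frac),
    pca = pca_fit(Xb, k = min(config$k_features, nrow(Xb), ncol(Xb))),
    none = NULL
  )
  Xr <- if (is.null(reduction)) Xb else reduce_apply(reduction, Xb)
  clf <- with_local_seed(config$seed,
    fit_classifier(Xr, yb, config$classifier, config$seed, class_levels)
  )
  structure(
    list(
      scaler = list(mean = mu, sd = sdev), reduction = reduction,
      classifier = clf, config = config,
      balance_summary = if (is.null(bal)) NULL else bal$summary
    ),
    class = "pcg_model"
  )
}

#' Predict task labels for new patients
#'
#' @param model A `pcg_model` from [pcg_train()].
#' @param X Feature matrix with the training-time column layout.
#' @return List with `pred` (labels) and `prob` (class-probability matrix).
#' @export
pcg_predict <- function(model, X) {
  if (!inherits(model, "pcg_model")) stop("expected a 'pcg_model'")
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$sd, `/`)
  Xr <- if (is.null(model$reduction)) Xs else reduce_apply(model$reduction, Xs)
  predict_classifier(model$classifier, Xr)
}

#' Score predictions on held-out patients
#'
#' For the murmur task: 3-class confusion matrix, weighted accuracy,
#' accuracy and macro-averaged one-vs-rest SE/SP/F/AUC with the per-class
#' breakdown. For the outcome task: outcome counts and clinical cost,
#' binary weighted accuracy and Abnormal-positive SE/SP/F/AUC.
#'
#' @param model A `pcg_model`.
#' @param X Held-out feature matrix.
#' @param y Held-out true labels.
#' @return A `pcg_report` list; see Details.
#' @export
pcg_evaluate <- function(model, X, y) {
  y <- as.character(y)
  out <- pcg_predict(model, X)
  if (model$config$task == "murmur") {
    cm <- confusion3(y, out$pred)
    pc <- per_class_metrics(y, out$pred, score_matrix = out$prob)
    rep <- list(
      task = "murmur",
      n_patients = length(y),
      confusion = unclass(cm),
      weighted_accuracy = weighted_accuracy(cm),
      accuracy = mean(y == out$pred),
      per_class = pc,
      macro_se = macro_average(pc$se),
      macro_sp = macro_average(pc$sp),
      macro_f = macro_average(pc$f_score)
    )
  } else {
    counts <- outcome_counts(y, out$pred)
    bm <- binary_metrics(y, out$pred, scores = out$prob[, "Abnormal"],
                         positive = "Abnormal")
    rep <- list(
      task = "outcome",
      n_patients = length(y),
      counts = unclass(counts),
      outcome_cost = outcome_cost(counts),
      weighted_accuracy = weighted_accuracy_binary(y, out$pred),
      accuracy = bm$acc, se = bm$se, sp = bm$sp, f_score = bm$f_score,
      auc = bm$auc
    )
  }
  structure(rep, class = "pcg_report")
}

#' @export
print.pcg_report <- function(x, ...) {
  if (x$task == "murmur") {
    cat(sprintf(
      "<pcg_report: murmur> n=%d  WAcc=%.4f  Acc=%.4f  macro SE/SP/F=%.3f/%.3f/%.3f\n",
      x$n_patients, x$weighted_accuracy, x$accuracy,
      x$macro_se, x$macro_sp, x$macro_f
    ))
  } else {
    cat(sprintf(
      "<pcg_report: outcome> n=%d  cost=%.2f  WAcc=%.4f  Acc=%.4f  SE=%.3f SP=%.3f AUC=%.3f\n",
      x$n_patients, x$outcome_cost, x$weighted_accuracy, x$accuracy,
      x$se, x$sp, x$auc
    ))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' The JSON form round-trips: parsing and re-emitting yields identical
#' bytes, and two identically seeded runs yield identical files.
#'
#' @param report A `pcg_report`.
#' @param path Output path (`NULL` returns the JSON string).
#' @return The JSON string, invisibly when written to file.
#' @export
write_report <- function(report, path = NULL) {
  obj <- unclass(report)
  if (!is.null(obj$confusion)) {
    obj$confusion <- as.data.frame(obj$confusion)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Run the full study on a cohort
#'
#' Splits patients (stratified, patient-level), extracts features once,
#' trains on the training side and scores the held-out side. This is the
#' one-call version of the whole pipeline.
#'
#' @param cohort A `pcg_cohort`.
#' @param config A [run_config()].
#' @param features Optional precomputed [compute_patient_features()] output
#'   (reused across configs for the same cohort/backbone).
#' @param verbose Print stage progress.
#' @return List with `report` (held-out `pcg_report`), `model`, `split`,
#'   and `features`.
#' @export
pcg_run <- function(cohort, config = run_config(), features = NULL,
                    verbose = FALSE) {
  labels_all <- task_labels(cohort, config$task)
  split <- patient_split(labels_all, config$split_frac, config$seed)
  if (is.null(features)) {
    if (verbose) message("extracting features for ", length(labels_all), " patients")
    features <- compute_patient_features(cohort, config, verbose = verbose)
  }
  y <- if (config$task == "murmur") features$murmur else features$outcome
  X <- features$X
  model <- pcg_train(X[split$train, , drop = FALSE], y[split$train], config)
  report <- pcg_evaluate(model, X[split$test, , drop = FALSE], y[split$test])
  list(report = report, model = model, split = split, features = features)
}
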