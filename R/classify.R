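#' Strain-classification protocol configuration
#'
#' The random-forest classification protocol: stratified 20% hold-out,
#' recursive feature elimination (RFE) with a random-forest estimator over
#' candidate feature-set sizes \{2^i, i = 7..11\} (clipped to the available
#' width), repeated cross-validation to pick the best size, grid-search
#' hyperparameter tuning, and a single final evaluation on the untouched
#' test set against chance (1 / number of strains).
#'
#' The full tuning grid is n_estimators 200..2000 by 200; max_features
#' \{auto, sqrt\} ("auto" meaning all features, the historical convention);
#' max_depth 10..110 by 10 plus unlimited; min_samples_split \{2, 5, 10\};
#' min_samples_leaf \{1, 2, 4\}. The `"fast"` preset shrinks the grid and
#' the repeat/fold counts for routine runs.
#'
#' @param preset `"fast"` or `"full"`.
#' @param test_fraction Held-out fraction per strain.
#' @param candidate_sizes Candidate feature-set sizes.
#' @param cv_folds Cross-validation folds.
#' @param repeats RFE cross-validation repeats.
#' @param rfe_step Fraction of remaining features dropped per RFE
#'   iteration.
#' @param rfe_num_trees Trees per forest during RFE and size scoring.
#' @param grid Data frame of hyperparameter combinations (overrides the
#'   preset grid).
#' @param seed Integer seed.
#' @return A `classifier_protocol_config` list.
#' @export
classifier_protocol_config <- function(preset = c("fast", "full"),
                                       test_fraction = 0.2,
                                       candidate_sizes = 2^(7:11),
                                       cv_folds = NULL, repeats = NULL,
                                       rfe_step = NULL, rfe_num_trees = NULL,
                                       grid = NULL, seed = 0) {
  preset <- match.arg(preset)
  if (preset == "full") {
    cv_folds <- cv_folds %||% 4L
    repeats <- repeats %||% 20L
    rfe_step <- rfe_step %||% 0.1
    rfe_num_trees <- rfe_num_trees %||% 500L
    grid <- grid %||% expand.grid(
      n_estimators = seq(200, 2000, by = 200),
      max_features = c("auto", "sqrt"),
      max_depth = c(seq(10, 110, by = 10), NA),
      min_samples_split = c(2, 5, 10),
      min_samples_leaf = c(1, 2, 4),
      stringsAsFactors = FALSE
    )
  } else {
    cv_folds <- cv_folds %||% 3L
    repeats <- repeats %||% 3L
    rfe_step <- rfe_step %||% 0.5
    rfe_num_trees <- rfe_num_trees %||% 100L
    grid <- grid %||% expand.grid(
      n_estimators = c(200, 1000),
      max_features = "sqrt",
      max_depth = c(10, NA),
      min_samples_split = 2,
      min_samples_leaf = 1,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(preset = preset, test_fraction = test_fraction,
         candidate_sizes = sort(unique(as.integer(candidate_sizes))),
         cv_folds = as.integer(cv_folds), repeats = as.integer(repeats),
         rfe_step = rfe_step, rfe_num_trees = as.integer(rfe_num_trees),
         grid = grid, seed = seed),
    class = "classifier_protocol_config"
  )
}

#' Stratified train/test split by strain
#'
#' Assigns `round(test_fraction * n)` wells of each strain to the test
#' set, the rest to the training/tuning set.
#'
#' @param labels Factor (or character) of strain labels.
#' @param config A [classifier_protocol_config()].
#' @return List with `train`, `test` (integer row indices) and `audit`
#'   (usage log).
#' @export
split_train_test <- function(labels, config = classifier_protocol_config()) {
  labels <- factor(labels)
  small <- levels(labels)[table(labels) < 5]
  if (length(small)) {
    stop("strain(s) with fewer than 5 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  test <- integer()
  for (s in levels(labels)) {
    idx <- which(labels == s)
    n_test <- round(config$test_fraction * length(idx))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  train <- setdiff(seq_along(labels), test)
  list(
    train = train, test = test,
    audit = tibble::tibble(stage = "split", uses_test = FALSE,
                           ids = list(train))
  )
}

rf_fit <- function(X, y, num_trees = 100, mtry = NULL, max_depth = NA,
                   min_split = 2, min_leaf = 1, importance = "none",
                   seed = 1) {
  ranger::ranger(
    x = X, y = y, num.trees = num_trees,
    mtry = mtry %||% max(1, floor(sqrt(ncol(X)))),
    max.depth = if (is.na(max_depth)) 0 else max_depth,
    min.node.size = min_split, min.bucket = min_leaf,
    importance = importance, seed = seed,
    num.threads = 1, verbose = FALSE
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (s in levels(y)) {
    idx <- sample(which(y == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# RFE path: snapshots of the selected feature set at each candidate size
rfe_path <- function(X, y, sizes, step, num_trees, seed) {
  cur <- colnames(X)
  snaps <- list()
  for (target in sort(sizes, decreasing = TRUE)) {
    while (length(cur) > target) {
      k_next <- max(target,
                    length(cur) - max(1L, floor(step * length(cur))))
      fit <- rf_fit(X[, cur, drop = FALSE], y, num_trees = num_trees,
                    importance = "impurity", seed = seed)
      imp <- sort(fit$variable.importance, decreasing = TRUE)
      cur <- names(imp)[seq_len(k_next)]
    }
    snaps[[as.character(target)]] <- cur
  }
  snaps
}

#' RFE feature selection with repeated cross-validation
#'
#' For each candidate feature-set size, each cross-validation training fold
#' is used to select that many features by recursive feature elimination
#' with random-forest impurity importances and to train a classifier; the
#' fold's held-out part estimates the accuracy. The process is repeated
#' with different fold assignments, the size with the highest mean CV
#' accuracy is chosen (ties to the smaller size), and the final feature
#' set of that size is re-selected on the entire training set.
#'
#' @param X Numeric feature matrix of the training set (columns named).
#' @param y Strain labels of the training set.
#' @param config A [classifier_protocol_config()].
#' @return List with `best_size`, `selected_features`, `curve` (tibble:
#'   `size`, `mean_accuracy`, `sd_accuracy`, `n_scores`).
#' @export
rfe_cv_select <- function(X, y, config = classifier_protocol_config()) {
  y <- droplevels(factor(y))
  sizes <- config$candidate_sizes
  skipped <- sizes[sizes > ncol(X)]
  if (length(skipped)) {
    warning("candidate size(s) exceeding feature count skipped: ",
            paste(skipped, collapse = ", "))
  }
  sizes <- sizes[sizes <= ncol(X)]
  stopifnot(length(sizes) >= 1)
  scores <- list()
  for (r in seq_len(config$repeats)) {
    set.seed(config$seed + 1000 * r)
    fold <- stratified_folds(y, config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      snaps <- rfe_path(X[tr, , drop = FALSE], y[tr], sizes,
                        config$rfe_step, config$rfe_num_trees,
                        seed = config$seed + r)
      for (sz in sizes) {
        sel <- snaps[[as.character(sz)]]
        fit <- rf_fit(X[tr, sel, drop = FALSE], y[tr],
                      num_trees = config$rfe_num_trees,
                      seed = config$seed + r)
        pred <- stats::predict(fit, data = X[!tr, sel, drop = FALSE])
        scores[[length(scores) + 1]] <- tibble::tibble(
          repeat_id = r, fold = f, size = sz,
          accuracy = mean(pred$predictions == y[!tr])
        )
      }
    }
  }
  curve <- dplyr::bind_rows(scores) |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      n_scores = dplyr::n(), .groups = "drop"
    )
  best_size <- curve$size[which.max(curve$mean_accuracy)]
  set.seed(config$seed)
  final <- rfe_path(X, y, best_size, config$rfe_step,
                    config$rfe_num_trees, seed = config$seed)
  list(
    best_size = best_size,
    selected_features = final[[as.character(best_size)]],
    curve = curve,
    raw_scores = dplyr::bind_rows(scores)
  )
}

#' Tune, fit and evaluate the final classifier
#'
#' Grid-search cross-validation on the training set over the configured
#' hyperparameter grid, refit with the best parameters on the full
#' training set, and a single evaluation on the untouched test set. The
#' test set enters only here, by construction.
#'
#' @param X_train,y_train Training features (selected columns) and labels.
#' @param X_test,y_test Held-out test features and labels.
#' @param config A [classifier_protocol_config()].
#' @return List with `best_params`, `cv_results`, `test_accuracy`,
#'   `confusion` (table), `chance`.
#' @export
tune_fit_evaluate <- function(X_train, y_train, X_test, y_test,
                              config = classifier_protocol_config()) {
  y_train <- droplevels(factor(y_train))
  y_test <- factor(y_test, levels = levels(y_train))
  grid <- config$grid
  set.seed(config$seed + 99)
  fold <- stratified_folds(y_train, config$cv_folds)
  cv <- purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    gp <- grid[gi, ]
    mtry <- if (gp$max_features == "sqrt") {
      max(1, floor(sqrt(ncol(X_train))))
    } else {
      ncol(X_train)
    }
    accs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      fit <- rf_fit(X_train[tr, , drop = FALSE], y_train[tr],
                    num_trees = gp$n_estimators, mtry = mtry,
                    max_depth = gp$max_depth,
                    min_split = gp$min_samples_split,
                    min_leaf = gp$min_samples_leaf,
                    seed = config$seed + f)
      pred <- stats::predict(fit, data = X_train[!tr, , drop = FALSE])
      mean(pred$predictions == y_train[!tr])
    }, 0)
    dplyr::bind_cols(tibble::as_tibble(gp),
                     tibble::tibble(mean_cv_accuracy = mean(accs)))
  })
  best <- cv[which.max(cv$mean_cv_accuracy), ]
  mtry <- if (best$max_features == "sqrt") {
    max(1, floor(sqrt(ncol(X_train))))
  } else {
    ncol(X_train)
  }
  final <- rf_fit(X_train, y_train, num_trees = best$n_estimators,
                  mtry = mtry, max_depth = best$max_depth,
                  min_split = best$min_samples_split,
                  min_leaf = best$min_samples_leaf,
                  seed = config$seed)
  pred <- stats::predict(final, data = X_test)$predictions
  list(
    best_params = best[, setdiff(names(best), "mean_cv_accuracy")],
    cv_results = cv,
    test_accuracy = mean(pred == y_test),
    confusion = table(truth = y_test, predicted = pred),
    chance = 1 / nlevels(y_train),
    model = final
  )
}

#' Run the full strain-classification protocol
#'
#' Hold-out split, RFE size selection with repeated CV, grid-search
#' tuning, final test evaluation — with an audit log showing that no test
#' sample is used before the final evaluation.
#'
#' @param table Feature tibble with a `strain` column (or supply
#'   `labels`).
#' @param labels Optional label vector overriding `table$strain`.
#' @param config A [classifier_protocol_config()].
#' @return A `strain_protocol` object.
#' @export
strain_classify <- function(table, labels = NULL,
                            config = classifier_protocol_config()) {
  labels <- factor(labels %||% table$strain)
  fc <- feature_cols(table)
  X <- as.matrix(table[, fc])
  sp <- split_train_test(labels, config)
  audit <- list(tibble::tibble(stage = "split", ids = list(sp$train)))
  sel <- rfe_cv_select(X[sp$train, , drop = FALSE], labels[sp$train], config)
  audit[[2]] <- tibble::tibble(stage = "rfe_cv_select", ids = list(sp$train))
  tune <- tune_fit_evaluate(
    X[sp$train, sel$selected_features, drop = FALSE], labels[sp$train],
    X[sp$test, sel$selected_features, drop = FALSE], labels[sp$test],
    config
  )
  audit[[3]] <- tibble::tibble(stage = "tune", ids = list(sp$train))
  audit[[4]] <- tibble::tibble(stage = "final_evaluation", ids = list(sp$test))
  structure(
    list(
      split = sp, selection = sel, tuning = tune,
      test_accuracy = tune$test_accuracy, chance = tune$chance,
      confusion = tune$confusion,
      audit = dplyr::bind_rows(audit),
      config = config
    ),
    class = "strain_protocol"
  )
}

#' @exportS3Method base::print
print.strain_protocol <- function(x, ...) {
  cat(sprintf(
    "<strain_protocol> best size %d, test accuracy %.1f%% (chance %.1f%%)\n",
    x$selection$best_size, 100 * x$test_accuracy, 100 * x$chance
  ))
  invisible(x)
}

#' @export
glance.strain_protocol <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$split$train), n_test = length(x$split$test),
    best_size = x$selection$best_size,
    test_accuracy = x$test_accuracy,
    chance = x$chance
  )
}

#' @export
tidy.strain_protocol <- function(x, ...) x$selection$curve

#' @export
autoplot.strain_protocol <- function(object, ...) {
  ggplot2::ggplot(object$selection$curve,
                  ggplot2::aes(x = .data$size, y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "candidate feature-set size",
                  y = "mean CV accuracy")
}

#' Verify that the test set never leaks into selection or tuning
#'
#' @param protocol A `strain_protocol`.
#' @return `TRUE` (invisibly) if no pre-evaluation stage touched a test
#'   sample; otherwise an error.
#' @export
audit_no_test_leak <- function(protocol) {
  test <- protocol$split$test
  pre <- protocol$audit[protocol$audit$stage != "final_evaluation", ]
  for (i in seq_len(nrow(pre))) {
    if (length(intersect(pre$ids[[i]], test))) {
      stop("test samples used in stage ", pre$stage[i], call. = FALSE)
    }
  }
  invisible(TRUE)
}
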