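test_that("stratified hold-out assigns a rounded 20% of each strain", {
  labs <- factor(rep(paste0("S", 1:3), times = c(20, 10, 7)))
  sp <- split_train_test(labs, classifier_protocol_config(seed = 2))
  cnt <- table(labs[sp$test])
  expect_equal(as.integer(cnt), c(4L, 2L, 1L))
  expect_setequal(c(sp$train, sp$test), seq_along(labs))
  expect_length(intersect(sp$train, sp$test), 0)

  # printed panel sizes of the 11-strain study -> per-strain test counts
  panel <- c(34, 21, 27, 29, 25, 25, 27, 29, 16, 20, 23)
  labs2 <- factor(rep(sprintf("W%02d", 1:11), times = panel))
  sp2 <- split_train_test(labs2, classifier_protocol_config(seed = 0))
  expect_equal(as.integer(table(labs2[sp2$test])), round(0.2 * panel))

  expect_error(
    split_train_test(factor(rep(c("a", "b"), c(10, 3)))),
    "fewer than 5"
  )
})

test_that("RFE finds the informative features and sizes are clipped", {
  ft <- make_feature_table(3, 14, 40, effect_size = 2, seed = 31,
                           n_informative = 8)
  # collapse to one period block so exactly 8 columns carry signal
  fc <- feature_cols(ft$table)[1:40]
  X <- as.matrix(ft$table[, fc])
  y <- factor(ft$table$strain)
  cfg <- classifier_protocol_config(
    preset = "fast", candidate_sizes = c(8, 16, 32), seed = 3
  )
  expect_warning(
    sel <- rfe_cv_select(X, y, classifier_protocol_config(
      preset = "fast", candidate_sizes = c(16, 64), repeats = 1, seed = 3
    )),
    "skipped"
  )
  sel2 <- rfe_cv_select(X, y, cfg)
  truth_feats <- paste0(ft$truth$informative_features, "_prestim")
  expect_gte(length(intersect(sel2$selected_features, truth_feats)),
             min(6, sel2$best_size))
  # accuracy does not keep improving beyond the informative size
  curve <- sel2$curve
  expect_gte(curve$mean_accuracy[curve$size == 8],
             max(curve$mean_accuracy) - 0.05)
  # fixed seed -> identical selection
  sel3 <- rfe_cv_select(X, y, cfg)
  expect_identical(sel2$selected_features, sel3$selected_features)
})

test_that("pure-noise features give chance-level CV accuracy", {
  ft <- make_feature_table(3, 12, 30, effect_size = 0, seed = 37)
  fc <- feature_cols(ft$table)[1:30]
  X <- as.matrix(ft$table[, fc])
  y <- factor(ft$table$strain)
  cfg <- classifier_protocol_config(preset = "fast",
                                    candidate_sizes = c(8, 16),
                                    repeats = 4, seed = 5)
  sel <- rfe_cv_select(X, y, cfg)
  accs <- sel$raw_scores$accuracy
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(mean(accs), 1 / 3 + 3 * se + 0.05)
})

test_that("the full protocol keeps the test set untouched and beats chance", {
  ft <- make_feature_table(5, 12, 32, effect_size = 1.5, seed = 41)
  qc <- qc_impute_normalize(ft$table)
  cfg <- classifier_protocol_config(preset = "fast",
                                    candidate_sizes = c(16, 32), seed = 7)
  res <- strain_classify(qc$table, config = cfg)
  expect_equal(res$chance, 1 / 5)
  expect_gt(res$test_accuracy, res$chance)
  expect_true(audit_no_test_leak(res))
  # reported best params come from the declared grid
  grid_keys <- do.call(paste, cfg$grid)
  best_key <- do.call(paste, as.data.frame(res$tuning$best_params))
  expect_true(best_key %in% grid_keys)
  # label permutation destroys the signal
  set.seed(8)
  perm <- qc$table
  perm$strain <- sample(perm$strain)
  res0 <- strain_classify(perm, config = cfg)
  accs <- res0$selection$raw_scores$accuracy
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(res0$test_accuracy, res0$chance + 3 * max(se, 0.05))
})

test_that("accuracy rises with effect size across synthetic panels", {
  effs <- c(0, 0.5, 1, 1.5, 2)
  accs <- vapply(seq_along(effs), function(i) {
    ft <- make_feature_table(4, 10, 24, effect_size = effs[i],
                             seed = 50) # same seed: only the effect varies
    qc <- qc_impute_normalize(ft$table)
    cfg <- classifier_protocol_config(preset = "fast",
                                      candidate_sizes = 24, repeats = 1,
                                      seed = 9)
    strain_classify(qc$table, config = cfg)$test_accuracy
  }, 0)
  expect_gt(suppressWarnings(stats::cor(effs, accs, method = "spearman")), 0)
  expect_gt(accs[5], accs[1])
})
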