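test_that("per-well summaries recover geometry of a known worm", {
  st <- straight_static_track(length_px = 60, width_px = 5)
  ft <- summarize_features(st)
  expect_equal(ft$length, 60, tolerance = 2 / 60) # within 2 px
  expect_equal(ft$speed, 0)
  expect_equal(ft$frac_st, 1)
  expect_equal(ft$curvature_midbody, 0)

  # averaging idempotence: two identical tracks = one track
  two <- dplyr::bind_rows(st, dplyr::mutate(st, track_id = 2L))
  f1 <- summarize_features(st)
  f2 <- summarize_features(two)
  fc <- feature_cols(f1)
  expect_equal(as.data.frame(f2[, fc]), as.data.frame(f1[, fc]))

  # bad wells still emit a (flagged) row
  ses <- tiny_session()
  wells <- ses$wells
  wells$bad[wells$name == "B2"] <- TRUE
  fb <- summarize_features(st, wells = wells)
  expect_equal(nrow(fb), 4)
  expect_true(fb$bad[fb$well == "B2"])
})

test_that("period concatenation obeys the 3x width contracts", {
  mk <- function(p) {
    tab <- tibble::tibble(well = c("A1", "A2"))
    X <- matrix(stats::rnorm(2 * p), 2, p,
                dimnames = list(NULL, sprintf("f%04d", seq_len(p))))
    out <- dplyr::bind_cols(tab, tibble::as_tibble(X))
    attr(out, "feature_cols") <- colnames(X)
    out
  }
  wide <- concatenate_periods(list(prestim = mk(3076), bluelight = mk(3076),
                                   poststim = mk(3076)))
  expect_equal(length(feature_cols(wide)), 9228)
  w2 <- concatenate_periods(list(prestim = mk(256), bluelight = mk(256),
                                 poststim = mk(256)))
  expect_equal(length(feature_cols(w2)), 768)

  bad <- mk(10)
  bad$well <- c("A1", "B9")
  expect_error(concatenate_periods(list(prestim = mk(10), bluelight = bad)),
               "well sets")
  expect_error(concatenate_periods(list(prestim = mk(10)[0, ])), "empty")
})

test_that("QC order of operations: samples, then features, then imputation", {
  set.seed(1)
  X <- matrix(stats::rnorm(100), 10, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  X[1, 1:5] <- NA          # row 1: 50% missing -> dropped
  X[3:5, 7] <- NA          # f07 missing in 3/9 remaining samples -> dropped
  tab <- tibble::as_tibble(X)
  attr(tab, "feature_cols") <- colnames(X)
  qc <- qc_impute_normalize(tab)
  expect_equal(qc$report$dropped_samples, 1L)
  expect_true("f07" %in% qc$report$dropped_features$feature)
  expect_equal(nrow(qc$table), 9)
  expect_false(anyNA(as.matrix(qc$table[, feature_cols(qc$table)])))
  # z-normalisation
  Z <- as.matrix(qc$table[, feature_cols(qc$table)])
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, stats::sd) - 1) < 1e-6))
})

test_that("QC is deterministic and row-order invariant", {
  ft <- make_feature_table(3, 6, 30, missing_frac = 0.1, seed = 5)
  a <- qc_impute_normalize(ft$table)
  b <- qc_impute_normalize(ft$table)
  expect_identical(a$table, b$table)
  perm <- sample(nrow(ft$table))
  c2 <- qc_impute_normalize(ft$table[perm, ])
  ord <- match(a$table$well_id, c2$table$well_id)
  expect_equal(as.data.frame(c2$table[ord, names(a$table)]),
               as.data.frame(a$table), tolerance = 1e-12)
})

test_that("imputation averages within the interval group", {
  # f1 missing in 1/3 of each interval group; four clean companion features
  # keep the rows below the sample-missingness threshold
  tab <- tibble::tibble(
    g = c("a", "a", "a", "b", "b", "b"),
    f1 = c(1, 2, NA, 10, 20, NA),
    f2 = stats::rnorm(6), f3 = stats::rnorm(6),
    f4 = stats::rnorm(6), f5 = stats::rnorm(6)
  )
  attr(tab, "feature_cols") <- paste0("f", 1:5)
  qc <- qc_impute_normalize(tab, interval = "g", feature_miss_max = 0.5)
  expect_equal(nrow(qc$table), 6)
  expect_equal(qc$report$n_imputed, 2L)
  filled <- c(1, 2, 1.5, 10, 20, 15)
  f1 <- as.numeric(qc$table$f1) * stats::sd(filled) + mean(filled)
  expect_equal(f1, filled, tolerance = 1e-9)
})

test_that("PCA projection: variance ordering, signs, reconstruction", {
  # one varying feature -> PC1 explains everything
  tab <- tibble::tibble(f1 = c(-2, -1, 0, 1, 2), f2 = 0.0, f3 = 0.0)
  attr(tab, "feature_cols") <- c("f1", "f2", "f3")
  p <- pca_project(tab, k = 1)
  expect_equal(p$explained[1], 1)
  # sign convention: largest-magnitude loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)

  set.seed(2)
  X <- matrix(stats::rnorm(8 * 5), 8, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  tab2 <- tibble::as_tibble(X)
  attr(tab2, "feature_cols") <- colnames(X)
  p2 <- pca_project(tab2, k = 5)
  rec <- as.matrix(p2$scores[, paste0("PC", 1:5)]) %*% t(p2$loadings)
  rec <- sweep(rec, 2, colMeans(X), "+")
  expect_lt(max(abs(rec - X)), 1e-9)
  expect_true(all(diff(p2$explained) < 1e-12))
  expect_error(pca_project(tab, k = 3), "rank")

  # two orthogonal clusters separate on PC1 (silhouette > 0.5)
  set.seed(3)
  Y <- rbind(matrix(stats::rnorm(60, 0), 10), matrix(stats::rnorm(60, 6), 10))
  colnames(Y) <- paste0("f", 1:6)
  tab3 <- tibble::as_tibble(Y)
  attr(tab3, "feature_cols") <- colnames(Y)
  s <- pca_project(tab3, k = 1)$scores$PC1
  grp <- rep(1:2, each = 10)
  sil <- vapply(1:20, function(i) {
    a <- mean(abs(s[i] - s[grp == grp[i]][-which(which(grp == grp[i]) == i)]))
    b <- mean(abs(s[i] - s[grp != grp[i]]))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("Kruskal-Wallis with BY control is calibrated and correct", {
  # BY adjustment oracle: hand-computed step-up with the harmonic factor
  p <- c(0.001, 0.01, 0.04, 0.8)
  m <- 4
  cm <- sum(1 / (1:m))
  manual <- rev(cummin(rev(pmin(1, sort(p) * cm * m / seq_len(m)))))
  expect_equal(sort(stats::p.adjust(p, method = "BY")), manual)

  # constant feature -> p = 1, not an error
  tab <- tibble::tibble(f1 = rep(1, 12), f2 = stats::rnorm(12))
  attr(tab, "feature_cols") <- c("f1", "f2")
  g <- rep(c("a", "b", "c"), each = 4)
  res <- kw_by_significance(tab, g)
  expect_equal(res$p[res$feature == "f1"], 1)

  # invariance under monotone transforms
  set.seed(4)
  tab2 <- tibble::tibble(f1 = stats::rexp(18))
  attr(tab2, "feature_cols") <- "f1"
  g2 <- rep(c("a", "b", "c"), 6)
  p1 <- kw_by_significance(tab2, g2)$p
  tab3 <- tibble::tibble(f1 = log(tab2$f1))
  attr(tab3, "feature_cols") <- "f1"
  expect_equal(kw_by_significance(tab3, g2)$p, p1, tolerance = 1e-12)
})

test_that("exact two-group KW p equals the enumerated permutation tail", {
  set.seed(5)
  x <- c(stats::rnorm(10), stats::rnorm(10) + 2.2)
  g <- rep(c("a", "b"), each = 10)
  tab <- tibble::tibble(f1 = x)
  attr(tab, "feature_cols") <- "f1"
  pe <- kw_by_significance(tab, g, p_method = "exact")$p
  # oracle: complete enumeration of the rank-sum distribution
  r <- rank(x)
  obs <- abs(sum(r[g == "a"]) - 10 * 21 / 2)
  combs <- utils::combn(20, 10)
  sums <- colSums(matrix(r[combs], nrow = 10))
  p_enum <- mean(abs(sums - 10 * 21 / 2) >= obs - 1e-9)
  expect_equal(pe, p_enum, tolerance = 0.1 * p_enum)
})

test_that("fingerprint clustering uses complete linkage on correlation distance", {
  set.seed(6)
  base <- stats::rnorm(20)
  X <- rbind(a1 = base + stats::rnorm(20, 0, 0.05),
             a2 = base + stats::rnorm(20, 0, 0.05),
             b1 = -base + stats::rnorm(20, 0, 0.05),
             b2 = -base + stats::rnorm(20, 0, 0.05))
  colnames(X) <- paste0("f", 1:20)
  cl <- cluster_fingerprints(X)
  # anti-correlated blocks split at the top of the dendrogram
  top <- stats::cutree(cl$row_hclust, k = 2)
  expect_equal(top[["a1"]], top[["a2"]])
  expect_equal(top[["b1"]], top[["b2"]])
  expect_false(top[["a1"]] == top[["b1"]])

  # duplicated row merges first at distance 0
  X2 <- rbind(X, a1dup = X["a1", ])
  cl2 <- cluster_fingerprints(X2)
  expect_equal(min(cl2$row_hclust$height), 0, tolerance = 1e-9)
  first <- cl2$row_hclust$merge[1, ]
  expect_setequal(rownames(X2)[-first], c("a1", "a1dup"))

  # deterministic leaf order
  expect_identical(cluster_fingerprints(X)$row_order, cl$row_order)

  # zero-variance row errors with its id
  X3 <- rbind(X, flat = rep(1, 20))
  expect_error(cluster_fingerprints(X3), "flat")
})

test_that("LMM screen handles unestimable compounds and detects real effects", {
  set.seed(7)
  days <- paste0("d", 1:3)
  mk_block <- function(cpd, day, shift = 0) {
    X <- matrix(stats::rnorm(4 * 6), 4, 6) + shift
    dplyr::bind_cols(tibble::tibble(compound = cpd, day = day),
                     tibble::as_tibble(as.data.frame(X)))
  }
  rows <- list()
  for (d in days) {
    rows <- c(rows, list(mk_block("DMSO", d), mk_block("hit", d, shift = 3)))
  }
  rows <- c(rows, list(mk_block("oneday", "d1")))
  tab <- dplyr::bind_rows(rows)
  attr(tab, "feature_cols") <- paste0("V", 1:6)
  res <- lmm_screen(tab, "compound", "day", q = 0.05)
  expect_false(res$estimable[res$compound == "oneday"])
  expect_true(res$hit[res$compound == "hit"])
})
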