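#' Summarise tracks into one feature vector per well
#'
#' Computes a reduced, representative behavioural feature set per track —
#' body length, width, mean absolute curvature by body part (head, neck,
#' midbody, hips, tail), speed, per-mode time fractions and per-mode mean
#' speeds — and averages across the tracks of each well into a single
#' vector. The aggregation machinery downstream is width-agnostic, so the
#' same pipeline applies unchanged to richer feature catalogues.
#'
#' @param tracks Tracks tibble (from [track_session()] / [classify_motion()]),
#'   with `well`, `mode`, `signed_speed`, `length`, `area`, `midline`.
#' @param wells Optional wells tibble (e.g. `grid$wells`); wells without
#'   tracks then yield all-missing rows, and bad flags are carried over.
#' @param period Optional recording-period label attached to the result.
#' @return A feature tibble: `well`, `bad`, `n_tracks`, then one column per
#'   feature.
#' @export
summarize_features <- function(tracks, wells = NULL, period = NULL) {
  per_track <- tracks |>
    dplyr::filter(!is.na(.data$well)) |>
    dplyr::group_by(.data$well, .data$track_id) |>
    dplyr::group_modify(function(df, key) track_features(df)) |>
    dplyr::ungroup()
  per_well <- per_track |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      dplyr::across(-"track_id", ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  if (!is.null(wells)) {
    base <- tibble::tibble(well = wells$name, bad = wells$bad)
    per_well <- dplyr::left_join(base, per_well, by = "well")
    per_well$n_tracks[is.na(per_well$n_tracks)] <- 0L
  } else if ("bad" %in% names(tracks)) {
    flags <- dplyr::distinct(tracks, .data$well, .data$bad)
    per_well <- dplyr::left_join(per_well, flags, by = "well") |>
      dplyr::relocate("bad", .after = "well")
  } else {
    per_well$bad <- FALSE
    per_well <- dplyr::relocate(per_well, "bad", .after = "well")
  }
  fc <- setdiff(names(per_well), c("well", "bad", "n_tracks"))
  if (!is.null(period)) {
    names(per_well)[match(fc, names(per_well))] <- paste0(fc, "_", period)
    fc <- paste0(fc, "_", period)
  }
  attr(per_well, "feature_cols") <- fc
  per_well
}

BODY_PARTS <- c("head", "neck", "midbody", "hips", "tail")

# features of a single track (averaged over its frames)
track_features <- function(df) {
  n <- nrow(df)
  curv <- matrix(NA_real_, n, 5, dimnames = list(NULL, BODY_PARTS))
  for (k in seq_len(n)) {
    ml <- df$midline[[k]]
    if (is.null(ml) || nrow(ml) < 5) next
    curv[k, ] <- midline_curvature_by_part(ml)
  }
  len <- stats::median(df$length, na.rm = TRUE)
  width <- mean(df$area / pmax(df$length, 1), na.rm = TRUE)
  sp <- df$signed_speed
  out <- tibble::tibble(
    length = len,
    width = width,
    speed = mean(abs(sp), na.rm = TRUE),
    frac_fw = mean(df$mode == "fw", na.rm = TRUE),
    frac_bw = mean(df$mode == "bw", na.rm = TRUE),
    frac_st = mean(df$mode == "st", na.rm = TRUE),
    speed_fw = mean(sp[!is.na(df$mode) & df$mode == "fw"], na.rm = TRUE),
    speed_bw = mean(sp[!is.na(df$mode) & df$mode == "bw"], na.rm = TRUE)
  )
  for (p in seq_along(BODY_PARTS)) {
    out[[paste0("curvature_", BODY_PARTS[p])]] <-
      mean(curv[, p], na.rm = TRUE)
  }
  out
}

# mean absolute curvature (turning angle per unit arc length) in five
# equal-arc-length body segments, head first
midline_curvature_by_part <- function(ml) {
  d <- diff(ml)
  seg_len <- sqrt(rowSums(d^2))
  ang <- atan2(d[, 2], d[, 1])
  dang <- diff(ang)
  dang <- atan2(sin(dang), cos(dang)) # wrap to (-pi, pi]
  mean_seg <- mean(seg_len)
  if (mean_seg == 0) return(rep(NA_real_, 5))
  kappa <- abs(dang) / mean_seg
  pos <- cumsum(seg_len)[-length(seg_len)] / sum(seg_len)
  part <- pmin(5L, 1L + floor(pos * 5))
  vapply(1:5, function(p) {
    if (any(part == p)) mean(kappa[part == p]) else NA_real_
  }, 0)
}

#' Concatenate per-period feature tables
#'
#' Joins the feature tables of the three recording periods (pre-stimulus,
#' blue light, post-stimulus) on the well set, yielding a combined table
#' whose width is the sum of the per-period widths (3x for equal widths:
#' 3 x 3076 = 9228, 3 x 256 = 768).
#'
#' @param tables Named list of feature tibbles (names = period labels);
#'   feature columns that do not yet carry the period suffix get it.
#' @return Combined feature tibble.
#' @export
concatenate_periods <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- c("prestim", "bluelight", "poststim")[seq_along(tables)]
  }
  key_cols <- c("well", "well_id", "bad", "strain", "n_tracks")
  base_wells <- NULL
  out <- NULL
  all_fc <- character()
  for (period in names(tables)) {
    tab <- tables[[period]]
    if (nrow(tab) == 0) stop("empty feature table for period ", period,
                             call. = FALSE)
    wcol <- intersect(c("well", "well_id"), names(tab))[1]
    fc <- feature_cols(tab)
    if (length(fc) == 0) stop("no feature columns in period ", period,
                              call. = FALSE)
    wells <- tab[[wcol]]
    if (is.null(base_wells)) {
      base_wells <- wells
      out <- tab[, intersect(key_cols, names(tab))]
    } else if (!setequal(wells, base_wells) ||
               length(wells) != length(base_wells)) {
      stop("well sets differ between period tables", call. = FALSE)
    }
    tab <- tab[match(base_wells, tab[[wcol]]), ]
    vals <- tab[, fc]
    suffix <- paste0("_", period)
    no_suffix <- !endsWith(fc, suffix)
    names(vals)[no_suffix] <- paste0(fc[no_suffix], suffix)
    out <- dplyr::bind_cols(out, vals)
    all_fc <- c(all_fc, names(vals))
  }
  attr(out, "feature_cols") <- all_fc
  out
}

#' Quality control, imputation and z-normalisation of a feature table
#'
#' Applies, in order: (1) drop samples in which more than
#' `sample_miss_max` of the features are missing; (2) drop features
#' missing in more than `feature_miss_max` of the samples within any
#' interval group; (3) impute remaining missing values with the
#' within-interval feature mean; (4) z-normalise each feature column over
#' the whole table. Features left entirely missing within an interval
#' (uninputable) and zero-variance features are dropped.
#'
#' @param table Feature tibble (missing = `NA` in feature columns).
#' @param sample_miss_max,feature_miss_max QC thresholds (fractions,
#'   exceeded strictly).
#' @param interval Optional row grouping (vector, or name of a column in
#'   `table`): the "time interval" for feature QC and imputation. Default:
#'   one group.
#' @return List with `table` (clean, z-normalised) and `report` (a
#'   `qc_report`: dropped samples/features, imputation counts).
#' @export
qc_impute_normalize <- function(table, sample_miss_max = 0.40,
                                feature_miss_max = 0.20, interval = NULL) {
  fc <- feature_cols(table)
  X <- as.matrix(table[, fc])
  if (is.character(interval) && length(interval) == 1 &&
      interval %in% names(table)) {
    interval <- table[[interval]]
  }
  interval <- interval %||% rep(1L, nrow(X))
  stopifnot(length(interval) == nrow(X))

  row_miss <- rowMeans(is.na(X))
  keep_rows <- row_miss <= sample_miss_max
  dropped_samples <- which(!keep_rows)
  X <- X[keep_rows, , drop = FALSE]
  interval <- interval[keep_rows]
  tab <- table[keep_rows, ]

  drop_feat <- rep(FALSE, ncol(X))
  reason <- rep(NA_character_, ncol(X))
  for (g in unique(interval)) {
    sel <- interval == g
    fm <- colMeans(is.na(X[sel, , drop = FALSE]))
    newly <- !drop_feat & fm > feature_miss_max
    drop_feat <- drop_feat | newly
    reason[newly] <- "missing_rate"
    all_na <- !drop_feat & fm == 1
    drop_feat <- drop_feat | all_na
    reason[all_na] <- "uninputable"
  }
  n_imputed <- 0L
  for (g in unique(interval)) {
    sel <- which(interval == g)
    mu <- colMeans(X[sel, , drop = FALSE], na.rm = TRUE)
    for (j in which(!drop_feat)) {
      na <- sel[is.na(X[sel, j])]
      if (length(na)) {
        X[na, j] <- mu[j]
        n_imputed <- n_imputed + length(na)
      }
    }
  }
  sds <- apply(X, 2, stats::sd)
  zero_var <- !drop_feat & (is.na(sds) | sds < .Machine$double.eps)
  reason[zero_var] <- "zero_variance"
  drop_feat <- drop_feat | zero_var
  Xz <- scale(X[, !drop_feat, drop = FALSE])
  clean <- dplyr::bind_cols(
    tab[, setdiff(names(tab), fc)],
    tibble::as_tibble(Xz)
  )
  attr(clean, "feature_cols") <- fc[!drop_feat]
  report <- structure(
    list(
      n_samples_in = nrow(table), n_samples_kept = nrow(clean),
      dropped_samples = dropped_samples,
      dropped_features = tibble::tibble(
        feature = fc[drop_feat], reason = reason[drop_feat]
      ),
      n_imputed = n_imputed
    ),
    class = "qc_report"
  )
  list(table = clean, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d/%d samples kept, %d features dropped, %d values imputed\n",
    x$n_samples_kept, x$n_samples_in, nrow(x$dropped_features), x$n_imputed
  ))
  invisible(x)
}

#' Principal component projection of a clean feature table
#'
#' PCA of the z-normalised feature matrix with a deterministic sign
#' convention: each component is flipped so its largest-magnitude loading
#' is positive.
#'
#' @param table Clean feature tibble (no missing values; see
#'   [qc_impute_normalize()]).
#' @param k Number of components (must not exceed the matrix rank).
#' @return List with `scores` (tibble: id columns + `PC1..PCk`),
#'   `loadings`, `explained` (variance fractions, non-increasing).
#' @export
pca_project <- function(table, k = 2) {
  fc <- feature_cols(table)
  X <- as.matrix(table[, fc])
  if (anyNA(X)) stop("feature table contains missing values", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  r <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (k > r) stop("k exceeds the rank of the feature matrix (", r, ")",
                  call. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = dplyr::bind_cols(table[, setdiff(names(table), fc)],
                              tibble::as_tibble(scores)),
    loadings = loadings,
    explained = expl[seq_len(k)],
    rank = r,
    prcomp = pc,
    flip = flip
  )
}

#' Kruskal-Wallis tests with Benjamini-Yekutieli control
#'
#' Tests each feature for a between-group location difference with the
#' Kruskal-Wallis rank test (tie-corrected) and controls the false
#' discovery rate over features with the Benjamini-Yekutieli step-up
#' procedure, which is valid under arbitrary dependence between features.
#' Constant features yield p = 1 (no evidence), not an error. For two
#' untied groups, `p_method = "exact"` uses the exact Wilcoxon rank-sum
#' null distribution instead of the chi-square approximation.
#'
#' @param table Feature tibble.
#' @param groups Group labels (vector, or name of a column in `table`).
#' @param q Target false discovery rate.
#' @param p_method `"asymptotic"` or `"exact"`.
#' @return Tibble with `feature`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
kw_by_significance <- function(table, groups, q = 0.05,
                               p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% names(table)) {
    groups <- table[[groups]]
  }
  g <- factor(groups)
  stopifnot(nlevels(g) >= 2)
  fc <- feature_cols(table)
  res <- purrr::map_dfr(fc, function(f) {
    x <- table[[f]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) <= 1 || length(unique(g[ok])) < 2) {
      return(tibble::tibble(feature = f, statistic = 0, p = 1))
    }
    if (p_method == "exact") {
      if (nlevels(droplevels(g[ok])) != 2) {
        stop("exact p-values are implemented for 2 groups only", call. = FALSE)
      }
      lv <- levels(droplevels(g[ok]))
      w <- stats::wilcox.test(x[ok][g[ok] == lv[1]], x[ok][g[ok] == lv[2]],
                              exact = TRUE, correct = FALSE)
      tibble::tibble(feature = f, statistic = unname(w$statistic),
                     p = w$p.value)
    } else {
      kt <- stats::kruskal.test(x[ok], g[ok])
      tibble::tibble(feature = f, statistic = unname(kt$statistic),
                     p = kt$p.value)
    }
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BY")
  res$significant <- res$p_adj <= q
  res
}

#' Hierarchically cluster behavioural fingerprints
#'
#' Clusters both samples (rows) and features (columns) of a z-normalised
#' feature table with complete linkage on correlation distance
#' (1 - Pearson correlation), the standard layout for fingerprint
#' heatmaps.
#'
#' @param table Clean feature tibble, or a numeric matrix.
#' @param ids Row identifiers (default: first id-like column, or row
#'   numbers).
#' @return List with `row_hclust`, `col_hclust`, `row_order`, `col_order`,
#'   `matrix`.
#' @export
cluster_fingerprints <- function(table, ids = NULL) {
  if (is.matrix(table)) {
    X <- table
    ids <- ids %||% rownames(X) %||% as.character(seq_len(nrow(X)))
  } else {
    fc <- feature_cols(table)
    X <- as.matrix(table[, fc])
    idc <- intersect(c("compound", "strain", "well_id", "well"), names(table))
    ids <- ids %||% (if (length(idc)) as.character(table[[idc[1]]]) else
      as.character(seq_len(nrow(X))))
  }
  if (anyNA(X)) stop("fingerprint matrix contains missing values", call. = FALSE)
  rv <- apply(X, 1, stats::sd)
  if (any(rv < .Machine$double.eps)) {
    stop("zero-variance row(s): ",
         paste(ids[rv < .Machine$double.eps], collapse = ", "), call. = FALSE)
  }
  cv <- apply(X, 2, stats::sd)
  if (any(cv < .Machine$double.eps)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[cv < .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  }
  rownames(X) <- ids
  row_d <- stats::as.dist(1 - stats::cor(t(X)))
  col_d <- stats::as.dist(1 - stats::cor(X))
  row_hc <- stats::hclust(row_d, method = "complete")
  col_hc <- stats::hclust(col_d, method = "complete")
  list(
    row_hclust = row_hc, col_hclust = col_hc,
    row_order = ids[row_hc$order], col_order = colnames(X)[col_hc$order],
    matrix = X
  )
}

#' Linear-mixed-model compound screen
#'
#' For each compound, fits per feature a linear mixed model
#' `feature ~ compound + (1 | day)` on the compound and control wells,
#' with imaging day as a random intercept to absorb day-to-day variation.
#' P-values for the compound fixed effect (Satterthwaite) are corrected
#' across features with Benjamini-Hochberg; a compound is a hit when at
#' least one feature is significant at `q`. Compounds present on a single
#' imaging day are unestimable and excluded.
#'
#' @param table Feature tibble.
#' @param compound Compound labels (vector or column name).
#' @param day Imaging-day labels (vector or column name).
#' @param q Per-compound FDR threshold across features.
#' @param control Label of the vehicle control group.
#' @param adjust Multiplicity correction across features (default
#'   `"BH"`).
#' @return Tibble with `compound`, `estimable`, `n_features`,
#'   `n_significant`, `min_p_adj`, `hit`.
#' @export
lmm_screen <- function(table, compound, day, q = 0.05, control = "DMSO",
                       adjust = "BH") {
  pick <- function(v) {
    if (is.character(v) && length(v) == 1 && v %in% names(table)) table[[v]]
    else v
  }
  cpd <- as.character(pick(compound))
  dy <- factor(pick(day))
  fc <- feature_cols(table)
  stopifnot(control %in% cpd)
  out <- purrr::map_dfr(setdiff(unique(cpd), control), function(cc) {
    sel <- cpd %in% c(cc, control)
    if (length(unique(dy[cpd == cc])) < 2) {
      return(tibble::tibble(
        compound = cc, estimable = FALSE, n_features = 0L,
        n_significant = NA_integer_, min_p_adj = NA_real_, hit = NA
      ))
    }
    ps <- vapply(fc, function(f) {
      df <- data.frame(
        y = table[[f]][sel],
        trt = factor(cpd[sel] == cc, levels = c(FALSE, TRUE)),
        day = droplevels(dy[sel])
      )
      df <- df[!is.na(df$y), ]
      p <- tryCatch({
        fit <- suppressMessages(suppressWarnings(
          lmerTest::lmer(y ~ trt + (1 | day), data = df)
        ))
        stats::coef(summary(fit))["trtTRUE", "Pr(>|t|)"]
      }, error = function(e) NA_real_)
      if (is.na(p)) {
        # fixed-effects fallback when the random effect cannot be fit
        fit <- stats::lm(y ~ trt + day, data = df)
        p <- stats::coef(summary(fit))["trtTRUE", "Pr(>|t|)"]
      }
      p
    }, 0)
    p_adj <- stats::p.adjust(ps, method = adjust)
    tibble::tibble(
      compound = cc, estimable = TRUE, n_features = length(fc),
      n_significant = sum(p_adj <= q, na.rm = TRUE),
      min_p_adj = suppressWarnings(min(p_adj, na.rm = TRUE)),
      hit = any(p_adj <= q, na.rm = TRUE)
    )
  })
  out
}
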