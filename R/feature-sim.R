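#' Simulate a strain-structured behavioural feature table
#'
#' Generates a wells x features matrix in the shape the summarisation
#' pipeline produces: for each recording period (`prestim`, `bluelight`,
#' `poststim`) a block of `n_features` features, concatenated with period
#' suffixes, with per-strain mean shifts, unit residual noise, and uniform
#' missingness. For each (strain, feature) pair one mean shift is drawn from
#' `N(0, effect_size^2)`; wells of that strain then scatter around it with
#' unit standard deviation, so `effect_size` is the between-strain effect in
#' z-units.
#'
#' @param n_strains Number of strains (>= 1).
#' @param wells_per_strain Wells per strain (>= 1).
#' @param n_features Features per recording period (>= 1).
#' @param effect_size Standard deviation of the per-(strain, feature) mean
#'   shift, in z-units; 0 gives a global null.
#' @param missing_frac Fraction of entries masked missing, in `[0, 1)`.
#' @param seed Integer seed.
#' @param n_informative If given, only this many features per period carry
#'   the strain effect; the rest are pure noise. Default: all.
#' @return List with `table` (a `feature_table`: tibble with `well_id`,
#'   `strain`, `bad`, and one column per feature), `mask` (logical matrix,
#'   TRUE = missing), `periods` (character vector tagging each feature
#'   column with its period), `truth` (per-well strain labels, plus the
#'   names of informative features).
#' @export
make_feature_table <- function(n_strains, wells_per_strain, n_features,
                               effect_size = 1, missing_frac = 0, seed = 0,
                               n_informative = NULL) {
  stopifnot(n_strains >= 1, wells_per_strain >= 1, n_features >= 1,
            missing_frac >= 0, missing_frac < 1)
  set.seed(seed)
  n_informative <- n_informative %||% n_features
  stopifnot(n_informative <= n_features)
  periods <- c("prestim", "bluelight", "poststim")
  n_wells <- n_strains * wells_per_strain
  strains <- sprintf("S%02d", rep(seq_len(n_strains), each = wells_per_strain))
  p_total <- 3L * n_features

  base <- sprintf("f%03d", seq_len(n_features))
  cols <- as.vector(vapply(periods, function(p) paste0(base, "_", p),
                           character(n_features)))
  period_of <- rep(periods, each = n_features)

  informative <- sprintf("f%03d", seq_len(n_informative))
  X <- matrix(stats::rnorm(n_wells * p_total), n_wells, p_total,
              dimnames = list(NULL, cols))
  if (effect_size > 0) {
    for (j in seq_len(p_total)) {
      if (!sub("_[a-z]+$", "", cols[j]) %in% informative) next
      shifts <- stats::rnorm(n_strains, 0, effect_size)
      X[, j] <- X[, j] + shifts[rep(seq_len(n_strains), each = wells_per_strain)]
    }
  }
  mask <- matrix(FALSE, n_wells, p_total, dimnames = list(NULL, cols))
  if (missing_frac > 0) {
    mask[sample.int(length(mask), round(missing_frac * length(mask)))] <- TRUE
  }
  X[mask] <- NA_real_

  tab <- dplyr::bind_cols(
    tibble::tibble(
      well_id = sprintf("well_%03d", seq_len(n_wells)),
      strain = strains,
      bad = FALSE
    ),
    tibble::as_tibble(X)
  )
  attr(tab, "feature_cols") <- cols
  attr(tab, "periods") <- period_of
  class(tab) <- c("feature_table", class(tab))
  list(
    table = tab,
    mask = mask,
    periods = period_of,
    truth = list(strain = strains, informative_features = informative)
  )
}

#' Feature columns of a feature table
#'
#' Identifies the numeric feature columns of a feature table (everything
#' except identifier/label columns).
#'
#' @param table A feature table (tibble).
#' @param id_cols Columns to treat as identifiers/labels.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table,
                         id_cols = c("well_id", "well", "video", "strain",
                                     "compound", "day", "period", "bad",
                                     "group", "n_tracks")) {
  fc <- attr(table, "feature_cols")
  if (!is.null(fc)) return(intersect(fc, names(table)))
  setdiff(names(table)[vapply(table, is.numeric, TRUE)], id_cols)
}
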