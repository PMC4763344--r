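# Single-view pathology patterns: per-ROI ANOVA -> Gaussian weights ->
# normalised pattern.

#' Per-ROI one-way ANOVA p-values
#'
#' For one view, tests each ROI's feature against the null hypothesis that
#' the diagnostic groups are random samples of one population, with a
#' fixed-effects one-way F-test (equal-variance). No multiplicity correction
#' is applied: the p-values feed a weighting transform, not a significance
#' report. Constant ROIs (zero total variance) get `p = 1` with a warning;
#' ROIs that are constant within groups but differ between them get `p = 0`.
#'
#' @param table A [cohort_table()].
#' @param view_name View to analyse.
#' @return Numeric vector of `K` p-values in `[0, 1]`, atlas order.
#' @export
anova_pvalues <- function(table, view_name) {
  x <- view_matrix(table, view_name)
  g <- droplevels(table$subjects$diagnosis)
  assert_that(nlevels(g) >= 2,
              "need at least 2 diagnosis groups for ANOVA, got ", nlevels(g))
  small <- names(which(table(g) < 2))
  assert_that(length(small) == 0,
              "group(s) with fewer than 2 subjects: ",
              paste(small, collapse = ", "))
  ps <- apply(x, 2, function(col) {
    if (max(col) - min(col) == 0) return(NA_real_) # constant, flagged below
    wg <- tapply(col, g, function(v) sum((v - mean(v))^2))
    if (sum(wg) == 0) return(0) # zero within-group variance, distinct means
    oneway.test(col ~ g, var.equal = TRUE)$p.value
  })
  if (anyNA(ps)) {
    rlang::warn(paste0("constant ROI column(s) assigned p = 1: ",
                       paste(utils::head(names(ps)[is.na(ps)], 5),
                             collapse = ", ")))
    ps[is.na(ps)] <- 1
  }
  unname(ps)
}

#' Gaussian p-value weighting
#'
#' Transforms p-values into discriminability weights
#' `w(i) = exp(-p(i)^2 / (2 sigma^2))`: 1 at `p = 0`, falling off with
#' bandwidth `sigma` (default 0.05, p-value units), effectively 0 once
#' `p >> sigma`.
#'
#' @param p_values Numeric vector of p-values.
#' @param config A [crossview_config()] (uses `pattern$sigma`).
#' @return Weights in `[0, 1]`, same length.
#' @examples
#' gaussian_weights(c(0, 0.05, 1)) # 1, exp(-1/2), ~0
#' @export
gaussian_weights <- function(p_values, config = crossview_config()) {
  sigma <- config$pattern$sigma
  assert_that(is.numeric(sigma) && sigma > 0, "sigma must be positive")
  exp(-p_values^2 / (2 * sigma^2))
}

#' Normalise weights into a pattern
#'
#' Floors each weight at `pattern$epsilon` (so downstream Kullback-Leibler
#' divergences stay finite even where the Gaussian transform underflowed to
#' exactly 0), then divides by the sum. The result is a probability vector
#' over ROIs.
#'
#' @param weights Nonnegative numeric vector.
#' @inheritParams gaussian_weights
#' @return Numeric vector summing to 1.
#' @export
normalize_pattern <- function(weights, config = crossview_config()) {
  eps <- config$pattern$epsilon
  assert_that(eps > 0 && eps < 1 / length(weights),
              "epsilon must lie in (0, 1/K)")
  assert_that(all(is.finite(weights)) && all(weights >= 0),
              "weights must be finite and nonnegative")
  if (all(weights == 0))
    cv_log("all weights zero before flooring; pattern is uniform")
  w <- pmax(weights, eps)
  w / sum(w)
}

#' Compute one view's pathology pattern
#'
#' Composition of [anova_pvalues()], [gaussian_weights()] and
#' [normalize_pattern()]: the normalised weights over ROIs form the view's
#' pathology pattern, a probability vector concentrating on the regions
#' where the view separates the diagnostic groups.
#'
#' @param table A [cohort_table()].
#' @param view_name View to analyse.
#' @param config A [crossview_config()].
#' @return A `view_pattern`: list with `view_name`, `p_values`, `weights`,
#'   `normalized` and `roi_ids`.
#' @export
compute_pattern <- function(table, view_name, config = crossview_config()) {
  p <- anova_pvalues(table, view_name)
  w <- gaussian_weights(p, config)
  nrm <- normalize_pattern(w, config)
  structure(list(view_name = view_name, p_values = p, weights = w,
                 normalized = nrm, roi_ids = table$atlas$roi_ids),
            class = "view_pattern")
}

#' @export
print.view_pattern <- function(x, ...) {
  top <- order(x$normalized, decreasing = TRUE)[seq_len(min(3, length(x$normalized)))]
  cat("<view_pattern>", x$view_name, "- K =", length(x$normalized),
      "ROIs; top:", paste0("roi_", x$roi_ids[top], " (",
                           signif(x$normalized[top], 3), ")",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.view_pattern <- function(x, ...) {
  tibble::tibble(view = x$view_name, roi_id = x$roi_ids,
                 p_value = x$p_values, weight = x$weights,
                 normalized = x$normalized)
}

#' Patterns for every view of a cohort
#'
#' @param table A [cohort_table()].
#' @param config A [crossview_config()].
#' @param views Views to include (default all).
#' @return A `crossview_patterns` object (named list of `view_pattern`s).
#' @examples
#' bench <- default_benchmark(seed = 1, n_scale = 0.2)
#' pats <- compute_patterns(bench$table)
#' tidy(pats)
#' @export
compute_patterns <- function(table, config = crossview_config(),
                             views = view_names(table)) {
  out <- lapply(views, function(v) compute_pattern(table, v, config))
  names(out) <- views
  structure(out, class = "crossview_patterns")
}

#' @export
print.crossview_patterns <- function(x, ...) {
  cat("<crossview_patterns>", length(x), "view(s):",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crossview_patterns <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @exportS3Method ggplot2::autoplot
autoplot.crossview_patterns <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$roi_id),
                                   y = .data$view,
                                   fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "P″") +
    ggplot2::labs(x = "ROI", y = NULL,
                  title = "Normalised pathology patterns") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Classify ROI consistency types across views
#'
#' Tags each ROI by how consistently it discriminates across views:
#' `disease-affected` when its Gaussian weight exceeds `t_hi` in at least a
#' fraction `f_hi` of views; `disease-spared` when the weight is below
#' `t_lo` in at least `f_hi` of views; otherwise `view-specific` — the ROIs
#' whose detectability depends on the view and that drive synergy or
#' interference between views.
#'
#' @param patterns A `crossview_patterns` object (or list of `view_pattern`).
#' @param config A [crossview_config()] (uses `roi_types`).
#' @return A tibble with `roi_id`, `n_high`, `n_low`, `type`.
#' @export
classify_roi_types <- function(patterns, config = crossview_config()) {
  th <- config$roi_types
  W <- vapply(patterns, function(p) p$weights,
              numeric(length(patterns[[1]]$weights)))
  m <- ncol(W)
  n_high <- rowSums(W > th$t_hi)
  n_low <- rowSums(W < th$t_lo)
  type <- dplyr::case_when(
    n_high >= th$f_hi * m ~ "disease-affected",
    n_low >= th$f_hi * m ~ "disease-spared",
    TRUE ~ "view-specific")
  tibble::tibble(roi_id = patterns[[1]]$roi_ids, n_high = as.integer(n_high),
                 n_low = as.integer(n_low), type = type)
}
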