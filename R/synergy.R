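# Synergy analysis: does a pair of views beat its members, and does the
# divergence structure predict the joint performance?

#' Assemble synergy records for view pairs
#'
#' One record per evaluated pair per metric, combining the pair's joint
#' performance (`e_joint`), the higher and lower single-view performances
#' (`e_high`, `e_low`), three divergence summaries — `d_mutual` (sum of the
#' two directed Kullback-Leibler divergences, the quantity inside the
#' affinity exponent), `d_high` and `d_low` (max and min of the directed
#' divergences) — and whether both views sit in the same cluster.
#'
#' @param singles Tibble of single-view performance with columns `view`,
#'   `metric`, `value` (e.g. stacked [glance()] output pivoted long).
#' @param pairs Tibble of pair performance with columns `view1`, `view2`,
#'   `metric`, `value`.
#' @param divergence A [divergence_matrix()] over (at least) the views in
#'   `pairs`.
#' @param clustering Optional [cluster_views()] result used to flag
#'   same-cluster pairs.
#' @return Tibble of synergy records.
#' @export
build_synergy_records <- function(singles, pairs, divergence,
                                  clustering = NULL) {
  for (col in c("view", "metric", "value"))
    assert_that(col %in% names(singles), "singles must have column ", col)
  for (col in c("view1", "view2", "metric", "value"))
    assert_that(col %in% names(pairs), "pairs must have column ", col)
  d <- unclass(divergence)
  nm <- rownames(d)
  lookup <- function(views, metric) {
    v <- singles$value[singles$metric == metric][match(views, singles$view[singles$metric == metric])]
    v
  }
  cl <- if (!is.null(clustering)) stats::setNames(clustering$cluster,
                                                  clustering$view)
  assert_that(all(c(pairs$view1, pairs$view2) %in% singles$view),
              "missing single-view result for a view appearing in pairs")
  recs <- pairs |>
    dplyr::rowwise() |>
    dplyr::mutate(
      e_single_1 = lookup(.data$view1, .data$metric),
      e_single_2 = lookup(.data$view2, .data$metric)) |>
    dplyr::ungroup()
  # an NA single-view value (e.g. a precision undefined in every fold) keeps
  # its record; correlations drop incomplete records downstream
  assert_that(all(recs$view1 %in% nm) && all(recs$view2 %in% nm),
              "divergence matrix does not cover all paired views")
  # d[r, c] = D(col || row); directed divergences of the two patterns
  d12 <- d[cbind(match(recs$view2, nm), match(recs$view1, nm))] # D(v1 || v2)
  d21 <- d[cbind(match(recs$view1, nm), match(recs$view2, nm))] # D(v2 || v1)
  out <- tibble::tibble(
    view1 = recs$view1, view2 = recs$view2, metric = recs$metric,
    e_joint = recs$value,
    e_high = pmax(recs$e_single_1, recs$e_single_2),
    e_low = pmin(recs$e_single_1, recs$e_single_2),
    d_mutual = d12 + d21,
    d_high = pmax(d12, d21),
    d_low = pmin(d12, d21),
    same_cluster = if (is.null(cl)) NA else
      unname(cl[recs$view1] == cl[recs$view2]))
  out
}

#' Correlate joint performance with a predictor
#'
#' Pearson correlation (with the usual two-sided t-distribution p-value on
#' `n - 2` degrees of freedom) between `e_joint` and one of the candidate
#' predictors, per metric.
#'
#' @param records A [build_synergy_records()] tibble.
#' @param predictor One of `"e_high"`, `"e_low"`, `"d_mutual"`, `"d_high"`,
#'   `"d_low"`.
#' @param metric Optional metric filter; default correlates each metric
#'   present.
#' @return Tibble with `predictor`, `metric`, `rho`, `p_value`, `n`.
#' @export
correlate <- function(records,
                      predictor = c("e_high", "e_low", "d_mutual",
                                    "d_high", "d_low"),
                      metric = NULL) {
  predictor <- match.arg(predictor)
  if (!is.null(metric)) records <- records[records$metric %in% metric, ]
  records |>
    dplyr::group_by(metric = .data$metric) |>
    dplyr::group_modify(function(df, key) {
      keep <- stats::complete.cases(df$e_joint, df[[predictor]])
      df <- df[keep, ]
      assert_that(nrow(df) >= 3,
                  "need at least 3 records to correlate (metric ",
                  key$metric, ")")
      if (stats::sd(df[[predictor]]) == 0 || stats::sd(df$e_joint) == 0) {
        rlang::warn(paste0("zero-variance predictor or response for metric ",
                           key$metric, "; correlation undefined"))
        return(tibble::tibble(predictor = predictor, rho = NA_real_,
                              p_value = NA_real_, n = nrow(df)))
      }
      ct <- cor.test(df[[predictor]], df$e_joint, method = "pearson")
      tibble::tibble(predictor = predictor,
                     rho = unname(ct$estimate),
                     p_value = ct$p.value, n = nrow(df))
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("predictor")
}

#' Best-pair report
#'
#' For each metric: the best-performing pair, whether its two views come
#' from different clusters, and how many of the top `top_n` pairs are
#' inter- vs intra-cluster — the operational form of the observation that
#' the best pairs combine views from different clusters.
#'
#' @param records A [build_synergy_records()] tibble (with `same_cluster`
#'   filled in).
#' @param top_n How many top pairs to tally (default 3).
#' @return Tibble with one row per metric.
#' @export
best_pair_report <- function(records, top_n = 3) {
  assert_that(!all(is.na(records$same_cluster)),
              "records carry no clustering; pass one to build_synergy_records")
  records |>
    dplyr::group_by(metric = .data$metric) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(-df$e_joint, df$view1, df$view2), ]
      top <- utils::head(df, top_n)
      tibble::tibble(
        best_view1 = df$view1[1], best_view2 = df$view2[1],
        best_e_joint = df$e_joint[1],
        best_inter_cluster = !df$same_cluster[1],
        n_inter_top = sum(!top$same_cluster),
        n_intra_top = sum(top$same_cluster))
    }) |>
    dplyr::ungroup()
}
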