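# Pair-synergy study on the synthetic benchmark: stage every single view and
# every pair across replicate cohorts, then relate pair performance to
# single-view performance, divergence structure and archetype membership.

#' Run the single-vs-pair staging study on the synthetic benchmark
#'
#' For each seed, draws a [default_benchmark()] cohort, cross-validates the
#' cascade for all nine single views and all 36 pairs, and averages each
#' view set's metrics over seeds. Divergences and archetype membership come
#' from the first seed's cohort (the archetype structure is identical across
#' seeds). The returned records feed [correlate()] and [best_pair_report()].
#'
#' This is the workhorse behind the package's synthetic evaluation; with the
#' default reduced sizes it is deliberately cheap rather than exhaustive.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n_scale Benchmark cohort scale (see [default_benchmark()]).
#' @param config A [crossview_config()]; the staging block sets folds /
#'   budget / inner folds.
#' @param metric Metric used for the synergy records (default `"accuracy"`).
#' @return List with `singles` (view, metric, value tibble of seed-averaged
#'   means), `pairs` (view1, view2, metric, value), `records`
#'   ([build_synergy_records()] output with archetype-based `same_cluster`),
#'   `divergence`, and `archetype` (named assignment).
#' @export
run_pair_benchmark <- function(seeds, n_scale = 0.25,
                               config = crossview_config(
                                 staging = list(folds = 3, budget = 4,
                                                inner_folds = 2)),
                               metric = "accuracy") {
  first <- default_benchmark(seed = seeds[1], n_scale = n_scale)
  views <- view_names(first$table)
  sets <- all_view_sets(views)
  set_ids <- vapply(sets, paste, character(1), collapse = "|")
  per_seed <- lapply(seeds, function(s) {
    bench <- default_benchmark(seed = s, n_scale = n_scale)
    run_seeds <- child_seeds(s + 1L, length(sets))
    vapply(seq_along(sets), function(i) {
      res <- cross_validate(bench$table, sets[[i]], config,
                            seed = run_seeds[i])
      res$summary$mean[res$summary$metric == metric]
    }, numeric(1))
  })
  mean_val <- rowMeans(do.call(cbind, per_seed))
  long <- tibble::tibble(views = set_ids, metric = metric, value = mean_val)
  singles <- long[!grepl("\\|", long$views), ]
  singles <- dplyr::rename(singles, view = "views")
  pairs <- tidyr::separate(long[grepl("\\|", long$views), ],
                           "views", c("view1", "view2"), sep = "\\|")
  d <- divergence_matrix(compute_patterns(first$table, config))
  arch <- first$truth$archetype
  clustering <- tibble::tibble(view = names(arch),
                               cluster = as.integer(arch))
  records <- build_synergy_records(singles, pairs, d, clustering)
  list(singles = singles, pairs = pairs, records = records,
       divergence = d, archetype = arch)
}
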