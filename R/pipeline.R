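# End-to-end pipeline: features -> patterns -> cross-view analysis ->
# staging -> synergy, with TSV artifacts and a reproducibility manifest.

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

matrix_to_df <- function(m) {
  df <- as.data.frame(unclass(m), check.names = FALSE)
  cbind(data.frame(view = rownames(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE), df)
}

#' Extract a cohort feature table from per-subject volumes
#'
#' Runs [extract_all_views()] on each subject's volume bundle and stacks the
#' results into a [cohort_table()].
#'
#' @param volumes Data frame with columns `subject_id`, `diagnosis`,
#'   `mri`, `pet`, `labelmap` and optionally `gm` (NIfTI paths).
#' @param atlas An [roi_atlas()].
#' @param config A [crossview_config()].
#' @return A [cohort_table()].
#' @export
extract_feature_table <- function(volumes, atlas,
                                  config = crossview_config()) {
  need <- c("subject_id", "diagnosis", "mri", "pet", "labelmap")
  assert_that(all(need %in% names(volumes)),
              "volumes needs columns: ", paste(need, collapse = ", "))
  rows <- purrr::pmap_dfr(volumes, function(...) {
    row <- list(...)
    bundle <- read_volume_bundle(row$mri, row$pet, row$labelmap, atlas,
                                 gm_path = row$gm)
    feats <- extract_all_views(bundle, config)
    purrr::imap_dfr(feats, function(v, nm) {
      dplyr::bind_cols(
        tibble::tibble(subject_id = row$subject_id,
                       diagnosis = row$diagnosis, view = nm),
        tibble::as_tibble(as.list(v)))
    })
  })
  cohort_table(rows, atlas)
}

all_view_sets <- function(views) {
  singles <- as.list(views)
  pairs <- utils::combn(views, 2, simplify = FALSE)
  c(singles, pairs)
}

#' Run the five-step cross-view analysis pipeline
#'
#' Takes a cohort feature table (object, TSV path, or per-subject volume
#' listing), computes per-view pathology patterns, the cross-view divergence
#' / affinity / spectral clustering, cross-validated staging for the
#' requested view sets, and the synergy analysis relating pair performance
#' to single-view performance and divergence. All artifacts are written as
#' TSV under `output_dir` together with a JSON manifest (inputs, config
#' hash, seed, output checksums). Reruns with identical inputs and seed
#' reproduce every TSV bitwise.
#'
#' @param input A [cohort_table()], a feature-table TSV path (requires
#'   `atlas`), or a data frame of per-subject volume paths (see
#'   [extract_feature_table()]).
#' @param output_dir Output directory (created if needed).
#' @param config A [crossview_config()].
#' @param atlas An [roi_atlas()]; required when `input` is a path or volume
#'   listing.
#' @param view_sets List of character vectors of views to stage; `"auto"`
#'   stages every single view and every pair.
#' @param seed Integer seed for staging and clustering.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(input, output_dir, config = crossview_config(),
                         atlas = NULL, view_sets = "auto",
                         seed = config$seed) {
  stage_ctx <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_cv("pipeline stage '", stage, "' failed: ", conditionMessage(e),
              class = "crossview_stage_error"))
  }
  table <- stage_ctx("ingest", {
    if (inherits(input, "cohort_table")) input
    else if (is.character(input)) {
      assert_that(!is.null(atlas), "reading a table path requires an atlas")
      read_feature_table(input, atlas)
    } else if (is.data.frame(input)) {
      assert_that(!is.null(atlas), "extracting from volumes requires an atlas")
      extract_feature_table(input, atlas, config)
    } else stop_cv("unsupported input type")
  })
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(output_dir, name)
  paths <- character()

  patterns <- stage_ctx("patterns", compute_patterns(table, config))
  paths["patterns"] <- write_tsv_plain(tidy(patterns), out("patterns.tsv"))

  cross <- stage_ctx("cross", {
    d <- divergence_matrix(patterns)
    a <- affinity_matrix(d)
    emb <- spectral_embed(a, k = config$cross$k,
                          include_trivial = config$cross$include_trivial)
    cl <- cluster_views(emb, n_clusters = config$cross$n_clusters,
                        seed = seed, restarts = config$cross$kmeans_restarts,
                        row_normalize = config$cross$row_normalize)
    list(d = d, a = a, emb = emb, cl = cl)
  })
  paths["divergence"] <- write_tsv_plain(matrix_to_df(cross$d),
                                         out("divergence.tsv"))
  paths["affinity"] <- write_tsv_plain(matrix_to_df(cross$a),
                                       out("affinity.tsv"))
  paths["embedding"] <- write_tsv_plain(tidy(cross$emb), out("embedding.tsv"))
  paths["clusters"] <- write_tsv_plain(cross$cl, out("clusters.tsv"))

  sets <- if (identical(view_sets, "auto")) all_view_sets(view_names(table))
          else view_sets
  seeds <- child_seeds(seed, length(sets))
  staging <- stage_ctx("staging", {
    purrr::imap(sets, function(vs, i)
      cross_validate(table, vs, config, seed = seeds[[as.integer(i)]]))
  })
  staging_tbl <- purrr::map_dfr(staging, tidy)
  paths["staging"] <- write_tsv_plain(staging_tbl, out("staging.tsv"))

  synergy <- stage_ctx("synergy", {
    long <- staging_tbl |>
      dplyr::select(views = "views", metric = "metric", value = "mean")
    singles <- long[!grepl("\\|", long$views), ] |>
      dplyr::rename(view = "views")
    pairs <- long[grepl("\\|", long$views), ]
    if (nrow(pairs) == 0) return(NULL)
    pairs <- tidyr::separate(pairs, "views", c("view1", "view2"), sep = "\\|")
    recs <- build_synergy_records(singles, pairs, cross$d, cross$cl)
    n_pairs <- nrow(dplyr::distinct(recs, .data$view1, .data$view2))
    cors <- if (n_pairs >= 3) {
      purrr::map_dfr(c("e_high", "e_low", "d_mutual", "d_high", "d_low"),
                     function(p) correlate(recs, p))
    } else { # too few pairs for a meaningful correlation; header-only table
      tibble::tibble(predictor = character(), metric = character(),
                     rho = numeric(), p_value = numeric(), n = integer())
    }
    list(records = recs, correlations = cors,
         best = best_pair_report(recs))
  })
  if (!is.null(synergy)) {
    paths["synergy"] <- write_tsv_plain(synergy$records, out("synergy.tsv"))
    paths["correlations"] <- write_tsv_plain(synergy$correlations,
                                             out("correlations.tsv"))
    paths["best_pairs"] <- write_tsv_plain(synergy$best, out("best_pairs.tsv"))
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    created = "run manifest",
    n_subjects = nrow(table$subjects),
    n_views = length(view_names(table)),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(unlist(paths))),
                                      names(paths))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
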