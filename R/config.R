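#' Analysis configuration
#'
#' One nested list drives every tunable in the package. `crossview_config()`
#' returns the defaults, optionally overridden; `read_config()` loads a YAML
#' file and merges it over the defaults, rejecting unknown keys so typos do
#' not silently fall back to defaults.
#'
#' Key groups and their meaning:
#' \describe{
#'   \item{seed}{Base seed for every randomized operation (default 20160223).}
#'   \item{pattern}{`sigma`: bandwidth of the Gaussian p-value transform, in
#'     p-value units (default 0.05). `epsilon`: probability floor applied
#'     before pattern normalisation so divergences stay finite (default
#'     1e-12).}
#'   \item{roi_types}{`t_hi`, `t_lo`, `f_hi`: weight thresholds and view
#'     fraction used to tag ROIs as disease-affected / disease-spared /
#'     view-specific.}
#'   \item{geometry}{`smooth_sigma`: Gaussian pre-smoothing of binary masks
#'     (voxels) before iso-surfacing; `close_radius`: ball radius (voxels) of
#'     the morphological closing that defines the outer envelope for the
#'     gyrification index.}
#'   \item{gm}{`quantiles`: intensity window (within-brain quantiles) used as
#'     a gray-matter proxy when no GM mask is supplied.}
#'   \item{dog}{Difference-of-Gaussian lesion detection: `scales` (mm),
#'     `ratio` between the two Gaussians, `threshold` on the negative
#'     response in cerebellum-normalised units, and `lesion_fallback`
#'     (`"roi"` or `"global"`) for lesion-free ROIs in the lesion-mean view.}
#'   \item{cross}{`k`: embedding dimension; `n_clusters`: number of view
#'     clusters; `include_trivial`: keep the 0-eigenvalue mode as the first
#'     embedding coordinate; `row_normalize`: row-normalise the embedding
#'     before k-means.}
#'   \item{staging}{`folds`, `inner_folds`, `budget`, `cost_range`,
#'     `gamma_range`, `stage3_restrict_mci` for the cascade classifier.}
#' }
#'
#' @param ... Named overrides, e.g. `crossview_config(pattern = list(sigma = 0.1))`.
#'   Partial group lists are merged over the group defaults.
#' @return A nested list of class `crossview_config`.
#' @examples
#' cfg <- crossview_config(pattern = list(sigma = 0.1))
#' cfg$pattern$sigma
#' @export
crossview_config <- function(...) {
  defaults <- list(
    seed = 20160223,
    pattern = list(sigma = 0.05, epsilon = 1e-12),
    roi_types = list(t_hi = 0.5, t_lo = 0.1, f_hi = 2 / 3),
    geometry = list(smooth_sigma = 0.8, close_radius = 5),
    gm = list(quantiles = c(0.3, 0.7)),
    dog = list(scales = c(1, 2, 4), ratio = 1.6, threshold = 0.1,
               lesion_fallback = "roi"),
    cross = list(k = 2, n_clusters = 4, include_trivial = TRUE,
                 row_normalize = FALSE, kmeans_restarts = 50),
    staging = list(folds = 5, inner_folds = 3, budget = 60,
                   cost_range = c(1e-2, 1e3), gamma_range = c(1e-4, 1e1),
                   stage3_restrict_mci = FALSE)
  )
  merged <- merge_config(defaults, list(...), path = "")
  structure(merged, class = c("crossview_config", "list"))
}

merge_config <- function(base, override, path = "") {
  if (length(override) == 0) return(base)
  nm <- names(override)
  assert_that(!is.null(nm) && all(nzchar(nm)), "config overrides must be named")
  unknown <- setdiff(nm, names(base))
  assert_that(length(unknown) == 0,
              "unknown config key(s): ",
              paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      ov <- override[[k]]
      assert_that(is.list(ov), "config key '", k, "' must be a list")
      base[[k]] <- merge_config(base[[k]], ov, path = paste0(path, ".", k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' @rdname crossview_config
#' @param path Path to a YAML configuration file.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(crossview_config, raw %||% list())
}

#' @export
print.crossview_config <- function(x, ...) {
  cat("<crossview_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
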