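#' Declare an ROI atlas
#'
#' An ROI atlas declares the `K` region labels that a labelmap (and every
#' per-ROI feature vector) is interpreted against: the integer label ids,
#' human-readable names, an anatomical category per region, and which regions
#' form the cerebellum (used as the metabolic reference when PET views are
#' extracted).
#'
#' @param roi_ids Integer vector of strictly positive, unique label ids
#'   (length `K >= 2`). Order is authoritative: feature vectors and table
#'   columns follow it.
#' @param roi_names Character vector of names, one per id. Defaults to
#'   `"roi_<id>"`.
#' @param category Character vector of anatomical categories, one per id,
#'   each one of `"cortical"`, `"ventricle"`, `"central-structure"`,
#'   `"cerebellum"`, `"brainstem"`, `"other-noncortical"`. Defaults to
#'   `"cortical"`, except ids listed in `cerebellum_ids`.
#' @param cerebellum_ids Integer vector, subset of `roi_ids`, naming the
#'   cerebellar reference regions. May be empty for MRI-only analyses.
#'
#' @return An object of class `roi_atlas`.
#' @examples
#' atlas <- roi_atlas(1:4, cerebellum_ids = 4L)
#' atlas
#' @export
roi_atlas <- function(roi_ids, roi_names = NULL, category = NULL,
                      cerebellum_ids = integer()) {
  roi_ids <- as.integer(roi_ids)
  assert_that(length(roi_ids) >= 2, "an atlas needs at least 2 ROIs (K >= 2)")
  assert_that(!anyNA(roi_ids) && all(roi_ids > 0),
              "roi_ids must be strictly positive integers")
  assert_that(!anyDuplicated(roi_ids), "roi_ids must be unique")
  cerebellum_ids <- as.integer(cerebellum_ids)
  assert_that(all(cerebellum_ids %in% roi_ids),
              "cerebellum_ids must be a subset of roi_ids")
  if (is.null(roi_names)) roi_names <- paste0("roi_", roi_ids)
  assert_that(length(roi_names) == length(roi_ids),
              "roi_names must have one entry per roi_id")
  if (is.null(category)) {
    category <- rep("cortical", length(roi_ids))
    category[roi_ids %in% cerebellum_ids] <- "cerebellum"
  }
  assert_that(length(category) == length(roi_ids),
              "category must have one entry per roi_id")
  bad <- setdiff(unique(category), ROI_CATEGORIES)
  assert_that(length(bad) == 0,
              "unknown ROI category: ", paste(bad, collapse = ", "))
  structure(
    list(roi_ids = roi_ids, roi_names = as.character(roi_names),
         category = as.character(category), cerebellum_ids = cerebellum_ids),
    class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("<roi_atlas> K =", length(x$roi_ids), "ROIs;",
      length(x$cerebellum_ids), "cerebellar reference region(s)\n")
  tab <- table(x$category)
  cat("  categories:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.roi_atlas <- function(x) length(x$roi_ids)

# Column names used for the ROI block in feature tables.
atlas_columns <- function(atlas) paste0("roi_", atlas$roi_ids)

#' @rdname roi_atlas
#' @export
#' @param x Object to test.
is_roi_atlas <- function(x) inherits(x, "roi_atlas")
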