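# The nine per-ROI biomarker views.
#
# MRI morphometry: GMV (gray-matter volume fraction of intracranial volume),
# LGI (buried-to-outer surface ratio), CNV (hull area / surface area), SLD
# (volume / hull volume). PET metabolism: M-IDX (cerebellum-normalised mean
# activity), F-IDX (coefficient of variation), and three lesion descriptors
# driven by multi-scale Difference-of-Gaussian detection: DoG-M (lesion mean
# activity), DoG-C (lesion vs non-lesion contrast), DoG-Z (lesion voxel
# fraction).

# Per-ROI voxel value lists, in atlas order (empty for absent ROIs).
roi_values <- function(vol, labelmap, atlas) {
  lab <- as.integer(labelmap)
  inside <- lab != 0L
  split(as.numeric(vol)[inside],
        factor(lab[inside], levels = atlas$roi_ids))[as.character(atlas$roi_ids)]
}

named_feature <- function(values, atlas, view_name) {
  names(values) <- atlas_columns(atlas)
  attr(values, "view_name") <- view_name
  values
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

gm_mask_of <- function(bundle, config) {
  if (!is.null(bundle$gm_mask)) return(bundle$gm_mask)
  q <- config$gm$quantiles
  assert_that(!is.null(q) && length(q) == 2,
              "no gray-matter definition: supply gm_mask or config$gm$quantiles")
  inside <- bundle$labelmap != 0L
  w <- quantile(bundle$mri[inside], probs = q, names = FALSE)
  bundle$mri >= w[1] & bundle$mri <= w[2] & inside
}

#' Gray-matter volume fraction (GMV)
#'
#' For cortical ROIs, the gray-matter volume inside the ROI divided by the
#' intracranial volume (all labelled voxels); non-cortical ROIs (ventricles,
#' central structures, cerebellum, brainstem, other non-cortical regions)
#' use their whole volume instead, since "gray matter" is not meaningful
#' there. The ratio is invariant to voxel spacing
#' and global intensity scale. If the bundle has no GM mask, an MRI intensity
#' window (config `gm$quantiles` of within-brain intensities) is used as a
#' phantom-friendly stand-in.
#'
#' @param bundle A [volume_bundle()].
#' @param config A [crossview_config()].
#' @return Named numeric vector of length `K` (atlas order).
#' @export
extract_gmv <- function(bundle, config = crossview_config()) {
  atlas <- bundle$atlas
  gm <- gm_mask_of(bundle, config)
  icv <- sum(bundle$labelmap != 0L)
  assert_that(icv > 0, "no ROIs present")
  lab <- as.integer(bundle$labelmap)
  counts_all <- tabulate(factor(lab[lab != 0L], levels = atlas$roi_ids),
                         nbins = length(atlas))
  labg <- lab[as.logical(gm) & lab != 0L]
  counts_gm <- tabulate(factor(labg, levels = atlas$roi_ids),
                        nbins = length(atlas))
  use_whole <- atlas$category != "cortical"
  vals <- ifelse(use_whole, counts_all, counts_gm) / icv
  named_feature(vals, atlas, "GMV")
}

#' Local gyrification index (LGI)
#'
#' Ratio of a cortical ROI's full (folded) surface area to the area of its
#' outer envelope, where the envelope is the morphological closing of the
#' ROI mask with a ball of `geometry$close_radius` voxels. A heavily folded
#' cortex buries surface inside sulci, so LGI > 1; atrophy flattens folds and
#' lowers it. Non-cortical ROIs report their raw surface area in mm^2.
#'
#' @inheritParams extract_gmv
#' @return Named numeric vector of length `K`.
#' @export
extract_lgi <- function(bundle, config = crossview_config()) {
  atlas <- bundle$atlas
  sig <- config$geometry$smooth_sigma
  vals <- vapply(seq_along(atlas$roi_ids), function(i) {
    id <- atlas$roi_ids[i]
    geo <- roi_geometry(bundle, id, smooth_sigma = sig)
    if (atlas$category[i] == "cortical") {
      env <- envelope_area(bundle, id, config$geometry$close_radius, sig)
      geo$surface_area / env
    } else {
      geo$surface_area
    }
  }, numeric(1))
  named_feature(vals, atlas, "LGI")
}

#' Convexity ratio (CNV)
#'
#' Area of the convex hull surface divided by the area of the ROI surface.
#' Roughening/folding of the ROI surface grows the denominator while the
#' hull barely changes, so CNV falls as the surface gets more convoluted;
#' it is 1 for convex shapes.
#'
#' @inheritParams extract_gmv
#' @return Named numeric vector of length `K`.
#' @export
extract_cnv <- function(bundle, config = crossview_config()) {
  atlas <- bundle$atlas
  vals <- vapply(atlas$roi_ids, function(id) {
    geo <- roi_geometry(bundle, id, smooth_sigma = config$geometry$smooth_sigma)
    geo$hull_area / geo$surface_area
  }, numeric(1))
  named_feature(vals, atlas, "CNV")
}

#' Solidity ratio (SLD)
#'
#' ROI volume divided by its convex-hull volume: 1 for solid convex shapes,
#' small for hollowed or C-shaped regions. Atrophic shrinkage away from the
#' hull lowers it.
#'
#' @inheritParams extract_gmv
#' @return Named numeric vector of length `K`.
#' @export
extract_sld <- function(bundle, config = crossview_config()) {
  atlas <- bundle$atlas
  vals <- vapply(atlas$roi_ids, function(id) {
    geo <- roi_geometry(bundle, id, smooth_sigma = config$geometry$smooth_sigma)
    geo$volume / geo$hull_volume
  }, numeric(1))
  named_feature(vals, atlas, "SLD")
}

#' Cerebellar reference activity
#'
#' Mean PET value over all voxels of the atlas's cerebellar ROIs, the
#' conventional intensity reference in FDG-PET of dementia (the cerebellum
#' is relatively spared). All PET views are expressed relative to it.
#'
#' @inheritParams extract_gmv
#' @return A positive scalar.
#' @export
cerebellum_reference <- function(bundle, config = crossview_config()) {
  atlas <- bundle$atlas
  assert_that(length(atlas$cerebellum_ids) > 0,
              "atlas declares no cerebellum ROIs; cannot normalise PET views")
  sel <- bundle$labelmap %in% atlas$cerebellum_ids
  assert_that(any(sel), "cerebellum ROIs are empty in the labelmap")
  mean(bundle$pet[sel])
}

#' Mean metabolic index (M-IDX)
#'
#' Mean PET activity of each ROI divided by the cerebellar reference, which
#' removes global intensity variation between acquisitions.
#'
#' @inheritParams extract_gmv
#' @param reference Optional precomputed [cerebellum_reference()].
#' @return Named numeric vector of length `K`.
#' @export
extract_midx <- function(bundle, config = crossview_config(),
                         reference = NULL) {
  atlas <- bundle$atlas
  ref <- reference %||% cerebellum_reference(bundle, config)
  vals <- vapply(roi_values(bundle$pet, bundle$labelmap, atlas),
                 function(v) if (length(v) == 0) NA_real_ else mean(v) / ref,
                 numeric(1))
  named_feature(vals, atlas, "M-IDX")
}

#' Fuzzy index (F-IDX)
#'
#' Coefficient of variation of PET activity within each ROI (population
#' standard deviation over mean). Partially hypometabolic ROIs mix normal
#' and depressed voxels and therefore score high; metabolically uniform
#' ROIs score near 0. ROIs with non-positive mean get NaN and a warning.
#'
#' @inheritParams extract_gmv
#' @return Named numeric vector of length `K`.
#' @export
extract_fidx <- function(bundle, config = crossview_config()) {
  atlas <- bundle$atlas
  vals <- vapply(roi_values(bundle$pet, bundle$labelmap, atlas), function(v) {
    if (length(v) == 0) return(NA_real_)
    m <- mean(v)
    if (m <= 0) return(NaN)
    pop_sd(v) / m
  }, numeric(1))
  if (any(is.nan(vals)))
    rlang::warn("F-IDX: ROI(s) with non-positive mean activity set to NaN")
  named_feature(vals, atlas, "F-IDX")
}

#' Detect hypometabolic lesions with a multi-scale DoG filter
#'
#' The cerebellum-normalised PET volume is band-pass filtered with
#' Difference-of-Gaussian kernels at each scale in `config$dog$scales` (mm):
#' `(G(s) - G(ratio * s)) / (ratio - 1)` where the `1/(ratio-1)` factor is
#' the usual scale-space normalisation making the response approximate the
#' blob depth. A voxel is lesional when its most negative response over
#' scales falls below `-threshold` and it lies inside the brain.
#'
#' @inheritParams extract_gmv
#' @param reference Optional precomputed [cerebellum_reference()].
#' @return A `lesion_map`: list with `mask` (3D logical), `scales`,
#'   `threshold`.
#' @export
detect_lesions <- function(bundle, config = crossview_config(),
                           reference = NULL) {
  atlas <- bundle$atlas
  brain <- bundle$labelmap != 0L
  assert_that(any(brain), "all-background volume; nothing to detect")
  ref <- reference %||% cerebellum_reference(bundle, config)
  petn <- bundle$pet / ref
  dims <- dim(petn)
  ratio <- config$dog$ratio
  resp_min <- array(Inf, dims)
  for (s in config$dog$scales) {
    sv <- s / bundle$spacing
    g1 <- cv_gauss3d(petn, dims, sv)
    g2 <- cv_gauss3d(petn, dims, ratio * sv)
    resp <- (g1 - g2) / (ratio - 1)
    resp_min <- pmin(resp_min, resp)
  }
  mask <- resp_min < -config$dog$threshold & brain
  structure(list(mask = mask, scales = config$dog$scales,
                 threshold = config$dog$threshold),
            class = "lesion_map")
}

#' DoG lesion views: mean, contrast, and fraction
#'
#' Given a lesion mask, three descriptors summarise each ROI:
#' * `extract_dogm()` — mean cerebellum-normalised activity over the ROI's
#'   lesional voxels. Lesion-free ROIs fall back to the ROI's mean index
#'   (`lesion_fallback = "roi"`, preserving activity-level semantics) or to
#'   the brain-wide lesion mean (`"global"`).
#' * `extract_dogc()` — variance-corrected contrast between non-lesion and
#'   lesion parts, `(mu_n - mu_l) / sqrt(sd_l^2 + sd_n^2 + 1e-12)` (a pooled
#'   t-like statistic); 0 when either part is empty.
#' * `extract_dogz()` — fraction of the ROI's voxels that are lesional, in
#'   `[0, 1]`; a proxy for disease progression.
#'
#' @inheritParams extract_gmv
#' @param lesions A `lesion_map` from [detect_lesions()], or any 3D logical
#'   mask of the PET shape.
#' @param reference Optional precomputed [cerebellum_reference()].
#' @return Named numeric vector of length `K`.
#' @export
extract_dogm <- function(bundle, lesions, config = crossview_config(),
                         reference = NULL) {
  atlas <- bundle$atlas
  mask <- lesion_mask(lesions, bundle)
  ref <- reference %||% cerebellum_reference(bundle, config)
  petn <- bundle$pet / ref
  midx <- extract_midx(bundle, config, reference = ref)
  global_mean <- if (any(mask)) mean(petn[mask]) else NA_real_
  lesional <- roi_values(petn * NA^(!mask), bundle$labelmap, atlas)
  vals <- vapply(seq_along(lesional), function(i) {
    v <- lesional[[i]][!is.na(lesional[[i]])]
    if (length(v) > 0) return(mean(v))
    if (identical(config$dog$lesion_fallback, "global") && !is.na(global_mean))
      global_mean
    else midx[[i]]
  }, numeric(1))
  named_feature(vals, atlas, "DoG-M")
}

#' @rdname extract_dogm
#' @export
extract_dogc <- function(bundle, lesions, config = crossview_config(),
                         reference = NULL) {
  atlas <- bundle$atlas
  mask <- lesion_mask(lesions, bundle)
  ref <- reference %||% cerebellum_reference(bundle, config)
  petn <- bundle$pet / ref
  les <- roi_values(petn * NA^(!mask), bundle$labelmap, atlas)
  non <- roi_values(petn * NA^(mask), bundle$labelmap, atlas)
  vals <- vapply(seq_along(les), function(i) {
    l <- les[[i]][!is.na(les[[i]])]
    n <- non[[i]][!is.na(non[[i]])]
    if (length(l) == 0 || length(n) == 0) return(0)
    (mean(n) - mean(l)) / sqrt(pop_sd(l)^2 + pop_sd(n)^2 + 1e-12)
  }, numeric(1))
  named_feature(vals, atlas, "DoG-C")
}

#' @rdname extract_dogm
#' @export
extract_dogz <- function(bundle, lesions, config = crossview_config()) {
  atlas <- bundle$atlas
  mask <- lesion_mask(lesions, bundle)
  lab <- as.integer(bundle$labelmap)
  n_all <- tabulate(factor(lab[lab != 0L], levels = atlas$roi_ids),
                    nbins = length(atlas))
  labl <- lab[as.logical(mask) & lab != 0L]
  n_les <- tabulate(factor(labl, levels = atlas$roi_ids),
                    nbins = length(atlas))
  vals <- ifelse(n_all > 0, n_les / n_all, NA_real_)
  named_feature(vals, atlas, "DoG-Z")
}

lesion_mask <- function(lesions, bundle) {
  mask <- if (inherits(lesions, "lesion_map")) lesions$mask else lesions
  assert_that(identical(dim(mask), dim(bundle$pet)),
              "lesion mask shape does not match the PET volume")
  as.logical(mask) & bundle$labelmap != 0L
}

#' Extract all nine biomarker views from one subject's volumes
#'
#' Runs the four MRI morphometry views and five PET metabolism views,
#' computing the cerebellar reference and the DoG lesion mask once and
#' sharing them across the lesion descriptors.
#'
#' @inheritParams extract_gmv
#' @return Named list of nine length-`K` feature vectors (`GMV`, `LGI`,
#'   `CNV`, `SLD`, `M-IDX`, `F-IDX`, `DoG-M`, `DoG-C`, `DoG-Z`).
#' @examples
#' ph <- generate_phantom(phantom_spec(), seed = 1)
#' views <- extract_all_views(ph$bundle)
#' names(views)
#' @export
extract_all_views <- function(bundle, config = crossview_config()) {
  ref <- cerebellum_reference(bundle, config)
  lesions <- detect_lesions(bundle, config, reference = ref)
  list(
    "GMV" = extract_gmv(bundle, config),
    "LGI" = extract_lgi(bundle, config),
    "CNV" = extract_cnv(bundle, config),
    "SLD" = extract_sld(bundle, config),
    "M-IDX" = extract_midx(bundle, config, reference = ref),
    "F-IDX" = extract_fidx(bundle, config),
    "DoG-M" = extract_dogm(bundle, lesions, config, reference = ref),
    "DoG-C" = extract_dogc(bundle, lesions, config, reference = ref),
    "DoG-Z" = extract_dogz(bundle, lesions, config)
  )
}
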