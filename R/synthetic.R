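# Synthetic ground-truth generators: phantom volume bundles with analytically
# known geometry and planted hypometabolic lesions, and cohort feature tables
# with latent view-archetype structure. They emulate the *structure* the
# analysis assumes (graded group effects on a subset of ROIs, views sharing
# or not sharing pathology patterns), not brain anatomy or MR/PET physics.

#' Phantom specification
#'
#' Describes a multi-label phantom volume: grid, spacing, a list of
#' non-overlapping shapes (each becoming one ROI label), planted Gaussian
#' hypometabolic dips in the PET channel, and additive Gaussian noise.
#'
#' Default shapes: a solid ball (r = 10), a solid box, a ball with 8 radial
#' finger indentations, a C-shaped (270-degree torus arc) region, and a ball
#' tagged as cerebellum to serve as the PET reference. The defaults plant one
#' dip (depth 0.4, sigma 3 mm) in the ball and a smaller one in the box.
#'
#' @param grid_shape Integer length-3 grid (default 64^3).
#' @param spacing Voxel spacing, mm.
#' @param roi_shapes List of shape descriptors; see defaults for the format.
#' @param lesion_specs List of `list(center, sigma, depth)` dips
#'   (normalised activity units).
#' @param background_activity Constant PET background.
#' @param noise_sd Gaussian noise sd added to both channels (>= 0).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                         roi_shapes = NULL, lesion_specs = NULL,
                         background_activity = 1, noise_sd = 0.01) {
  if (is.null(roi_shapes)) {
    roi_shapes <- list(
      list(type = "ball", label = 1L, center = c(18, 18, 20), r = 10,
           category = "cortical", mri = 100),
      list(type = "box", label = 2L, lo = c(38, 10, 10), size = c(14, 14, 14),
           category = "cortical", mri = 90),
      list(type = "indented_ball", label = 3L, center = c(18, 46, 20), r = 9,
           n_fingers = 8, finger_r = 3, category = "cortical", mri = 95),
      list(type = "c_shape", label = 4L, center = c(46, 44, 22), R = 11, r = 3,
           arc = 270, category = "other-noncortical", mri = 85),
      list(type = "ball", label = 5L, center = c(32, 32, 48), r = 8,
           category = "cerebellum", mri = 80))
  }
  if (is.null(lesion_specs)) {
    lesion_specs <- list(list(center = c(18, 18, 20), sigma = 3, depth = 0.4),
                         list(center = c(45, 17, 17), sigma = 2.5, depth = 0.3))
  }
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 roi_shapes = roi_shapes, lesion_specs = lesion_specs,
                 background_activity = background_activity,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

grid_coords <- function(dims) {
  list(x = slice.index(array(0, dims), 1),
       y = slice.index(array(0, dims), 2),
       z = slice.index(array(0, dims), 3))
}

rasterize_shape <- function(shape, co) {
  switch(shape$type,
    ball = {
      (co$x - shape$center[1])^2 + (co$y - shape$center[2])^2 +
        (co$z - shape$center[3])^2 <= shape$r^2
    },
    box = {
      hi <- shape$lo + shape$size - 1
      co$x >= shape$lo[1] & co$x <= hi[1] &
        co$y >= shape$lo[2] & co$y <= hi[2] &
        co$z >= shape$lo[3] & co$z <= hi[3]
    },
    indented_ball = {
      m <- (co$x - shape$center[1])^2 + (co$y - shape$center[2])^2 +
        (co$z - shape$center[3])^2 <= shape$r^2
      ang <- 2 * pi * seq_len(shape$n_fingers) / shape$n_fingers
      for (a in ang) {
        fc <- shape$center + shape$r * c(cos(a), sin(a), 0)
        m <- m & !((co$x - fc[1])^2 + (co$y - fc[2])^2 +
                     (co$z - fc[3])^2 <= shape$finger_r^2)
      }
      m
    },
    c_shape = {
      rad <- sqrt((co$x - shape$center[1])^2 + (co$y - shape$center[2])^2)
      theta <- atan2(co$y - shape$center[2], co$x - shape$center[1])
      theta <- (theta %% (2 * pi)) * 180 / pi
      (rad - shape$R)^2 + (co$z - shape$center[3])^2 <= shape$r^2 &
        theta <= shape$arc
    },
    stop_cv("unknown shape type: ", shape$type))
}

#' Generate a phantom volume bundle with known ground truth
#'
#' Builds the labelmap from the spec's shapes, an MRI channel with
#' shape-specific constant intensities, a gray-matter mask as the 2-voxel
#' outer shell of each cortical shape, and a PET channel
#' `background * (1 - sum of Gaussian dips) + noise`. Deterministic under a
#' fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise.
#' @return List with `bundle` (a [volume_bundle()]) and `truth` (per-ROI
#'   voxel counts, the planted lesion support at half depth, per-ROI lesion
#'   fractions, and the dip field).
#' @export
generate_phantom <- function(spec, seed = 20160223) {
  dims <- spec$grid_shape
  co <- grid_coords(dims)
  labelmap <- array(0L, dims)
  mri <- array(0, dims)
  gm <- array(FALSE, dims)
  for (shape in spec$roi_shapes) {
    m <- rasterize_shape(shape, co)
    assert_that(!any(labelmap[m] != 0L), "phantom shapes overlap (label ",
                shape$label, ")")
    labelmap[m] <- shape$label
    mri[m] <- shape$mri
    if (identical(shape$category, "cortical")) {
      shell <- m & !cv_ball_erode(m, dims, 2)
      gm <- gm | shell
    }
  }
  dip <- array(0, dims)
  support <- array(FALSE, dims)
  for (les in spec$lesion_specs) {
    d2 <- (co$x - les$center[1])^2 + (co$y - les$center[2])^2 +
      (co$z - les$center[3])^2
    g <- les$depth * exp(-d2 / (2 * les$sigma^2))
    dip <- dip + g
    if (les$depth > 0) support <- support | (g >= les$depth / 2)
  }
  pet <- spec$background_activity * (1 - dip)
  local_seed(seed, {
    if (spec$noise_sd > 0) {
      mri <- mri + rnorm(length(mri), sd = spec$noise_sd)
      pet <- pet + rnorm(length(pet), sd = spec$noise_sd)
    }
  })
  cats <- vapply(spec$roi_shapes, `[[`, character(1), "category")
  labels <- vapply(spec$roi_shapes, `[[`, integer(1), "label")
  atlas <- roi_atlas(labels, category = cats,
                     cerebellum_ids = labels[cats == "cerebellum"])
  bundle <- volume_bundle(mri, pet, labelmap, atlas, gm_mask = gm,
                          spacing = spec$spacing)
  support <- support & labelmap != 0L
  n_vox <- vapply(labels, function(l) sum(labelmap == l), numeric(1))
  n_les <- vapply(labels, function(l) sum(support & labelmap == l), numeric(1))
  truth <- list(
    roi_voxels = stats::setNames(n_vox, labels),
    lesion_support = support,
    lesion_fraction = stats::setNames(n_les / n_vox, labels),
    dip = dip)
  list(bundle = bundle, truth = truth)
}

#' Cohort specification
#'
#' Latent-archetype model for synthetic cohort feature tables. Each view is
#' assigned to one archetype, a normalised loading vector over ROIs; the
#' feature of subject `s` (group `g`) for view `v` at ROI `i` is
#'
#' `mu0 + delta_g * noise_sd * loading(i)/max(loading) * scale_v + N(0, noise_sd^2)`
#'
#' so `delta_g` is the per-ROI standardised effect size (Cohen's d vs NC) on
#' the archetype's fully loaded ROIs, graded over groups
#' (`0 = delta_NC <= delta_MCI <= delta_AD`). Views sharing an archetype
#' share their expected ANOVA pattern (low mutual divergence); disjoint
#' archetypes give divergent patterns.
#'
#' @param n_per_group Subject counts `(NC, MCI, AD)`.
#' @param K Number of ROIs.
#' @param archetypes `C x K` matrix of nonnegative loadings, rows summing
#'   to 1. Default: 4 archetypes uniform over disjoint blocks of
#'   `floor(K/4)` ROIs (at most 20 each).
#' @param view_assignment Named integer vector, view name -> archetype row.
#'   Default: the nine standard views split 3/1/3/2 across 4 archetypes.
#' @param effect_sizes `(NC, MCI, AD)` standardised shifts; NC must be 0.
#' @param view_scale Named per-view effect multipliers (view quality);
#'   default 1.
#' @param noise_sd Gaussian noise sd.
#' @param mu0 Baseline feature level.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(NC = 77, MCI = 169, AD = 85),
                        K = 83, archetypes = NULL, view_assignment = NULL,
                        effect_sizes = c(NC = 0, MCI = 0.6, AD = 1.2),
                        view_scale = NULL, noise_sd = 1, mu0 = 1) {
  n_per_group <- stats::setNames(as.integer(n_per_group), DIAGNOSIS_LEVELS)
  if (is.null(view_assignment))
    view_assignment <- c("GMV" = 1L, "LGI" = 1L, "CNV" = 1L, "SLD" = 2L,
                         "F-IDX" = 3L, "DoG-C" = 3L, "DoG-Z" = 3L,
                         "M-IDX" = 4L, "DoG-M" = 4L)
  n_arch <- max(view_assignment)
  if (is.null(archetypes)) {
    assert_that(K >= n_arch, "K must be at least the number of archetypes")
    block <- min(20L, max(1L, K %/% n_arch))
    archetypes <- matrix(0, n_arch, K)
    for (a in seq_len(n_arch)) {
      idx <- ((a - 1) * block + 1):(a * block)
      archetypes[a, idx] <- 1 / block
    }
  }
  assert_that(nrow(archetypes) >= n_arch,
              "archetypes matrix has fewer rows than assigned archetypes")
  assert_that(ncol(archetypes) == K, "archetypes must have K columns")
  assert_that(all(abs(rowSums(archetypes) - 1) < 1e-8),
              "archetype loading rows must sum to 1")
  assert_that(effect_sizes[1] == 0, "delta_NC must be 0")
  assert_that(!is.unsorted(effect_sizes),
              "effect sizes must satisfy 0 = delta_NC <= delta_MCI <= delta_AD")
  if (is.null(view_scale))
    view_scale <- stats::setNames(rep(1, length(view_assignment)),
                                  names(view_assignment))
  structure(list(n_per_group = n_per_group, K = as.integer(K),
                 archetypes = archetypes, view_assignment = view_assignment,
                 effect_sizes = stats::setNames(effect_sizes, DIAGNOSIS_LEVELS),
                 view_scale = view_scale, noise_sd = noise_sd, mu0 = mu0),
            class = "cohort_spec")
}

#' Generate a synthetic cohort feature table
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return List with `table` (a [cohort_table()]) and `truth` (archetype
#'   assignment, planted ROI sets per archetype and per view).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = c(5, 5, 5), K = 10),
#'                           seed = 42)
#' cohort$table
#' @export
generate_cohort <- function(spec, seed = 20160223) {
  n <- spec$n_per_group
  N <- sum(n)
  diagnosis <- factor(rep(DIAGNOSIS_LEVELS, times = n),
                      levels = DIAGNOSIS_LEVELS)
  subject_id <- sprintf("S%04d", seq_len(N))
  atlas <- roi_atlas(seq_len(spec$K))
  delta <- spec$effect_sizes[as.character(diagnosis)]
  views <- local_seed(seed, {
    lapply(stats::setNames(nm = names(spec$view_assignment)), function(v) {
      a <- spec$view_assignment[[v]]
      u <- spec$archetypes[a, ]
      shift_roi <- if (max(u) > 0) u / max(u) else u
      shift <- outer(delta * spec$noise_sd * spec$view_scale[[v]], shift_roi)
      m <- spec$mu0 + shift +
        matrix(rnorm(N * spec$K, sd = spec$noise_sd), N, spec$K)
      rownames(m) <- subject_id
      colnames(m) <- atlas_columns(atlas)
      m
    })
  })
  table <- structure(
    list(subjects = tibble::tibble(subject_id = subject_id,
                                   diagnosis = diagnosis),
         views = views, atlas = atlas),
    class = "cohort_table")
  planted_arch <- lapply(seq_len(nrow(spec$archetypes)), function(a)
    which(spec$archetypes[a, ] > 0))
  truth <- list(
    archetype = spec$view_assignment,
    planted = planted_arch,
    planted_by_view = lapply(spec$view_assignment, function(a)
      planted_arch[[a]]))
  list(table = table, truth = truth, spec = spec)
}

#' The default synthetic benchmark cohort
#'
#' Nine views over `K = 83` ROIs assigned to four archetypes sized 3/1/3/2
#' (mirroring the four empirically observed view clusters: three MRI
#' morphometry views; solidity alone; three lesion-consistency PET views;
#' two activity-level PET views), with cohort sizes `(77, 169, 85)` for
#' `(NC, MCI, AD)` scaled by `n_scale`. Archetypes load uniformly on
#' disjoint blocks of 20 ROIs; effect sizes are `0 / 0.6 / 1.2` standard
#' deviations on fully loaded ROIs, with per-view quality multipliers
#' between 0.6 and 1.1 so views differ in staging performance.
#'
#' @param seed Integer seed.
#' @param n_scale Cohort scale factor (1 = full size; smaller for quick
#'   runs; group sizes never drop below 6).
#' @return As [generate_cohort()].
#' @export
default_benchmark <- function(seed = 20160223, n_scale = 1) {
  n <- pmax(as.integer(round(c(77, 169, 85) * n_scale)), 6L)
  spec <- cohort_spec(
    n_per_group = n, K = 83,
    view_scale = c("GMV" = 1.0, "LGI" = 0.7, "CNV" = 0.9, "SLD" = 0.8,
                   "F-IDX" = 1.1, "DoG-C" = 0.9, "DoG-Z" = 0.6,
                   "M-IDX" = 1.0, "DoG-M" = 1.05))
  generate_cohort(spec, seed)
}
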