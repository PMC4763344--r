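# Shared fixtures, built in code at test time.

# Minimal two-ROI bundle with explicit voxel contents: ROI 1 and ROI 2 are
# axis-aligned boxes inside a padded grid. Useful for exact counting checks.
make_box_bundle <- function(pet1 = 1, pet2 = 1, mri1 = 10, mri2 = 20,
                            gm_mask = NULL, spacing = c(1, 1, 1),
                            category = c("cortical", "cortical"),
                            cerebellum = 2L, dims = c(30L, 20L, 20L)) {
  lab <- array(0L, dims)
  lab[6:13, 6:13, 6:13] <- 1L    # 512 voxels
  lab[18:25, 6:13, 6:13] <- 2L   # 512 voxels
  mri <- array(0, dims); mri[lab == 1L] <- mri1; mri[lab == 2L] <- mri2
  pet <- array(0, dims); pet[lab == 1L] <- pet1; pet[lab == 2L] <- pet2
  atlas <- roi_atlas(1:2, category = category, cerebellum_ids = cerebellum)
  volume_bundle(mri, pet, lab, atlas, gm_mask = gm_mask, spacing = spacing)
}

ball_mask <- function(dims, center, r) {
  x <- slice.index(array(0, dims), 1)
  y <- slice.index(array(0, dims), 2)
  z <- slice.index(array(0, dims), 3)
  (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= r^2
}

# Single-ball bundle (ball is ROI 1, a second small cerebellum ball ROI 2).
make_ball_bundle <- function(r = 10, dims = c(48L, 48L, 48L),
                             center = c(16, 16, 16), pet_fun = NULL) {
  lab <- array(0L, dims)
  lab[ball_mask(dims, center, r)] <- 1L
  lab[ball_mask(dims, c(38, 38, 38), 6)] <- 2L
  pet <- array(1, dims)
  if (!is.null(pet_fun)) pet <- pet_fun(dims)
  atlas <- roi_atlas(1:2, category = c("cortical", "cerebellum"),
                     cerebellum_ids = 2L)
  volume_bundle(array(1, dims), pet, lab, atlas, spacing = c(1, 1, 1))
}

# Random probability vectors
random_pattern <- function(k, concentration = 1) {
  a <- rexp(k)^concentration
  a / sum(a)
}

# Tiny well-formed long-format feature data frame
tiny_table_df <- function() {
  data.frame(subject_id = c("s1", "s2"), diagnosis = c("AD", "NC"),
             view = "GMV", roi_1 = c(0.1, 0.2), roi_2 = c(0.3, 0.4),
             stringsAsFactors = FALSE)
}

# One-view separable-ish cohort used by staging tests
make_simple_cohort <- function(n = 30, K = 6, delta = c(0, 1, 2), sd = 0.5,
                               seed = 1) {
  arch <- matrix(0, 1, K); arch[1, seq_len(K %/% 2)] <- 1 / (K %/% 2)
  spec <- cohort_spec(n_per_group = rep(n, 3), K = K, archetypes = arch,
                      view_assignment = c(V1 = 1L),
                      effect_sizes = c(NC = delta[1], MCI = delta[2],
                                       AD = delta[3]),
                      noise_sd = sd)
  generate_cohort(spec, seed = seed)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
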