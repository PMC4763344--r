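# The nine biomarker views against counting oracles and invariances.

test_that("GMV counts gray matter for cortical and whole volume otherwise", {
  dims <- c(20L, 20L, 20L)
  lab <- array(0L, dims)
  lab[2:11, 2:11, 2:11] <- 2L         # 1000 voxels
  lab[14:18, 2:6, 2:5] <- 1L          # 100 voxels, all declared GM
  gm <- lab == 1L
  atlas <- roi_atlas(1:2, category = c("cortical", "ventricle"))
  b <- volume_bundle(array(0, dims), array(1, dims), lab, atlas, gm_mask = gm)
  gmv <- extract_gmv(b)
  expect_equal(unname(gmv[1]), 100 / 1100)
  # ventricle-tagged ROI ignores the GM mask entirely
  expect_equal(unname(gmv[2]), 1000 / 1100)
  b_nogm <- volume_bundle(array(0, dims), array(1, dims), lab, atlas,
                          gm_mask = array(FALSE, dims))
  expect_equal(unname(extract_gmv(b_nogm)[2]), 1000 / 1100)
  # spacing cancels in the ratio
  b2 <- volume_bundle(array(0, dims), array(1, dims), lab, atlas,
                      gm_mask = gm, spacing = c(2, 2, 2))
  expect_equal(extract_gmv(b2), gmv)
})

test_that("LGI is ~1 for a smooth ball, larger for an indented ball, and the
           raw surface area for non-cortical ROIs", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0), seed = 1)
  lgi <- extract_lgi(ph$bundle)
  expect_gt(lgi[["roi_1"]], 0.95); expect_lt(lgi[["roi_1"]], 1.05)
  expect_gt(lgi[["roi_3"]], lgi[["roi_1"]]) # fingers bury surface
  g4 <- roi_geometry(ph$bundle, 4L)
  expect_equal(lgi[["roi_4"]], g4$surface_area)
})

test_that("CNV drops when a convex ball is indented", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0), seed = 1)
  cnv <- extract_cnv(ph$bundle)
  expect_lt(cnv[["roi_3"]], cnv[["roi_1"]])
  expect_gt(cnv[["roi_1"]], 0.95); expect_lt(cnv[["roi_1"]], 1.05)
})

test_that("SLD separates convex from concave and shrinks as a cavity grows", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0), seed = 1)
  sld <- extract_sld(ph$bundle)
  expect_gt(sld[["roi_2"]], 0.95); expect_lt(sld[["roi_2"]], 1.05)
  expect_lt(sld[["roi_4"]], 0.67)
  # growing internal cavity -> monotonically falling solidity
  dims <- c(32L, 32L, 32L)
  sld_at_cavity <- vapply(c(0, 3, 5, 7), function(rc) {
    m <- ball_mask(dims, c(16, 16, 16), 11)
    if (rc > 0) m <- m & !ball_mask(dims, c(16, 16, 16), rc)
    lab <- array(0L, dims); lab[m] <- 1L
    lab[ball_mask(dims, c(27, 27, 27), 4)] <- 2L
    b <- volume_bundle(array(0, dims), array(1, dims), lab,
                       roi_atlas(1:2, cerebellum_ids = 2L))
    g <- roi_geometry(b, 1L)
    g$volume / g$hull_volume
  }, numeric(1))
  expect_true(all(diff(sld_at_cavity) < 0))
})

test_that("cerebellar reference pools voxels across cerebellar ROIs", {
  b <- make_box_bundle(pet1 = 1, pet2 = 3,
                       category = c("cerebellum", "cerebellum"),
                       cerebellum = 1:2)
  # equal sizes, means 1 and 3 -> pooled mean 2
  expect_equal(cerebellum_reference(b), 2)
  # pooled mean equals the voxel-weighted mean of per-ROI means
  n1 <- sum(b$labelmap == 1L); n2 <- sum(b$labelmap == 2L)
  expect_equal(cerebellum_reference(b), (1 * n1 + 3 * n2) / (n1 + n2))
  const <- make_ball_bundle(r = 6)
  expect_equal(cerebellum_reference(const), 1)
})

test_that("M-IDX is the cerebellum-normalised ROI mean and scale-invariant", {
  b <- make_box_bundle(pet1 = 0.6, pet2 = 1.0) # ROI 2 is the reference
  midx <- extract_midx(b)
  expect_equal(unname(midx[1]), 0.6)
  expect_equal(unname(midx[2]), 1.0)
  b_const <- make_ball_bundle(r = 7)
  expect_true(all(abs(extract_midx(b_const) - 1) < 1e-12))
  for (lam in c(0.5, 2)) {
    bs <- b; bs$pet <- b$pet * lam
    expect_equal(extract_midx(bs), midx, tolerance = 1e-12)
  }
})

test_that("F-IDX is the population coefficient of variation", {
  b <- make_box_bundle(pet1 = 1, pet2 = 1)
  # half the ROI-1 voxels at 1, half at 3: sd = 1, mean = 2 -> 1/2
  sel <- which(b$labelmap == 1L)
  b$pet[sel[seq(1, length(sel), by = 2)]] <- 3
  fidx <- extract_fidx(b)
  expect_equal(unname(fidx[1]), 0.5)
  expect_equal(unname(fidx[2]), 0) # constant ROI
  for (lam in c(0.5, 2)) {
    bs <- b; bs$pet <- b$pet * lam
    expect_equal(extract_fidx(bs), fidx, tolerance = 1e-12)
  }
  bneg <- b; bneg$pet[b$labelmap == 1L] <- -1
  expect_warning(fn <- extract_fidx(bneg), "non-positive")
  expect_true(is.nan(fn[[1]]))
})

test_that("DoG detection is empty on constant PET and recovers a planted
           cold spot with Dice >= 0.5", {
  const <- make_ball_bundle(r = 10)
  les <- detect_lesions(const)
  expect_equal(sum(les$mask), 0)
  spec <- phantom_spec(
    roi_shapes = list(list(type = "ball", label = 1L, center = c(24, 24, 24),
                           r = 14, category = "cortical", mri = 10),
                      list(type = "ball", label = 2L, center = c(50, 50, 50),
                           r = 8, category = "cerebellum", mri = 5)),
    lesion_specs = list(list(center = c(24, 24, 24), sigma = 3, depth = 0.5)),
    noise_sd = 0)
  ph <- generate_phantom(spec, seed = 1)
  les <- detect_lesions(ph$bundle)
  planted <- ph$truth$lesion_support
  dice <- 2 * sum(les$mask & planted) / (sum(les$mask) + sum(planted))
  expect_gte(dice, 0.5)
  # deepening the cold spot never shrinks the detected mask
  masks <- lapply(c(0.3, 0.5, 0.8), function(d) {
    sp <- spec; sp$lesion_specs[[1]]$depth <- d
    detect_lesions(generate_phantom(sp, seed = 1)$bundle)$mask
  })
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
})

test_that("DoG-M averages lesional activity with the mean-index fallback", {
  b <- make_box_bundle(pet1 = 1, pet2 = 1)
  sel <- which(b$labelmap == 1L)
  lesion <- array(FALSE, dim(b$pet))
  lesion[sel[seq_len(length(sel) / 2)]] <- TRUE
  b$pet[lesion] <- 0.5 # half lesional at 0.5, reference stays 1
  dogm <- extract_dogm(b, lesion)
  expect_equal(unname(dogm[1]), 0.5)
  midx <- extract_midx(b)
  expect_equal(unname(dogm[2]), unname(midx[2])) # lesion-free fallback
  # fully lesional ROI coincides with M-IDX
  full <- array(FALSE, dim(b$pet)); full[b$labelmap == 1L] <- TRUE
  expect_equal(unname(extract_dogm(b, full)[1]), unname(midx[1]))
  # global fallback option
  cfg <- crossview_config(dog = list(lesion_fallback = "global"))
  dogg <- extract_dogm(b, lesion, cfg)
  expect_equal(unname(dogg[2]), mean(b$pet[lesion]))
})

test_that("DoG-C is the variance-corrected lesion contrast", {
  b <- make_box_bundle(pet1 = 1, pet2 = 1)
  sel <- which(b$labelmap == 1L)
  lesion <- array(FALSE, dim(b$pet))
  lesion[sel[seq_len(length(sel) / 2)]] <- TRUE
  # lesion part: mean .5, sd .25; normal part: mean 1, sd .25
  les_idx <- which(lesion); non_idx <- setdiff(sel, les_idx)
  b$pet[les_idx] <- rep(c(0.25, 0.75), length.out = length(les_idx))
  b$pet[non_idx] <- rep(c(0.75, 1.25), length.out = length(non_idx))
  dogc <- extract_dogc(b, lesion)
  expect_equal(unname(dogc[1]), 0.5 / sqrt(0.125), tolerance = 1e-6)
  expect_equal(unname(dogc[2]), 0) # lesion-free
  for (lam in c(0.5, 2)) {
    bs <- b; bs$pet <- b$pet * lam
    expect_equal(extract_dogc(bs, lesion), dogc, tolerance = 1e-6)
  }
})

test_that("DoG-Z is the exact lesion fraction for an injected mask", {
  b <- make_box_bundle()
  expect_true(all(extract_dogz(b, array(FALSE, dim(b$pet))) == 0))
  sel <- which(b$labelmap == 1L)
  lesion <- array(FALSE, dim(b$pet))
  lesion[sel[seq_len(length(sel) / 4)]] <- TRUE # exactly 25%
  dz <- extract_dogz(b, lesion)
  expect_identical(unname(dz[1]), 0.25)
  # dilation can only grow the fraction
  bigger <- lesion; bigger[sel[seq_len(length(sel) / 2)]] <- TRUE
  expect_true(all(extract_dogz(b, bigger) >= dz))
})

test_that("extract_all_views returns the nine views, consistently and
           deterministically", {
  ph <- generate_phantom(phantom_spec(), seed = 5)
  v1 <- extract_all_views(ph$bundle)
  v2 <- extract_all_views(ph$bundle)
  expect_setequal(names(v1), c("GMV", "LGI", "CNV", "SLD", "M-IDX", "F-IDX",
                               "DoG-M", "DoG-C", "DoG-Z"))
  expect_identical(v1, v2)
  expect_equal(v1$GMV, extract_gmv(ph$bundle))
  expect_equal(v1$`M-IDX`, extract_midx(ph$bundle))
  ref <- cerebellum_reference(ph$bundle)
  les <- detect_lesions(ph$bundle, reference = ref)
  expect_equal(v1$`DoG-Z`, extract_dogz(ph$bundle, les))
})
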