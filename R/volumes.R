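#' Aligned volume bundle
#'
#' Bundles a subject's co-registered grids: a T1-MRI-like intensity volume,
#' an FDG-PET-like activity volume, an integer ROI labelmap and an optional
#' binary gray-matter mask, all on one grid with a common voxel spacing.
#' Registration/skull-stripping happen upstream; the bundle is post-alignment.
#'
#' @param mri,pet 3D numeric arrays (same shape).
#' @param labelmap 3D integer array; values are `0` (background) or ids
#'   declared in `atlas`.
#' @param atlas An [roi_atlas()].
#' @param gm_mask Optional 3D logical array marking gray matter.
#' @param spacing Numeric length-3 voxel spacing in mm (all `> 0`).
#' @return An object of class `volume_bundle`.
#' @export
volume_bundle <- function(mri, pet, labelmap, atlas, gm_mask = NULL,
                          spacing = c(1, 1, 1)) {
  assert_that(is_roi_atlas(atlas), "atlas must be an roi_atlas")
  dims <- dim(mri)
  assert_that(length(dims) == 3, "volumes must be 3D arrays")
  for (nm in c("pet", "labelmap")) {
    d <- dim(get(nm))
    assert_that(identical(dim(get(nm)), dims),
                "shape mismatch: mri is ", paste(dims, collapse = "x"),
                " but ", nm, " is ", paste(d, collapse = "x"))
  }
  if (!is.null(gm_mask)) {
    assert_that(identical(dim(gm_mask), dims),
                "shape mismatch: mri is ", paste(dims, collapse = "x"),
                " but gm_mask is ", paste(dim(gm_mask), collapse = "x"))
    storage.mode(gm_mask) <- "logical"
  }
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 positive lengths (mm)")
  storage.mode(labelmap) <- "integer"
  labs <- sort(unique(as.vector(labelmap)))
  labs <- labs[labs != 0L]
  assert_that(length(labs) > 0, "no ROIs present in labelmap")
  unknown <- setdiff(labs, atlas$roi_ids)
  if (length(unknown) > 0) {
    rlang::warn(paste0("labelmap contains label(s) not declared in atlas, ",
                       "excluded: ", paste(unknown, collapse = ", ")))
    labelmap[labelmap %in% unknown] <- 0L
    labs <- setdiff(labs, unknown)
    assert_that(length(labs) > 0, "no ROIs present after excluding unknown labels")
  }
  structure(list(mri = mri, pet = pet, labelmap = labelmap,
                 gm_mask = gm_mask, spacing = spacing, atlas = atlas),
            class = "volume_bundle")
}

#' @export
print.volume_bundle <- function(x, ...) {
  cat("<volume_bundle>", paste(dim(x$mri), collapse = "x"), "voxels @",
      paste(signif(x$spacing, 3), collapse = "x"), "mm;",
      length(setdiff(unique(as.vector(x$labelmap)), 0L)), "labelled ROI(s);",
      if (is.null(x$gm_mask)) "no GM mask" else "GM mask present", "\n")
  invisible(x)
}

#' Read a volume bundle from NIfTI files
#'
#' All files must live on identical grids (the package assumes PET has been
#' registered to MRI upstream). Labelmap values are validated against the
#' atlas; undeclared labels are excluded with a warning so atlas subsets can
#' be analysed.
#'
#' @param mri_path,pet_path,labelmap_path NIfTI file paths (`.nii`/`.nii.gz`).
#' @param atlas An [roi_atlas()].
#' @param gm_path Optional NIfTI path of a binary gray-matter mask.
#' @return A [volume_bundle()].
#' @export
read_volume_bundle <- function(mri_path, pet_path, labelmap_path, atlas,
                               gm_path = NULL) {
  rd <- function(p) {
    assert_that(file.exists(p), "NIfTI file not found: ", p)
    img <- RNifti::readNifti(p)
    list(arr = array(as.numeric(img), dim = dim(img)),
         spacing = abs(RNifti::pixdim(img))[seq_len(3)])
  }
  mri <- rd(mri_path); pet <- rd(pet_path); lab <- rd(labelmap_path)
  gm <- if (!is.null(gm_path)) rd(gm_path) else NULL
  labarr <- round(lab$arr)
  storage.mode(labarr) <- "integer"
  volume_bundle(mri$arr, pet$arr, labarr, atlas,
                gm_mask = if (!is.null(gm)) gm$arr > 0.5 else NULL,
                spacing = mri$spacing)
}

#' Write a 3D array as NIfTI
#'
#' @param vol 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param bundle A [volume_bundle()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `write_volume_bundle()` returns the named vector of paths written.
#' @export
write_volume_bundle <- function(bundle, dir, prefix = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mri = file.path(dir, paste0(prefix, "_mri.nii.gz")),
             pet = file.path(dir, paste0(prefix, "_pet.nii.gz")),
             labelmap = file.path(dir, paste0(prefix, "_labels.nii.gz")))
  write_volume(bundle$mri, paths["mri"], bundle$spacing)
  write_volume(bundle$pet, paths["pet"], bundle$spacing)
  write_volume(bundle$labelmap, paths["labelmap"], bundle$spacing)
  if (!is.null(bundle$gm_mask)) {
    paths <- c(paths, gm = file.path(dir, paste0(prefix, "_gm.nii.gz")))
    write_volume(bundle$gm_mask * 1, paths["gm"], bundle$spacing)
  }
  invisible(paths)
}

#' Back-project a pattern onto a labelmap
#'
#' Exports a scalar NIfTI volume in which every voxel of ROI `i` carries that
#' ROI's normalised pattern weight, for overlay rendering on the subject or
#' template anatomy. Background voxels are 0.
#'
#' @param pattern A [compute_pattern()] result (`view_pattern`) or a numeric
#'   vector of length `K` in atlas order.
#' @param labelmap 3D integer array of ROI labels.
#' @param atlas An [roi_atlas()].
#' @param path Output NIfTI path.
#' @param spacing Voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
export_pattern_labelmap <- function(pattern, labelmap, atlas, path,
                                    spacing = c(1, 1, 1)) {
  w <- if (inherits(pattern, "view_pattern")) pattern$normalized else as.numeric(pattern)
  assert_that(length(w) == length(atlas),
              "pattern length ", length(w), " does not match atlas K = ",
              length(atlas))
  lut <- numeric(max(atlas$roi_ids) + 1L) # index = label + 1
  lut[atlas$roi_ids + 1L] <- w
  lab <- as.integer(labelmap)
  lab[!(lab %in% c(0L, atlas$roi_ids))] <- 0L
  out <- array(lut[lab + 1L], dim = dim(labelmap))
  write_volume(out, path, spacing)
}
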