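#' Masked image stack
#'
#' The central data container: an observations x voxels matrix of beta /
#' contrast values restricted to an in-brain mask, tied to a 3-D voxel grid
#' and per-observation metadata (subject, condition, trial, rating).
#'
#' @param data Numeric matrix, observations in rows, in-mask voxels in columns.
#' @param mask Logical 3-D array; `sum(mask)` must equal `ncol(data)`.
#' @param obs_meta Data frame with one row per observation. Must contain
#'   `subject` and `condition`; `trial` and `rating` are optional. Ratings,
#'   when present and non-missing, must be integers in 1..5.
#' @param affine 4x4 voxel-to-world affine (RAS+). Defaults to 2 mm isotropic
#'   voxels centred on the grid.
#' @return An object of class `masked_image_stack`.
#' @export
masked_image_stack <- function(data, mask, obs_meta, affine = NULL) {
  data <- as.matrix(data)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stopf("`mask` must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  V <- sum(mask)
  if (V == 0L) stopf("mask is empty: no in-mask voxels")
  if (ncol(data) != V)
    stopf("data has %d columns but mask has %d voxels", ncol(data), V)
  if (anyNA(data) || any(!is.finite(data)))
    stopf("non-finite values in data at %d cells", sum(!is.finite(data)))
  obs_meta <- as.data.frame(obs_meta)
  if (nrow(obs_meta) != nrow(data))
    stopf("obs_meta has %d rows but data has %d observations",
          nrow(obs_meta), nrow(data))
  for (f in c("subject", "condition"))
    if (is.null(obs_meta[[f]])) stopf("obs_meta lacks required column '%s'", f)
  if (!is.null(obs_meta$rating)) {
    r <- obs_meta$rating[!is.na(obs_meta$rating)]
    if (length(r) && (any(r != round(r)) || any(r < 1 | r > 5)))
      stopf("ratings must be integers in [1, 5]")
  }
  if (is.null(affine)) affine <- default_affine(dim(mask))
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(
    data = data, mask = mask, voxel_index = which(mask),
    grid_shape = dim(mask), affine = affine, obs_meta = obs_meta
  ), class = "masked_image_stack")
}

default_affine <- function(grid_shape, voxel_mm = 2) {
  a <- diag(c(rep(voxel_mm, 3), 1))
  a[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  a
}

#' @export
print.masked_image_stack <- function(x, ...) {
  cat(sprintf("<masked_image_stack> %d observations x %d voxels (grid %s)\n",
              nrow(x$data), ncol(x$data),
              paste(x$grid_shape, collapse = "x")))
  cat(sprintf("  subjects: %d  conditions: %s\n",
              length(unique(x$obs_meta$subject)),
              paste(unique(x$obs_meta$condition), collapse = ", ")))
  invisible(x)
}

#' Subset a masked image stack by observation
#'
#' @param stack A `masked_image_stack`.
#' @param idx Logical or integer index over observations.
#' @return A `masked_image_stack` with the selected observations.
#' @export
stack_subset <- function(stack, idx) {
  masked_image_stack(stack$data[idx, , drop = FALSE], stack$mask,
                     stack$obs_meta[idx, , drop = FALSE], stack$affine)
}

same_voxel_space <- function(a_mask, a_affine, b_mask, b_affine, tol = 1e-4) {
  identical(dim(a_mask), dim(b_mask)) &&
    all(a_mask == b_mask) &&
    max(abs(a_affine - b_affine)) <= tol
}

# ---- NIfTI / TSV round-trip -------------------------------------------------

as_nifti <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  # pixdim must match the affine scales before the xforms are assigned,
  # or the qform assignment rescales the matrix
  scales <- sqrt(colSums(affine[1:3, 1:3]^2))
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(scales, rep(1, max(0, nd - 3)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img
}

#' Write a masked image stack to disk
#'
#' Writes a 4-D NIfTI of the unmasked volumes (out-of-mask voxels zero), a
#' 3-D uint8 mask NIfTI, a TSV observation-metadata table, and a JSON sidecar.
#'
#' @param stack A `masked_image_stack`.
#' @param prefix Path prefix; files `<prefix>.nii.gz`, `<prefix>_mask.nii.gz`,
#'   `<prefix>_meta.tsv`, `<prefix>.json` are produced.
#' @return Invisibly, the vector of file paths written.
#' @export
write_stack <- function(stack, prefix) {
  n <- nrow(stack$data)
  vol <- array(0, dim = c(stack$grid_shape, n))
  flat <- matrix(0, prod(stack$grid_shape), n)
  flat[stack$voxel_index, ] <- t(stack$data)
  vol[] <- flat
  paths <- c(img = paste0(prefix, ".nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             meta = paste0(prefix, "_meta.tsv"),
             json = paste0(prefix, ".json"))
  RNifti::writeNifti(as_nifti(vol, stack$affine), paths["img"])
  RNifti::writeNifti(as_nifti(array(as.integer(stack$mask),
                                    dim = stack$grid_shape), stack$affine),
                     paths["mask"], datatype = "uint8")
  utils::write.table(stack$obs_meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_obs = n, n_voxels = ncol(stack$data),
                            grid_shape = stack$grid_shape),
                       paths["json"], auto_unbox = TRUE)
  invisible(paths)
}

#' Load a masked image stack from NIfTI + TSV
#'
#' @param nifti_4d Path to a 4-D NIfTI of volumes.
#' @param mask_nifti Path to a 3-D mask NIfTI on the same grid.
#' @param meta_tsv Path to a TSV with one row per volume.
#' @return A `masked_image_stack`.
#' @export
load_stack <- function(nifti_4d, mask_nifti, meta_tsv) {
  for (p in c(nifti_4d, mask_nifti, meta_tsv))
    if (!file.exists(p)) stopf("input file not found: %s", p)
  img <- RNifti::readNifti(nifti_4d)
  msk <- RNifti::readNifti(mask_nifti)
  if (length(dim(img)) == 3L) dim(img) <- c(dim(img), 1L)
  if (!identical(dim(img)[1:3], dim(msk)))
    stopf("image grid %s does not match mask grid %s",
          paste(dim(img)[1:3], collapse = "x"),
          paste(dim(msk), collapse = "x"))
  a_img <- unclass(RNifti::xform(img)); a_msk <- unclass(RNifti::xform(msk))
  if (max(abs(a_img - a_msk)) > 1e-4)
    stopf("image and mask affines disagree beyond 1e-4")
  mask <- array(msk != 0, dim = dim(msk))
  n <- dim(img)[4]
  flat <- matrix(as.numeric(img), prod(dim(msk)), n)
  data <- t(flat[which(mask), , drop = FALSE])
  if (anyNA(data))
    stopf("NaN values in %d in-mask cells; refusing to load silently",
          sum(is.na(data)))
  meta <- utils::read.delim(meta_tsv, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stopf("metadata has %d rows but image has %d volumes", nrow(meta), n)
  masked_image_stack(data, mask, meta, a_img)
}

#' Write and read a signature weight map
#'
#' The weight vector is stored as a 3-D NIfTI (zeros outside the mask) with a
#' JSON sidecar carrying the intercept, label map and training provenance.
#'
#' @param model A `linear_pattern_model`.
#' @param stack The `masked_image_stack` defining the voxel space.
#' @param prefix Path prefix for `<prefix>.nii.gz` + `<prefix>.json`.
#' @return Invisibly, the paths written.
#' @export
write_signature <- function(model, stack, prefix) {
  vol <- array(0, dim = stack$grid_shape)
  vol[stack$voxel_index] <- model$weights
  RNifti::writeNifti(as_nifti(vol, stack$affine), paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(intercept = model$intercept,
                            label_map = model$label_map,
                            training = model$training),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(prefix, ".nii.gz"), paste0(prefix, ".json")))
}

#' @rdname write_signature
#' @export
read_signature <- function(prefix, stack) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  w <- resample_weights(img, stack)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  linear_pattern_model(w, side$intercept, side$label_map, side$training)
}

#' Resample a weight image onto a stack's voxel grid
#'
#' Nearest-neighbour resampling through the two affines; voxels falling
#' outside the source image are set to 0.
#'
#' @param weight_img An RNifti image (or path to one).
#' @param stack Target `masked_image_stack`.
#' @param min_overlap Minimum tolerated fraction of in-mask target voxels with
#'   source support (default 0.1); below it an error is raised.
#' @return Numeric weight vector over the stack's in-mask voxels, with an
#'   attribute `overlap` giving the supported fraction.
#' @export
resample_weights <- function(weight_img, stack, min_overlap = 0.1) {
  if (is.character(weight_img)) weight_img <- RNifti::readNifti(weight_img)
  src_aff <- unclass(RNifti::xform(weight_img))
  src_dim <- dim(weight_img)[1:3]
  idx <- stack$voxel_index
  ijk <- arrayInd(idx, stack$grid_shape) - 1L      # 0-based voxel coords
  world <- cbind(ijk, 1) %*% t(stack$affine)
  src <- world %*% t(solve(src_aff))
  sijk <- round(src[, 1:3])
  inb <- sijk[, 1] >= 0 & sijk[, 1] < src_dim[1] &
         sijk[, 2] >= 0 & sijk[, 2] < src_dim[2] &
         sijk[, 3] >= 0 & sijk[, 3] < src_dim[3]
  w <- numeric(length(idx))
  if (any(inb)) {
    lin <- 1 + sijk[inb, 1] + src_dim[1] * (sijk[inb, 2] + src_dim[2] * sijk[inb, 3])
    w[inb] <- as.numeric(weight_img)[lin]
  }
  overlap <- mean(inb & TRUE)
  if (overlap < min_overlap)
    stopf("only %.1f%% of target voxels overlap the weight image", 100 * overlap)
  attr(w, "overlap") <- overlap
  w
}
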