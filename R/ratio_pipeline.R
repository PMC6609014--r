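## T1w/T2w ratio mapping: receive-bias estimation from the square root of
## the product of the two weighted images (the T1w contrast x is
## approximately the inverse of the T2w contrast, so sqrt((xF)(F/x)) = F),
## the ratio map itself, and residual (low-spatial-frequency) bias
## correction of surface maps against a group reference.

#' Estimate the receive bias field from T1w and T2w images
#'
#' `raw = sqrt(t1w * t2w)` inside the mask, normalized to unit within-mask
#' mean, then conditioned by the shared [field_prep_chain()] (within-mask
#' smoothing, low-tail threshold, island removal, extrapolation, final
#' smoothing; 5 mm kernel by default).
#'
#' @param t1w_vol,t2w_vol nonnegative 3D arrays.
#' @param brain_mask logical 3D array (nonempty).
#' @param params a [field_prep_params()].
#' @param voxel_size_mm voxel size (mm).
#' @return full-grid estimated receive field, unit mean inside the mask
#'   before conditioning; attribute `n_clipped` counts negative-product
#'   voxels clipped to zero.
#' @export
estimate_receive_field <- function(t1w_vol, t2w_vol, brain_mask,
                                   params = field_prep_params(),
                                   voxel_size_mm) {
  stopifnot(identical(dim(t1w_vol), dim(t2w_vol)),
            identical(dim(t1w_vol), dim(brain_mask)))
  if (!any(brain_mask)) stop("empty brain mask")
  prod_ <- t1w_vol * t2w_vol
  neg <- prod_ < 0 & brain_mask
  if (any(neg)) {
    warning(sum(neg), " negative-product voxels clipped to 0")
    prod_[neg] <- 0
  }
  raw <- array(0, dim(prod_))
  raw[brain_mask] <- sqrt(prod_[brain_mask])
  mu <- mean(raw[brain_mask])
  if (mu <= 0) stop("degenerate input: zero mean field inside mask")
  raw <- raw / mu
  out <- field_prep_chain(raw, brain_mask, params, voxel_size_mm)
  attr(out, "n_clipped") <- sum(neg)
  out
}

#' Divide an image by the estimated receive field
#'
#' @param vol 3D array.
#' @param estimated_F positive 3D field.
#' @param brain_mask optional logical array: correction applied inside,
#'   zero outside; default everywhere.
#' @return corrected 3D array.
#' @export
correct_receive <- function(vol, estimated_F, brain_mask = NULL) {
  stopifnot(identical(dim(vol), dim(estimated_F)))
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(vol))
  if (any(estimated_F[brain_mask] <= 0))
    stop("zeros (or negative values) in the estimated receive field")
  out <- array(0, dim(vol))
  out[brain_mask] <- vol[brain_mask] / estimated_F[brain_mask]
  out
}

#' Voxelwise T1w/T2w ratio map
#'
#' @param t1w_vol,t2w_vol 3D arrays.
#' @param brain_mask logical 3D array.
#' @return ratio array: `t1w/t2w` inside the mask, 0 outside. Voxels with
#'   `t2w <= 0` inside the mask are set `NaN` and counted in attribute
#'   `n_invalid`.
#' @export
ratio_map <- function(t1w_vol, t2w_vol, brain_mask) {
  stopifnot(identical(dim(t1w_vol), dim(t2w_vol)),
            identical(dim(t1w_vol), dim(brain_mask)))
  out <- array(0, dim(t1w_vol))
  bad <- brain_mask & t2w_vol <= 0
  ok <- brain_mask & !bad
  out[ok] <- t1w_vol[ok] / t2w_vol[ok]
  out[bad] <- NaN
  attr(out, "n_invalid") <- sum(bad)
  out
}

#' Residual bias correction of a surface map against a group reference
#'
#' The residual bias is estimated as the surface-Gaussian-smoothed
#' difference between the individual map and the reference map (additive on
#' the map scale), and subtracted: only low-spatial-frequency deviations are
#' treated as bias, high-frequency content is preserved.
#'
#' @param map per-vertex values.
#' @param reference per-vertex group reference on the same mesh.
#' @param mesh the common surface mesh.
#' @param fwhm_mm bias smoothing kernel (default 30 mm at paper brain scale;
#'   scale it with the mesh for desk-scale phantoms).
#' @return corrected per-vertex vector.
#' @export
residual_bias_correct <- function(map, reference, mesh, fwhm_mm = 30) {
  if (length(map) != length(reference) ||
      length(map) != nrow(mesh$vertices))
    stop("mesh mismatch: map, reference and mesh sizes differ")
  bias <- smooth_surface(map - reference, mesh, fwhm_mm)
  map - bias
}
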