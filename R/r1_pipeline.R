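## B1-corrected T1/R1 estimation from the MP2RAGE UNI image: transmit-field
## specific UNI-vs-T1 lookup tables, the measured-B1 preprocessing chain
## (within-mask smoothing, outlier threshold, island removal, extrapolation),
## and per-voxel lookup inversion.

#' Bias-field preprocessing parameters
#'
#' @param smooth_fwhm_mm Gaussian smoothing kernel (default 5 mm).
#' @param outlier_k one-sided outlier threshold: voxels with
#'   field/smoothed-field below `mean - outlier_k * SD` are discarded.
#' @param min_island_voxels connected components (6-connectivity) smaller
#'   than this are removed before extrapolation.
#' @return named list of class `field_prep_params`.
#' @export
field_prep_params <- function(smooth_fwhm_mm = 5, outlier_k = 2,
                              min_island_voxels = 27) {
  structure(list(smooth_fwhm_mm = smooth_fwhm_mm, outlier_k = outlier_k,
                 min_island_voxels = min_island_voxels),
            class = "field_prep_params")
}

#' Build transmit-field specific UNI-vs-T1 lookup tables
#'
#' For every `b` in `b_grid` the UNI contrast is tabulated over `t1_grid`
#' and the largest contiguous strictly monotone interval containing the
#' typical grey-matter value `anchor_t1` is recorded as the invertible
#' branch. (The UNI curve is bounded in \[-0.5, 0.5\] and globally
#' non-injective: it saturates at both very short and very long T1.)
#'
#' @param protocol an [mp2rage_protocol()].
#' @param t1_grid T1 sample points (s).
#' @param b_grid transmit scaling sample points.
#' @param anchor_t1 T1 value (s) that the monotone branch must contain.
#' @return object of class `mp2rage_lookup`: `t1_grid`, `b_grid`,
#'   `uni_table` (length(b_grid) x length(t1_grid)), per-b branch index
#'   ranges and the generating protocol.
#' @export
build_lookup <- function(protocol, t1_grid = seq(0.05, 5, by = 0.005),
                         b_grid = seq(0.5, 1.5, by = 0.01),
                         anchor_t1 = 1.35) {
  stopifnot(inherits(protocol, "mp2rage_protocol"),
            all(diff(t1_grid) > 0), all(diff(b_grid) >= 0))
  nt <- length(t1_grid); nb <- length(b_grid)
  tab <- matrix(NA_real_, nb, nt)
  branch <- matrix(NA_integer_, nb, 2,
                   dimnames = list(NULL, c("first", "last")))
  ia <- which.min(abs(t1_grid - anchor_t1))
  for (k in seq_len(nb)) {
    s <- mp2rage_signal(t1_grid, b_grid[k], protocol)
    u <- uni_combine(s$s1, s$s2, undefined = "zero")
    tab[k, ] <- u
    dsign <- sign(diff(u))
    anchor_sign <- dsign[min(ia, nt - 1)]
    if (anchor_sign == 0)
      stop("degenerate-protocol error: UNI flat at the anchor T1")
    ok <- dsign == anchor_sign
    ## maximal run of consistent strict monotonicity containing the anchor
    runs <- rle(ok)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & starts <= min(ia, nt - 1) & ends >= min(ia, nt - 1))
    if (length(hit) != 1 || runs$lengths[hit] < 10)
      stop("degenerate-protocol error: no monotone interval of length >= 10 ",
           "containing T1 = ", anchor_t1, " at b = ", b_grid[k])
    branch[k, ] <- c(starts[hit], ends[hit] + 1L)
  }
  structure(list(t1_grid = t1_grid, b_grid = b_grid, uni_table = tab,
                 branch = branch, anchor_t1 = anchor_t1, protocol = protocol),
            class = "mp2rage_lookup")
}

#' T1 range of the invertible lookup branch
#' @param lookup an `mp2rage_lookup`.
#' @param b transmit scaling value(s); the intersection over the bracketing
#'   rows is returned.
#' @return c(t1_min, t1_max) in seconds.
#' @export
lookup_branch_range <- function(lookup, b = NULL) {
  br <- lookup$branch
  if (!is.null(b)) {
    rows <- unique(pmin(pmax(findInterval(b, lookup$b_grid), 1), nrow(br)))
    rows <- unique(c(rows, pmin(rows + 1L, nrow(br))))
    br <- br[rows, , drop = FALSE]
  }
  c(lookup$t1_grid[max(br[, 1])], lookup$t1_grid[min(br[, 2])])
}

#' Invert UNI values to T1 using the lookup tables
#'
#' For each element the two `b_grid` rows bracketing `b` are inverted on
#' their monotone branches by linear interpolation in UNI, and the two T1
#' estimates are linearly interpolated in `b`. UNI values outside a branch
#' are clamped to the branch endpoint and flagged; `b` outside the grid is
#' clamped to the nearest grid edge and flagged.
#'
#' @param uni UNI values (vector).
#' @param b transmit scaling values (vector, recycled against `uni`).
#' @param lookup an `mp2rage_lookup`.
#' @return list with `t1` (s), `clamped` (logical: UNI outside the branch),
#'   `b_clamped` (logical: b outside the grid).
#' @export
invert_uni <- function(uni, b, lookup) {
  n <- length(uni)
  b <- rep_len(b, n)
  bg <- lookup$b_grid; tg <- lookup$t1_grid
  b_clamped <- b < bg[1] | b > bg[length(bg)]
  bc <- pmin(pmax(b, bg[1]), bg[length(bg)])
  nbg <- length(bg)
  if (nbg == 1) {
    lo <- rep(1L, n); w <- rep(0, n)
  } else {
    lo <- pmin(pmax(findInterval(bc, bg), 1L), nbg - 1L)
    w <- (bc - bg[lo]) / (bg[lo + 1] - bg[lo])
  }
  invert_row <- function(row, u) {
    i0 <- lookup$branch[row, 1]; i1 <- lookup$branch[row, 2]
    xu <- lookup$uni_table[row, i0:i1]; yt <- tg[i0:i1]
    if (xu[1] > xu[length(xu)]) { xu <- rev(xu); yt <- rev(yt) }
    cl <- u < xu[1] | u > xu[length(xu)]
    t1 <- approx(xu, yt, xout = pmin(pmax(u, xu[1]), xu[length(xu)]),
                 ties = "ordered")$y
    list(t1 = t1, clamped = cl)
  }
  t1 <- numeric(n); clamped <- logical(n)
  for (row in sort(unique(lo))) {
    sel <- which(lo == row)
    r0 <- invert_row(row, uni[sel])
    if (nbg == 1) {
      t1[sel] <- r0$t1; clamped[sel] <- r0$clamped
    } else {
      r1 <- invert_row(row + 1L, uni[sel])
      t1[sel] <- (1 - w[sel]) * r0$t1 + w[sel] * r1$t1
      clamped[sel] <- r0$clamped | r1$clamped
    }
  }
  list(t1 = t1, clamped = clamped, b_clamped = b_clamped)
}

#' Preprocess a measured B1 map
#'
#' Mirrors the HCP-style bias-field conditioning chain: (1) upsample the
#' coarse acquisition to the target grid (trilinear); (2) within-mask
#' Gaussian smoothing (normalized convolution) at `smooth_fwhm_mm`;
#' (3) divide by the smoothed version and keep voxels with ratio at or above
#' `mean - outlier_k * SD` (one-sided low-tail threshold); (4) remove small
#' connected components and keep the largest; (5) extrapolate the surviving
#' values to the whole field of view (nearest valid neighbour) and apply a
#' final smoothing pass.
#'
#' @param b1_measured coarse 3D array (or full-grid array when
#'   `down_factor = 1`).
#' @param brain_mask logical 3D array on the target grid.
#' @param params a [field_prep_params()].
#' @param voxel_size_mm target grid voxel size (mm).
#' @param down_factor integer ratio between target and measured grids.
#' @return full-grid cleaned B1 field (3D array).
#' @export
prep_b1 <- function(b1_measured, brain_mask, params = field_prep_params(),
                    voxel_size_mm, down_factor = 1) {
  if (!any(brain_mask)) stop("empty brain mask")
  vol <- if (down_factor > 1) upsample_trilinear_3d(b1_measured, down_factor)
         else b1_measured
  stopifnot(identical(dim(vol), dim(brain_mask)))
  field_prep_chain(vol, brain_mask, params, voxel_size_mm)
}

#' Shared mask/threshold/extrapolate/smooth conditioning chain
#'
#' Steps (2)-(5) of [prep_b1()], shared with the receive-field estimator.
#'
#' @inheritParams prep_b1
#' @param vol full-grid field to condition.
#' @return conditioned full-grid field.
#' @export
field_prep_chain <- function(vol, brain_mask, params = field_prep_params(),
                             voxel_size_mm) {
  sm <- gaussian_smooth_3d(vol, params$smooth_fwhm_mm, voxel_size_mm,
                           mask = brain_mask)
  ratio <- array(1, dim(vol))
  ok <- brain_mask & sm > .Machine$double.eps
  ratio[ok] <- vol[ok] / sm[ok]
  rv <- ratio[brain_mask]
  thr <- mean(rv) - params$outlier_k * sd(rv)
  if (is.na(thr)) thr <- -Inf # single-voxel mask
  keep <- brain_mask & ratio >= thr
  if (!any(keep)) stop("empty surviving mask after outlier thresholding")
  comp <- connected_components_3d(keep)
  sizes <- tabulate(comp[comp > 0L])
  survivors <- which(sizes >= params$min_island_voxels)
  if (length(survivors) == 0) survivors <- 1L # largest always survives
  keep <- comp == min(survivors) # components are size-ordered: 1 = largest
  if (!any(keep)) stop("empty surviving mask after island removal")
  filled <- fill_nearest_3d(vol, keep)
  gaussian_smooth_3d(filled, params$smooth_fwhm_mm, voxel_size_mm)
}

#' Fit T1 and R1 volumes from a UNI image and a cleaned B1 field
#'
#' Per-voxel lookup inversion inside the brain mask; `r1 = 1/t1` is reported
#' in Hz (or mHz with `scale = "mHz"`, mirroring tools that express R1 from
#' a millisecond-scale T1). Voxels outside the mask are 0, or `NaN` when
#' `na_outside = TRUE`.
#'
#' @param uni_vol UNI 3D array.
#' @param b1_clean full-grid transmit field (e.g. from [prep_b1()]).
#' @param lookup an `mp2rage_lookup`.
#' @param brain_mask logical 3D array.
#' @param scale `"Hz"` (default) or `"mHz"` for the R1 output.
#' @param na_outside fill value selector outside the mask.
#' @param protocol optional protocol; if supplied it must be identical to
#'   the one the lookup was built from.
#' @return list with `t1_vol` (s), `r1_vol`, `clamped` (logical array),
#'   `scale`.
#' @export
fit_r1_volume <- function(uni_vol, b1_clean, lookup, brain_mask,
                          scale = c("Hz", "mHz"), na_outside = FALSE,
                          protocol = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(lookup, "mp2rage_lookup"),
            identical(dim(uni_vol), dim(brain_mask)),
            identical(dim(b1_clean), dim(brain_mask)))
  if (!is.null(protocol) && !identical(unclass(protocol), unclass(lookup$protocol)))
    stop("lookup/protocol mismatch: lookup was built from a different protocol")
  fill <- if (na_outside) NaN else 0
  d <- dim(uni_vol)
  t1v <- array(fill, d); r1v <- array(fill, d); cl <- array(FALSE, d)
  idx <- which(brain_mask)
  inv <- invert_uni(uni_vol[idx], b1_clean[idx], lookup)
  t1v[idx] <- inv$t1
  r1v[idx] <- (if (scale == "mHz") 1000 else 1) / inv$t1
  cl[idx] <- inv$clamped
  list(t1_vol = t1v, r1_vol = r1v, clamped = cl, scale = scale)
}
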