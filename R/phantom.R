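## Digital two-hemisphere brain phantom: each hemisphere is a concentric
## shell "brain" (white-matter core, parcellated cortical grey-matter shell,
## CSF exterior), mirror-symmetric about the mid-sagittal plane. No
## anatomical realism is attempted: the point is exactly known ground truth
## for every downstream statistic.

WM_LABEL <- 1L
CSF_LABEL <- 2L
GM_LABEL_LEFT <- 100L  # left-hemisphere parcel p -> 100 + p
GM_LABEL_RIGHT <- 200L # right-hemisphere parcel p -> 200 + p

#' Is a label a cortical (grey matter) parcel label?
#' @param label integer vector of voxel/vertex labels.
#' @return logical vector.
#' @export
is_gm_label <- function(label) label >= GM_LABEL_LEFT

#' Quasi-uniform unit directions (Fibonacci sphere)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default phantom configuration
#'
#' The desk-scale default is a 64^3 grid at 2 mm voxel scale (the acquisition
#' scale of 0.8 mm is a configuration choice, not a requirement). Tissue
#' parameters are typical 3T values; grey-matter T1 varies across parcels
#' over `gm_t1_range` to emulate myeloarchitectonic contrast. The T2 values
#' are apparent T2s appropriate for the phenomenological T2w model.
#'
#' @param ... overrides of the default fields.
#' @return named list of phantom parameters.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    grid_shape = c(64L, 64L, 64L),
    voxel_size_mm = 2,
    geometry = "two_shell_sphere",
    symmetric = TRUE,
    asym_scale = 0.03,      # right-radii scaling when symmetric = FALSE
    hemi_offset_mm = 22,
    r_wm_mm = 14,
    r_gm_mm = 20,
    r_csf_mm = 24,
    n_parcels = 12L,
    t1 = list(wm = 0.85, gm = 1.35, csf = 4.0),
    t2 = list(wm = 0.25, gm = 0.35, csf = 2.0),
    pd = list(wm = 0.70, gm = 0.85, csf = 1.00),
    gm_t1_range = c(1.2, 1.5),
    gm_parcel_t1 = NULL     # explicit per-parcel T1 overrides gm_t1_range
  )
  utils::modifyList(cfg, list(...))
}

.voxel_centers <- function(n, vs) (seq_len(n) - 0.5) * vs

#' Build the digital brain phantom
#'
#' @param config a [phantom_config()] list.
#' @return object of class `mp2r_phantom` with fields `t1_vol`, `t2_vol`,
#'   `pd_vol` (seconds / arbitrary units per voxel), `label_vol` (0 outside,
#'   1 WM, 2 CSF, 100+p / 200+p left/right GM parcel p), `brain_mask`,
#'   `voxel_size_mm`, `grid_shape`, plus geometry ground truth (`centers`,
#'   `radii`, `parcel_seeds`, `parcel_t1`).
#' @export
make_phantom <- function(config = phantom_config()) {
  cfg <- utils::modifyList(phantom_config(), config)
  d <- as.integer(cfg$grid_shape); vs <- cfg$voxel_size_mm
  stopifnot(length(d) == 3, all(d > 0), vs > 0)
  tis <- unlist(cfg$t1); tis2 <- unlist(cfg$t2); pds <- unlist(cfg$pd)
  if (any(tis <= 0) || any(tis2 <= 0) || any(pds < 0))
    stop("validation error: non-positive tissue parameters")
  if (!is.null(cfg$gm_parcel_t1) && any(cfg$gm_parcel_t1 <= 0))
    stop("validation error: non-positive parcel T1")
  if (cfg$geometry != "two_shell_sphere")
    stop("unknown geometry preset: ", cfg$geometry)

  fov <- d * vs
  xmid <- fov[1] / 2
  rR <- if (cfg$symmetric) 1 else 1 + cfg$asym_scale
  cL <- c(xmid - cfg$hemi_offset_mm, fov[2] / 2, fov[3] / 2)
  cR <- c(xmid + cfg$hemi_offset_mm, fov[2] / 2, fov[3] / 2)
  if (cfg$hemi_offset_mm + cfg$r_csf_mm * max(1, rR) > min(xmid, fov[2] / 2, fov[3] / 2))
    stop("geometry error: grid too small to contain the shells")
  if (!(cfg$r_wm_mm < cfg$r_gm_mm && cfg$r_gm_mm < cfg$r_csf_mm))
    stop("geometry error: radii must satisfy r_wm < r_gm < r_csf")

  P <- as.integer(cfg$n_parcels)
  stopifnot(P >= 1)
  seeds <- fibonacci_sphere(P)

  parcel_t1 <- cfg$gm_parcel_t1
  if (is.null(parcel_t1)) {
    parcel_t1 <- if (P == 1) mean(cfg$gm_t1_range) else
      seq(cfg$gm_t1_range[1], cfg$gm_t1_range[2], length.out = P)
  }
  stopifnot(length(parcel_t1) == P)

  x <- .voxel_centers(d[1], vs); y <- .voxel_centers(d[2], vs); z <- .voxel_centers(d[3], vs)
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)

  dL <- sqrt((X - cL[1])^2 + (Y - cL[2])^2 + (Z - cL[3])^2)
  dR <- sqrt((X - cR[1])^2 + (Y - cR[2])^2 + (Z - cR[3])^2) / rR
  left <- dL <= dR
  dist <- ifelse(left, dL, dR)

  label <- array(0L, d)
  label[dist <= cfg$r_csf_mm] <- CSF_LABEL
  label[dist <= cfg$r_gm_mm] <- -1L # GM placeholder
  label[dist <= cfg$r_wm_mm] <- WM_LABEL
  gm <- which(label == -1L)
  if (length(gm)) {
    cx <- ifelse(left[gm], cL[1], cR[1])
    ux <- (X[gm] - cx) / pmax(dist[gm], 1e-12)
    uy <- (Y[gm] - cL[2]) / pmax(dist[gm], 1e-12)
    uz <- (Z[gm] - cL[3]) / pmax(dist[gm], 1e-12)
    ## mirror right-hemisphere directions so parcel p corresponds across sides
    ux <- ifelse(left[gm], ux, -ux)
    sim <- cbind(ux, uy, uz) %*% t(seeds)
    parcel <- max.col(sim, ties.method = "first")
    label[gm] <- ifelse(left[gm], GM_LABEL_LEFT, GM_LABEL_RIGHT) + parcel
  }
  mask <- label > 0L

  t1v <- array(0, d); t2v <- array(0, d); pdv <- array(0, d)
  t1v[label == WM_LABEL] <- cfg$t1$wm
  t1v[label == CSF_LABEL] <- cfg$t1$csf
  t2v[label == WM_LABEL] <- cfg$t2$wm
  t2v[label == CSF_LABEL] <- cfg$t2$csf
  pdv[label == WM_LABEL] <- cfg$pd$wm
  pdv[label == CSF_LABEL] <- cfg$pd$csf
  for (p in seq_len(P)) {
    in_p <- label == GM_LABEL_LEFT + p | label == GM_LABEL_RIGHT + p
    t1v[in_p] <- parcel_t1[p]
    t2v[in_p] <- cfg$t2$gm
    pdv[in_p] <- cfg$pd$gm
  }

  ph <- structure(list(
    t1_vol = t1v, t2_vol = t2v, pd_vol = pdv,
    label_vol = label, brain_mask = mask,
    voxel_size_mm = vs, grid_shape = d,
    centers = list(left = cL, right = cR),
    radii = c(wm = cfg$r_wm_mm, gm = cfg$r_gm_mm, csf = cfg$r_csf_mm),
    parcel_seeds = seeds, parcel_t1 = parcel_t1,
    config = cfg), class = "mp2r_phantom")
  validate_phantom(ph)
  ph
}

#' Validate phantom invariants
#' @param ph an `mp2r_phantom`.
#' @return `ph`, invisibly; errors if an invariant is violated.
#' @export
validate_phantom <- function(ph) {
  m <- ph$brain_mask
  if (any(ph$t1_vol[m] <= 0) || any(ph$t2_vol[m] <= 0))
    stop("invariant violated: non-positive T1/T2 inside brain mask")
  if (any(ph$t2_vol[m] >= ph$t1_vol[m]))
    stop("invariant violated: t2 >= t1 inside brain mask")
  if (any(ph$pd_vol < 0)) stop("invariant violated: negative proton density")
  if (any(ph$label_vol[!m] != 0L)) stop("invariant violated: labels outside mask")
  invisible(ph)
}

#' Reassign per-parcel grey-matter T1 values in a phantom
#'
#' Used to draw subject-specific tissue without rebuilding geometry.
#'
#' @param ph an `mp2r_phantom`.
#' @param parcel_t1 numeric vector (one T1 per parcel, seconds) applied to
#'   both hemispheres, or a list `list(left =, right =)` for asymmetric draws.
#' @return updated phantom.
#' @export
set_parcel_t1 <- function(ph, parcel_t1) {
  P <- length(ph$parcel_t1)
  if (!is.list(parcel_t1)) parcel_t1 <- list(left = parcel_t1, right = parcel_t1)
  stopifnot(length(parcel_t1$left) == P, length(parcel_t1$right) == P)
  if (any(unlist(parcel_t1) <= 0)) stop("validation error: non-positive parcel T1")
  for (p in seq_len(P)) {
    ph$t1_vol[ph$label_vol == GM_LABEL_LEFT + p] <- parcel_t1$left[p]
    ph$t1_vol[ph$label_vol == GM_LABEL_RIGHT + p] <- parcel_t1$right[p]
  }
  ph$parcel_t1 <- parcel_t1$left
  ph$parcel_t1_right <- parcel_t1$right
  validate_phantom(ph)
  ph
}

## ---------------------------------------------------------------------------
## Bias fields
## ---------------------------------------------------------------------------

#' Default field configuration
#'
#' The transmit field decreases smoothly from the brain centre (high values)
#' to the periphery (low values); the receive field increases towards the
#' coil elements at the periphery; the B0 offset is a smooth blob largest in
#' the "frontal" (+y) region. Asymmetry parameters (`asym`) shift the
#' left-right hemispheric means.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
field_config <- function(...) {
  cfg <- list(
    b1 = list(center = 1.1, edge = 0.8, asym = 0),
    rx = list(center = 0.85, edge = 1.25, asym = 0),
    b0 = list(amp_hz = 40, width_mm = 25, asym = 0),
    asym_width_mm = 8,
    smoothness_cap = 0.05 # max allowed |voxel-to-voxel difference| / value scale
  )
  utils::modifyList(cfg, list(...))
}

.radial_profile <- function(ph, center, edge) {
  d <- ph$grid_shape; vs <- ph$voxel_size_mm
  fov <- d * vs; c0 <- fov / 2
  x <- .voxel_centers(d[1], vs); y <- .voxel_centers(d[2], vs); z <- .voxel_centers(d[3], vs)
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  r <- sqrt((X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2)
  rmax <- max(r[ph$brain_mask])
  center + (edge - center) * pmin(r / rmax, 1)^2
}

.lr_sign_field <- function(ph, width_mm) {
  ## smooth field ~ +1 in the left hemisphere, -1 in the right
  d <- ph$grid_shape; vs <- ph$voxel_size_mm
  xmid <- d[1] * vs / 2
  x <- .voxel_centers(d[1], vs)
  s <- tanh((xmid - x) / width_mm)
  array(rep(s, times = d[2] * d[3]), d)
}

.left_mask <- function(ph) {
  d <- ph$grid_shape; vs <- ph$voxel_size_mm
  x <- .voxel_centers(d[1], vs)
  array(rep(x < d[1] * vs / 2, times = d[2] * d[3]), d)
}

#' Generate transmit, receive and B0 offset fields
#'
#' @param config a [field_config()] list.
#' @param phantom an `mp2r_phantom`.
#' @return object of class `mp2r_fields` with 3D arrays `b1_tx`, `rx_field`,
#'   `b0_off` (Hz) on the phantom grid.
#' @export
make_fields <- function(config = field_config(), phantom) {
  cfg <- utils::modifyList(field_config(), config)
  ph <- phantom
  mk <- function(fc) {
    f <- .radial_profile(ph, fc$center, fc$edge)
    if (!is.null(fc$asym) && fc$asym != 0) {
      s <- .lr_sign_field(ph, cfg$asym_width_mm)
      left <- .left_mask(ph) & ph$brain_mask
      right <- !.left_mask(ph) & ph$brain_mask
      gap <- mean(s[left]) - mean(s[right])
      f <- f + (fc$asym / gap) * s
    }
    f
  }
  b1 <- mk(cfg$b1)
  rx <- mk(cfg$rx)
  ## B0: Gaussian blob centred at the front of the brain (+y)
  d <- ph$grid_shape; vs <- ph$voxel_size_mm; fov <- d * vs
  front <- c(fov[1] / 2, fov[2] / 2 + ph$radii["csf"] + ph$config$hemi_offset_mm * 0,
             fov[3] / 2)
  x <- .voxel_centers(d[1], vs); y <- .voxel_centers(d[2], vs); z <- .voxel_centers(d[3], vs)
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  rho2 <- (X - front[1])^2 + (Y - front[2])^2 + (Z - front[3])^2
  b0 <- cfg$b0$amp_hz * exp(-rho2 / (2 * cfg$b0$width_mm^2))
  if (!is.null(cfg$b0$asym) && cfg$b0$asym != 0)
    b0 <- b0 * (1 + cfg$b0$asym * .lr_sign_field(ph, cfg$asym_width_mm))
  if (any(b1 <= 0) || any(rx <= 0))
    stop("validation error: non-positive transmit/receive field")
  structure(list(b1_tx = b1, rx_field = rx, b0_off = b0, config = cfg),
            class = "mp2r_fields")
}

#' Maximum voxel-to-voxel jump of a field (smoothness diagnostic)
#' @param field 3D array.
#' @return largest absolute nearest-neighbour difference.
#' @export
max_voxel_jump <- function(field) {
  d <- dim(field)
  m <- 0
  m <- max(m, max(abs(field[-1, , ] - field[-d[1], , ])))
  m <- max(m, max(abs(field[, -1, ] - field[, -d[2], ])))
  m <- max(m, max(abs(field[, , -1] - field[, , -d[3]])))
  m
}
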