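## 3D volume utilities: separable Gaussian smoothing, connected components,
## nearest-valid-neighbour fill, block down/up-sampling. Volumes are plain 3D
## arrays; physical scale enters through voxel_size_mm.

.gauss_kernel_matrix <- function(n, sigma_vox) {
  ## dense n x n band matrix of a row-normalized truncated Gaussian
  half <- max(1L, ceiling(4 * sigma_vox))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- i - j
    ifelse(abs(d) <= half, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  K / rowSums(K)
}

.apply_axis <- function(vol, K, axis) {
  d <- dim(vol)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dp <- dim(v)
  out <- K %*% matrix(v, nrow = dp[1])
  dim(out) <- dp
  aperm(out, order(perm))
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Row-normalized truncated (4 sigma) Gaussian applied along each axis, so
#' constants are preserved exactly, including at volume edges.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum (mm); 0 returns `vol`.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param mask optional logical array: perform normalized convolution
#'   `smooth(vol * mask) / smooth(mask)` restricted to the mask support;
#'   voxels where the smoothed mask is zero are set to 0.
#' @return smoothed 3D array.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm, mask = NULL) {
  stopifnot(length(dim(vol)) == 3, fwhm_mm >= 0, voxel_size_mm > 0)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  d <- dim(vol)
  Ks <- lapply(d, .gauss_kernel_matrix, sigma_vox = sigma_vox)
  smooth1 <- function(x) {
    for (ax in 1:3) x <- .apply_axis(x, Ks[[ax]], ax)
    x
  }
  if (is.null(mask)) return(smooth1(vol))
  m <- array(as.numeric(mask), d)
  num <- smooth1(vol * m)
  den <- smooth1(m)
  out <- array(0, d)
  ok <- den > .Machine$double.eps
  out[ok] <- num[ok] / den[ok]
  out
}

#' 6-connected components of a logical 3D mask
#'
#' @param mask logical 3D array.
#' @return integer array: 0 outside, component id (1 = largest) inside.
#' @export
connected_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, d))
  pos <- arrayInd(idx, d)
  key <- idx
  lookup <- integer(prod(d)) # voxel linear index -> node id
  lookup[key] <- seq_along(idx)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    has <- lookup[nb] > 0L
    if (any(has))
      edges[[ax]] <- cbind(lookup[idx[ok][has]], lookup[nb[has]])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_graph(edges = t(em), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  out <- array(0L, d)
  out[idx] <- relabel[comp$membership]
  out
}

#' Fill a volume from a mask of valid voxels by nearest-neighbour dilation
#'
#' Iteratively assigns to each unfilled voxel the mean of its already-filled
#' 6-neighbours until the whole field of view is covered (grassfire /
#' L1-nearest extrapolation). Constant inputs are preserved exactly.
#'
#' @param vol 3D numeric array (values outside `valid` are ignored).
#' @param valid logical 3D array of voxels whose values are trusted.
#' @return fully populated 3D array.
#' @export
fill_nearest_3d <- function(vol, valid) {
  d <- dim(vol)
  stopifnot(identical(dim(valid), d))
  if (!any(valid)) stop("no valid voxels to extrapolate from")
  x <- array(0, d); x[valid] <- vol[valid]
  dist <- array(Inf, d); dist[valid] <- 0
  ## chamfer-style directional sweeps propagating (value, L1 distance);
  ## repeated until stable (2 passes suffice for convex-ish masks)
  sweep_axis <- function(ax, forward) {
    n <- d[ax]
    ids <- if (forward) 2:n else (n - 1):1
    step <- if (forward) -1L else 1L
    for (i in ids) {
      if (ax == 1) {
        cand <- dist[i + step, , ] + 1
        upd <- cand < dist[i, , ]
        if (any(upd)) {
          xi <- x[i, , ]; xs <- x[i + step, , ]; di <- dist[i, , ]
          xi[upd] <- xs[upd]; di[upd] <- cand[upd]
          x[i, , ] <<- xi; dist[i, , ] <<- di
        }
      } else if (ax == 2) {
        cand <- dist[, i + step, ] + 1
        upd <- cand < dist[, i, ]
        if (any(upd)) {
          xi <- x[, i, ]; xs <- x[, i + step, ]; di <- dist[, i, ]
          xi[upd] <- xs[upd]; di[upd] <- cand[upd]
          x[, i, ] <<- xi; dist[, i, ] <<- di
        }
      } else {
        cand <- dist[, , i + step] + 1
        upd <- cand < dist[, , i]
        if (any(upd)) {
          xi <- x[, , i]; xs <- x[, , i + step]; di <- dist[, , i]
          xi[upd] <- xs[upd]; di[upd] <- cand[upd]
          x[, , i] <<- xi; dist[, , i] <<- di
        }
      }
    }
  }
  for (pass in 1:3) {
    for (ax in 1:3) { sweep_axis(ax, TRUE); sweep_axis(ax, FALSE) }
    if (all(is.finite(dist))) break
  }
  if (!all(is.finite(dist))) stop("nearest-fill failed to converge")
  x
}

#' Block-average downsampling of a 3D volume
#'
#' @param vol 3D array with dimensions divisible by `factor`.
#' @param factor integer downsampling factor.
#' @return downsampled array (each output voxel = mean of a factor^3 block).
#' @export
block_downsample_3d <- function(vol, factor) {
  d <- dim(vol)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  a <- array(vol, c(factor, dn[1], factor, dn[2], factor, dn[3]))
  apply(a, c(2, 4, 6), mean)
}

#' Trilinear upsampling of a coarse volume onto a fine grid
#'
#' Coarse voxel centres are assumed to sit at the centres of `factor^3`
#' blocks of the fine grid (the inverse of [block_downsample_3d()]); values
#' beyond the coarse-grid boundary are clamped.
#'
#' @param vol coarse 3D array.
#' @param factor integer upsampling factor.
#' @return fine 3D array with dimensions `dim(vol) * factor`.
#' @export
upsample_trilinear_3d <- function(vol, factor) {
  d <- dim(vol)
  df <- d * factor
  ## fine voxel centre i (1-based) lies at coarse coordinate
  ## (i - 0.5)/factor + 0.5 in coarse voxel units
  coord <- function(n) pmin(pmax((seq_len(n * factor) - 0.5) / factor + 0.5, 1), n)
  cx <- coord(d[1]); cy <- coord(d[2]); cz <- coord(d[3])
  interp_axis <- function(a, cc, ax) {
    n <- dim(a)[ax]
    i0 <- pmin(floor(cc), n - 1); w <- cc - i0
    idx0 <- as.integer(i0); idx1 <- idx0 + 1L
    if (ax == 1) {
      a[idx0, , , drop = FALSE] * (1 - w) + a[idx1, , , drop = FALSE] * w
    } else if (ax == 2) {
      sweep_w <- rep(w, each = dim(a)[1])
      a0 <- a[, idx0, , drop = FALSE]; a1 <- a[, idx1, , drop = FALSE]
      a0 * array(1 - rep(w, each = dim(a)[1]), dim(a0)) +
        a1 * array(sweep_w, dim(a1))
    } else {
      a0 <- a[, , idx0, drop = FALSE]; a1 <- a[, , idx1, drop = FALSE]
      w3 <- array(rep(w, each = dim(a)[1] * dim(a)[2]), dim(a0))
      a0 * (1 - w3) + a1 * w3
    }
  }
  out <- interp_axis(vol, cx, 1)
  out <- interp_axis(out, cy, 2)
  out <- interp_axis(out, cz, 3)
  dim(out) <- df
  out
}
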