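## Parcellated hemispheric surface meshes. Each hemisphere is a subdivided
## icosahedron placed at the mid-thickness radius of its cortical shell; the
## right mesh is the mirror image of the left, so cross-hemisphere vertex
## correspondence is the identity map on vertex indices.

ICOSPHERE_COUNTS <- 10 * 4^(0:6) + 2 # 12, 42, 162, 642, 2562, 10242, 40962

#' Unit icosphere mesh
#'
#' Subdivided icosahedron with `10 * 4^level + 2` vertices projected onto the
#' unit sphere.
#'
#' @param n_vertices requested vertex count (must be one of the valid counts).
#' @return list with `vertices` (n x 3) and `triangles` (m x 3, 1-based).
#' @export
icosphere <- function(n_vertices) {
  lvl <- match(n_vertices, ICOSPHERE_COUNTS) - 1L
  if (is.na(lvl))
    stop("vertex budget not realizable by subdivision; valid counts: ",
         paste(ICOSPHERE_COUNTS, collapse = ", "))
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(lvl)) {
    nv <- nrow(v)
    edge_key <- function(i, j) ifelse(i < j, i * (nv + 1) + j, j * (nv + 1) + i)
    e1 <- edge_key(f[, 1], f[, 2]); e2 <- edge_key(f[, 2], f[, 3]); e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    ki <- (keys %/% (nv + 1)); kj <- keys %% (nv + 1)
    mid <- (v[ki, , drop = FALSE] + v[kj, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- setNames(nv + seq_along(keys), keys)
    v <- rbind(v, mid)
    m1 <- midx[as.character(e1)]; m2 <- midx[as.character(e2)]; m3 <- midx[as.character(e3)]
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  dimnames(f) <- NULL
  list(vertices = v, triangles = f)
}

#' Default surface-model configuration
#' @param ... overrides.
#' @return named list (`n_vertices` per hemisphere, `n_parcels`).
#' @export
surface_config <- function(...) {
  utils::modifyList(list(n_vertices = 10242L, n_parcels = NULL), list(...))
}

#' Build the parcellated two-hemisphere surface model
#'
#' Mid-thickness vertices lie on the sphere midway between the white-matter
#' and pial radii of each hemisphere's cortical shell. Parcels are the
#' spherical Voronoi patches of the same seed directions used for the
#' volumetric parcellation, so surface and volume labels agree. The
#' left/right correspondence is the mirror map, which under the shared
#' vertex ordering is the identity on indices.
#'
#' @param config a [surface_config()] list.
#' @param phantom an `mp2r_phantom` built with the shell geometry.
#' @return object of class `mp2r_surface` with per-hemisphere meshes
#'   (`left`, `right`: vertices, triangles, midthickness, normals, labels,
#'   hemi) and `correspondence` (right vertex index for each left vertex).
#' @export
make_surface_model <- function(config = surface_config(), phantom) {
  cfg <- utils::modifyList(surface_config(), config)
  ph <- phantom
  n_parcels <- cfg$n_parcels
  if (is.null(n_parcels)) n_parcels <- nrow(ph$parcel_seeds)
  if (n_parcels != nrow(ph$parcel_seeds))
    stop("surface parcel count must match the phantom parcellation")
  ico <- icosphere(cfg$n_vertices)
  r_mid <- (ph$radii["wm"] + ph$radii["gm"]) / 2
  seeds <- ph$parcel_seeds

  sim <- ico$vertices %*% t(seeds)
  labels <- max.col(sim, ties.method = "first")

  left_v <- sweep(ico$vertices * r_mid, 2, ph$centers$left, `+`)
  right_dir <- ico$vertices; right_dir[, 1] <- -right_dir[, 1]
  right_v <- sweep(right_dir * r_mid, 2, ph$centers$right, `+`)
  tri_r <- ico$triangles[, c(1, 3, 2)] # restore outward orientation

  left <- list(vertices = left_v, triangles = ico$triangles,
               midthickness = left_v, normals = ico$vertices,
               labels = labels, hemi = "L")
  right <- list(vertices = right_v, triangles = tri_r,
                midthickness = right_v, normals = right_dir,
                labels = labels, hemi = "R")
  ## cache adjacency + mean squared edge length (smoothing uses them a lot)
  left$adjacency <- .mesh_adjacency(left)
  left$h2 <- .mean_sq_edge(left)
  right$adjacency <- left$adjacency # identical connectivity
  right$h2 <- left$h2
  surf <- structure(list(left = left, right = right,
                         correspondence = seq_len(nrow(left_v)),
                         n_parcels = n_parcels, r_mid = unname(r_mid)),
                    class = "mp2r_surface")
  ## construction check: every mid-thickness vertex sits in a GM voxel
  for (h in c("left", "right")) {
    vox <- mm_to_voxel(surf[[h]]$midthickness, ph$voxel_size_mm, ph$grid_shape)
    lab <- ph$label_vol[vox]
    if (!all(is_gm_label(lab)))
      warning(sum(!is_gm_label(lab)), " mid-thickness vertices (", h,
              ") fall outside the cortical shell")
  }
  surf
}

#' Convert mm coordinates to voxel array indices
#' @param xyz n x 3 matrix of mm coordinates (voxel centre convention:
#'   voxel i spans `[(i-1)*vs, i*vs]`).
#' @param voxel_size_mm voxel size.
#' @param grid_shape 3 integers; coordinates are clamped into the grid.
#' @return n x 3 integer index matrix.
#' @export
mm_to_voxel <- function(xyz, voxel_size_mm, grid_shape) {
  idx <- ceiling(xyz / voxel_size_mm)
  idx <- pmax(idx, 1)
  idx <- sweep(idx, 2, grid_shape, pmin)
  storage.mode(idx) <- "integer"
  idx
}

#' Regular planar triangulated mesh (test/calibration substrate)
#'
#' Grid of `nx x ny` vertices spaced `spacing` mm apart in the z = 0 plane,
#' each cell split into two triangles.
#'
#' @param nx,ny vertex counts along x and y.
#' @param spacing vertex spacing (mm).
#' @return mesh list (`vertices`, `triangles`, `normals`).
#' @export
make_planar_mesh <- function(nx, ny, spacing = 1) {
  xy <- expand.grid(x = (seq_len(nx) - 1) * spacing, y = (seq_len(ny) - 1) * spacing)
  v <- cbind(xy$x, xy$y, 0)
  id <- function(i, j) (j - 1) * nx + i
  tris <- list()
  k <- 1
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    tris[[k]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1)); k <- k + 1
    tris[[k]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1)); k <- k + 1
  }
  list(vertices = v, triangles = do.call(rbind, tris),
       normals = matrix(rep(c(0, 0, 1), each = nrow(v)), ncol = 3))
}
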