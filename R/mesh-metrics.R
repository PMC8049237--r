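#' Signed tetrahedron volumes
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of signed volumes in mm^3 (positive for
#'   right-handed elements).
#' @export
tet_volumes <- function(mesh) {
  p <- mesh$points; t4 <- mesh$tets
  a <- p[t4[, 2], , drop = FALSE] - p[t4[, 1], , drop = FALSE]
  b <- p[t4[, 3], , drop = FALSE] - p[t4[, 1], , drop = FALSE]
  c_ <- p[t4[, 4], , drop = FALSE] - p[t4[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Scaled Jacobian element quality
#'
#' Per-element scaled Jacobian in the Verdict/CUBIT normalisation: a regular
#' (equilateral) tetrahedron scores 1, degenerate elements score 0 and
#' inverted elements are negative. SJ = sqrt(2) * 6V / max over the four
#' corners of the product of the three edge lengths meeting at that corner.
#' Elements with repeated vertices score 0 with a warning.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector in \[-1, 1\], one value per element.
#' @export
scaled_jacobian <- function(mesh) {
  p <- mesh$points; t4 <- mesh$tets
  jac <- 6 * tet_volumes(mesh)
  elen <- function(i, j) {
    d <- p[t4[, i], , drop = FALSE] - p[t4[, j], , drop = FALSE]
    sqrt(rowSums(d^2))
  }
  l12 <- elen(1, 2); l13 <- elen(1, 3); l14 <- elen(1, 4)
  l23 <- elen(2, 3); l24 <- elen(2, 4); l34 <- elen(3, 4)
  denom <- pmax(l12 * l13 * l14,  # corner 1
                l12 * l23 * l24,  # corner 2
                l13 * l23 * l34,  # corner 3
                l14 * l24 * l34)  # corner 4
  repeated <- pmin(l12, l13, l14, l23, l24, l34) == 0
  if (any(repeated)) {
    warning(sum(repeated), " element(s) with repeated vertices; ",
            "scaled Jacobian set to 0")
    denom[repeated] <- 1
    jac[repeated] <- 0
  }
  zero_denom <- denom <= 0
  denom[zero_denom] <- 1
  jac[zero_denom] <- 0
  sj <- sqrt(2) * jac / denom
  pmin(pmax(sj, -1), 1)
}

surface_boundary_ok <- function(triangles) {
  # closed surface <=> every undirected edge is used exactly twice
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Cavity volume of a closed surface by the divergence theorem
#'
#' Computes volume = (1/3) * sum over triangles of centroid . (area-weighted
#' outward normal), the 3D Stokes-theorem form, and converts mm^3 to mL.
#'
#' @param points numeric matrix `n x 3` (mm).
#' @param triangles integer matrix `m x 3` of 1-based vertex indices,
#'   consistently outward-oriented and closed.
#' @return volume in mL.
#' @export
cavity_volume_stokes <- function(points, triangles) {
  triangles <- as.matrix(triangles)
  if (!surface_boundary_ok(triangles)) {
    stop("surface is not closed: boundary edges exist", call. = FALSE)
  }
  p1 <- points[triangles[, 1], , drop = FALSE]
  p2 <- points[triangles[, 2], , drop = FALSE]
  p3 <- points[triangles[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nvec <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])  # 2 * area * normal
  centroid <- (p1 + p2 + p3) / 3
  vol_mm3 <- sum(rowSums(centroid * nvec)) / 6
  if (vol_mm3 < 0) {
    stop("orientation error: surface normals point inward ",
         "(negative enclosed volume)", call. = FALSE)
  }
  vol_mm3 / 1000
}

triangle_areas <- function(points, triangles) {
  p1 <- points[triangles[, 1], , drop = FALSE]
  p2 <- points[triangles[, 2], , drop = FALSE]
  p3 <- points[triangles[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nvec <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sqrt(rowSums(nvec^2)) / 2
}

#' Edge length statistics
#'
#' Statistics over the unique undirected edge set of the mesh.
#'
#' @param mesh a [tet_mesh()].
#' @return tibble with `mean`, `sd`, `min`, `max` (mm) and `n_edges`.
#' @export
edge_length_stats <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$points[e[, 1], , drop = FALSE] - mesh$points[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  tibble::tibble(mean = mean(len),
                 sd = if (length(len) > 1) stats::sd(len) else 0,
                 min = min(len), max = max(len), n_edges = length(len))
}

#' Lumped anatomical measures per ventricle
#'
#' Derives the scalar anatomy the beat surrogate consumes: end-diastolic
#' cavity volume (closed endocardial surface, divergence theorem),
#' myocardial wall volume (sum of element volumes by label), mass
#' (wall volume x density), endocardial area, apicobasal length (extent
#' along the first principal axis of the ventricle's nodes) and mean wall
#' thickness approximated as wall volume / endocardial area.
#'
#' @param mesh a [tet_mesh()] carrying `meta$surfaces` (per-ventricle closed
#'   endocardial triangle sets, as built by [build_template()]) and cell
#'   labels from `meta$tags`.
#' @param density myocardial density in g/mL (default 1.05).
#' @return tibble, one row per ventricle: `ventricle`, `edv` (mL),
#'   `wall_volume` (mL), `mass` (g), `endo_area` (cm^2),
#'   `apicobasal_length` (mm), `mean_wall_thickness` (mm).
#' @export
lumped_anatomy <- function(mesh, density = 1.05) {
  if (is.null(mesh$cell_labels) || is.null(mesh$meta$surfaces)) {
    stop("lumped_anatomy needs cell labels and meta$surfaces ",
         "(endocardial surface sets)", call. = FALSE)
  }
  tags <- mesh$meta$tags %||% c(LV = 1L, RV = 2L)
  vols <- tet_volumes(mesh)
  purrr::map_dfr(names(mesh$meta$surfaces), function(vent) {
    surf <- mesh$meta$surfaces[[vent]]
    wall_mm3 <- sum(vols[mesh$cell_labels == tags[[vent]]])
    edv <- cavity_volume_stokes(mesh$points, rbind(surf$wall, surf$cap))
    area_mm2 <- sum(triangle_areas(mesh$points, surf$wall))
    nodes <- mesh$meta$node_sets[[vent]]$all
    pts <- mesh$points[nodes, , drop = FALSE]
    ax <- stats::prcomp(pts, center = TRUE, scale. = FALSE)$x[, 1]
    tibble::tibble(
      ventricle = vent,
      edv = edv,
      wall_volume = wall_mm3 / 1000,
      mass = wall_mm3 / 1000 * density,
      endo_area = area_mm2 / 100,
      apicobasal_length = diff(range(ax)),
      mean_wall_thickness = wall_mm3 / area_mm2)
  })
}

#' Per-mesh quality-control report
#'
#' @param mesh a [tet_mesh()].
#' @param sj_threshold elements with scaled Jacobian below this fraction are
#'   counted as poor (default 0.2).
#' @return one-row tibble with SJ min/mean, percentage of poor elements,
#'   edge statistics and total myocardial volume.
#' @export
mesh_qc_report <- function(mesh, sj_threshold = 0.2) {
  sj <- scaled_jacobian(mesh)
  es <- edge_length_stats(mesh)
  tibble::tibble(
    name = mesh$name, n_points = nrow(mesh$points), n_tets = nrow(mesh$tets),
    sj_min = min(sj), sj_mean = mean(sj),
    pct_sj_below = 100 * mean(sj < sj_threshold),
    edge_mean = es$mean, edge_sd = es$sd,
    total_volume_ml = sum(tet_volumes(mesh)) / 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
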