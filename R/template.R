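# Idealised biventricular template -------------------------------------------
#
# Each ventricle is a thick-walled truncated ellipsoid "cup": the endocardial
# surface is an ellipsoid (semi-axes a, b, c) truncated by the base plane
# z = k*c, and the wall is obtained by offsetting along the outward surface
# normal by the wall thickness h. Nodes live on a structured (u, phi, w)
# grid (apicobasal angle, circumferential angle, transmural fraction); each
# hexahedral grid cell is split into 12 tetrahedra through its centroid
# (apex wedges into 8), which is face-compatible by construction.

cup_geom <- function(center, a, b, c, h, k, label, name) {
  list(center = center, a = a, b = b, c = c, h = h, k = k,
       u_max = acos(-k), label = as.integer(label), name = name)
}

# endocardial point + unit outward normal for parametric coordinates
cup_endo <- function(geom, u, phi) {
  su <- sin(u)
  ex <- geom$a * su * cos(phi)
  ey <- geom$b * su * sin(phi)
  ez <- -geom$c * cos(u)
  nx <- su * cos(phi) / geom$a
  ny <- su * sin(phi) / geom$b
  nz <- -cos(u) / geom$c
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  list(endo = cbind(geom$center[1] + ex, geom$center[2] + ey,
                    geom$center[3] + ez),
       normal = cbind(nx / nn, ny / nn, nz / nn))
}

# shell node positions for a wall thickness h (mm)
cup_positions <- function(geom, u, phi, w, h) {
  e <- cup_endo(geom, u, phi)
  e$endo + (w * h) * e$normal
}

split_quads <- function(quads) {
  # split each quad (rows, cyclic vertex order) along the diagonal through
  # its smallest global vertex index; face-compatible across cells
  amin <- max.col(-quads, ties.method = "first")
  odd <- amin == 1L | amin == 3L
  t1 <- cbind(quads[, 1], quads[, 2], quads[, 3])
  t2 <- cbind(quads[, 1], quads[, 3], quads[, 4])
  t1[!odd, ] <- cbind(quads[!odd, 2], quads[!odd, 3], quads[!odd, 4])
  t2[!odd, ] <- cbind(quads[!odd, 2], quads[!odd, 4], quads[!odd, 1])
  rbind(t1, t2)
}

build_cup <- function(geom, resolution, offset) {
  if (geom$h < resolution / 2) {
    stop("resolution ", resolution, " mm too coarse for the ", geom$name,
         " wall (", geom$h, " mm): fewer than one element through thickness",
         call. = FALSE)
  }
  mean_r <- (geom$a + geom$c) / 2
  nu <- max(4L, as.integer(round(geom$u_max * mean_r / resolution)))
  # azimuthal count uses ~3/4 of the equatorial circumference: lat-long
  # grids over-resolve azimuthally towards the pole, and slightly wider
  # equatorial cells keep the apex elements well shaped
  nphi <- max(8L, as.integer(round(0.75 * pi * (geom$a + geom$b) /
                                     resolution)))
  nw <- max(1L, as.integer(round(geom$h / resolution)))

  B <- nu * nphi + 1L  # nodes per transmural layer (apex + shell rings)
  apex_id <- function(l) offset + l * B + 1L
  shell_id <- function(i, j, l) {
    offset + l * B + 1L + (i - 1L) * nphi + (j %% nphi) + 1L
  }

  # frame: parametric coordinates per shell node, layer-major; the
  # apicobasal grid is power-graded (exponent 0.75) to widen the first ring
  # around the pole, which keeps the apex wedge elements from degenerating
  l_seq <- rep(0:nw, each = B)
  u_frac <- (seq_len(nu) / nu)^0.75
  within_layer_u <- c(0, rep(u_frac, each = nphi) * geom$u_max)
  within_layer_phi <- c(0, rep(2 * pi * (0:(nphi - 1)) / nphi, times = nu))
  frame <- data.frame(
    u = rep(within_layer_u, nw + 1L),
    phi = rep(within_layer_phi, nw + 1L),
    w = l_seq / nw,
    type = rep(c("apex", rep("shell", nu * nphi)), nw + 1L),
    stringsAsFactors = FALSE)
  n_shell_nodes <- nrow(frame)

  # hexahedral cells (i >= 1) and apex wedges (i = 0)
  hx <- expand.grid(j = 0:(nphi - 1L), i = 1:(nu - 1L), l = 0:(nw - 1L))
  hex_corners <- cbind(
    shell_id(hx$i,      hx$j,      hx$l),
    shell_id(hx$i + 1L, hx$j,      hx$l),
    shell_id(hx$i + 1L, hx$j + 1L, hx$l),
    shell_id(hx$i,      hx$j + 1L, hx$l),
    shell_id(hx$i,      hx$j,      hx$l + 1L),
    shell_id(hx$i + 1L, hx$j,      hx$l + 1L),
    shell_id(hx$i + 1L, hx$j + 1L, hx$l + 1L),
    shell_id(hx$i,      hx$j + 1L, hx$l + 1L))
  wd <- expand.grid(j = 0:(nphi - 1L), l = 0:(nw - 1L))
  wedge_corners <- cbind(
    apex_id(wd$l),
    shell_id(1L, wd$j,      wd$l),
    shell_id(1L, wd$j + 1L, wd$l),
    apex_id(wd$l + 1L),
    shell_id(1L, wd$j,      wd$l + 1L),
    shell_id(1L, wd$j + 1L, wd$l + 1L))

  n_hex <- nrow(hex_corners)
  centroid_hex <- offset + n_shell_nodes + seq_len(n_hex)

  hex_faces <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 4, 8, 5),
                    c(2, 3, 7, 6), c(1, 2, 6, 5), c(4, 3, 7, 8))
  tets <- vector("list", 7L)
  k <- 1L
  for (f in hex_faces) {
    tris <- split_quads(hex_corners[, f, drop = FALSE])
    tets[[k]] <- cbind(tris, rep(centroid_hex, 2L)); k <- k + 1L
  }
  # apex wedges (prisms A,P0,Q0 / B,P1,Q1) split directly into 3 tets each;
  # the outer-quad diagonal follows the smallest-global-index rule so the
  # split stays compatible with the neighbouring hex faces
  wA <- wedge_corners[, 1]; wP0 <- wedge_corners[, 2]
  wQ0 <- wedge_corners[, 3]; wB <- wedge_corners[, 4]
  wP1 <- wedge_corners[, 5]; wQ1 <- wedge_corners[, 6]
  pq <- wP0 < wQ0
  w1 <- cbind(wA, ifelse(pq, wP0, wQ0), ifelse(pq, wQ0, wP0),
              ifelse(pq, wQ1, wP1))
  w2 <- cbind(wA, ifelse(pq, wP0, wQ0), ifelse(pq, wQ1, wP1),
              ifelse(pq, wP1, wQ1))
  w3 <- cbind(wA, wP1, wQ1, wB)
  tets[[k]] <- rbind(w1, w2, w3)
  tets <- do.call(rbind, tets)

  # endocardial cavity surface: apex fan + shell quads + basal cap,
  # outward-oriented with respect to the enclosed cavity
  j0 <- 0:(nphi - 1L)
  apex_fan <- cbind(apex_id(0L), shell_id(1L, j0 + 1L, 0L),
                    shell_id(1L, j0, 0L))
  sq <- expand.grid(j = 0:(nphi - 1L), i = 1:(nu - 1L))
  wall_quads <- cbind(shell_id(sq$i, sq$j, 0L),
                      shell_id(sq$i, sq$j + 1L, 0L),
                      shell_id(sq$i + 1L, sq$j + 1L, 0L),
                      shell_id(sq$i + 1L, sq$j, 0L))
  wall <- rbind(apex_fan,
                cbind(wall_quads[, 1], wall_quads[, 2], wall_quads[, 3]),
                cbind(wall_quads[, 1], wall_quads[, 3], wall_quads[, 4]))
  rim <- shell_id(nu, j0, 0L)
  cap <- cbind(rim[1], rim[2:(nphi - 1L)], rim[3:nphi])

  list(geom = geom, nu = nu, nphi = nphi, nw = nw, frame = frame,
       n_shell_nodes = n_shell_nodes,
       centroid_corners = hex_corners,
       centroid_ids = centroid_hex,
       tets = tets,
       n_cells = n_hex,
       surfaces = list(wall = wall, cap = cap),
       shell_ids = offset + seq_len(n_shell_nodes),
       endo_ids = offset + which(frame$w == 0),
       epi_ids = offset + which(frame$w == 1),
       apex_endo_id = apex_id(0L))
}

# positions of every node of a cup (shell from the parametric frame,
# centroids as corner means), given a wall thickness
cup_all_positions <- function(cup, h) {
  shell <- cup_positions(cup$geom, cup$frame$u, cup$frame$phi,
                         cup$frame$w, h)
  shell
}

centroid_positions <- function(points, centroid_corners) {
  # corner means; wedge rows repeat two corners, mean over stored 8 columns
  # weights them consistently for every call
  (points[centroid_corners[, 1], ] + points[centroid_corners[, 2], ] +
   points[centroid_corners[, 3], ] + points[centroid_corners[, 4], ] +
   points[centroid_corners[, 5], ] + points[centroid_corners[, 6], ] +
   points[centroid_corners[, 7], ] + points[centroid_corners[, 8], ]) / 8
}

#' Build the biventricular template mesh
#'
#' Constructs a fixed-topology, idealised two-ventricle tetrahedral mesh:
#' a thick-walled truncated-ellipsoid LV and a thinner, flattened
#' truncated-ellipsoid RV. Cell labels mark LV/RV myocardium, closed
#' endocardial surface triangle sets and endo/epi node sets are attached as
#' metadata, and UVC (transmural rho, circumferential phi, apicobasal Z in
#' \[0, 1\], ventricle flag V = -1 LV / +1 RV) are stored per point.
#' Topology is identical for every call at the same resolution.
#'
#' @param resolution target mean edge length in mm (default 6; clinical
#'   ~1 mm meshes are cluster-sized, this default keeps the pipeline at
#'   desk scale with a few thousand nodes).
#' @param lv,rv named lists overriding the default cup geometry
#'   (`a`, `b`, `c` endocardial semi-axes mm, `h` wall thickness mm,
#'   `k` basal truncation fraction, `center`).
#' @return a [tet_mesh()] with full `meta`.
#' @export
build_template <- function(resolution = 6, lv = list(), rv = list()) {
  lv_def <- list(center = c(0, 0, 0), a = 28, b = 28, c = 48, h = 10,
                 k = 0.35)
  rv_def <- list(center = c(75, 0, 0), a = 34, b = 22, c = 44, h = 5,
                 k = 0.30)
  lv <- utils::modifyList(lv_def, lv)
  rv <- utils::modifyList(rv_def, rv)
  tags <- c(LV = 1L, RV = 2L)
  geoms <- list(
    LV = cup_geom(lv$center, lv$a, lv$b, lv$c, lv$h, lv$k, tags["LV"], "LV"),
    RV = cup_geom(rv$center, rv$a, rv$b, rv$c, rv$h, rv$k, tags["RV"], "RV"))

  cups <- list()
  offset <- 0L
  for (v in names(geoms)) {
    cup <- build_cup(geoms[[v]], resolution, offset)
    offset <- offset + cup$n_shell_nodes + cup$n_cells
    cups[[v]] <- cup
  }

  n_points <- offset
  points <- matrix(0, n_points, 3)
  uvc <- matrix(0, n_points, 4)
  frame <- data.frame(node = seq_len(n_points),
                      ventricle = NA_character_, type = NA_character_,
                      u = NA_real_, phi = NA_real_, w = NA_real_)
  tets <- NULL; labels <- NULL
  surfaces <- list(); node_sets <- list()
  centroid_ids <- integer(0); centroid_corners <- NULL

  for (v in names(cups)) {
    cup <- cups[[v]]
    shell <- cup_all_positions(cup, cup$geom$h)
    points[cup$shell_ids, ] <- shell
    frame$ventricle[cup$shell_ids] <- v
    frame$type[cup$shell_ids] <- cup$frame$type
    frame$u[cup$shell_ids] <- cup$frame$u
    frame$phi[cup$shell_ids] <- cup$frame$phi
    frame$w[cup$shell_ids] <- cup$frame$w
    frame$ventricle[cup$centroid_ids] <- v
    frame$type[cup$centroid_ids] <- "centroid"
    points[cup$centroid_ids, ] <- centroid_positions(points,
                                                     cup$centroid_corners)
    tets <- rbind(tets, cup$tets)
    labels <- c(labels, rep(cup$geom$label, nrow(cup$tets)))
    surfaces[[v]] <- cup$surfaces
    node_sets[[v]] <- list(
      all = c(cup$shell_ids, cup$centroid_ids),
      endo = cup$endo_ids, epi = cup$epi_ids,
      apex_endo = cup$apex_endo_id)
    centroid_ids <- c(centroid_ids, cup$centroid_ids)
    centroid_corners <- rbind(centroid_corners, cup$centroid_corners)

    vflag <- if (v == "LV") -1 else 1
    z_ab <- pmin(1, pmax(0, cup$frame$u / cup$geom$u_max))
    uvc[cup$shell_ids, ] <- cbind(cup$frame$w, cup$frame$phi, z_ab, vflag)
    cz <- (z_ab[cup$centroid_corners[, 1] - min(cup$shell_ids) + 1L] * 0)
    # centroid UVC: mean of corner values (phi via unit-vector mean)
    corner_local <- cup$centroid_corners - min(cup$shell_ids) + 1L
    mean_of <- function(x) {
      rowMeans(matrix(x[corner_local], nrow = nrow(corner_local)))
    }
    cphi <- atan2(mean_of(sin(cup$frame$phi)), mean_of(cos(cup$frame$phi)))
    uvc[cup$centroid_ids, ] <- cbind(mean_of(cup$frame$w), cphi,
                                     mean_of(z_ab), vflag)
  }

  # enforce positive element orientation once; connectivity is then frozen
  mesh0 <- tet_mesh(points, tets, name = "template")
  vneg <- tet_volumes(mesh0) < 0
  tets[vneg, 2:3] <- tets[vneg, 3:2, drop = FALSE]

  # endocardial surfaces: flip jointly if the enclosed volume comes out
  # negative (deterministic safeguard, orientation is outward by design)
  for (v in names(surfaces)) {
    tri <- rbind(surfaces[[v]]$wall, surfaces[[v]]$cap)
    vol <- tryCatch(cavity_volume_stokes(points, tri), error = function(e) -1)
    if (vol < 0) {
      surfaces[[v]]$wall <- surfaces[[v]]$wall[, c(1, 3, 2)]
      surfaces[[v]]$cap <- surfaces[[v]]$cap[, c(1, 3, 2)]
    }
  }

  tet_mesh(points, tets, cell_labels = labels, uvc = uvc, name = "template",
           meta = list(
             tags = tags, resolution = resolution,
             geoms = geoms, frame = frame,
             cups = lapply(cups, function(cup) {
               cup[c("nu", "nphi", "nw", "shell_ids", "centroid_ids",
                     "n_shell_nodes")]
             }),
             centroid_ids = centroid_ids,
             centroid_corners = centroid_corners,
             surfaces = surfaces, node_sets = node_sets))
}
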