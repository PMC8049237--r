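# Latent-factor deformations of the template ---------------------------------

#' Anatomical deformation parameters
#'
#' The latent factors the synthetic cohort varies, chosen to mimic the
#' anatomical meaning of dominant shape modes in biventricular cohorts:
#' global size, sphericity (long-axis vs short-axis ratio), wall
#' thicknesses, whole-heart orientation, and a localised septal-basal bulge.
#'
#' @param scale global size factor (1 = template), applied about the heart
#'   centroid.
#' @param sphericity long-axis modifier: the apicobasal (z) axis is scaled
#'   by `scale / sphericity`, so values > 1 shorten the heart (more
#'   spherical), values < 1 elongate it.
#' @param lv_wall_thickness,rv_wall_thickness wall thicknesses in mm
#'   (template defaults 10 and 5).
#' @param orientation length-3 axis-angle vector in degrees (norm = angle,
#'   direction = axis); rigid rotation about the heart centroid.
#' @param basal_bulge amplitude (mm, >= 0) of a Gaussian-windowed inward
#'   displacement of septal LV nodes with apicobasal Z > 0.8.
#' @return object of class `anatomy_params`.
#' @export
anatomy_params <- function(scale = 1, sphericity = 1,
                           lv_wall_thickness = 10, rv_wall_thickness = 5,
                           orientation = c(0, 0, 0), basal_bulge = 0) {
  stopifnot(scale > 0, sphericity > 0, lv_wall_thickness > 0,
            rv_wall_thickness > 0, basal_bulge >= 0,
            length(orientation) == 3)
  structure(list(scale = scale, sphericity = sphericity,
                 lv_wall_thickness = lv_wall_thickness,
                 rv_wall_thickness = rv_wall_thickness,
                 orientation = orientation, basal_bulge = basal_bulge),
            class = "anatomy_params")
}

rotation_matrix_axis_angle <- function(axis_angle_deg) {
  angle <- sqrt(sum(axis_angle_deg^2))
  if (angle == 0) return(diag(3))
  k <- axis_angle_deg / angle
  th <- angle * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# recompute centroid rows and return the full point matrix
finish_points <- function(points, meta) {
  points[meta$centroid_ids, ] <-
    centroid_positions(points, meta$centroid_corners)
  points
}

check_not_inverted <- function(points, template, stage) {
  m <- template
  m$points <- points
  if (min(tet_volumes(m)) <= 0) {
    stop("deformation inverts mesh elements; offending factor: ", stage,
         call. = FALSE)
  }
}

#' Deform the template with latent anatomical factors
#'
#' Applies, in order: wall-thickness reconstruction from the parametric
#' frame (endocardium fixed, transmural offset rescaled), the septal-basal
#' bulge, a single anisotropic scaling about the heart centroid combining
#' global `scale` and `sphericity`, and the rigid `orientation` rotation.
#' Identity parameters reproduce the template exactly. Parameters that
#' invert any element raise an error naming the offending factor.
#'
#' @param template mesh from [build_template()].
#' @param params an [anatomy_params()].
#' @return a deformed [tet_mesh()] sharing the template topology and meta.
#' @export
deform_template <- function(template, params) {
  meta <- template$meta
  if (is.null(meta$frame)) {
    stop("deform_template needs a template from build_template()",
         call. = FALSE)
  }
  h_new <- c(LV = params$lv_wall_thickness, RV = params$rv_wall_thickness)
  points <- template$points
  for (v in names(meta$geoms)) {
    cup <- meta$cups[[v]]
    ids <- cup$shell_ids
    points[ids, ] <- cup_positions(meta$geoms[[v]],
                                   meta$frame$u[ids], meta$frame$phi[ids],
                                   meta$frame$w[ids], h_new[[v]])
  }
  points <- finish_points(points, meta)
  if (any(h_new != vapply(meta$geoms, function(g) g$h, 0))) {
    check_not_inverted(points, template, "wall thickness")
  }

  if (params$basal_bulge > 0) {
    g <- meta$geoms$LV
    ids <- meta$cups$LV$shell_ids
    u <- meta$frame$u[ids]; phi <- meta$frame$phi[ids]
    z_ab <- u / g$u_max
    # septum faces the RV (+x): window centred at phi = 0, basal Z = 1
    dphi <- atan2(sin(phi), cos(phi))
    win <- exp(-(dphi^2 / (2 * 0.9^2) + (z_ab - 1)^2 / (2 * 0.15^2)))
    win[z_ab <= 0.8] <- 0
    nrm <- cup_endo(g, u, phi)$normal
    points[ids, ] <- points[ids, ] - (params$basal_bulge * win) * nrm
    points <- finish_points(points, meta)
    check_not_inverted(points, template, "basal_bulge")
  }

  if (params$scale != 1 || params$sphericity != 1) {
    shell <- unlist(lapply(meta$cups, `[[`, "shell_ids"))
    c0 <- colMeans(points[shell, , drop = FALSE])
    s <- c(params$scale, params$scale, params$scale / params$sphericity)
    points <- sweep(sweep(points, 2, c0), 2, s, `*`)
    points <- sweep(points, 2, c0, `+`)
    points <- finish_points(points, meta)
    check_not_inverted(points, template,
                       if (params$sphericity != 1) "sphericity" else "scale")
  }

  if (any(params$orientation != 0)) {
    shell <- unlist(lapply(meta$cups, `[[`, "shell_ids"))
    c0 <- colMeans(points[shell, , drop = FALSE])
    R <- rotation_matrix_axis_angle(params$orientation)
    points <- sweep(sweep(points, 2, c0) %*% t(R), 2, c0, `+`)
    points <- finish_points(points, meta)
  }

  out <- template
  out$points <- points
  validate_tet_mesh(out)
  out
}
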