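# Synthetic cohort generation -------------------------------------------------

#' Cohort sampling specification
#'
#' @param n_cases number of cases (>= 3; default 19, the size of the SSM
#'   training cohort the pipeline emulates).
#' @param latent_sds standard deviations of the independent zero-mean
#'   Gaussian latent factors, strictly positive and non-increasing. Up to
#'   five factors are interpreted, in order: global scale, sphericity, wall
#'   thickness, orientation, basal bulge (see [latent_to_params()]). The
#'   defaults, together with the fixed factor gains and the node noise,
#'   shape the cohort's variance spectrum like a small healthy-adult cohort:
#'   the first two aligned modes carry roughly half the variance and ~90%
#'   is reached around mode 9.
#' @param node_noise_sd mm of iid per-node Gaussian jitter standing in for
#'   local anatomical variability the latent factors do not model
#'   (default 0.4).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 19,
                        latent_sds = c(0.035, 0.028, 0.021, 0.014, 0.0105),
                        node_noise_sd = 0.4, seed = 1L) {
  stopifnot(n_cases >= 3, all(latent_sds > 0),
            all(diff(latent_sds) <= 0), node_noise_sd >= 0,
            length(latent_sds) >= 1, length(latent_sds) <= 5)
  structure(list(n_cases = as.integer(n_cases), latent_sds = latent_sds,
                 node_noise_sd = node_noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Map dimensionless latent factors to anatomical parameters
#'
#' Factors are dimensionless; fixed gains convert them to physical
#' parameters: `scale = 1 + 0.4 z1`, `sphericity = 1 + z2`, wall
#' thicknesses multiplied by `1 + 4.4 z3`, orientation `36 z4` degrees
#' about the z axis, basal bulge `210 |z5|` mm. The gains equalise the
#' whole-mesh displacement each factor contributes per unit latent value,
#' so the default `latent_sds` translate directly into the cohort's
#' variance spectrum. Unused trailing factors default to the identity.
#'
#' @param z numeric vector of up to 5 latent factors.
#' @param template template mesh (for its baseline wall thicknesses).
#' @return an [anatomy_params()].
#' @export
latent_to_params <- function(z, template) {
  z <- c(z, rep(0, 5 - length(z)))
  g <- template$meta$geoms
  anatomy_params(
    scale = 1 + 0.4 * z[1],
    sphericity = 1 + z[2],
    lv_wall_thickness = g$LV$h * (1 + 4.4 * z[3]),
    rv_wall_thickness = g$RV$h * (1 + 4.4 * z[3]),
    orientation = c(0, 0, 36 * z[4]),
    basal_bulge = 210 * abs(z[5]))
}

#' Sample a synthetic cohort with known latent factors
#'
#' Draws independent zero-mean Gaussian latent factors per case, deforms the
#' template, and adds iid per-node jitter. All meshes share the template
#' topology (exact point correspondence). Deterministic for a fixed seed.
#' A case whose deformation inverts elements is redrawn (up to 5 retries).
#'
#' @param spec a [cohort_spec()].
#' @param template mesh from [build_template()] (built at its default
#'   resolution when omitted).
#' @return list with `meshes` (named list of [tet_mesh()]), `factors`
#'   (tibble of the true latent factors, one row per case), and `spec`.
#' @export
sample_cohort <- function(spec, template = build_template()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  K <- length(spec$latent_sds)
  meshes <- vector("list", spec$n_cases)
  factors <- matrix(NA_real_, spec$n_cases, K)
  shell_ids <- unlist(lapply(template$meta$cups, `[[`, "shell_ids"))
  for (i in seq_len(spec$n_cases)) {
    mesh <- NULL
    for (attempt in 1:5) {
      z <- stats::rnorm(K, 0, spec$latent_sds)
      mesh <- tryCatch(
        deform_template(template, latent_to_params(z, template)),
        error = function(e) NULL)
      if (!is.null(mesh) && spec$node_noise_sd > 0) {
        noise <- matrix(stats::rnorm(3 * length(shell_ids), 0,
                                     spec$node_noise_sd),
                        ncol = 3)
        mesh$points[shell_ids, ] <- mesh$points[shell_ids, ] + noise
        mesh$points <- finish_points(mesh$points, template$meta)
        if (min(tet_volumes(mesh)) <= 0) mesh <- NULL
      }
      if (!is.null(mesh)) break
    }
    if (is.null(mesh)) {
      stop("case ", i, ": deformation kept inverting elements after 5 ",
           "retries; reduce latent_sds or node_noise_sd", call. = FALSE)
    }
    mesh$name <- sprintf("case_%02d", i)
    meshes[[i]] <- mesh
    factors[i, ] <- z
  }
  names(meshes) <- vapply(meshes, `[[`, "", "name")
  colnames(factors) <- paste0("factor_", seq_len(K))
  list(meshes = meshes,
       factors = tibble::as_tibble(cbind(
         tibble::tibble(case = names(meshes)),
         tibble::as_tibble(factors))),
       spec = spec)
}
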