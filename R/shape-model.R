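# Statistical shape model ------------------------------------------------------

kabsch_rotation <- function(P, Q) {
  # least-squares rotation (no scaling) mapping centred P onto centred Q
  # returns W with P %*% W ~ Q (rows are points)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigidly align a cohort of corresponding meshes to a reference
#'
#' Least-squares rotation + translation (no scaling) per mesh, minimising
#' the point RMSD to the reference; size differences deliberately survive
#' into the shape model.
#'
#' @param meshes list of [tet_mesh()] sharing the reference topology.
#' @param reference a [tet_mesh()].
#' @return list with `meshes` (aligned), `transforms` (list of `R`, `t`),
#'   and `rmsd` tibble (residual RMSD in mm per case).
#' @export
rigid_align <- function(meshes, reference) {
  ref <- reference$points
  ref_c <- sweep(ref, 2, colMeans(ref))
  out <- purrr::map(meshes, function(m) {
    if (nrow(m$points) != nrow(ref) || !identical(dim(m$tets),
                                                  dim(reference$tets))) {
      stop("topology mismatch: all meshes must share the reference topology",
           call. = FALSE)
    }
    mu <- colMeans(m$points)
    P <- sweep(m$points, 2, mu)
    R <- kabsch_rotation(P, ref_c)
    aligned <- sweep(P %*% R, 2, colMeans(ref), `+`)
    a <- m
    a$points <- aligned
    list(mesh = a, R = R, t = colMeans(ref) - mu %*% R,
         rmsd = sqrt(mean(rowSums((aligned - ref)^2))))
  })
  list(meshes = purrr::map(out, "mesh"),
       transforms = purrr::map(out, ~ .x[c("R", "t")]),
       rmsd = tibble::tibble(
         case = names(meshes) %||% as.character(seq_along(meshes)),
         rmsd = purrr::map_dbl(out, "rmsd")))
}

#' Fit a PCA statistical shape model on node displacement fields
#'
#' PCA of the n x 3N matrix of node displacements from the cohort mean.
#' Modes are orthonormal displacement fields ordered by decreasing variance;
#' subject weights reproduce each case exactly when all modes are retained.
#' Mode signs are fixed so each mode's largest-magnitude coordinate is
#' positive.
#'
#' @param meshes list of >= 3 aligned [tet_mesh()] with shared topology.
#' @param exclude optional case names to drop before fitting.
#' @return object of class `shape_model` with fields `mean_points`, `modes`
#'   (3N x K), `mode_sds`, `explained_variance_ratio`, `subject_weights`
#'   (n x K, mm scale), `case_names`, `template` (topology carrier).
#' @export
fit_ssm <- function(meshes, exclude = NULL) {
  if (!is.null(exclude)) meshes <- meshes[setdiff(names(meshes), exclude)]
  n <- length(meshes)
  if (n < 3) stop("need at least 3 meshes to fit a shape model",
                  call. = FALSE)
  X <- t(vapply(meshes, function(m) flatten_points(m$points),
                numeric(3 * nrow(meshes[[1]]$points))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = n, nv = n)
  keep <- which(s$d > max(s$d) * 1e-10)
  keep <- keep[keep <= n - 1]
  modes <- s$v[, keep, drop = FALSE]
  # sign convention: largest-magnitude coordinate of each mode positive
  for (k in seq_along(keep)) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) {
      modes[, k] <- -modes[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  d <- s$d[keep]
  weights <- s$u[, keep, drop = FALSE] %*% diag(d, length(keep))
  colnames(weights) <- paste0("mode_", seq_along(keep))
  rownames(weights) <- names(meshes)
  structure(list(
    mean_points = unflatten_points(mu),
    modes = modes,
    mode_sds = d / sqrt(n - 1),
    explained_variance_ratio = d^2 / sum(d^2),
    subject_weights = weights,
    case_names = names(meshes),
    template = meshes[[1]]), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("shape_model:", length(x$case_names), "subjects,",
      ncol(x$modes), "modes over", nrow(x$modes), "coordinates\n")
  cat("  explained variance (first 5):",
      paste0(round(100 * utils::head(x$explained_variance_ratio, 5), 2),
             "%", collapse = ", "), "\n")
  invisible(x)
}

#' Project a mesh onto the shape model
#'
#' Mode-wise inner products of the displacement from the model mean.
#'
#' @param mesh a [tet_mesh()] rigidly aligned to the model frame.
#' @param model a [fit_ssm()] model.
#' @param units `"raw"` (mm scale) or `"sd"` (per-mode standard deviations).
#' @return numeric weight vector of length K.
#' @export
project_shape <- function(mesh, model, units = c("raw", "sd")) {
  units <- match.arg(units)
  d <- flatten_points(mesh$points) - flatten_points(model$mean_points)
  w <- drop(crossprod(model$modes, d))
  if (units == "sd") w <- w / model$mode_sds
  stats::setNames(w, colnames(model$subject_weights))
}

#' Reconstruct a mesh from shape-model weights
#'
#' @param weights numeric vector of length K (raw mm scale, or SD units with
#'   `units = "sd"`).
#' @param model a [fit_ssm()] model.
#' @param units interpretation of `weights`.
#' @param name name for the reconstructed mesh.
#' @return a [tet_mesh()] on the model's template topology.
#' @export
reconstruct_shape <- function(weights, model, units = c("raw", "sd"),
                              name = "reconstruction") {
  units <- match.arg(units)
  if (length(weights) != ncol(model$modes)) {
    stop("weight vector length ", length(weights),
         " does not match the model's ", ncol(model$modes), " modes",
         call. = FALSE)
  }
  if (units == "sd") weights <- weights * model$mode_sds
  pts <- unflatten_points(flatten_points(model$mean_points) +
                            drop(model$modes %*% weights))
  out <- model$template
  out$points <- pts
  out$name <- name
  out
}

#' Number of modes needed to reach a variance fraction
#'
#' @param model a [fit_ssm()] model.
#' @param fraction target cumulative explained-variance fraction in (0, 1].
#' @return smallest K whose cumulative explained variance ratio >= fraction.
#' @export
modes_for_threshold <- function(model, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  cum <- cumsum(model$explained_variance_ratio)
  which(cum >= fraction - 1e-12)[1]
}

#' Generate an extreme synthetic cohort along single modes
#'
#' One mesh per (mode, signed multiplier): average + multiplier * mode SD *
#' mode. Meshes with inverted elements are still emitted but flagged,
#' mirroring cohorts in which extreme anatomies fail downstream.
#'
#' @param model a [fit_ssm()] model.
#' @param modes integer mode indices (default: all).
#' @param multipliers signed SD multipliers, subset of -3:3 (default
#'   `c(-3, 3)`).
#' @return list with `meshes` (named list) and `manifest` tibble
#'   (`case`, `mode`, `multiplier`, `inverted`).
#' @export
make_extreme_cohort <- function(model, modes = seq_len(ncol(model$modes)),
                                multipliers = c(-3, 3)) {
  stopifnot(all(multipliers %in% -3:3), all(modes <= ncol(model$modes)))
  grid <- expand.grid(multiplier = multipliers, mode = modes)
  meshes <- list()
  manifest <- purrr::pmap_dfr(grid, function(multiplier, mode) {
    w <- numeric(ncol(model$modes))
    w[mode] <- multiplier * model$mode_sds[mode]
    nm <- sprintf("mode%02d_%+dsd", mode, multiplier)
    mesh <- reconstruct_shape(w, model, name = nm)
    meshes[[nm]] <<- mesh
    tibble::tibble(case = nm, mode = mode, multiplier = multiplier,
                   inverted = min(tet_volumes(mesh)) <= 0)
  })
  list(meshes = meshes, manifest = manifest)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.shape_model <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$mode_sds),
                 sd = x$mode_sds,
                 explained_variance_ratio = x$explained_variance_ratio,
                 cumulative_variance = cumsum(x$explained_variance_ratio))
}

#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$case_names),
                 n_modes = ncol(x$modes),
                 n_points = nrow(x$mean_points),
                 modes_for_90pct = modes_for_threshold(x, 0.9))
}

#' Subject weights as a tibble
#'
#' @param model a [fit_ssm()] model.
#' @param units `"raw"` (mm) or `"sd"`.
#' @return tibble with `case` and one column per mode.
#' @export
ssm_weights <- function(model, units = c("raw", "sd")) {
  units <- match.arg(units)
  w <- model$subject_weights
  if (units == "sd") w <- sweep(w, 2, model$mode_sds, `/`)
  tibble::as_tibble(cbind(tibble::tibble(case = model$case_names),
                          tibble::as_tibble(w)))
}
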