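# Graph-eikonal activation -----------------------------------------------------

#' Simulate ventricular activation as shortest traversal times
#'
#' Eikonal-style activation over the mesh edge graph: the traversal time of
#' an edge is its length divided by the conduction velocity (CV), and a fast
#' endocardial conduction (FEC) layer emulating the Purkinje system applies
#' the faster `cv_fec` to any edge whose two endpoints are both endocardial
#' with apicobasal coordinate Z at or below `fec_extent`. Activation times
#' are exact single-source (multi-source) shortest-path times from the
#' stimulus set.
#'
#' @param mesh a [tet_mesh()] with `meta$node_sets` (endocardial flags) and
#'   UVC Z.
#' @param stimulus integer vector of stimulus node indices (default: the
#'   apical endocardial node of each ventricle).
#' @param cv_myo myocardial conduction velocity, mm/ms (default 0.5).
#' @param cv_fec FEC-layer conduction velocity, mm/ms (default 2.0).
#' @param fec_extent apicobasal fraction covered by the FEC layer
#'   (default 0.7, boundary inclusive).
#' @return object of class `activation_map`: list with `times` (ms per
#'   node; `Inf` for disconnected nodes, with a warning), `stimulus`,
#'   `cv_myo`, `cv_fec`, `fec_extent`.
#' @export
simulate_activation <- function(mesh, stimulus = NULL, cv_myo = 0.5,
                                cv_fec = 2.0, fec_extent = 0.7) {
  stopifnot(cv_myo > 0, cv_fec > 0)
  ns <- mesh$meta$node_sets
  if (is.null(stimulus)) {
    if (is.null(ns)) {
      stop("no stimulus given and the mesh carries no node sets",
           call. = FALSE)
    }
    stimulus <- vapply(ns, `[[`, 0L, "apex_endo")
  }
  if (length(stimulus) == 0) stop("stimulus set is empty", call. = FALSE)

  e <- mesh_edges(mesh)
  d <- mesh$points[e[, 1], , drop = FALSE] - mesh$points[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d^2))

  endo <- rep(FALSE, nrow(mesh$points))
  if (!is.null(ns)) endo[unlist(lapply(ns, `[[`, "endo"))] <- TRUE
  z <- if (!is.null(mesh$uvc)) mesh$uvc[, 3] else rep(Inf, nrow(mesh$points))
  in_fec <- endo & z <= fec_extent & z >= 0
  fast <- in_fec[e[, 1]] & in_fec[e[, 2]]
  wt <- len / ifelse(fast, cv_fec, cv_myo)

  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$points)) {
    g <- igraph::add_vertices(g, nrow(mesh$points) - igraph::vcount(g))
  }
  dm <- igraph::distances(g, v = stimulus, weights = wt, algorithm = "dijkstra")
  times <- apply(dm, 2, min)
  if (any(!is.finite(times))) {
    warning(sum(!is.finite(times)),
            " node(s) unreachable from the stimulus; activation time Inf")
  }
  structure(list(times = times, stimulus = stimulus, cv_myo = cv_myo,
                 cv_fec = cv_fec, fec_extent = fec_extent),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  fin <- x$times[is.finite(x$times)]
  cat("activation_map:", length(x$times), "nodes,",
      length(x$stimulus), "stimulus node(s)\n")
  cat(sprintf("  span %.1f ms (CV myo %.2f, FEC %.2f mm/ms, extent %.2f)\n",
              if (length(fin)) max(fin) - min(fin) else NA_real_,
              x$cv_myo, x$cv_fec, x$fec_extent))
  invisible(x)
}

#' Per-ventricle activation trigger times
#'
#' The beat surrogate couples electrophysiology to mechanics through a
#' single trigger per ventricle: the mean activation time of that
#' ventricle's nodes.
#'
#' @param act an [simulate_activation()] map.
#' @param mesh the mesh it was computed on.
#' @return named numeric vector of mean activation times (ms) per ventricle.
#' @export
activation_triggers <- function(act, mesh) {
  vapply(mesh$meta$node_sets, function(s) mean(act$times[s$all]), 0)
}
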