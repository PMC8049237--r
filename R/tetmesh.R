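#' Labelled tetrahedral heart mesh
#'
#' `tet_mesh()` constructs the anatomical unit used throughout the package:
#' a tetrahedral mesh with optional per-element anatomical labels, fibre and
#' sheet direction fields, and per-point universal ventricular coordinates
#' (UVC). Coordinates are in millimetres.
#'
#' Vertex indices are 1-based in memory (R convention) and 0-based on disk
#' (VTK convention); [read_vtk_mesh()] and [write_vtk_mesh()] translate.
#'
#' @param points numeric matrix, `n_points x 3`, coordinates in mm.
#' @param tets integer matrix, `n_tets x 4`, 1-based vertex indices.
#' @param cell_labels optional integer vector, one anatomical tag per element.
#' @param fibre_dir,sheet_dir optional `n_tets x 3` matrices of unit vectors.
#' @param uvc optional `n_points x 4` matrix of universal ventricular
#'   coordinates in the order rho, phi, Z, V. The sentinel value -10 marks
#'   points outside the ventricular myocardium.
#' @param name identifier string.
#' @param meta optional list of construction metadata (surface triangle sets,
#'   node sets, parametric frame). Not serialised to VTK.
#'
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(points, tets, cell_labels = NULL, fibre_dir = NULL,
                     sheet_dir = NULL, uvc = NULL, name = "mesh",
                     meta = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  mesh <- structure(
    list(points = points, tets = tets, cell_labels = cell_labels,
         fibre_dir = fibre_dir, sheet_dir = sheet_dir, uvc = uvc,
         name = name, meta = meta),
    class = "tet_mesh")
  validate_tet_mesh(mesh)
  mesh
}

#' Validate tet_mesh invariants
#'
#' Checks index ranges, unit norm of fibre/sheet fields (within 1e-6), and
#' that the UVC apicobasal coordinate Z lies in \[0, 1\] or equals the -10
#' sentinel.
#'
#' @param mesh a [tet_mesh()].
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_tet_mesh <- function(mesh) {
  stopifnot(is.matrix(mesh$points), ncol(mesh$points) == 3)
  stopifnot(is.matrix(mesh$tets), ncol(mesh$tets) == 4)
  n <- nrow(mesh$points)
  if (nrow(mesh$tets) > 0 &&
      (min(mesh$tets) < 1L || max(mesh$tets) > n)) {
    stop("mesh integrity error: tetrahedron vertex index out of range [1, ",
         n, "]", call. = FALSE)
  }
  if (!is.null(mesh$cell_labels) &&
      length(mesh$cell_labels) != nrow(mesh$tets)) {
    stop("cell_labels length must equal the number of elements", call. = FALSE)
  }
  for (fld in c("fibre_dir", "sheet_dir")) {
    v <- mesh[[fld]]
    if (!is.null(v)) {
      stopifnot(is.matrix(v), ncol(v) == 3, nrow(v) == nrow(mesh$tets))
      nrm <- sqrt(rowSums(v^2))
      if (any(abs(nrm - 1) > 1e-6)) {
        stop(fld, " contains non-unit vectors (tolerance 1e-6)", call. = FALSE)
      }
    }
  }
  if (!is.null(mesh$uvc)) {
    stopifnot(is.matrix(mesh$uvc), ncol(mesh$uvc) == 4,
              nrow(mesh$uvc) == n)
    z <- mesh$uvc[, 3]
    bad <- !(z == -10 | (z >= 0 & z <= 1))
    if (any(bad)) {
      stop("uvc Z must lie in [0, 1] or equal the -10 sentinel",
           call. = FALSE)
    }
  }
  invisible(mesh)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh '", x$name, "': ", nrow(x$points), " points, ",
      nrow(x$tets), " tetrahedra\n", sep = "")
  if (!is.null(x$cell_labels)) {
    tab <- table(x$cell_labels)
    cat("  cell labels:", paste(names(tab), "(", tab, ")",
                                sep = "", collapse = ", "), "\n")
  }
  if (!is.null(x$fibre_dir)) cat("  fibre/sheet directions present\n")
  if (!is.null(x$uvc)) cat("  UVC (rho, phi, Z, V) present\n")
  invisible(x)
}

#' Unique undirected edges of a tetrahedral mesh
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix `n_edges x 2` with each undirected edge once,
#'   smaller index first.
#' @export
mesh_edges <- function(mesh) {
  t4 <- mesh$tets
  pairs <- rbind(t4[, c(1, 2)], t4[, c(1, 3)], t4[, c(1, 4)],
                 t4[, c(2, 3)], t4[, c(2, 4)], t4[, c(3, 4)])
  e <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# flatten n x 3 coordinates column-major (all x, all y, all z); the single
# convention shared by the shape model and its tests
flatten_points <- function(points) as.numeric(points)

unflatten_points <- function(v) matrix(v, ncol = 3)
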