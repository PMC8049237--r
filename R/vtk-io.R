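#' Read a legacy ASCII VTK unstructured-grid tetrahedral mesh
#'
#' Parses the published cohort layout: `POINTS` (coordinates in mm),
#' `CELLS` / `CELL_TYPES` (all type 10, tetrahedra), optional `CELL_DATA`
#' with a scalar tag field and two `VECTORS` fields (fibre and sheet
#' directions), and optional `POINT_DATA` with four scalar lookup tables
#' holding the UVC in the order rho, phi, Z, V (sentinel -10 outside the
#' ventricular myocardium).
#'
#' @param path path to a legacy ASCII `.vtk` file.
#' @return a [tet_mesh()].
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4 || !grepl("^# vtk DataFile", lines[1])) {
    stop("VTK parse error at line 1: expected '# vtk DataFile' header",
         call. = FALSE)
  }
  name <- trimws(lines[2])
  fmt <- toupper(trimws(lines[3]))
  if (fmt != "ASCII") {
    stop("VTK parse error at line 3: only ASCII files are supported, got '",
         lines[3], "'", call. = FALSE)
  }
  ds <- toupper(trimws(lines[4]))
  if (!grepl("^DATASET\\s+UNSTRUCTURED_GRID", ds)) {
    stop("VTK parse error at line 4: expected 'DATASET UNSTRUCTURED_GRID', ",
         "got '", lines[4], "'", call. = FALSE)
  }

  # tokenize the body once; section keywords remain ordinary tokens
  toks <- scan(text = paste(lines[-(1:4)], collapse = "\n"), what = "",
               quiet = TRUE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function(k = 1L) {
    out <- toks[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  take_num <- function(k) {
    v <- suppressWarnings(as.numeric(take(k)))
    if (anyNA(v)) stop("VTK parse error: non-numeric value in section body",
                       call. = FALSE)
    v
  }

  points <- NULL; tets <- NULL; labels <- NULL
  fibre <- NULL; sheet <- NULL; uvc_cols <- list()
  n_cells <- NA_integer_
  context <- ""  # "cell" or "point" after CELL_DATA/POINT_DATA

  while (!is.na(peek())) {
    kw <- toupper(take())
    if (kw == "POINTS") {
      np <- as.integer(take())
      take()  # dtype
      points <- matrix(take_num(3L * np), ncol = 3, byrow = TRUE)
    } else if (kw == "CELLS") {
      n_cells <- as.integer(take())
      total <- as.integer(take())
      body <- take_num(total)
      # every record must be a 4-vertex cell for the layout to be rectangular
      if (total != 5L * n_cells || any(body[seq(1, total, by = 5)] != 4)) {
        stop("unsupported element: only 4-vertex tetrahedral cells are ",
             "supported", call. = FALSE)
      }
      idx <- matrix(body, ncol = 5, byrow = TRUE)[, 2:5, drop = FALSE]
      if (any(idx < 0) || any(idx >= nrow(points))) {
        stop("mesh integrity error: cell vertex index out of range",
             call. = FALSE)
      }
      tets <- idx + 1L
      storage.mode(tets) <- "integer"
    } else if (kw == "CELL_TYPES") {
      nt <- as.integer(take())
      types <- take_num(nt)
      if (any(types != 10)) {
        stop("unsupported element: CELL_TYPES contains type ",
             paste(unique(types[types != 10]), collapse = ", "),
             " (only 10, tetrahedra, is supported)", call. = FALSE)
      }
    } else if (kw == "CELL_DATA") {
      take(); context <- "cell"
    } else if (kw == "POINT_DATA") {
      take(); context <- "point"
    } else if (kw == "SCALARS") {
      sname <- take(); take()  # dtype; optional numComp handled below
      if (!is.na(peek()) && !is.na(suppressWarnings(as.integer(peek())))) {
        take()
      }
      lt <- toupper(take())
      if (lt != "LOOKUP_TABLE") {
        stop("VTK parse error: expected LOOKUP_TABLE after SCALARS ", sname,
             call. = FALSE)
      }
      take()  # table name
      n_val <- if (context == "cell") n_cells else nrow(points)
      vals <- take_num(n_val)
      if (context == "cell") {
        labels <- as.integer(round(vals))
      } else {
        uvc_cols[[sname]] <- vals
      }
    } else if (kw == "VECTORS") {
      take(2L)  # name, dtype
      n_val <- if (context == "cell") n_cells else nrow(points)
      m <- matrix(take_num(3L * n_val), ncol = 3, byrow = TRUE)
      if (is.null(fibre)) fibre <- m else sheet <- m
    } else {
      stop("VTK parse error: unexpected token '", kw, "'", call. = FALSE)
    }
  }
  if (is.null(points) || is.null(tets)) {
    stop("VTK parse error: file lacks POINTS or CELLS section", call. = FALSE)
  }
  uvc <- NULL
  if (length(uvc_cols) == 4L) {
    uvc <- cbind(uvc_cols[[1]], uvc_cols[[2]], uvc_cols[[3]], uvc_cols[[4]])
    colnames(uvc) <- names(uvc_cols)
  } else if (length(uvc_cols) > 0) {
    stop("VTK parse error: expected four UVC scalar fields (rho, phi, Z, V), ",
         "found ", length(uvc_cols), call. = FALSE)
  }
  tet_mesh(points, tets, cell_labels = labels, fibre_dir = fibre,
           sheet_dir = sheet, uvc = uvc, name = name)
}

fmt_num <- function(x) {
  # shortest representation that round-trips doubles exactly
  formatC(x, format = "g", digits = 17)
}

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' Emits sections in the order POINTS, CELLS, CELL_TYPES, CELL_DATA (tags,
#' then fibre and sheet VECTORS), and POINT_DATA with the four UVC lookup
#' tables in the order rho, phi, Z, V. All CELL_TYPES values are 10.
#' Coordinates are written with enough digits to round-trip exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path) {
  validate_tet_mesh(mesh)
  np <- nrow(mesh$points); nt <- nrow(mesh$tets)
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0", mesh$name, "ASCII",
    "DATASET UNSTRUCTURED_GRID")
  w(paste("POINTS", np, "double"))
  w(apply(mesh$points, 1, function(r) paste(fmt_num(r), collapse = " ")))
  w(paste("CELLS", nt, 5L * nt))
  w(apply(mesh$tets - 1L, 1, function(r) paste(c(4L, r), collapse = " ")))
  w(paste("CELL_TYPES", nt))
  w(as.character(rep(10L, nt)))
  if (!is.null(mesh$cell_labels) || !is.null(mesh$fibre_dir)) {
    w(paste("CELL_DATA", nt))
    if (!is.null(mesh$cell_labels)) {
      w("SCALARS tags int 1", "LOOKUP_TABLE default")
      w(as.character(as.integer(mesh$cell_labels)))
    }
    if (!is.null(mesh$fibre_dir)) {
      w("VECTORS fibres double")
      w(apply(mesh$fibre_dir, 1,
              function(r) paste(fmt_num(r), collapse = " ")))
    }
    if (!is.null(mesh$sheet_dir)) {
      w("VECTORS sheets double")
      w(apply(mesh$sheet_dir, 1,
              function(r) paste(fmt_num(r), collapse = " ")))
    }
  }
  if (!is.null(mesh$uvc)) {
    w(paste("POINT_DATA", np))
    nms <- c("rho", "phi", "Z", "V")
    for (k in 1:4) {
      w(paste("SCALARS", nms[k], "double 1"), "LOOKUP_TABLE default")
      w(fmt_num(mesh$uvc[, k]))
    }
  }
  invisible(path)
}
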