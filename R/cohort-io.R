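#' Write cohort mode-weight and phenotype tables as CSV
#'
#' Writes one row per case and one column per mode weight or phenotype,
#' with a mandatory header row. Missing phenotype values (failed
#' simulations) are written as empty fields. The CSV dialect is
#' comma-separated, '.' decimal, UTF-8.
#'
#' @param weights tibble with a `case` column and one numeric column per
#'   mode weight.
#' @param phenotypes tibble with a `case` column and one column per
#'   phenotype (Table-style abbreviations such as `ESV_LV`, `EF_LV`, `QRS`).
#' @param dir output directory; `weights.csv` and `phenotypes.csv` are
#'   written inside it.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_cohort_tables <- function(weights, phenotypes, dir) {
  weights <- tibble::as_tibble(weights)
  phenotypes <- tibble::as_tibble(phenotypes)
  for (tb in list(weights, phenotypes)) {
    if (!"case" %in% names(tb)) stop("tables need a 'case' column",
                                     call. = FALSE)
    if (anyDuplicated(tb$case)) {
      stop("duplicate case identifiers: ",
           paste(unique(tb$case[duplicated(tb$case)]), collapse = ", "),
           call. = FALSE)
    }
  }
  shared <- intersect(weights$case, phenotypes$case)
  if (length(shared) == 0 && nrow(weights) > 0 && nrow(phenotypes) > 0) {
    warning("weights and phenotypes share no case identifiers")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(weights = file.path(dir, "weights.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  readr::write_csv(weights, paths[["weights"]], na = "")
  readr::write_csv(phenotypes, paths[["phenotypes"]], na = "")
  invisible(paths)
}

#' Read back cohort tables written by [write_cohort_tables()]
#'
#' @param dir directory containing `weights.csv` and `phenotypes.csv`.
#' @return list with tibbles `weights` and `phenotypes`; empty fields come
#'   back as `NA`.
#' @export
read_cohort_tables <- function(dir) {
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                    na = c("", "NA"), progress = FALSE)
  list(weights = rd(file.path(dir, "weights.csv")),
       phenotypes = rd(file.path(dir, "phenotypes.csv")))
}
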