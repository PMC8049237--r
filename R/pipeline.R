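# End-to-end study pipeline ------------------------------------------------------

#' Pipeline run configuration
#'
#' @param cohort a [cohort_spec()].
#' @param resolution template resolution, mm.
#' @param variance_threshold cumulative variance fraction selecting the modes
#'   carried into the extreme cohorts and the GSA (default 0.9).
#' @param exclude_cases case names dropped before fitting the SSM.
#' @param extreme_multipliers unsigned SD multipliers for the extreme
#'   cohorts, subset of `c(1, 2, 3)` (each expands to +/-).
#' @param stress,circ surrogate parameter bundles.
#' @param dt,duration integrator settings, ms.
#' @param cv_myo,cv_fec,fec_extent activation settings.
#' @param range_threshold normalised-range filter threshold (default 0.2).
#' @param gsa_n Saltelli base sample size.
#' @param gsa_phenotypes optional subset of phenotypes for the GSA stage
#'   (default: all retained); the correlation stage always uses all.
#' @param run_lsa whether to run the local sensitivity battery on the
#'   average mesh.
#' @param seed master seed.
#' @return object of class `run_config` (serialisable to JSON).
#' @export
run_config <- function(cohort = cohort_spec(),
                       resolution = 6,
                       variance_threshold = 0.9,
                       exclude_cases = character(0),
                       extreme_multipliers = c(2, 3),
                       stress = tanh_stress_params(),
                       circ = circulation_params(),
                       dt = 0.1, duration = 800,
                       cv_myo = 0.5, cv_fec = 2.0, fec_extent = 0.7,
                       range_threshold = 0.2,
                       gsa_n = 500,
                       gsa_phenotypes = NULL,
                       run_lsa = FALSE,
                       seed = 1L) {
  stopifnot(all(extreme_multipliers %in% 1:3))
  structure(list(cohort = cohort, resolution = resolution,
                 variance_threshold = variance_threshold,
                 exclude_cases = exclude_cases,
                 extreme_multipliers = extreme_multipliers,
                 stress = stress, circ = circ, dt = dt, duration = duration,
                 cv_myo = cv_myo, cv_fec = cv_fec, fec_extent = fec_extent,
                 range_threshold = range_threshold, gsa_n = gsa_n,
                 gsa_phenotypes = gsa_phenotypes, run_lsa = run_lsa,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full anatomy-to-function study
#'
#' generate -> align -> SSM -> extreme cohorts -> simulate -> phenotypes ->
#' normalised-range filter -> correlations -> GPE/Sobol GSA (-> LSA),
#' writing meshes, tables and a machine-readable manifest under `out_dir`.
#' Failed simulations are excluded downstream, never fatal. Idempotent for a
#' fixed config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with every stage result and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cardiosense_run_")) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()

  template <- build_template(resolution = config$resolution)
  cohort <- sample_cohort(config$cohort, template)

  aligned <- rigid_align(cohort$meshes, template)
  model <- fit_ssm(aligned$meshes, exclude = config$exclude_cases)
  k90 <- modes_for_threshold(model, config$variance_threshold)

  mult <- sort(unique(c(-config$extreme_multipliers,
                        config$extreme_multipliers)))
  extremes <- make_extreme_cohort(model, modes = seq_len(k90),
                                  multipliers = mult)
  average <- reconstruct_shape(numeric(ncol(model$modes)), model,
                               name = "average")
  sim_meshes <- c(
    aligned$meshes[model$case_names],
    stats::setNames(list(average), "average"),
    extremes$meshes)
  cohort_of <- c(rep("CT", length(model$case_names)), "Average",
                 paste0("Extreme",
                        abs(extremes$manifest$multiplier)))

  run <- run_cohort(sim_meshes, stress = config$stress, circ = config$circ,
                    dt = config$dt, duration = config$duration,
                    cv_myo = config$cv_myo, cv_fec = config$cv_fec,
                    fec_extent = config$fec_extent)
  phenos <- phenotype_table(run, sim_meshes)
  completion <- completion_table(run$completion, cohort_of)

  # weights for every simulated mesh in the SSM coordinate system
  weights <- purrr::imap_dfr(sim_meshes, function(m, nm) {
    w <- project_shape(m, model)
    tibble::as_tibble(as.list(c(case = nm, w)))
  }) |>
    dplyr::mutate(dplyr::across(-"case", as.numeric))

  nrf <- normalized_range_filter(
    phenos[phenos$case %in% model$case_names, ],
    threshold = config$range_threshold)
  retained <- nrf$phenotype[nrf$retained]

  cors <- mode_phenotype_correlations(
    weights[weights$case %in% model$case_names, ],
    phenos[phenos$case %in% model$case_names, ],
    phenotypes = retained)

  synthetic_cases <- setdiff(phenos$case, model$case_names)
  gsa_targets <- config$gsa_phenotypes %||% retained
  mode_cols <- paste0("mode_", seq_len(k90))
  gsa <- purrr::map(gsa_targets, function(ph) {
    tryCatch(
      gsa_phenotype(weights[c("case", mode_cols)], phenos, ph,
                    synthetic = synthetic_cases, N = config$gsa_n,
                    seed = config$seed),
      error = function(e) NULL)
  })
  names(gsa) <- gsa_targets

  lsa <- NULL
  if (isTRUE(config$run_lsa)) {
    lsa <- lsa_battery(
      average,
      config = default_lsa_config(stress = config$stress,
                                  circ = config$circ, dt = config$dt,
                                  duration = config$duration,
                                  cv_myo = config$cv_myo,
                                  cv_fec = config$cv_fec,
                                  fec_extent = config$fec_extent),
      phenotypes = retained)
  }

  # outputs -------------------------------------------------------------
  mesh_dir <- file.path(out_dir, "meshes")
  dir.create(mesh_dir, showWarnings = FALSE)
  write_vtk_mesh(average, file.path(mesh_dir, "average.vtk"))
  for (nm in names(extremes$meshes)) {
    write_vtk_mesh(extremes$meshes[[nm]], file.path(mesh_dir,
                                                    paste0(nm, ".vtk")))
  }
  write_cohort_tables(weights, phenos, out_dir)
  readr::write_csv(nrf, file.path(out_dir, "normalized_range.csv"))
  readr::write_csv(cors$correlations, file.path(out_dir, "correlations.csv"))
  readr::write_csv(completion, file.path(out_dir, "completion.csv"))
  sob_tbl <- purrr::imap_dfr(gsa, function(g, ph) {
    if (is.null(g)) return(NULL)
    dplyr::mutate(tidy(g$sobol), phenotype = ph, .before = 1)
  })
  if (nrow(sob_tbl)) readr::write_csv(sob_tbl, file.path(out_dir, "sobol.csv"))
  if (!is.null(lsa)) readr::write_csv(lsa, file.path(out_dir, "lsa.csv"))
  readr::write_csv(cohort$factors, file.path(out_dir, "true_factors.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cardiosense")),
    seed = config$seed, cohort_seed = config$cohort$seed,
    n_cases = config$cohort$n_cases, resolution = config$resolution,
    n_modes = ncol(model$modes), modes_for_threshold = k90,
    n_extreme_meshes = length(extremes$meshes),
    retained_phenotypes = retained,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = sort(c(list.files(out_dir, recursive = TRUE),
                     "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(template = template, cohort = cohort, model = model,
                 k90 = k90, extremes = extremes, average = average,
                 run = run, phenotypes = phenos, completion = completion,
                 weights = weights, norm_range = nrf, correlations = cors,
                 gsa = gsa, lsa = lsa, out_dir = out_dir))
}
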