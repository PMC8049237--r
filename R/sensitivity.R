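# Mode-phenotype sensitivity analyses -------------------------------------------

#' Normalised-range filter for phenotypes
#'
#' The range of each phenotype over the completed cases normalised by the
#' magnitude of its mean, `(max - min) / |mean|`: the maximum percentage
#' change of the phenotype over the cohort (the absolute value keeps the
#' statistic meaningful for negative-valued phenotypes such as dPdtmin). Phenotypes whose value falls strictly below
#' the threshold are flagged as discarded; a zero or non-finite mean makes
#' the statistic undefined and the phenotype is discarded with a warning.
#'
#' @param phenos a [phenotype_table()] (tibble with `case`, `completed` and
#'   numeric phenotype columns).
#' @param threshold discard threshold (default 0.2; comparison is
#'   "retain if >= threshold").
#' @return tibble with `phenotype`, `norm_range`, `retained`.
#' @export
normalized_range_filter <- function(phenos, threshold = 0.2) {
  df <- phenos[if ("completed" %in% names(phenos)) phenos$completed else TRUE, ]
  cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], "case")
  if (nrow(df) < 2) stop("need >= 2 completed cases", call. = FALSE)
  purrr::map_dfr(cols, function(cl) {
    v <- df[[cl]]
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0 || !is.finite(mean(v))) {
      warning("phenotype ", cl, ": normalised range undefined (zero or ",
              "non-finite mean); discarded")
      return(tibble::tibble(phenotype = cl, norm_range = NA_real_,
                            retained = FALSE))
    }
    nr <- (max(v) - min(v)) / abs(mean(v))
    tibble::tibble(phenotype = cl, norm_range = nr,
                   retained = nr >= threshold)
  })
}

#' Correlations between shape-mode weights and phenotypes
#'
#' Pearson (default) correlation per (mode, phenotype) pair over completed
#' cases, plus the per-mode summary used to rank modes: mean and SD of |R|
#' across phenotypes.
#'
#' @param weights tibble with `case` and `mode_*` columns.
#' @param phenos a [phenotype_table()].
#' @param phenotypes optional subset of phenotype columns (default: all
#'   numeric phenotype columns).
#' @param method `"pearson"` or `"spearman"`.
#' @return object of class `mode_pheno_cor`: list with `correlations`
#'   (long tibble `mode`, `phenotype`, `r`), `summary` (per-mode
#'   `mean_abs_r`, `sd_abs_r`), `method`.
#' @export
mode_phenotype_correlations <- function(weights, phenos, phenotypes = NULL,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- dplyr::inner_join(weights, phenos, by = "case")
  if ("completed" %in% names(df)) df <- df[df$completed, ]
  if (nrow(df) < 3) stop("need >= 3 completed cases", call. = FALSE)
  mode_cols <- grep("^mode_", names(df), value = TRUE)
  ph_cols <- phenotypes %||%
    setdiff(names(phenos)[vapply(phenos, is.numeric, TRUE)], "case")
  cors <- tidyr::expand_grid(mode = mode_cols, phenotype = ph_cols)
  cors$r <- purrr::map2_dbl(cors$mode, cors$phenotype, function(m, p) {
    x <- df[[m]]; y <- df[[p]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok], method = method)
  })
  summary <- cors |>
    dplyr::group_by(mode = .data$mode) |>
    dplyr::summarise(mean_abs_r = mean(abs(.data$r), na.rm = TRUE),
                     sd_abs_r = stats::sd(abs(.data$r), na.rm = TRUE),
                     .groups = "drop")
  structure(list(correlations = cors, summary = summary, method = method),
            class = "mode_pheno_cor")
}

#' @export
print.mode_pheno_cor <- function(x, ...) {
  cat("mode_pheno_cor (", x$method, "):",
      dplyr::n_distinct(x$correlations$mode), "modes x",
      dplyr::n_distinct(x$correlations$phenotype), "phenotypes\n")
  print(dplyr::arrange(x$summary, dplyr::desc(.data$mean_abs_r)), n = 5)
  invisible(x)
}

#' @export
tidy.mode_pheno_cor <- function(x, ...) x$correlations

#' Local sensitivity coefficient
#'
#' The normalised slope of the output over a symmetric relative perturbation
#' of one input: `SC = (x0 / y0) * (y_plus - y_minus) / (x_plus - x_minus)`
#' with `x_minus = x0 - delta * x0` and `x_plus = x0 + delta * x0`
#' (default 10% perturbation). Under linearity, SC close to +/-1 means a 10%
#' input change moves the output by +/-10%.
#'
#' @param x0 baseline input value (non-zero).
#' @param y0 baseline output value (non-zero, or the coefficient is
#'   undefined).
#' @param y_minus,y_plus outputs at the perturbed inputs.
#' @param delta relative perturbation (default 0.1).
#' @return the sensitivity coefficient (vectorised over outputs).
#' @export
sensitivity_coefficient <- function(x0, y0, y_minus, y_plus, delta = 0.1) {
  if (any(y0 == 0)) {
    stop("sensitivity coefficient undefined: baseline output is zero",
         call. = FALSE)
  }
  if (any(x0 == 0) || delta <= 0) {
    stop("perturbation degenerate: x_plus equals x_minus", call. = FALSE)
  }
  (x0 / y0) * (y_plus - y_minus) / (2 * delta * x0)
}

#' Percent change of a scenario output relative to baseline
#'
#' @param y_base baseline output (non-zero).
#' @param y_mod modified-scenario output.
#' @return `100 * (y_mod - y_base) / y_base` (vectorised).
#' @export
scenario_delta <- function(y_base, y_mod) {
  if (any(y_base == 0)) {
    stop("scenario delta undefined: baseline output is zero", call. = FALSE)
  }
  100 * (y_mod - y_base) / y_base
}

# simulate one mesh under a parameter bundle and return the wide phenotype row
run_single_config <- function(mesh, cfg) {
  run <- run_cohort(list(case = mesh), stress = cfg$stress, circ = cfg$circ,
                    dt = cfg$dt, duration = cfg$duration,
                    cv_myo = cfg$cv_myo, cv_fec = cfg$cv_fec,
                    fec_extent = cfg$fec_extent)
  phenotype_table(run, list(case = mesh))
}

#' Baseline parameter bundle for the local sensitivity battery
#'
#' Collects the surrogate's tunable parameters (active stress, circulation,
#' integrator step, conduction velocities, FEC extent) into the single
#' config object [lsa_battery()] perturbs.
#'
#' @param stress a [tanh_stress_params()].
#' @param circ a [circulation_params()].
#' @param dt,duration integrator settings, ms.
#' @param cv_myo,cv_fec conduction velocities, mm/ms.
#' @param fec_extent apicobasal extent of the FEC layer.
#' @return a named list consumed by [lsa_battery()].
#' @export
default_lsa_config <- function(stress = tanh_stress_params(),
                               circ = circulation_params(), dt = 0.1,
                               duration = 800, cv_myo = 0.5, cv_fec = 2.0,
                               fec_extent = 0.7) {
  list(stress = stress, circ = circ, dt = dt, duration = duration,
       cv_myo = cv_myo, cv_fec = cv_fec, fec_extent = fec_extent)
}

lsa_param_accessors <- function() {
  list(
    # the FEC layer is a fixed velocity ratio to working myocardium, so
    # perturbing the myocardial CV rescales both and activation times obey
    # the eikonal 1/CV law exactly; cv_fec below perturbs the ratio alone
    cv_myo = list(
      get = function(cfg) cfg$cv_myo,
      set = function(cfg, v) {
        cfg$cv_fec <- cfg$cv_fec * v / cfg$cv_myo
        cfg$cv_myo <- v
        cfg
      }),
    cv_fec = list(
      get = function(cfg) cfg$cv_fec,
      set = function(cfg, v) { cfg$cv_fec <- v; cfg }),
    aortic_resistance = list(
      get = function(cfg) cfg$circ$systemic$r_p,
      set = function(cfg, v) { cfg$circ$systemic$r_p <- v; cfg }),
    pulmonary_resistance = list(
      get = function(cfg) cfg$circ$pulmonary$r_p,
      set = function(cfg, v) { cfg$circ$pulmonary$r_p <- v; cfg }),
    preload_lv = list(
      get = function(cfg) cfg$circ$preload[["LV"]],
      set = function(cfg, v) { cfg$circ$preload[["LV"]] <- v; cfg }),
    preload_rv = list(
      get = function(cfg) cfg$circ$preload[["RV"]],
      set = function(cfg, v) { cfg$circ$preload[["RV"]] <- v; cfg }),
    peak_tension = list(
      get = function(cfg) cfg$stress$peak_tension,
      set = function(cfg, v) { cfg$stress$peak_tension <- v; cfg }),
    passive_a = list(
      get = function(cfg) cfg$circ$passive_a,
      set = function(cfg, v) { cfg$circ$passive_a <- v; cfg }))
}

#' Local sensitivity battery on one mesh
#'
#' Perturbs each model parameter by +/- `delta` (default 10%) around its
#' baseline on a single (typically the average) mesh, reruns the surrogate,
#' and applies [sensitivity_coefficient()] per phenotype. Parameters in
#' scope: myocardial and FEC-layer conduction velocities, systemic and
#' pulmonary peripheral resistances, LV/RV preload pressures, peak isometric
#' tension and the passive stiffness scale. Perturbed runs that fail leave
#' that cell missing.
#'
#' @param mesh the mesh to analyse (template topology with meta).
#' @param parameters names of parameters to perturb (default: all).
#' @param config baseline bundle from `default_lsa_config()`.
#' @param delta relative perturbation (default 0.1).
#' @param phenotypes optional subset of phenotype column names.
#' @return object of class `lsa_result`: tibble `parameter`, `phenotype`,
#'   `sc`; the baseline phenotype row is attached as attribute `baseline`.
#' @export
lsa_battery <- function(mesh, parameters = names(lsa_param_accessors()),
                        config = default_lsa_config(), delta = 0.1,
                        phenotypes = NULL) {
  acc <- lsa_param_accessors()
  stopifnot(all(parameters %in% names(acc)))
  base <- run_single_config(mesh, config)
  if (!base$completed[1]) {
    stop("baseline simulation did not complete on this mesh", call. = FALSE)
  }
  ph_cols <- phenotypes %||%
    setdiff(names(base)[vapply(base, is.numeric, TRUE)], "case")
  rows <- purrr::map_dfr(parameters, function(pn) {
    x0 <- acc[[pn]]$get(config)
    run_at <- function(mult) {
      cfg <- acc[[pn]]$set(config, x0 * mult)
      tryCatch(run_single_config(mesh, cfg), error = function(e) NULL)
    }
    lo <- run_at(1 - delta)
    hi <- run_at(1 + delta)
    purrr::map_dfr(ph_cols, function(cl) {
      y0 <- base[[cl]]
      sc <- if (is.null(lo) || is.null(hi) || !lo$completed[1] ||
                !hi$completed[1] || !is.finite(y0) || y0 == 0 ||
                !is.finite(lo[[cl]]) || !is.finite(hi[[cl]])) {
        NA_real_
      } else {
        sensitivity_coefficient(x0, y0, lo[[cl]], hi[[cl]], delta)
      }
      tibble::tibble(parameter = pn, phenotype = cl, sc = sc)
    })
  })
  structure(rows, class = c("lsa_result", class(rows)), baseline = base)
}

#' Emulator-based global sensitivity analysis for one phenotype
#'
#' Trains the leave-one-out emulator for a phenotype and estimates Sobol'
#' indices over the per-mode input ranges (default: the \[min, max\] of the
#' observed cohort weights, mirroring a GSA restricted to the range of modes
#' present in the cohort).
#'
#' @param weights tibble with `case` and `mode_*` columns.
#' @param phenos a [phenotype_table()].
#' @param phenotype phenotype column name.
#' @param synthetic marker of synthetic cases (see [train_gpes_loo()]).
#' @param ranges optional `D x 2` input ranges (default from `weights`).
#' @param N Saltelli base sample size.
#' @param seed integer seed.
#' @return list with `emulator` ([train_gpes_loo()]) and `sobol`
#'   ([sobol_saltelli()]).
#' @export
gsa_phenotype <- function(weights, phenos, phenotype, synthetic = FALSE,
                          ranges = NULL, N = 1000, seed = 1L) {
  em <- train_gpes_loo(weights, phenos, phenotype, synthetic = synthetic)
  mode_cols <- em$mode_cols
  if (is.null(ranges)) {
    ranges <- t(vapply(mode_cols, function(cl) range(weights[[cl]]),
                       numeric(2)))
  }
  sob <- sobol_saltelli(em, ranges, N = N, seed = seed,
                        input_names = mode_cols)
  list(emulator = em, sobol = sob)
}
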