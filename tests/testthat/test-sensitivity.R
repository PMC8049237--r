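test_that("normalised-range filter follows the range/mean definition", {
  phenos <- tibble::tibble(
    case = c("a", "b", "c"),
    const = c(4, 4, 4),
    wide = c(1, 2, 3),
    boundary = c(0.9, 1.0, 1.1),
    zero_mean = c(-1, 0, 1),
    completed = TRUE)
  expect_warning(nrf <- normalized_range_filter(phenos), "undefined")
  get <- function(ph, col) nrf[[col]][nrf$phenotype == ph]
  expect_equal(get("const", "norm_range"), 0)
  expect_false(get("const", "retained"))
  expect_equal(get("wide", "norm_range"), 1.0)
  expect_true(get("wide", "retained"))
  # exactly at the threshold: retained (>= comparison)
  expect_equal(get("boundary", "norm_range"), 0.2, tolerance = 1e-12)
  expect_true(get("boundary", "retained"))
  expect_false(get("zero_mean", "retained"))
})

test_that("only completed cases enter the filter", {
  phenos <- tibble::tibble(case = c("a", "b", "c", "d"),
                           y = c(1, 2, 3, 1000),
                           completed = c(TRUE, TRUE, TRUE, FALSE))
  nrf <- normalized_range_filter(phenos)
  expect_equal(nrf$norm_range[nrf$phenotype == "y"], 1.0)
})

test_that("mode-phenotype correlations recover exact and null relations", {
  set.seed(10)
  n <- 50
  w <- tibble::tibble(case = sprintf("c%02d", 1:n),
                      mode_1 = rnorm(n), mode_2 = rnorm(n))
  ph <- tibble::tibble(case = w$case,
                       linear = 2 * w$mode_1,
                       noise = rnorm(n),
                       completed = TRUE)
  mc <- mode_phenotype_correlations(w, ph)
  r <- function(m, p) {
    mc$correlations$r[mc$correlations$mode == m &
                        mc$correlations$phenotype == p]
  }
  expect_equal(r("mode_1", "linear"), 1.0, tolerance = 1e-12)
  expect_lt(abs(r("mode_1", "noise")), 0.4)
  expect_lt(abs(r("mode_2", "noise")), 0.4)
  # summary is the mean/SD of |R| across phenotypes per mode
  m1 <- abs(c(r("mode_1", "linear"), r("mode_1", "noise")))
  expect_equal(mc$summary$mean_abs_r[mc$summary$mode == "mode_1"], mean(m1))
  # zero-variance phenotype reported as missing
  ph$flat <- 1
  mc2 <- mode_phenotype_correlations(w, ph)
  expect_true(all(is.na(
    mc2$correlations$r[mc2$correlations$phenotype == "flat"])))
})

test_that("the sensitivity coefficient is exact on canonical responses", {
  # linear y = x: SC = 1 for any perturbation size
  x0 <- 3
  expect_equal(sensitivity_coefficient(x0, x0, 0.9 * x0, 1.1 * x0), 1)
  # constant output
  expect_equal(sensitivity_coefficient(x0, 5, 5, 5), 0)
  # quadratic y = x^2 at +/-10%: SC = 2 exactly
  expect_equal(
    sensitivity_coefficient(x0, x0^2, (0.9 * x0)^2, (1.1 * x0)^2), 2)
  expect_error(sensitivity_coefficient(1, 0, -1, 1), "zero")
  expect_error(sensitivity_coefficient(0, 1, 0.9, 1.1), "degenerate")
})

test_that("SC of a linear response is invariant to the perturbation size", {
  f <- function(x) 4 * x - 7
  x0 <- 10
  sc1 <- sensitivity_coefficient(x0, f(x0), f(0.9 * x0), f(1.1 * x0), 0.1)
  sc2 <- sensitivity_coefficient(x0, f(x0), f(0.8 * x0), f(1.2 * x0), 0.2)
  expect_equal(sc1, sc2, tolerance = 1e-12)
})

test_that("scenario deltas are percent changes with the algebraic identity", {
  expect_equal(scenario_delta(100, 100), 0)
  expect_equal(scenario_delta(100, 110), 10)
  a <- 80; b <- 95
  expect_equal(scenario_delta(a, b), -scenario_delta(b, a) * (b / a),
               tolerance = 1e-12)
  expect_error(scenario_delta(0, 1), "zero")
})

test_that("local sensitivity battery: no-pathway zeros and the eikonal law", {
  tm <- tpl8()
  lsa <- lsa_battery(tm, parameters = c("cv_myo", "pulmonary_resistance"),
                     config = default_lsa_config(dt = 0.2),
                     phenotypes = c("AT", "QRS", "ESV_LV", "EF_LV"))
  sc <- function(p, ph) lsa$sc[lsa$parameter == p & lsa$phenotype == ph]
  # activation times obey AT ~ 1/CV: SC = -(1/1.1 - 1/0.9)/0.2
  expect_equal(sc("cv_myo", "AT"), -1.0101, tolerance = 0.05)
  expect_equal(sc("cv_myo", "QRS"), -1.0101, tolerance = 0.05)
  # the pulmonary circulation has no pathway to LV phenotypes or EP times
  expect_equal(sc("pulmonary_resistance", "ESV_LV"), 0, tolerance = 1e-6)
  expect_equal(sc("pulmonary_resistance", "AT"), 0, tolerance = 1e-9)
  base <- attr(lsa, "baseline")
  expect_true(base$completed[1])
})

test_that("GPE-based GSA recovers the modes a synthetic phenotype depends on", {
  model <- ssm19()
  w_ct <- ssm_weights(model)
  ex <- make_extreme_cohort(model, modes = 1:9, multipliers = c(-2, 2))
  w_ex <- purrr::imap_dfr(ex$meshes, function(m, nm) {
    tibble::as_tibble(as.list(c(case = nm, project_shape(m, model))))
  }) |>
    dplyr::mutate(dplyr::across(-"case", as.numeric))
  weights <- dplyr::bind_rows(w_ct, w_ex)[, c("case", paste0("mode_", 1:9))]
  set.seed(77)
  y <- weights$mode_2 / model$mode_sds[2] +
    weights$mode_9 / model$mode_sds[9] +
    rnorm(nrow(weights), 0, 0.02)
  phenos <- tibble::tibble(case = weights$case, Y = y, completed = TRUE)
  g <- gsa_phenotype(weights, phenos, "Y", synthetic = w_ex$case,
                     N = 256, seed = 3)
  s1 <- g$sobol$indices$S1
  top2 <- order(s1, decreasing = TRUE)[1:2]
  expect_setequal(g$sobol$indices$input[top2], c("mode_2", "mode_9"))
  expect_gte(s1[2] + s1[9], 0.8)
  expect_lt(g$emulator$mean_mse, 0.05)
})
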