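test_that("activation along a collinear chain is distance over CV", {
  mesh <- chain_mesh(n_nodes = 12, spacing = 1)
  act <- simulate_activation(mesh, stimulus = 1, cv_myo = 0.5, cv_fec = 2)
  expect_equal(act$times, (0:11) * 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("doubling conduction velocities halves all activation times", {
  tm <- tpl8()
  a1 <- simulate_activation(tm, cv_myo = 0.5, cv_fec = 2)
  a2 <- simulate_activation(tm, cv_myo = 1.0, cv_fec = 4)
  expect_equal(a2$times, a1$times / 2, tolerance = 1e-10)
})

test_that("activation equals an independent Bellman-Ford oracle", {
  mesh <- random_tet_mesh(n_tets = 12, n_points = 30, seed = 21,
                          with_fields = FALSE)
  act <- suppressWarnings(
    simulate_activation(mesh, stimulus = c(1, 2), cv_myo = 0.7))
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$points[e[, 1], ] - mesh$points[e[, 2], ])^2))
  oracle <- bellman_ford(30, e, len / 0.7, c(1, 2))
  expect_equal(act$times, oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("disconnected nodes get infinite times with a warning", {
  mesh <- random_tet_mesh(n_tets = 3, n_points = 30, seed = 2,
                          with_fields = FALSE)
  expect_warning(act <- simulate_activation(mesh, stimulus = mesh$tets[1, 1]),
                 "unreachable")
  expect_true(any(!is.finite(act$times)))
})

test_that("FEC layer speeds up endocardial edges below the extent only", {
  tm <- tpl8()
  slow <- simulate_activation(tm, cv_myo = 0.5, cv_fec = 0.5)
  fast <- simulate_activation(tm, cv_myo = 0.5, cv_fec = 2.0)
  expect_lt(max(fast$times), max(slow$times))
  # only nodes fed through the FEC region can differ
  z <- tm$uvc[, 3]
  apex_nodes <- which(z <= 0.05)
  expect_true(any(fast$times[apex_nodes] < slow$times[apex_nodes] - 1e-9) ||
                max(fast$times) < max(slow$times))
})

test_that("tanh stress: support, bound, and closed-form value", {
  p <- tanh_stress_params()
  expect_equal(tanh_active_stress(c(0, 10, p$t_emd - 1e-9), 0, p),
               c(0, 0, 0))
  grid <- seq(0, 1200, by = 0.25)
  vals <- tanh_active_stress(grid, 100, p)
  expect_lte(max(vals), p$peak_tension)
  expect_gte(min(vals), 0)
  # direct symbolic evaluation at elapsed = t_dur / 2
  s <- p$t_dur / 2
  expected <- p$peak_tension * tanh(s / p$tau_contr)^2 *
    tanh((p$t_dur - s) / p$tau_relax)^2
  expect_equal(tanh_active_stress(100 + p$t_emd + s, 100, p), expected,
               tolerance = 1e-12)
  # continuity at the end of the active window
  expect_lt(tanh_active_stress(100 + p$t_emd + p$t_dur - 0.01, 100, p), 0.01)
})

test_that("near-zero tension produces no ejection", {
  tb <- template_beat()
  bt <- simulate_beat(tb$anatomy, activation_triggers(tb$act, tb$mesh),
                      stress = tanh_stress_params(peak_tension = 1e-9))
  lv <- bt$trace[bt$trace$ventricle == "LV", ]
  expect_equal(max(lv$q_out), 0)   # the aortic valve never opens
  expect_false(any(bt$events$valve == "outflow" &
                     bt$events$ventricle == "LV"))
  expect_lt(max(lv$volume) - min(lv$volume), 1e-3)  # stroke volume ~ 0
})

test_that("volume conservation and isovolumic phases are exact", {
  tb <- template_beat()
  for (v in c("LV", "RV")) {
    tr <- tb$beat$trace[tb$beat$trace$ventricle == v, ]
    net <- sum(tr$q_in - tr$q_out) * tb$beat$dt
    expect_lt(abs(net - (tr$volume[nrow(tr)] - tr$volume[1])), 1e-3)
    # outflow integral equals EDV - ESV
    expect_lt(abs(sum(tr$q_out) * tb$beat$dt -
                    (tr$volume[1] - min(tr$volume))), 1e-3)
    closed <- tr$q_in == 0 & tr$q_out == 0
    dv <- abs(diff(tr$volume)) / tb$beat$dt
    expect_lt(max(dv[closed[-length(closed)]]), 1e-6)
  }
})

test_that("phenotypes are grid-converged under dt halving", {
  tb <- template_beat()
  trig <- activation_triggers(tb$act, tb$mesh)
  b2 <- simulate_beat(tb$anatomy, trig, dt = 0.05)
  edv <- tb$anatomy$edv[tb$anatomy$ventricle == "LV"]
  p1 <- extract_mechanical(tb$beat, "LV", edv)
  p2 <- extract_mechanical(b2, "LV", edv)
  vals <- unlist(p1[mech_phenotype_names])
  rel <- abs(unlist(p2[mech_phenotype_names]) - vals) / abs(vals)
  expect_lt(max(rel), 0.005)
})

test_that("default parameters put the template LV EF in a physiological band", {
  tb <- template_beat()
  edv <- tb$anatomy$edv[tb$anatomy$ventricle == "LV"]
  ph <- extract_mechanical(tb$beat, "LV", edv)
  expect_gt(ph$EF, 50)
  expect_lt(ph$EF, 65)
  ep <- extract_ep(tb$act, tb$mesh$meta$node_sets$LV$all)
  expect_gt(ep$QRS, 40)    # simulated QRS within the reported normal range
  expect_lt(ep$QRS, 120)
})

test_that("identical meshes give bitwise-identical phenotypes", {
  tm <- tpl8()
  run <- run_cohort(list(a = tm, b = tm), dt = 0.2)
  ph <- phenotype_table(run, list(a = tm, b = tm))
  expect_identical(unlist(ph[1, -1]), unlist(ph[2, -1]))
})

test_that("completion table percentages follow finished/total x 100", {
  comp <- tibble::tibble(case = c("a", "b", "c"),
                         completed = c(TRUE, FALSE, TRUE))
  tab <- completion_table(comp, cohort = c("X", "X", "Y"))
  x <- tab[tab$cohort == "X", ]
  expect_equal(x$pct, 100 * 1 / 2)
  expect_equal(x$failed_cases, "b")
  expect_equal(tab$pct[tab$cohort == "Y"], 100)
})

test_that("EDV ordering is preserved in ESV over scaled anatomies", {
  tm <- tpl8()
  meshes <- list(
    small = deform_template(tm, anatomy_params(scale = 0.92)),
    base = tm,
    large = deform_template(tm, anatomy_params(scale = 1.08)))
  run <- run_cohort(meshes, dt = 0.2)
  ph <- phenotype_table(run, meshes)
  expect_true(all(diff(ph$ESV_LV) > 0))
  expect_true(all(diff(ph$ESV_RV) > 0))
})
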