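# hand-built beat traces with known phenotype values ---------------------------

synthetic_beat <- function(dt = 1) {
  # triangular LV volume 120 -> 50 -> 120 with a flow-consistent outflow
  # pulse peaking at t = 25 (V = 90 there) and pressure rising linearly to a
  # plateau; valve events encoded directly
  time <- seq(0, 200, by = dt)
  v_down <- pmax(50, 120 - 1.4 * time)
  v_up <- pmin(120, 50 + 1.4 * pmax(0, time - 100))
  volume <- ifelse(time <= 100, v_down, v_up)
  q_out <- ifelse(time > 10 & time <= 50,
                  1.4 * exp(-((time - 25) / 20)^2), 0)
  q_out[which.max(q_out)] <- 1.5  # unique peak at t = 25
  q_in <- ifelse(time > 120, 1.4, 0)
  pressure <- pmin(100, 2 * time)
  trace <- tibble::tibble(time = time, ventricle = "LV", volume = volume,
                          pressure = pressure, q_in = q_in, q_out = q_out,
                          p_arterial = 80, completed = TRUE)
  idx25 <- which.min(abs(time - 25))
  trace$volume[idx25] <- 90
  events <- tibble::tibble(ventricle = "LV",
                           valve = c("outflow", "inflow"),
                           open = c(10, 120), close = c(50, NA))
  structure(list(trace = trace, events = events,
                 triggers = c(LV = 5), completed = c(LV = TRUE),
                 dt = dt, duration = 200), class = "beat_trace")
}

test_that("mechanical phenotypes follow their defining arithmetic", {
  bt <- synthetic_beat()
  ph <- extract_mechanical(bt, "LV", edv = 120)
  expect_equal(ph$ESV, 50)
  expect_equal(ph$SV, 70)
  expect_equal(ph$EF, 100 * 70 / 120, tolerance = 1e-9)  # 58.333%
  expect_equal(ph$V1, 90)
  expect_equal(ph$EF1, 25)
  expect_equal(ph$ET, 40)
  expect_equal(ph$ICT, 5)    # trigger at 5, valve opens at 10
  expect_equal(ph$IRT, 70)   # close 50 -> inflow opens 120
  expect_equal(ph$tsys, ph$ICT + ph$ET)
  expect_equal(ph$PeakP, 100)
  # linear pressure ramp of slope 2 mmHg/ms
  expect_equal(ph$dPdtmax, 2, tolerance = 1e-9)
  expect_equal(ph$ESP, 100)  # pressure at t = 50 has reached the plateau
})

test_that("incomplete traces yield missing phenotype rows, not errors", {
  bt <- synthetic_beat()
  bt$trace$completed <- FALSE
  ph <- extract_mechanical(bt, "LV", edv = 120)
  expect_false(ph$completed)
  expect_true(all(is.na(unlist(ph[mech_phenotype_names]))))
})

test_that("EP phenotypes use span and nearest-rank percentile conventions", {
  act <- structure(list(times = 1:100, stimulus = 1L), class = "activation_map")
  ep <- extract_ep(act, lv_nodes = 1:50)
  expect_equal(ep$QRS, 99)
  expect_equal(ep$AT1090, 80)   # t(90) - t(10)
  expect_equal(ep$AT, 49)

  simultaneous <- structure(list(times = rep(3, 40), stimulus = 1L),
                            class = "activation_map")
  ep0 <- extract_ep(simultaneous, lv_nodes = 1:10)
  expect_equal(unlist(ep0), c(QRS = 0, AT1090 = 0, AT = 0))

  expect_error(extract_ep(act, lv_nodes = integer(0)), "empty")
  inf_act <- structure(list(times = c(1, 2, Inf), stimulus = 1L),
                       class = "activation_map")
  expect_error(extract_ep(inf_act, lv_nodes = 1:3), "non-finite")
})

test_that("identities hold on simulated beats", {
  tb <- template_beat()
  for (v in c("LV", "RV")) {
    edv <- tb$anatomy$edv[tb$anatomy$ventricle == v]
    ph <- extract_mechanical(tb$beat, v, edv)
    expect_equal(ph$SV, edv - ph$ESV, tolerance = 1e-9)
    expect_gt(ph$EF, 0); expect_lt(ph$EF, 100)
    expect_true(all(c(ph$ET, ph$ICT, ph$IRT, ph$tsys) >= 0))
    expect_lte(ph$ET + ph$ICT + ph$IRT, tb$beat$duration)
  }
})

test_that("duration phenotypes are invariant to uniform time shifts", {
  bt <- synthetic_beat()
  shifted <- bt
  shifted$trace$time <- shifted$trace$time + 37
  shifted$events$open <- shifted$events$open + 37
  shifted$events$close <- shifted$events$close + 37
  shifted$triggers <- bt$triggers + 37
  a <- extract_mechanical(bt, "LV", 120)
  b <- extract_mechanical(shifted, "LV", 120)
  for (ph in c("ET", "ICT", "IRT", "tsys", "ESV", "SV", "EF", "V1", "EF1")) {
    expect_equal(b[[ph]], a[[ph]], tolerance = 1e-9)
  }
  expect_equal(b$tpeak, a$tpeak + 37, tolerance = 1e-9)
})

test_that("the cohort phenotype table has Table-style columns per case", {
  tm <- tpl8()
  run <- run_cohort(list(case_a = tm), dt = 0.2)
  ph <- phenotype_table(run, list(case_a = tm))
  expect_equal(ph$case, "case_a")
  expect_true(all(paste0(mech_phenotype_names, "_LV") %in% names(ph)))
  expect_true(all(paste0(mech_phenotype_names, "_RV") %in% names(ph)))
  expect_true(all(ep_phenotype_names %in% names(ph)))
  expect_true(ph$completed)
})
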