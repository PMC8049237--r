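# Lumped (0D) electromechanical beat surrogate ---------------------------------

KPA_MMHG <- 7.50061683

#' Tanh active-stress parameters
#'
#' Phenomenological activation-based active tension built from squared
#' hyperbolic-tangent ramps. Defaults are calibration choices that land the
#' template LV ejection fraction in a physiological band; they are plain
#' config values, never hard-coded elsewhere.
#'
#' @param peak_tension peak isometric tension, kPa.
#' @param t_emd electromechanical delay, ms.
#' @param tau_contr contraction time constant, ms.
#' @param tau_relax relaxation time constant, ms.
#' @param t_dur active duration, ms.
#' @param length_dep linear length-dependence slope of active tension
#'   (Frank-Starling analogue): tension is scaled by
#'   `max(0, 1 + length_dep * (stretch - 1))`.
#' @return object of class `tanh_stress_params`.
#' @export
tanh_stress_params <- function(peak_tension = 32, t_emd = 15,
                               tau_contr = 50, tau_relax = 40,
                               t_dur = 350, length_dep = 4) {
  stopifnot(peak_tension > 0, t_emd > 0, tau_contr > 0, tau_relax > 0,
            t_dur > 0, length_dep >= 0)
  structure(list(peak_tension = peak_tension, t_emd = t_emd,
                 tau_contr = tau_contr, tau_relax = tau_relax,
                 t_dur = t_dur, length_dep = length_dep),
            class = "tanh_stress_params")
}

#' Tanh active stress time course
#'
#' Zero before `t_act + t_emd`; for elapsed time `s` in `[0, t_dur]` equals
#' `peak_tension * tanh^2(s / tau_contr) * tanh^2((t_dur - s) / tau_relax)`;
#' zero afterwards. Continuous and bounded by `peak_tension`.
#'
#' @param t time(s), ms (vectorised).
#' @param t_act activation trigger time, ms.
#' @param p a [tanh_stress_params()].
#' @return active tension in kPa, same length as `t`.
#' @export
tanh_active_stress <- function(t, t_act, p) {
  s <- t - t_act - p$t_emd
  out <- numeric(length(s))
  on <- s >= 0 & s <= p$t_dur
  out[on] <- p$peak_tension *
    tanh(s[on] / p$tau_contr)^2 *
    tanh((p$t_dur - s[on]) / p$tau_relax)^2
  out
}

#' Circulation and passive-mechanics parameters
#'
#' Three-element Windkessel afterloads (characteristic resistance,
#' peripheral resistance, compliance) for the systemic and pulmonary
#' circulations, ideal-diode valves with forward resistances, prescribed
#' preload pressures, and the isotropic exponential passive law
#' `sigma = a * (exp(b * (stretch - 1)) - 1)` with scale parameter `a`.
#' Resistances in mmHg*ms/mL, compliances in mL/mmHg, pressures in mmHg,
#' `a` in kPa.
#'
#' @param systemic,pulmonary lists with `z_c`, `r_p`, `compliance`,
#'   `r_valve`, `p_art0` (initial arterial pressure).
#' @param preload named prescribed end-diastolic pressures, mmHg.
#' @param r_inflow inflow (atrioventricular) valve forward resistance.
#' @param passive_a,passive_b passive stress scale (kPa) and exponent.
#' @return object of class `circulation_params`.
#' @export
circulation_params <- function(
    systemic = list(z_c = 45, r_p = 1100, compliance = 1.4, r_valve = 8,
                    p_art0 = 78),
    pulmonary = list(z_c = 15, r_p = 170, compliance = 4, r_valve = 5,
                     p_art0 = 11),
    preload = c(LV = 10, RV = 4),
    r_inflow = 3,
    passive_a = 1.8, passive_b = 5) {
  vals <- c(unlist(systemic), unlist(pulmonary), preload, r_inflow,
            passive_a, passive_b)
  stopifnot(all(vals > 0))
  structure(list(systemic = systemic, pulmonary = pulmonary,
                 preload = preload, r_inflow = r_inflow,
                 passive_a = passive_a, passive_b = passive_b),
            class = "circulation_params")
}

# thick-wall sphere pressure (mmHg) from total wall stress (kPa)
laplace_pressure <- function(sigma_kpa, v_ml, wall_ml) {
  ri3 <- 3 * v_ml * 1000 / (4 * pi)
  ro3 <- 3 * (v_ml + wall_ml) * 1000 / (4 * pi)
  sigma_kpa * (2 / 3) * log(ro3 / ri3) * KPA_MMHG
}

# unloaded volume such that the passive law balances the prescribed
# end-diastolic pressure at the imaged volume (0D analogue of an
# unloading step to a stress-free reference)
unloaded_volume <- function(edv, wall_ml, preload_mmhg, a, b) {
  geom <- (2 / 3) * log((edv + wall_ml) / edv) * KPA_MMHG
  sigma_needed <- preload_mmhg / geom
  lam <- 1 + log(1 + sigma_needed / a) / b
  edv / lam^3
}

simulate_beat_ventricle <- function(edv, wall_ml, trigger, side, stress,
                                    circ, dt, duration) {
  wk <- circ[[side$circulation]]
  p_pre <- circ$preload[[side$ventricle]]
  a <- circ$passive_a; b <- circ$passive_b
  v0 <- unloaded_volume(edv, wall_ml, p_pre, a, b)
  n <- as.integer(round(duration / dt)) + 1L
  time <- (seq_len(n) - 1) * dt
  V <- P <- Qin <- Qout <- Pa <- rep(NA_real_, n)
  V[1] <- edv
  Pa[1] <- wk$p_art0
  completed <- TRUE
  last <- n
  for (i in seq_len(n)) {
    lam <- (V[i] / v0)^(1 / 3)
    sig_p <- a * (exp(b * (lam - 1)) - 1)
    sig_a <- tanh_active_stress(time[i], trigger, stress) *
      max(0, 1 + stress$length_dep * (lam - 1))
    P[i] <- laplace_pressure(sig_p + sig_a, V[i], wall_ml)
    Qin[i] <- max(0, (p_pre - P[i]) / circ$r_inflow)
    Qout[i] <- max(0, (P[i] - Pa[i]) / (wk$z_c + wk$r_valve))
    if (i < n) {
      V[i + 1] <- V[i] + dt * (Qin[i] - Qout[i])
      Pa[i + 1] <- Pa[i] + dt * (Qout[i] - Pa[i] / wk$r_p) / wk$compliance
      if (!is.finite(V[i + 1]) || V[i + 1] <= 0 || !is.finite(Pa[i + 1])) {
        completed <- FALSE
        last <- i
        break
      }
    }
  }
  keep <- seq_len(last)
  tibble::tibble(time = time[keep], ventricle = side$ventricle,
                 volume = V[keep], pressure = P[keep],
                 q_in = Qin[keep], q_out = Qout[keep],
                 p_arterial = Pa[keep], completed = completed)
}

flow_events <- function(tr) {
  ev <- function(flow, valve) {
    open_idx <- which(flow > 0)
    if (length(open_idx) == 0) return(NULL)
    runs <- split(open_idx, cumsum(c(1, diff(open_idx) != 1)))
    purrr::map_dfr(runs, function(r) {
      tibble::tibble(valve = valve,
                     open = tr$time[r[1]],
                     close = if (max(r) < nrow(tr)) tr$time[max(r) + 1]
                             else NA_real_)
    })
  }
  dplyr::bind_rows(ev(tr$q_out, "outflow"), ev(tr$q_in, "inflow"))
}

#' Simulate one cardiac beat with the lumped surrogate
#'
#' For each ventricle, a thick-wall sphere model: the cavity pressure is the
#' Laplace transform of passive exponential plus tanh active stress (with
#' linear length dependence), the inner radius follows the cavity volume and
#' the wall conserves its volume. Valves are ideal diodes with forward
#' resistance; ejection couples to a three-element Windkessel, filling comes
#' from a constant preload pressure. Fixed-step explicit Euler integration;
#' the four beat phases (filling, isovolumic contraction, ejection,
#' isovolumic relaxation) emerge from the diode logic. A ventricle whose
#' state becomes non-finite or non-positive is flagged incomplete rather
#' than raising an error.
#'
#' @param anatomy tibble from [lumped_anatomy()].
#' @param triggers named per-ventricle activation trigger times, ms
#'   (from [activation_triggers()]).
#' @param stress a [tanh_stress_params()].
#' @param circ a [circulation_params()].
#' @param dt time step, ms (default 0.1).
#' @param duration beat duration, ms (default 800).
#' @return object of class `beat_trace`: list with `trace` (long tibble),
#'   `events` (valve open/close times), `triggers`, `completed` (named
#'   logical), `dt`, `duration`.
#' @export
simulate_beat <- function(anatomy, triggers, stress = tanh_stress_params(),
                          circ = circulation_params(), dt = 0.1,
                          duration = 800) {
  if (dt <= 0 || duration <= dt) stop("invalid dt or duration",
                                      call. = FALSE)
  sides <- list(LV = list(ventricle = "LV", circulation = "systemic"),
                RV = list(ventricle = "RV", circulation = "pulmonary"))
  traces <- purrr::map(names(sides), function(v) {
    row <- anatomy[anatomy$ventricle == v, ]
    if (nrow(row) != 1) stop("anatomy must have one row per ventricle",
                             call. = FALSE)
    simulate_beat_ventricle(row$edv, row$wall_volume, triggers[[v]],
                            sides[[v]], stress, circ, dt, duration)
  })
  trace <- dplyr::bind_rows(traces)
  events <- purrr::map_dfr(traces, function(tr) {
    e <- flow_events(tr)
    if (is.null(e) || nrow(e) == 0) return(NULL)
    dplyr::mutate(e, ventricle = tr$ventricle[1], .before = 1)
  })
  completed <- vapply(traces, function(tr) tr$completed[1], TRUE)
  names(completed) <- names(sides)
  structure(list(trace = trace, events = events, triggers = triggers,
                 completed = completed, dt = dt, duration = duration),
            class = "beat_trace")
}

#' @export
print.beat_trace <- function(x, ...) {
  cat("beat_trace: dt", x$dt, "ms, duration", x$duration, "ms\n")
  for (v in unique(x$trace$ventricle)) {
    tr <- x$trace[x$trace$ventricle == v, ]
    cat(sprintf("  %s: EDV %.1f mL, min V %.1f mL, peak P %.1f mmHg (%s)\n",
                v, tr$volume[1], min(tr$volume), max(tr$pressure),
                if (x$completed[[v]]) "completed" else "FAILED"))
  }
  invisible(x)
}

#' Run the surrogate over a cohort of meshes
#'
#' Shared parameters across all cases, per-mesh anatomy via
#' [lumped_anatomy()], activation via [simulate_activation()], one beat per
#' mesh. Failed beats are flagged, never raised.
#'
#' @param meshes named list of [tet_mesh()] (template topology, with meta).
#' @param stress,circ,dt,duration passed to [simulate_beat()].
#' @param cv_myo,cv_fec,fec_extent passed to [simulate_activation()].
#' @return list with `results` (per case: `anatomy`, `act`, `beat`) and
#'   `completion` tibble (`case`, `completed`).
#' @export
run_cohort <- function(meshes, stress = tanh_stress_params(),
                       circ = circulation_params(), dt = 0.1,
                       duration = 800, cv_myo = 0.5, cv_fec = 2.0,
                       fec_extent = 0.7) {
  results <- purrr::map(meshes, function(m) {
    anatomy <- lumped_anatomy(m)
    act <- simulate_activation(m, cv_myo = cv_myo, cv_fec = cv_fec,
                               fec_extent = fec_extent)
    beat <- simulate_beat(anatomy, activation_triggers(act, m),
                          stress = stress, circ = circ, dt = dt,
                          duration = duration)
    list(anatomy = anatomy, act = act, beat = beat)
  })
  completion <- tibble::tibble(
    case = names(meshes),
    completed = vapply(results, function(r) all(r$beat$completed), TRUE))
  list(results = results, completion = completion)
}

#' Per-cohort completion summary
#'
#' Counts of finished simulations per cohort with percentages
#' (finished/total x 100) and the names of failed cases.
#'
#' @param completion tibble with `case` and `completed`.
#' @param cohort optional character vector assigning each case to a cohort
#'   (default: one cohort named "all").
#' @return tibble with `cohort`, `finished`, `total`, `pct`, `failed_cases`.
#' @export
completion_table <- function(completion, cohort = NULL) {
  completion$cohort <- cohort %||% "all"
  completion |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      finished = sum(.data$completed),
      total = dplyr::n(),
      pct = 100 * sum(.data$completed) / dplyr::n(),
      failed_cases = paste(.data$case[!.data$completed], collapse = ", "),
      .groups = "drop")
}
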