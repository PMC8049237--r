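# Functional phenotype extraction ----------------------------------------------

mech_phenotype_names <- c("ESV", "SV", "EF", "V1", "EF1", "ESP", "dPdtmax",
                          "dPdtmin", "PeakP", "tpeak", "ET", "ICT", "IRT",
                          "tsys")
ep_phenotype_names <- c("QRS", "AT1090", "AT")

#' Extract mechanical phenotypes from one ventricle's beat trace
#'
#' ESV = minimum volume; SV = EDV - ESV; EF = 100 SV / EDV; V1 = volume at
#' the time of peak outflow-valve flow; EF1 = 100 (EDV - V1) / EDV
#' (first-phase ejection fraction); ESP = pressure at outflow-valve closure;
#' PeakP / tpeak = maximum pressure and its time; dPdtmax / dPdtmin =
#' extrema of centred finite-difference dP/dt (one-sided at the ends);
#' ET = outflow valve open-to-close; ICT = activation trigger to outflow
#' valve opening; IRT = outflow-valve closure to inflow-valve (re)opening;
#' tsys = ICT + ET. An incomplete trace yields a row of missing values.
#'
#' @param beat a [simulate_beat()] result.
#' @param ventricle `"LV"` or `"RV"`.
#' @param edv end-diastolic volume in mL (from the mesh anatomy).
#' @return one-row tibble of the mechanical phenotypes plus `completed`.
#' @export
extract_mechanical <- function(beat, ventricle, edv) {
  tr <- beat$trace[beat$trace$ventricle == ventricle, ]
  na_row <- function() {
    out <- tibble::as_tibble(as.list(stats::setNames(
      rep(NA_real_, length(mech_phenotype_names)), mech_phenotype_names)))
    out$completed <- FALSE
    out
  }
  if (nrow(tr) == 0 || !tr$completed[1]) return(na_row())
  ev <- beat$events
  out_ev <- ev[ev$ventricle == ventricle & ev$valve == "outflow", ]
  if (nrow(out_ev) == 0 || is.na(out_ev$close[1])) return(na_row())
  t_open <- out_ev$open[1]; t_close <- out_ev$close[1]

  esv <- min(tr$volume)
  sv <- edv - esv
  i_qmax <- which.max(tr$q_out)
  v1 <- tr$volume[i_qmax]
  dpdt <- dpdt_centered(tr$pressure, beat$dt)
  i_peak <- which.max(tr$pressure)
  # inflow valve reopening after ejection
  in_ev <- ev[ev$ventricle == ventricle & ev$valve == "inflow" &
                ev$open > t_close, ]
  irt <- if (nrow(in_ev)) in_ev$open[1] - t_close else NA_real_
  trig <- beat$triggers[[ventricle]]
  ict <- t_open - trig
  et <- t_close - t_open
  tibble::tibble(
    ESV = esv, SV = sv, EF = 100 * sv / edv,
    V1 = v1, EF1 = 100 * (edv - v1) / edv,
    ESP = tr$pressure[which.min(abs(tr$time - t_close))],
    dPdtmax = max(dpdt), dPdtmin = min(dpdt),
    PeakP = tr$pressure[i_peak], tpeak = tr$time[i_peak],
    ET = et, ICT = ict, IRT = irt, tsys = ict + et,
    completed = TRUE)
}

dpdt_centered <- function(p, dt) {
  n <- length(p)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
  d[1] <- (p[2] - p[1]) / dt
  d[n] <- (p[n] - p[n - 1]) / dt
  d
}

#' Extract electrophysiological phenotypes from an activation map
#'
#' QRS = total activation span (max - min) over both ventricles; AT1090 =
#' time between the 10th- and 90th-percentile activated nodes
#' (nearest-rank order statistics over all ventricular nodes); AT = span
#' over LV nodes only.
#'
#' @param act an [simulate_activation()] map.
#' @param lv_nodes integer indices of LV nodes.
#' @param all_nodes integer indices of all ventricular nodes (default: all
#'   nodes in the map).
#' @return one-row tibble with `QRS`, `AT1090`, `AT` in ms.
#' @export
extract_ep <- function(act, lv_nodes, all_nodes = seq_along(act$times)) {
  if (length(lv_nodes) == 0 || length(all_nodes) == 0) {
    stop("empty node set", call. = FALSE)
  }
  tv <- act$times[all_nodes]
  tl <- act$times[lv_nodes]
  if (any(!is.finite(tv)) || any(!is.finite(tl))) {
    stop("activation times contain non-finite values ",
         "(disconnected nodes); cannot extract EP phenotypes",
         call. = FALSE)
  }
  ts <- sort(tv)
  n <- length(ts)
  i10 <- max(1L, ceiling(0.1 * n))
  i90 <- max(1L, ceiling(0.9 * n))
  tibble::tibble(QRS = max(tv) - min(tv),
                 AT1090 = ts[i90] - ts[i10],
                 AT = max(tl) - min(tl))
}

#' Build the per-case phenotype table for a simulated cohort
#'
#' One row per case; per-ventricle mechanical phenotypes carry `_LV` / `_RV`
#' suffixes, EP phenotypes (QRS, AT1090, AT) are per case. Failed beats
#' yield missing phenotype values with `completed = FALSE`.
#'
#' @param cohort_run result of [run_cohort()].
#' @param meshes the named mesh list the run was computed on.
#' @return tibble (`phenotype_table`), one row per case.
#' @export
phenotype_table <- function(cohort_run, meshes) {
  rows <- purrr::imap(cohort_run$results, function(r, nm) {
    mesh <- meshes[[nm]]
    mech <- purrr::map(c(LV = "LV", RV = "RV"), function(v) {
      edv <- r$anatomy$edv[r$anatomy$ventricle == v]
      m <- extract_mechanical(r$beat, v, edv)
      stats::setNames(m[mech_phenotype_names],
                      paste0(mech_phenotype_names, "_", v))
    })
    ep <- tryCatch(
      extract_ep(r$act, lv_nodes = mesh$meta$node_sets$LV$all),
      error = function(e) tibble::tibble(QRS = NA_real_, AT1090 = NA_real_,
                                         AT = NA_real_))
    dplyr::bind_cols(tibble::tibble(case = nm), mech$LV, mech$RV, ep,
                     tibble::tibble(completed = all(r$beat$completed)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phenotype_table", class(out))
  out
}
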