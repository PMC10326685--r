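#' PBPK simulation engine
#'
#' Integrates the minimal whole-body system {oral depot, gut wall, liver,
#' central, peripheral} with enzyme-turnover states and repeated dosing, and
#' derives non-compartmental metrics at steady state.  The right-hand side is
#' compiled C (see `src/pbpk_model.c`); dosing is handled as solver events
#' that increment the depot.
#'
#' @name pbpk_engine
NULL

#' Dosing regimen
#'
#' @param dose Dose per administration (mg); 0 simulates a drug-free run.
#' @param interval Dosing interval (h).
#' @param n_doses Number of doses (>= 1).
#' @param route Only "oral" is supported.
#' @return A `dose_regimen` object.
#' @export
dose_regimen <- function(dose = 400, interval = 24, n_doses = 14, route = "oral") {
  route <- match.arg(route)
  if (dose < 0) stop_validation("dose must be non-negative")
  check_positive(interval, "interval")
  if (n_doses < 1) stop_validation("n_doses must be >= 1")
  structure(list(dose = dose, interval = interval, n_doses = n_doses,
                 route = route), class = "dose_regimen")
}

#' Solver and model options
#'
#' @param rtol,atol Relative/absolute integration tolerances (mg scale).
#' @param mbi Enable mechanism-based autoinhibition of CYP3A4 by imatinib.
#' @param saturable_binding Use concentration-dependent AAG binding; if
#'   `FALSE` the unbound fraction is fixed at the individual's dilute-limit
#'   value (linearised binding).
#' @param gut_metabolism Enable gut-wall CYP3A4 metabolism.
#' @param dt_dense Output spacing (h) over the final dosing interval.
#' @param t_end Optional simulation end time (h); defaults to
#'   `n_doses * interval`.
#' @return A list of options for [simulate_pbpk()].
#' @export
pbpk_options <- function(rtol = 1e-8, atol = 1e-10, mbi = TRUE,
                         saturable_binding = TRUE, gut_metabolism = TRUE,
                         dt_dense = 0.1, t_end = NULL) {
  list(rtol = rtol, atol = atol, mbi = mbi,
       saturable_binding = saturable_binding,
       gut_metabolism = gut_metabolism, dt_dense = dt_dense, t_end = t_end)
}

# map a perpetrator model onto the fixed interaction slots of the C core
perp_slots <- function(perp, drug) {
  s <- c(pon = 0, pdose = 0, ptau = 24, pnd = 1, pt0 = 0, pka = 1, pke = 0.1,
         pv = 100, pfu = 1, pmfr = 0, pmke = 0.1, pmv = 100, pmfu = 1,
         ki28c = 0, ki34c = 0, ki34m = 0, kin34m = 0, ki28m = 0, kin28m = 0,
         kig34m = 0, king34 = 0, indg = 0, ic50g = 0, indh = 0, ic50h = 0)
  if (is.null(perp)) return(s)
  stopifnot(inherits(perp, "perpetrator_model"))
  pk <- perp$pk
  s["pon"] <- 1
  s["pdose"] <- perp$regimen$dose_mg
  s["ptau"] <- perp$regimen$interval_h
  s["pnd"] <- perp$regimen$n_doses
  s["pt0"] <- perp$regimen$start_offset_h
  s["pka"] <- pk$ka_per_h
  s["pke"] <- pk$cl_over_f_L_per_h / pk$v_over_f_L
  s["pv"] <- pk$v_over_f_L
  s["pfu"] <- pk$fu
  if (!is.null(perp$metabolite)) {
    m <- perp$metabolite
    s["pmfr"] <- m$fraction_formed
    s["pmke"] <- m$ke_per_h
    s["pmv"] <- m$v_L
    s["pmfu"] <- m$fu
  }
  mw <- pk$mw_g_mol
  for (it in perp$interactions) {
    key <- paste(it$enzyme, it$site, it$mechanism, sep = ".")
    switch(key,
      "CYP2C8.hepatic.competitive" = { s["ki28c"] <- uM_to_mgL(it$Ki_uM, mw) },
      "CYP3A4.hepatic.competitive" = { s["ki34c"] <- uM_to_mgL(it$Ki_uM, mw) },
      "CYP3A4.hepatic.mbi" = {
        s["ki34m"] <- uM_to_mgL(it$KI_uM, mw); s["kin34m"] <- it$kinact_per_h
      },
      "CYP2C8.hepatic.mbi" = {
        s["ki28m"] <- uM_to_mgL(it$KI_uM, mw); s["kin28m"] <- it$kinact_per_h
      },
      "CYP3A4.gut.mbi" = {
        s["kig34m"] <- uM_to_mgL(it$KI_uM, mw); s["king34"] <- it$kinact_per_h
      },
      "CYP3A4.gut.induction" = {
        s["indg"] <- it$Indmax; s["ic50g"] <- uM_to_mgL(it$IndC50_uM, mw)
      },
      "CYP3A4.hepatic.induction" = {
        s["indh"] <- it$Indmax; s["ic50h"] <- uM_to_mgL(it$IndC50_uM, mw)
      },
      stop_config(sprintf("unsupported interaction '%s'", key))
    )
  }
  s
}

state_names <- c("depot", "gut_wall", "liver", "central", "peripheral",
                 "e_cyp3a4_hepatic", "e_cyp3a4_gut", "e_cyp2c8_hepatic",
                 "elim_cyp3a4", "elim_cyp2c8", "elim_other", "elim_biliary",
                 "elim_renal", "elim_gut", "unabsorbed")

#' Simulate one individual's imatinib concentration-time profile
#'
#' Integrates the whole-body system for a multiple-dose regimen with
#' concentration-dependent plasma protein binding, abundance-scaled hepatic
#' clearance modulated by time-varying enzyme activities (CYP3A4
#' autoinhibition, perpetrator inhibition/induction) and a perpetrator
#' forcing function.  Steady-state metrics are extracted over the final
#' dosing interval.
#'
#' @param ind A `pbpk_individual`.
#' @param drug A `drug_model`.
#' @param regimen A [dose_regimen()].
#' @param defaults A `system_defaults` (enzyme degradation constants).
#' @param perpetrator Optional `perpetrator_model`.
#' @param options See [pbpk_options()].
#' @return A `pbpk_sim` object: list with `series` (tibble of the full time
#'   course), `metrics` (tibble with `auc_0_24_ss`, `css_max`, `css_min`,
#'   `cl_over_f`), `balance_error` and the inputs.
#' @export
simulate_pbpk <- function(ind, drug, regimen, defaults,
                          perpetrator = NULL, options = pbpk_options()) {
  stopifnot(inherits(ind, "pbpk_individual"), inherits(drug, "drug_model"),
            inherits(regimen, "dose_regimen"))
  t_end <- options$t_end %||% (regimen$n_doses * regimen$interval)
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval
  if (max(dose_times) >= t_end) {
    stop_validation("simulation end time must exceed the last dose time")
  }
  if (!is.null(perpetrator)) {
    p_last <- perpetrator$regimen$start_offset_h +
      (perpetrator$regimen$n_doses - 1) * perpetrator$regimen$interval_h
    if (p_last >= t_end) {
      stop_validation("perpetrator regimen does not fit within the simulated window")
    }
  }

  clint <- clint_components(ind, drug)
  conv <- drug$binding_capacity_per_aag * drug$molecular_weight /
    drug$aag_molecular_weight * 1000
  fu_fixed <- if (options$saturable_binding) 0 else ind$fu_baseline
  kgm <- if (options$gut_metabolism) {
    clu_gut <- ind$gut_cyp3a4 * drug$clint_per_pmol[["CYP3A4_gut"]] * 0.06  # L/h
    clu_gut * drug$fu_gut / drug$gut_wall_volume
  } else 0
  kdeg <- defaults$kdeg_per_h

  parms <- c(
    ka = drug$ka, fa = drug$fa, kgw = drug$gut_transit, kgm = kgm,
    qh = ind$qh * drug$blood_plasma_ratio,
    vl = ind$liver_weight / 1050, kpl = drug$kp_liver,
    vc = drug$vc_per_kg * ind$weight, vp = drug$vp_per_kg * ind$weight,
    q = drug$q_inter, clr = renal_clearance_individual(ind, drug),
    m34 = clint[["CYP3A4_hepatic"]], m28 = clint[["CYP2C8_hepatic"]],
    moth = clint[["other_CYP"]], bil = clint[["biliary"]],
    kd = drug$kd_app * conv, bmax = ind$aag * conv, fufix = fu_fixed,
    kdeg34 = kdeg$CYP3A4_hepatic, kdegg = kdeg$CYP3A4_gut,
    kdeg28 = kdeg$CYP2C8_hepatic,
    kiima = uM_to_mgL(drug$autoinhibition$KI_uM, drug$molecular_weight),
    kinima = if (options$mbi) drug$autoinhibition$kinact else 0,
    res1 = 0, res2 = 0,
    perp_slots(perpetrator, drug)
  )

  interval <- regimen$interval
  times <- sort(unique(c(
    seq(0, min(interval, t_end), by = 0.25),
    seq(0, t_end, by = 2),
    seq(max(0, t_end - interval), t_end, by = options$dt_dense),
    dose_times, t_end
  )))
  y0 <- setNames(c(rep(0, 5), 1, 1, 1, rep(0, 7)), state_names)
  ev <- data.frame(var = "depot", time = dose_times, value = regimen$dose,
                   method = "add")

  out <- try(deSolve::ode(
    y = y0, times = times, func = "imat_derivs", parms = unname(parms),
    dllname = "imatpbpk", initfunc = "imat_initmod", nout = 5,
    outnames = c("conc", "fu", "cu_liver", "c_perp_u", "c_met_u"),
    method = "lsoda", rtol = options$rtol, atol = options$atol,
    events = list(data = ev), maxsteps = 50000
  ), silent = TRUE)
  if (inherits(out, "try-error")) {
    abort(paste0("PBPK integration failed: ", attr(out, "condition")$message),
          class = "imatpbpk_integration_error")
  }
  m <- as.data.frame(out)
  names(m) <- c("time_h", state_names, "conc", "fu", "cu_liver",
                "c_perp_u", "c_met_u")
  if (min(m$conc) < -1e-6 * max(abs(m$conc), 1e-12)) {
    abort("PBPK integration produced negative concentrations beyond tolerance",
          class = "imatpbpk_integration_error")
  }

  total_admin <- regimen$dose * sum(dose_times <= t_end)
  final <- m[nrow(m), ]
  recovered <- sum(final[c("depot", "gut_wall", "liver", "central", "peripheral",
                           "elim_cyp3a4", "elim_cyp2c8", "elim_other",
                           "elim_biliary", "elim_renal", "elim_gut",
                           "unabsorbed")])
  balance_error <- if (total_admin > 0) abs(recovered - total_admin) / total_admin else 0

  series <- tibble::as_tibble(m) |>
    dplyr::rename(conc_mg_per_L = "conc")
  res <- structure(list(
    series = series, regimen = regimen, individual = ind,
    perpetrator = perpetrator, balance_error = balance_error,
    options = options
  ), class = "pbpk_sim")
  res$metrics <- nca(res, c(t_end - interval, t_end))
  res
}

#' Non-compartmental metrics over a dosing interval
#'
#' AUC by the trapezoid rule on the dense output grid, peak concentration
#' over the interval, trough as the end-of-interval (pre-next-dose)
#' concentration, and apparent clearance `CL/F = dose / AUC`.
#'
#' @param result A `pbpk_sim`.
#' @param interval Numeric `c(t_start, t_end)` in hours, within the
#'   simulated span.
#' @return One-row tibble with `auc_0_24_ss` (ug*h/mL), `css_max`, `css_min`
#'   (ug/mL) and `cl_over_f` (L/h).
#' @export
nca <- function(result, interval) {
  stopifnot(inherits(result, "pbpk_sim"), length(interval) == 2)
  tt <- result$series$time_h
  if (interval[1] < min(tt) - 1e-9 || interval[2] > max(tt) + 1e-9 ||
      interval[1] >= interval[2]) {
    stop_domain("NCA interval must lie within the simulated time span")
  }
  sel <- tt >= interval[1] - 1e-9 & tt <= interval[2] + 1e-9
  t_i <- tt[sel]
  c_i <- result$series$conc_mg_per_L[sel]
  keep <- !duplicated(t_i)
  t_i <- t_i[keep]; c_i <- c_i[keep]
  auc <- sum(diff(t_i) * (head(c_i, -1) + c_i[-1]) / 2)
  cmin <- c_i[length(c_i)]
  dose <- result$regimen$dose
  tibble::tibble(
    auc_0_24_ss = auc,
    css_max = max(c_i),
    css_min = cmin,
    cl_over_f = if (auc > 0) dose / auc else NA_real_
  )
}

#' Steady-state enzyme activity under constant drivers
#'
#' Closed form of the turnover model: production `kdeg * induction_mult`
#' against first-order loss `kdeg + inact_rate` gives
#' `e_ss = e0 * induction_mult * kdeg / (kdeg + inact_rate)`.
#'
#' @param e0 Baseline relative activity.
#' @param kdeg Enzyme degradation rate constant (1/h, > 0).
#' @param inact_rate Additional inactivation rate (1/h, >= 0).
#' @param induction_mult Induction multiplier on synthesis (>= 0).
#' @return Steady-state relative activity.
#' @export
enzyme_steady_state <- function(e0, kdeg, inact_rate = 0, induction_mult = 1) {
  check_positive(kdeg, "kdeg")
  if (any(inact_rate < 0) || any(induction_mult < 0)) {
    stop_domain("inact_rate and induction_mult must be non-negative")
  }
  e0 * induction_mult * kdeg / (kdeg + inact_rate)
}

#' @importFrom utils head
NULL
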