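#' Closed-form pharmacokinetic primitives
#'
#' Saturable AAG plasma protein binding, abundance-scaled hepatic intrinsic
#' clearance, the well-stirred liver model and individualised renal clearance.
#'
#' @name mechanisms
NULL

#' Unbound fraction in plasma under saturable one-site AAG binding
#'
#' Solves the one-site binding equilibrium for the unbound drug concentration
#' (the physical root of the binding quadratic) and returns the unbound
#' fraction `fu = Cu / C`.  In the dilute limit this reduces to
#' `fu = 1 / (1 + aag / kd_app)`; with increasing total drug concentration
#' the binding protein saturates and `fu` rises towards 1.
#'
#' @param c_total Total plasma drug concentration (mg/L); vectorised.
#' @param aag AAG concentration (g/L).
#' @param kd_app Apparent dissociation constant on the AAG g/L scale (see
#'   [calibrate_binding_constant()]).
#' @param capacity Binding sites per AAG molecule.
#' @param mw_drug,mw_aag Molecular weights (g/mol) used to convert the AAG
#'   concentration to drug-equivalent binding capacity.
#' @return Unbound fraction(s) in (0, 1].
#' @examples
#' kd <- calibrate_binding_constant(0.05, 0.91)
#' unbound_fraction(1e-9, 0.91, kd)   # dilute limit: 0.05
#' @export
unbound_fraction <- function(c_total, aag, kd_app, capacity = 1,
                             mw_drug = 493.6, mw_aag = 44000) {
  if (any(c_total < 0) || any(aag < 0)) {
    stop_domain("c_total and aag must be non-negative")
  }
  if (any(kd_app <= 0)) stop_domain("kd_app must be strictly positive")
  conv <- capacity * mw_drug / mw_aag * 1000   # mg drug-equivalents per g AAG
  bmax <- aag * conv
  kd <- kd_app * conv
  dilute <- kd / (kd + bmax)
  b <- kd + bmax - c_total
  cu <- 0.5 * (-b + sqrt(b^2 + 4 * kd * c_total))
  fu <- ifelse(c_total < 1e-12, dilute, cu / c_total)
  pmin(pmax(fu, 1e-12), 1)
}

# per-pathway unbound intrinsic clearances (L/h) for one individual
clint_components <- function(ind, drug,
                             enzyme_activity = c(CYP3A4_hepatic = 1,
                                                 CYP2C8_hepatic = 1,
                                                 other_CYP = 1)) {
  act <- c(CYP3A4_hepatic = 1, CYP2C8_hepatic = 1, other_CYP = 1)
  act[names(enzyme_activity)] <- enzyme_activity
  if (any(act < 0)) stop_domain("enzyme activities must be non-negative")
  scale <- ind$mppgl * ind$liver_weight * 6e-5   # pmol/mg * mg/g * g * uL/min -> L/h
  cl <- drug$clint_per_pmol
  met <- c(
    CYP3A4_hepatic = unname(ind$enzyme_abundance[["CYP3A4_hepatic"]] *
                              cl[["CYP3A4_hepatic"]] * act[["CYP3A4_hepatic"]]),
    CYP2C8_hepatic = unname(ind$enzyme_abundance[["CYP2C8_hepatic"]] *
                              cl[["CYP2C8_hepatic"]] * act[["CYP2C8_hepatic"]]),
    other_CYP = unname(cl[["other_CYP"]] * act[["other_CYP"]])
  ) * scale
  size <- ind$liver_weight / 1650   # biliary capacity scales with liver size
  bil <- sum(ind$transporter_abundance * drug$clint_biliary_per_abundance) * size
  c(met, biliary = unname(bil))
}

#' Hepatic unbound intrinsic clearance of an individual
#'
#' Sum of enzyme-abundance-scaled metabolic intrinsic clearance
#' (abundance x activity x per-pmol clearance x MPPGL x liver weight, unit
#' converted to L/h) and transporter-abundance-scaled biliary intrinsic
#' clearance.  Linear in every abundance and activity.
#'
#' @param ind A `pbpk_individual`.
#' @param drug A `drug_model`.
#' @param enzyme_activity Named vector of relative enzyme activities
#'   (baseline 1).
#' @return Unbound intrinsic clearance in L/h.
#' @export
hepatic_intrinsic_clearance <- function(ind, drug,
                                        enzyme_activity = c(CYP3A4_hepatic = 1,
                                                            CYP2C8_hepatic = 1,
                                                            other_CYP = 1)) {
  sum(clint_components(ind, drug, enzyme_activity))
}

#' Well-stirred hepatic clearance
#'
#' `CLh = qh * fu_blood * clint_u / (qh + fu_blood * clint_u)` with
#' `fu_blood = fu / blood_plasma_ratio`.  Returns blood clearance referenced
#' to hepatic blood flow.
#'
#' @param qh Hepatic blood flow (L/h).
#' @param fu_blood Unbound fraction in blood.
#' @param clint_u Unbound intrinsic clearance (L/h).
#' @return Hepatic clearance (L/h).
#' @examples
#' well_stirred_hepatic_clearance(90, 0.0625, 2000)  # ~52.3 L/h
#' @export
well_stirred_hepatic_clearance <- function(qh, fu_blood, clint_u) {
  if (any(qh < 0) || any(fu_blood < 0) || any(clint_u < 0)) {
    stop_domain("all inputs must be non-negative")
  }
  num <- fu_blood * clint_u
  ifelse(qh + num > 0, qh * num / (qh + num), 0)
}

#' Individualised renal clearance
#'
#' Scales the reference renal clearance of imatinib (an observed systemic
#' value in patients) by the individual's glomerular filtration rate and, for
#' its filtration-like component, by the individual's baseline unbound
#' fraction:
#' `CL_R,i = cl_renal_ref * (eGFR_i / eGFR_ref) *
#'  (w * fu_i / fu_ref + (1 - w))`,
#' where `w` is the filtration-like (binding-sensitive) fraction of renal
#' elimination; the remainder represents capacity-limited tubular secretion,
#' which for an avidly transported base is insensitive to plasma protein
#' binding.  Floored at zero.
#'
#' @param ind A `pbpk_individual` with `egfr` set.
#' @param drug A `drug_model`.
#' @return Renal clearance (L/h).
#' @export
renal_clearance_individual <- function(ind, drug) {
  if (is.null(ind$egfr) || !is.finite(ind$egfr)) {
    stop_domain("individual has no eGFR set")
  }
  w <- drug$renal_filtration_like_fraction
  max(0, drug$cl_renal_ref * (ind$egfr / drug$egfr_ref) *
        (w * ind$fu_baseline / drug$fu_ref + (1 - w)))
}
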