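#' Virtual individuals and virtual twins
#'
#' Generation of virtual subjects (healthy, cirrhotic, renally impaired;
#' European/Chinese/Japanese ancestry) from the system parameter
#' distributions, and mapping of observed patient covariate records to
#' "virtual twin" parameterisations in which observed covariates are fixed
#' and unobserved physiology is sampled.
#'
#' @name population
NULL

#' Estimated GFR by the 2009 CKD-EPI creatinine equation
#'
#' Original published constants (no ancestry coefficient applied).
#'
#' @param sex "male" or "female"; vectorised with `age` and
#'   `serum_creatinine`.
#' @param age Age in years (> 0).
#' @param serum_creatinine Serum creatinine in umol/L (> 0).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckd_epi("female", 50, 61.9)
#' @export
egfr_ckd_epi <- function(sex, age, serum_creatinine) {
  if (any(age <= 0) || any(serum_creatinine <= 0)) {
    stop_domain("age and serum_creatinine must be strictly positive")
  }
  sex <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  scr_mg <- serum_creatinine / 88.4
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  141 * pmin(scr_mg / kappa, 1)^alpha * pmax(scr_mg / kappa, 1)^(-1.209) *
    0.993^age * ifelse(sex == "female", 1.018, 1)
}

#' Body surface area by the Du Bois formula
#'
#' @param weight Body weight (kg).
#' @param height Height (cm).
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  0.007184 * weight^0.425 * height^0.725
}

ancestry_or_stop <- function(defaults, ancestry) {
  if (!ancestry %in% names(defaults$body_size)) {
    stop_config(sprintf("unknown ancestry '%s' (configured: %s)", ancestry,
                        paste(names(defaults$body_size), collapse = ", ")))
  }
  ancestry
}

# correlated hepatic CYP3A4/CYP2C8 draw: Gaussian copula with truncated
# log-normal marginals; Pearson correlation on the latent normals chosen to
# induce the configured Spearman rank correlation.
sample_hepatic_cyps <- function(defaults) {
  rs <- defaults$cyp3a4_cyp2c8_rank_correlation
  rho <- 2 * sin(pi * rs / 6)
  z1 <- rnorm(1)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
  e34 <- defaults$enzyme_abundance$CYP3A4_hepatic
  e28 <- defaults$enzyme_abundance$CYP2C8_hepatic
  c(CYP3A4_hepatic = qlnorm_trunc(pnorm(z1), e34$mean_pmol_mg, e34$cv, e34$min, e34$max),
    CYP2C8_hepatic = qlnorm_trunc(pnorm(z2), e28$mean_pmol_mg, e28$cv, e28$min, e28$max))
}

finalize_individual <- function(ind, drug) {
  ind$bsa <- bsa_dubois(ind$weight, ind$height)
  if (!is.null(ind$serum_creatinine) && is.finite(ind$serum_creatinine) &&
      is.na(ind$egfr)) {
    ind$egfr <- egfr_ckd_epi(ind$sex, ind$age, ind$serum_creatinine)
  }
  ind$fu_baseline <- unbound_fraction(0, ind$aag, drug$kd_app,
                                      drug$binding_capacity_per_aag,
                                      drug$molecular_weight,
                                      drug$aag_molecular_weight)
  structure(ind, class = "pbpk_individual")
}

#' Sample a virtual individual
#'
#' Draws the unobserved physiology of one subject from the configured
#' population distributions: body size from ancestry/sex-specific normals
#' (unless supplied), liver weight and hepatic blood flow scaled by body
#' surface area with a linear age decline, MPPGL and enzyme/transporter
#' abundances from truncated log-normals (hepatic CYP3A4 and CYP2C8
#' correlated through a Gaussian copula), AAG from its ancestry/sex
#' distribution, and serum creatinine (hence eGFR by CKD-EPI).
#' Deterministic given `seed`.
#'
#' @param defaults A `system_defaults`.
#' @param drug A `drug_model` (needed for the baseline unbound fraction).
#' @param demographics List with at least `age`, `sex`, `ancestry`;
#'   optionally fixed `weight`, `height`, `serum_creatinine`.
#' @param seed Integer seed for this individual's substream.
#' @param overrides Named list of direct physiology overrides applied after
#'   sampling (e.g. `list(aag = 3.2)` or
#'   `list(enzyme_abundance = c(CYP2C8_hepatic = 85))`); used by the
#'   sensitivity sweeps.
#' @return A `pbpk_individual`.
#' @export
sample_individual <- function(defaults, drug, demographics, seed, overrides = list()) {
  stopifnot(is.list(demographics))
  for (f in c("age", "sex", "ancestry")) {
    if (is.null(demographics[[f]])) {
      stop_validation(sprintf("demographics is missing mandatory field '%s'", f))
    }
  }
  anc <- ancestry_or_stop(defaults, demographics$ancestry)
  sex <- match.arg(tolower(demographics$sex), c("male", "female"))
  age <- demographics$age

  with_local_seed(seed, {
    bs <- defaults$body_size[[anc]]
    wkey <- paste0("weight_", sex, "_kg")
    hkey <- paste0("height_", sex, "_cm")
    weight <- demographics$weight %||%
      rnorm_trunc(1, bs[[wkey]][1], bs[[wkey]][2], lo = 35)
    height <- demographics$height %||%
      rnorm_trunc(1, bs[[hkey]][1], bs[[hkey]][2], lo = 140)
    bsa <- bsa_dubois(weight, height)

    age_fac_lw <- max(0.4, 1 - defaults$liver_weight_age_decline_per_yr *
                        max(0, age - defaults$age_reference_yr))
    liver_weight <- defaults$liver_weight_bsa_coef_g *
      bsa^defaults$liver_weight_bsa_exponent * age_fac_lw *
      rlnorm_trunc(1, 1, defaults$liver_weight_cv)
    age_fac_qh <- max(0.4, 1 - defaults$qh_age_decline_per_yr *
                        max(0, age - defaults$age_reference_yr))
    qh <- defaults$qh_bsa_coef_L_h_per_m2 * bsa * age_fac_qh
    mppgl <- rlnorm_trunc(1, defaults$mppgl_mean_mg_per_g, defaults$mppgl_cv)

    enz <- sample_hepatic_cyps(defaults)
    g <- defaults$gut_cyp3a4_abundance
    gut_cyp3a4 <- rlnorm_trunc(1, g$mean_nmol, g$cv, g$min, g$max)
    tr <- defaults$transporter_abundance
    transporters <- c(
      `P-gp` = rlnorm_trunc(1, tr$`P-gp`$mean_pmol_per_1e6_cells, tr$`P-gp`$cv),
      BCRP = rlnorm_trunc(1, tr$BCRP$mean_pmol_per_1e6_cells, tr$BCRP$cv)
    )
    aagd <- defaults$aag_distribution
    aag <- rlnorm_trunc(1, aagd$mean_g_per_L[[anc]][[sex]], aagd$cv,
                        aagd$min_g_per_L, aagd$max_g_per_L)
    scr_d <- defaults$serum_creatinine_umol_L[[sex]]
    scr <- demographics$serum_creatinine %||%
      rnorm_trunc(1, scr_d$mean, scr_d$sd, lo = 35)

    ind <- list(
      id = demographics$id %||% NA_character_,
      age = age, sex = sex, ancestry = anc,
      weight = weight, height = height, bsa = bsa,
      liver_weight = liver_weight, mppgl = mppgl, qh = qh,
      enzyme_abundance = enz, gut_cyp3a4 = gut_cyp3a4,
      transporter_abundance = transporters,
      aag = aag, serum_creatinine = scr, egfr = NA_real_,
      cirrhosis_class = "none", renal_band = "normal",
      fu_baseline = NA_real_
    )
    for (nm in names(overrides)) {
      if (nm %in% c("enzyme_abundance", "transporter_abundance")) {
        ov <- overrides[[nm]]
        ind[[nm]][names(ov)] <- ov
      } else {
        ind[[nm]] <- overrides[[nm]]
      }
    }
    finalize_individual(ind, drug)
  })
}

#' @export
print.pbpk_individual <- function(x, ...) {
  cat(sprintf("<pbpk_individual> %s, %s, %s, %.0f y, %.1f kg\n",
              x$id, x$sex, x$ancestry, x$age, x$weight))
  cat(sprintf("  liver %.0f g | Qh %.1f L/h | MPPGL %.1f | AAG %.2f g/L | eGFR %.1f\n",
              x$liver_weight, x$qh, x$mppgl, x$aag, x$egfr))
  cat(sprintf("  CYP3A4 %.1f, CYP2C8 %.1f pmol/mg | gut CYP3A4 %.1f nmol | fu0 %.4f\n",
              x$enzyme_abundance[["CYP3A4_hepatic"]],
              x$enzyme_abundance[["CYP2C8_hepatic"]], x$gut_cyp3a4, x$fu_baseline))
  if (x$cirrhosis_class != "none") cat("  cirrhosis:", x$cirrhosis_class, "\n")
  if (x$renal_band != "normal") cat("  renal band:", x$renal_band, "\n")
  invisible(x)
}

#' Apply a special-population condition to a healthy individual
#'
#' Applies the configured multiplier tables for liver cirrhosis
#' (Child-Pugh A/B/C: reduced liver weight, hepatic blood flow, hepatic CYP
#' abundances and AAG, graded A < B < C) or chronic kidney dysfunction
#' (eGFR bands: raised AAG as an acute-phase response, reduced CYP abundances
#' in default mode, healthy CYP abundances when `modified_renal` is set).
#'
#' @param ind A healthy `pbpk_individual` (condition "none").
#' @param drug A `drug_model`.
#' @param defaults A `system_defaults` carrying the multiplier tables.
#' @param condition One of `"A"`, `"B"`, `"C"` (cirrhosis) or `"30to60"`,
#'   `"lt30"` (renal bands).
#' @param modified_renal If `TRUE`, keep healthy CYP abundances in the renal
#'   bands (the "modified" kidney-dysfunction population).
#' @return A new `pbpk_individual`.
#' @export
apply_special_population <- function(ind, drug, defaults, condition,
                                     modified_renal = FALSE) {
  if (ind$cirrhosis_class != "none" || ind$renal_band != "normal") {
    stop_validation("stacking two special-population conditions is unsupported")
  }
  cyp_names <- c("CYP3A4_hepatic", "CYP2C8_hepatic")
  if (condition %in% c("A", "B", "C")) {
    m <- defaults$cirrhosis_multipliers[[condition]]
    ind$liver_weight <- ind$liver_weight * m$liver_weight
    ind$qh <- ind$qh * m$qh
    ind$enzyme_abundance[cyp_names] <- ind$enzyme_abundance[cyp_names] * m$cyp
    ind$aag <- ind$aag * m$aag
    ind$cirrhosis_class <- condition
  } else if (condition %in% c("30to60", "lt30")) {
    m <- defaults$renal_multipliers[[condition]]
    ind$aag <- ind$aag * m$aag
    if (!modified_renal) {
      ind$enzyme_abundance[cyp_names] <- ind$enzyme_abundance[cyp_names] * m$cyp
    }
    ind$egfr <- m$egfr_set
    ind$serum_creatinine <- NA_real_   # no longer consistent with the set eGFR
    ind$renal_band <- condition
  } else {
    stop_config(sprintf("unknown special-population condition '%s'", condition))
  }
  finalize_individual(ind, drug)
}

#' Build a virtual twin of an observed patient record
#'
#' Observed covariates (age, sex, ancestry, weight, height, serum creatinine,
#' cirrhosis class) are fixed to the record; unobserved physiology (enzyme
#' and transporter abundances, AAG, MPPGL) is sampled conditional on the
#' demographics.  Missing weight/height are imputed with the ancestry/sex
#' distribution centres; eGFR is computed from serum creatinine when present.
#'
#' @param rec A one-row patient record (list or one-row data frame) with at
#'   least `id`, `age`, `sex`, `ancestry`, `dose_mg_per_day`.
#' @param defaults A `system_defaults`.
#' @param drug A `drug_model`.
#' @param seed Integer seed.
#' @return A `pbpk_individual`.
#' @export
make_virtual_twin <- function(rec, defaults, drug, seed) {
  rec <- as.list(rec)
  for (f in c("id", "age", "sex", "ancestry", "dose_mg_per_day")) {
    if (is.null(rec[[f]]) || is.na(rec[[f]])) {
      stop_validation(sprintf("patient record is missing mandatory field '%s'", f))
    }
  }
  if (rec$dose_mg_per_day <= 0) stop_validation("field 'dose_mg_per_day' must be > 0")
  demo <- list(id = as.character(rec$id), age = rec$age, sex = rec$sex,
               ancestry = rec$ancestry)
  for (f in c("weight", "height", "serum_creatinine")) {
    if (!is.null(rec[[f]]) && is.finite(rec[[f]])) demo[[f]] <- rec[[f]]
  }
  bs <- defaults$body_size[[ancestry_or_stop(defaults, rec$ancestry)]]
  sex <- match.arg(tolower(rec$sex), c("male", "female"))
  demo$weight <- demo$weight %||% bs[[paste0("weight_", sex, "_kg")]][1]
  demo$height <- demo$height %||% bs[[paste0("height_", sex, "_cm")]][1]
  ind <- sample_individual(defaults, drug, demo, seed)
  cls <- rec$cirrhosis_class %||% "none"
  if (!is.na(cls) && !identical(cls, "none") && nzchar(cls)) {
    ind <- apply_special_population(ind, drug, defaults, cls)
  }
  ind
}
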