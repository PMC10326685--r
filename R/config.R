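#' Drug, system and perpetrator parameter configuration
#'
#' The model is driven by a single structured-text (YAML) configuration with
#' three sections: `drug` (imatinib-specific absorption, binding, clearance
#' and autoinhibition parameters), `system` (population physiology:
#' demographic covariate models, enzyme/transporter abundance distributions,
#' AAG distributions, disease multiplier tables) and `perpetrators`
#' (co-medication forcing functions and their enzyme interaction terms).
#'
#' @name config
NULL

drug_required_keys <- c(
  "name", "molecular_weight_g_mol", "aag_molecular_weight_g_mol", "ka_per_h",
  "fa_fraction", "blood_plasma_ratio", "fu_ref_fraction", "aag_ref_g_per_L",
  "binding_capacity_per_aag", "clint_per_pmol_uL_min",
  "clint_biliary_per_abundance_L_h", "cl_renal_ref_L_per_h",
  "renal_filtration_like_fraction", "egfr_ref_mL_min",
  "autoinhibition", "vc_per_kg_L", "vp_per_kg_L", "q_inter_L_per_h",
  "kp_liver", "fu_gut", "gut_wall_volume_L", "gut_transit_per_h"
)
drug_optional_keys <- "kd_app_g_per_L"

system_required_keys <- c(
  "qh_bsa_coef_L_h_per_m2", "qh_age_decline_per_yr", "liver_weight_bsa_coef_g",
  "liver_weight_bsa_exponent", "liver_weight_age_decline_per_yr",
  "liver_weight_cv", "reference_liver_weight_g", "age_reference_yr",
  "mppgl_mean_mg_per_g", "mppgl_cv", "enzyme_abundance",
  "gut_cyp3a4_abundance", "cyp3a4_cyp2c8_rank_correlation",
  "transporter_abundance", "aag_distribution", "serum_creatinine_umol_L",
  "kdeg_per_h", "body_size", "cirrhosis_multipliers", "renal_multipliers"
)

clint_enzymes <- c("CYP3A4_hepatic", "CYP2C8_hepatic", "CYP3A4_gut", "other_CYP")
biliary_transporters <- c("P-gp", "BCRP")
known_ancestries <- c("European", "Chinese", "Japanese")

check_keys <- function(x, required, optional = character(), where) {
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop_config(sprintf("configuration section '%s' is missing required key(s): %s",
                        where, paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    stop_config(sprintf("configuration section '%s' has unknown key(s): %s",
                        where, paste(unknown, collapse = ", ")))
  }
  invisible(x)
}

#' Construct a drug model from a parsed configuration section
#' @noRd
new_drug_model <- function(d) {
  check_keys(d, drug_required_keys, drug_optional_keys, "drug")
  check_keys(d$clint_per_pmol_uL_min, clint_enzymes, where = "drug$clint_per_pmol_uL_min")
  check_keys(d$clint_biliary_per_abundance_L_h, biliary_transporters,
             where = "drug$clint_biliary_per_abundance_L_h")
  check_keys(d$autoinhibition, c("KI_uM", "kinact_per_h"), where = "drug$autoinhibition")

  check_fraction(d$fu_ref_fraction, "fu_ref")
  check_fraction(d$fa_fraction, "fa", closed_upper = TRUE)
  for (f in c("molecular_weight_g_mol", "aag_molecular_weight_g_mol", "ka_per_h",
              "blood_plasma_ratio", "aag_ref_g_per_L", "binding_capacity_per_aag",
              "cl_renal_ref_L_per_h", "egfr_ref_mL_min", "vc_per_kg_L",
              "vp_per_kg_L", "q_inter_L_per_h", "kp_liver", "fu_gut",
              "gut_wall_volume_L", "gut_transit_per_h")) {
    check_positive(d[[f]], f)
  }
  clint <- unlist(d$clint_per_pmol_uL_min)[clint_enzymes]
  if (any(!is.finite(clint)) || any(clint < 0)) {
    stop_validation("field 'clint_per_pmol' entries must be non-negative")
  }
  bil <- unlist(d$clint_biliary_per_abundance_L_h)[biliary_transporters]
  if (any(!is.finite(bil)) || any(bil < 0)) {
    stop_validation("field 'clint_biliary_per_abundance' entries must be non-negative")
  }
  check_positive(d$autoinhibition$KI_uM, "autoinhibition$KI_uM")
  check_positive(d$autoinhibition$kinact_per_h, "autoinhibition$kinact_per_h")

  kd <- calibrate_binding_constant(d$fu_ref_fraction, d$aag_ref_g_per_L,
                                   d$binding_capacity_per_aag)
  if (!is.null(d$kd_app_g_per_L) &&
      abs(d$kd_app_g_per_L - kd) > 1e-8 * kd) {
    stop_validation("field 'kd_app_g_per_L' is inconsistent with fu_ref and aag_ref")
  }

  structure(list(
    name = d$name,
    molecular_weight = d$molecular_weight_g_mol,
    aag_molecular_weight = d$aag_molecular_weight_g_mol,
    ka = d$ka_per_h,
    fa = d$fa_fraction,
    blood_plasma_ratio = d$blood_plasma_ratio,
    fu_ref = d$fu_ref_fraction,
    aag_ref = d$aag_ref_g_per_L,
    binding_capacity_per_aag = d$binding_capacity_per_aag,
    kd_app = kd,
    clint_per_pmol = clint,
    clint_biliary_per_abundance = bil,
    cl_renal_ref = d$cl_renal_ref_L_per_h,
    renal_filtration_like_fraction = d$renal_filtration_like_fraction,
    egfr_ref = d$egfr_ref_mL_min,
    autoinhibition = list(KI_uM = d$autoinhibition$KI_uM,
                          kinact = d$autoinhibition$kinact_per_h),
    vc_per_kg = d$vc_per_kg_L,
    vp_per_kg = d$vp_per_kg_L,
    q_inter = d$q_inter_L_per_h,
    kp_liver = d$kp_liver,
    fu_gut = d$fu_gut,
    gut_wall_volume = d$gut_wall_volume_L,
    gut_transit = d$gut_transit_per_h
  ), class = "drug_model")
}

check_dist <- function(x, fields, where) {
  check_keys(x, fields, where = where)
  vals <- unlist(x)
  if (any(!is.finite(vals))) stop_validation(sprintf("'%s' has non-finite entries", where))
  if (!is.null(x$min) && !is.null(x$max)) {
    mean_field <- grep("^mean", fields, value = TRUE)[1]
    if (x[[mean_field]] < x$min || x[[mean_field]] > x$max) {
      stop_validation(sprintf("'%s': mean outside [min, max]", where))
    }
  }
  invisible(x)
}

#' @noRd
new_system_defaults <- function(s) {
  check_keys(s, system_required_keys, where = "system")
  check_keys(s$enzyme_abundance, c("CYP3A4_hepatic", "CYP2C8_hepatic"),
             where = "system$enzyme_abundance")
  for (e in names(s$enzyme_abundance)) {
    check_dist(s$enzyme_abundance[[e]], c("mean_pmol_mg", "cv", "min", "max"),
               paste0("system$enzyme_abundance$", e))
  }
  check_dist(s$gut_cyp3a4_abundance, c("mean_nmol", "cv", "min", "max"),
             "system$gut_cyp3a4_abundance")
  rs <- s$cyp3a4_cyp2c8_rank_correlation
  if (!is.finite(rs) || rs < -1 || rs > 1) {
    stop_validation("field 'cyp3a4_cyp2c8_rank_correlation' must lie in [-1, 1]")
  }
  check_keys(s$transporter_abundance, biliary_transporters,
             where = "system$transporter_abundance")
  check_keys(s$aag_distribution, c("cv", "min_g_per_L", "max_g_per_L", "mean_g_per_L"),
             where = "system$aag_distribution")
  check_keys(s$aag_distribution$mean_g_per_L, known_ancestries,
             where = "system$aag_distribution$mean_g_per_L")
  check_keys(s$body_size, known_ancestries, where = "system$body_size")
  check_keys(s$kdeg_per_h, c("CYP3A4_hepatic", "CYP3A4_gut", "CYP2C8_hepatic"),
             where = "system$kdeg_per_h")
  check_keys(s$cirrhosis_multipliers, c("A", "B", "C"),
             where = "system$cirrhosis_multipliers")
  check_keys(s$renal_multipliers, c("30to60", "lt30"),
             where = "system$renal_multipliers")
  for (cls in names(s$cirrhosis_multipliers)) {
    m <- unlist(s$cirrhosis_multipliers[[cls]])
    if (any(m <= 0)) stop_validation("cirrhosis multipliers must be strictly positive")
  }
  for (bnd in names(s$renal_multipliers)) {
    m <- unlist(s$renal_multipliers[[bnd]])
    if (any(m <= 0)) stop_validation("renal multipliers must be strictly positive")
  }
  aagm <- unlist(s$aag_distribution$mean_g_per_L)
  if (any(aagm < s$aag_distribution$min_g_per_L) ||
      any(aagm > s$aag_distribution$max_g_per_L)) {
    stop_validation("AAG distribution means must lie within [min, max]")
  }
  structure(s, class = "system_defaults")
}

interaction_keys <- list(
  competitive = c("enzyme", "site", "mechanism", "Ki_uM"),
  mbi = c("enzyme", "site", "mechanism", "KI_uM", "kinact_per_h"),
  induction = c("enzyme", "site", "mechanism", "Indmax", "IndC50_uM")
)
valid_enzyme_sites <- c("CYP3A4.hepatic", "CYP3A4.gut", "CYP2C8.hepatic")

#' @noRd
new_perpetrator_model <- function(name, pdef) {
  check_keys(pdef, c("regimen", "pk", "interactions"), where = paste0("perpetrators$", name))
  reg <- pdef$regimen
  check_keys(reg, c("dose_mg", "interval_h", "n_doses", "start_offset_h"),
             where = paste0(name, "$regimen"))
  if (reg$n_doses < 1) stop_validation(sprintf("%s: regimen n_doses must be >= 1", name))
  if (reg$dose_mg < 0) stop_validation(sprintf("%s: dose_mg must be non-negative", name))
  check_positive(reg$interval_h, paste0(name, "$interval_h"))
  pk <- pdef$pk
  check_keys(pk, c("mw_g_mol", "ka_per_h", "v_over_f_L", "cl_over_f_L_per_h",
                   "fu", "blood_plasma_ratio"), optional = "metabolite",
             where = paste0(name, "$pk"))
  for (f in c("mw_g_mol", "ka_per_h", "v_over_f_L", "cl_over_f_L_per_h", "fu")) {
    check_positive(pk[[f]], paste0(name, "$pk$", f))
  }
  met <- NULL
  if (!is.null(pk$metabolite)) {
    check_keys(pk$metabolite, c("name", "fraction_formed", "ke_per_h", "v_L", "fu"),
               where = paste0(name, "$pk$metabolite"))
    met <- pk$metabolite
    check_fraction(met$fraction_formed, "metabolite$fraction_formed", closed_upper = TRUE)
  }
  ints <- lapply(pdef$interactions, function(it) {
    mech <- it$mechanism %||% stop_config(sprintf("%s: interaction without mechanism", name))
    if (!mech %in% names(interaction_keys)) {
      stop_config(sprintf("%s: unknown interaction mechanism '%s'", name, mech))
    }
    check_keys(it, interaction_keys[[mech]], optional = "driver",
               where = paste0(name, "$interactions"))
    es <- paste(it$enzyme, it$site, sep = ".")
    if (!es %in% valid_enzyme_sites) {
      stop_config(sprintf("%s: interaction names unknown enzyme x site '%s'", name, es))
    }
    kin <- unlist(it[setdiff(names(it), c("enzyme", "site", "mechanism", "driver"))])
    if (any(kin <= 0)) stop_validation(sprintf("%s: interaction constants must be > 0", name))
    it
  })
  structure(list(name = name, regimen = reg, pk = pk, metabolite = met,
                 interactions = ints),
            class = "perpetrator_model")
}

#' Load the drug/system/perpetrator configuration
#'
#' Reads a YAML model configuration, validates it (unknown keys are rejected,
#' required keys and invariants are enforced) and returns unit-normalised
#' parameter objects.
#'
#' @param path Path to a YAML configuration file. Defaults to the
#'   configuration shipped with the package.
#' @return A list with elements `drug` (a `drug_model`), `system`
#'   (a `system_defaults`) and `perpetrators` (named list of
#'   `perpetrator_model` objects).
#' @examples
#' cfg <- load_model_config()
#' cfg$drug$fu_ref
#' @export
load_model_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop_config(sprintf("configuration file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("drug", "system", "perpetrators"), where = "<root>")
  perps <- lapply(names(raw$perpetrators), function(nm) {
    new_perpetrator_model(nm, raw$perpetrators[[nm]])
  })
  names(perps) <- names(raw$perpetrators)
  list(drug = new_drug_model(raw$drug),
       system = new_system_defaults(raw$system),
       perpetrators = perps)
}

#' Path of the configuration file shipped with the package
#' @export
default_config_path <- function() {
  system.file("extdata", "config_imatinib.yaml", package = "imatpbpk", mustWork = TRUE)
}

#' Write a configuration back to YAML
#'
#' Serialises the objects returned by [load_model_config()] so that a
#' write/re-load round trip reproduces identical objects.
#'
#' @param cfg Configuration list (`drug`, `system`, `perpetrators`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cfg, path) {
  d <- cfg$drug
  drug_raw <- list(
    name = d$name,
    molecular_weight_g_mol = d$molecular_weight,
    aag_molecular_weight_g_mol = d$aag_molecular_weight,
    ka_per_h = d$ka,
    fa_fraction = d$fa,
    blood_plasma_ratio = d$blood_plasma_ratio,
    fu_ref_fraction = d$fu_ref,
    aag_ref_g_per_L = d$aag_ref,
    binding_capacity_per_aag = d$binding_capacity_per_aag,
    kd_app_g_per_L = d$kd_app,
    clint_per_pmol_uL_min = as.list(d$clint_per_pmol),
    clint_biliary_per_abundance_L_h = as.list(d$clint_biliary_per_abundance),
    cl_renal_ref_L_per_h = d$cl_renal_ref,
    renal_filtration_like_fraction = d$renal_filtration_like_fraction,
    egfr_ref_mL_min = d$egfr_ref,
    autoinhibition = list(KI_uM = d$autoinhibition$KI_uM,
                          kinact_per_h = d$autoinhibition$kinact),
    vc_per_kg_L = d$vc_per_kg,
    vp_per_kg_L = d$vp_per_kg,
    q_inter_L_per_h = d$q_inter,
    kp_liver = d$kp_liver,
    fu_gut = d$fu_gut,
    gut_wall_volume_L = d$gut_wall_volume,
    gut_transit_per_h = d$gut_transit
  )
  perps_raw <- lapply(cfg$perpetrators, function(p) {
    pk <- p$pk
    if (!is.null(p$metabolite)) pk$metabolite <- p$metabolite
    list(regimen = p$regimen, pk = pk, interactions = p$interactions)
  })
  out <- list(drug = drug_raw, system = unclass(cfg$system), perpetrators = perps_raw)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Calibrate the apparent AAG dissociation constant
#'
#' Finds the apparent dissociation constant `kd_app` (on the AAG g/L scale)
#' such that the dilute-limit unbound fraction at the reference AAG
#' concentration equals `fu_ref`.  For one-site binding the dilute limit is
#' `fu = 1 / (1 + aag / kd_app)`, giving the closed form
#' `kd_app = aag_ref * fu_ref / (1 - fu_ref)`.
#'
#' @param fu_ref Reference unbound fraction in plasma, in (0, 1).
#' @param aag_ref Reference AAG concentration (g/L).
#' @param binding_capacity_per_aag Binding sites per AAG molecule (the dilute
#'   limit does not depend on it; retained for interface symmetry).
#' @return `kd_app` in g/L.
#' @examples
#' calibrate_binding_constant(0.05, 0.91)
#' @export
calibrate_binding_constant <- function(fu_ref, aag_ref, binding_capacity_per_aag = 1) {
  if (!is.finite(fu_ref) || fu_ref <= 0 || fu_ref >= 1) {
    stop_domain("fu_ref must lie strictly within (0, 1)")
  }
  if (fu_ref > 0.99) {
    stop_domain("fu_ref is too close to 1: no measurable binding, kd_app diverges")
  }
  check_positive(aag_ref, "aag_ref")
  check_positive(binding_capacity_per_aag, "binding_capacity_per_aag")
  aag_ref * fu_ref / (1 - fu_ref)
}

#' Hepatic metabolic pathway fractions at reference abundances
#'
#' Computes the fraction of total hepatic metabolic intrinsic clearance
#' attributable to each enzyme pathway at the reference abundances and
#' baseline (uninhibited) enzyme activity, and flags a deviation of the
#' aggregate non-CYP3A4/CYP2C8 share from its nominal 3%.
#'
#' @param drug A `drug_model`.
#' @param defaults A `system_defaults`.
#' @return A tibble with columns `pathway`, `clint_L_h`, `fraction` and
#'   `other_within_tolerance`.
#' @export
validate_pathway_fractions <- function(drug, defaults) {
  scale <- defaults$mppgl_mean_mg_per_g * defaults$reference_liver_weight_g * 6e-5
  cl <- drug$clint_per_pmol
  ab <- c(CYP3A4_hepatic = defaults$enzyme_abundance$CYP3A4_hepatic$mean_pmol_mg,
          CYP2C8_hepatic = defaults$enzyme_abundance$CYP2C8_hepatic$mean_pmol_mg,
          other_CYP = 1)
  clint <- c(CYP3A4_hepatic = unname(ab["CYP3A4_hepatic"] * cl["CYP3A4_hepatic"]),
             CYP2C8_hepatic = unname(ab["CYP2C8_hepatic"] * cl["CYP2C8_hepatic"]),
             other_CYP = unname(ab["other_CYP"] * cl["other_CYP"])) * scale
  total <- sum(clint)
  frac <- if (total > 0) clint / total else clint * 0
  tibble::tibble(
    pathway = names(clint),
    clint_L_h = unname(clint),
    fraction = unname(frac),
    other_within_tolerance = abs(frac[["other_CYP"]] - 0.03) <= 0.01
  )
}
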