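#' Synthetic patient cohort
#'
#' Generates a synthetic cohort with the covariate structure and outcome
#' prevalences of a real-world chronic myeloid leukemia population treated
#' with once-daily imatinib, so that the complete exposure-outcome analysis
#' pipeline runs without any external patient data.  The marginal covariate
#' distributions are documented stand-ins, not estimates of any real cohort.
#'
#' @name synthetic_cohort
NULL

#' Cohort generator settings
#'
#' @param age_range Age range (years).
#' @param age_mean,age_sd Centre/spread of the truncated normal age draw.
#' @param prop_female Proportion female.
#' @param ancestry_probs Named probabilities for European/Chinese/Japanese.
#' @param dose_levels,dose_probs Daily dose levels (mg) and probabilities.
#' @param prop_cirrhosis Probability of (mild) cirrhosis per class A/B/C.
#' @param comedication_prob Probability that each perpetrator co-medication
#'   flag is set.
#' @return A list of generator settings.
#' @export
cohort_spec <- function(age_range = c(20, 91), age_mean = 58, age_sd = 15,
                        prop_female = 0.4,
                        ancestry_probs = c(European = 0.7, Chinese = 0.2,
                                           Japanese = 0.1),
                        dose_levels = c(300, 400, 600, 800),
                        dose_probs = c(0.1, 0.75, 0.1, 0.05),
                        prop_cirrhosis = c(A = 0.03, B = 0.015, C = 0.005),
                        comedication_prob = 0.08) {
  stopifnot(abs(sum(ancestry_probs) - 1) < 1e-9, abs(sum(dose_probs) - 1) < 1e-9)
  list(age_range = age_range, age_mean = age_mean, age_sd = age_sd,
       prop_female = prop_female, ancestry_probs = ancestry_probs,
       dose_levels = dose_levels, dose_probs = dose_probs,
       prop_cirrhosis = prop_cirrhosis, comedication_prob = comedication_prob)
}

perpetrator_names <- c("diltiazem", "verapamil", "trimethoprim",
                       "clopidogrel", "hyperforin")

#' Generate a synthetic patient cohort
#'
#' @param n Number of patients.
#' @param seed Integer seed (the table is deterministic per seed).
#' @param spec A [cohort_spec()].
#' @param defaults A `system_defaults` for body-size and creatinine draws.
#' @return A `CohortTable` tibble, one row per patient.
#' @export
generate_cohort <- function(n, seed, spec = cohort_spec(),
                            defaults = load_model_config()$system) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    sex <- ifelse(runif(n) < spec$prop_female, "female", "male")
    ancestry <- sample(names(spec$ancestry_probs), n, replace = TRUE,
                       prob = spec$ancestry_probs)
    age <- rnorm_trunc(n, spec$age_mean, spec$age_sd,
                       lo = spec$age_range[1], hi = spec$age_range[2])
    weight <- height <- scr <- numeric(n)
    for (i in seq_len(n)) {
      bs <- defaults$body_size[[ancestry[i]]]
      weight[i] <- rnorm_trunc(1, bs[[paste0("weight_", sex[i], "_kg")]][1],
                               bs[[paste0("weight_", sex[i], "_kg")]][2], lo = 35)
      height[i] <- rnorm_trunc(1, bs[[paste0("height_", sex[i], "_cm")]][1],
                               bs[[paste0("height_", sex[i], "_cm")]][2], lo = 140)
      sc <- defaults$serum_creatinine_umol_L[[sex[i]]]
      scr[i] <- rnorm_trunc(1, sc$mean, sc$sd, lo = 35)
    }
    u <- runif(n)
    pc <- cumsum(spec$prop_cirrhosis)
    cirrhosis <- dplyr::case_when(
      u < pc[["A"]] ~ "A", u < pc[["B"]] ~ "B", u < pc[["C"]] ~ "C",
      .default = "none"
    )
    dose <- sample(spec$dose_levels, n, replace = TRUE, prob = spec$dose_probs)
    comeds <- matrix(runif(n * length(perpetrator_names)) < spec$comedication_prob,
                     nrow = n,
                     dimnames = list(NULL, paste0("comed_", perpetrator_names)))
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      age = age, sex = sex, ancestry = ancestry,
      weight = weight, height = height, serum_creatinine = scr,
      cirrhosis_class = cirrhosis, dose_mg_per_day = dose,
      tibble::as_tibble(comeds),
      emr_evaluable = NA, emr_achieved = NA, adr_grade3 = NA
    )
  })
}

#' Exposure-outcome link settings
#'
#' Logistic links from log steady-state exposure to the probabilities of
#' early molecular response (EMR, among the evaluable subset) and grade >= 3
#' adverse drug reactions.  Positive slopes encode the observed directions
#' (higher exposure, higher EMR and ADR probability); intercepts are
#' calibrated so that expected prevalences at the default exposure
#' distribution are approximately 35/45 (EMR) and 47/68 (ADR).
#'
#' @param emr_intercept,emr_slope Logistic coefficients on `log(AUC)` for EMR.
#' @param adr_intercept,adr_slope Likewise for grade >= 3 ADR.
#' @param evaluable_fraction Fraction of patients evaluable for EMR.
#' @return An `outcome_link` list.
#' @export
outcome_link <- function(emr_intercept = -17.24, emr_slope = 5,
                         adr_intercept = -14.26, adr_slope = 4,
                         evaluable_fraction = 45 / 68) {
  if (emr_slope < 0 || adr_slope < 0) {
    stop_validation("outcome link slopes must be non-negative (observed directions)")
  }
  list(emr_intercept = emr_intercept, emr_slope = emr_slope,
       adr_intercept = adr_intercept, adr_slope = adr_slope,
       evaluable_fraction = evaluable_fraction)
}

#' Assign outcome labels from simulated exposure
#'
#' @param cohort A `CohortTable` tibble from [generate_cohort()].
#' @param exposures Positive per-patient steady-state AUC values aligned with
#'   the cohort rows.
#' @param link An [outcome_link()].
#' @param seed Integer seed.
#' @return The cohort with `emr_evaluable`, `emr_achieved`, `adr_grade3`
#'   filled in (EMR labels are `NA` outside the evaluable subset).
#' @export
assign_outcomes <- function(cohort, exposures, link = outcome_link(), seed = 1L) {
  if (nrow(cohort) != length(exposures)) {
    stop_validation("exposures must align with cohort rows")
  }
  if (any(!is.finite(exposures)) || any(exposures <= 0)) {
    stop_validation("exposures must be positive")
  }
  with_local_seed(seed + 7919L, {
    n <- nrow(cohort)
    evaluable <- runif(n) < link$evaluable_fraction
    p_emr <- stats::plogis(link$emr_intercept + link$emr_slope * log(exposures))
    p_adr <- stats::plogis(link$adr_intercept + link$adr_slope * log(exposures))
    emr <- ifelse(evaluable, runif(n) < p_emr, NA)
    adr <- runif(n) < p_adr
    dplyr::mutate(cohort, emr_evaluable = evaluable, emr_achieved = emr,
                  adr_grade3 = adr)
  })
}

#' Simulate steady-state exposure for every patient in a cohort
#'
#' Builds a virtual twin per patient record, simulates the patient's own
#' once-daily regimen for 14 days (co-medications from the record's flags)
#' and returns the per-patient steady-state metrics.
#'
#' @param cohort A `CohortTable` tibble.
#' @param drug,defaults Model configuration objects.
#' @param perpetrators Named list of `perpetrator_model`s used to honour
#'   co-medication flags (set to `NULL` to ignore them).
#' @param seed Root seed for the twins' unobserved physiology.
#' @param options See [pbpk_options()].
#' @return Tibble with `id`, `dose_mg_per_day` and the steady-state metrics.
#' @export
simulate_cohort <- function(cohort, drug, defaults, perpetrators = NULL,
                            seed = 1L, options = pbpk_options()) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- as.list(cohort[i, ])
    ind <- make_virtual_twin(rec, defaults, drug, subject_seed(seed, 1L, i))
    perp <- NULL
    if (!is.null(perpetrators)) {
      flags <- as.logical(unlist(rec[paste0("comed_", names(perpetrators))]))
      on <- which(!is.na(flags) & flags)
      if (length(on)) perp <- perpetrators[[on[1]]]
    }
    sim <- simulate_pbpk(ind, drug, dose_regimen(dose = rec$dose_mg_per_day),
                         defaults, perpetrator = perp, options = options)
    dplyr::bind_cols(tibble::tibble(id = rec$id,
                                    dose_mg_per_day = rec$dose_mg_per_day),
                     sim$metrics)
  })
  dplyr::bind_rows(rows)
}

cohort_columns <- c("id", "age", "sex", "ancestry", "weight", "height",
                    "serum_creatinine", "cirrhosis_class", "dose_mg_per_day",
                    paste0("comed_", perpetrator_names),
                    "emr_evaluable", "emr_achieved", "adr_grade3")

#' Write / read the cohort CSV schema
#'
#' One row per patient record; missing values as empty cells.
#'
#' @param cohort A `CohortTable` tibble.
#' @param path CSV file path.
#' @return `path` (write) or the cohort tibble (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort[, cohort_columns], path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = "c", age = "d", sex = "c", ancestry = "c", weight = "d",
    height = "d", serum_creatinine = "d", cirrhosis_class = "c",
    dose_mg_per_day = "d", .default = "l"
  ))
}
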