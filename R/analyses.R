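#' Virtual-trial study analyses
#'
#' The three study designs built on the simulation engine: virtual-trial
#' exposure prediction with outcome-group statistics, one-at-a-time
#' sensitivity sweeps over physiological parameters, and paired
#' perpetrator drug-drug interaction studies summarised as geometric mean
#' ratios.
#'
#' @name study_analyses
NULL

#' Virtual trial design
#'
#' @param n_trials Number of virtual trials.
#' @param n_subjects Subjects per trial.
#' @param age_range Two-element numeric range of ages (years).
#' @param prop_female Proportion of female subjects per trial (fixed
#'   composition, e.g. 0.4 gives 4 of 10).
#' @param ancestry Ancestry label for all subjects.
#' @param seed Root seed; per-subject substreams are derived from it.
#' @return A `trial_design` object.
#' @export
trial_design <- function(n_trials = 10, n_subjects = 10, age_range = c(20, 91),
                         prop_female = 0.4, ancestry = "European", seed = 1L) {
  if (n_trials < 1 || n_subjects < 1) stop_validation("trial counts must be >= 1")
  if (prop_female < 0 || prop_female > 1) {
    stop_validation("prop_female must lie in [0, 1]")
  }
  structure(list(n_trials = n_trials, n_subjects = n_subjects,
                 age_range = age_range, prop_female = prop_female,
                 ancestry = ancestry, seed = seed), class = "trial_design")
}

# build the demographics of subject (t, j) under a design + scenario
subject_demographics <- function(design, t, j, scenario = list()) {
  n_f <- round(design$prop_female * design$n_subjects)
  sex <- if (j <= n_f) "female" else "male"
  age <- with_local_seed(subject_seed(design$seed + 1, t, j), {
    runif(1, design$age_range[1], design$age_range[2])
  })
  demo <- list(id = sprintf("T%02dS%02d", t, j), age = age, sex = sex,
               ancestry = design$ancestry)
  for (nm in names(scenario$demographics %||% list())) {
    demo[[nm]] <- scenario$demographics[[nm]]
  }
  demo
}

build_subject <- function(design, t, j, drug, defaults, scenario = list()) {
  demo <- subject_demographics(design, t, j, scenario)
  ind <- sample_individual(defaults, drug, demo, subject_seed(design$seed, t, j),
                           overrides = scenario$overrides %||% list())
  cond <- scenario$condition %||% "none"
  if (!identical(cond, "none")) {
    ind <- apply_special_population(ind, drug, defaults, cond,
                                    modified_renal = isTRUE(scenario$modified_renal))
  }
  ind
}

#' Run a set of virtual trials
#'
#' Simulates `n_trials x n_subjects` independent virtual subjects under a
#' dosing regimen and returns a long per-subject metrics table.  Subjects
#' whose simulation fails are excluded with a warning; more than 10%
#' failures abort the run.
#'
#' @param design A [trial_design()].
#' @param drug,defaults Model configuration objects.
#' @param regimen A [dose_regimen()].
#' @param scenario Optional list with `demographics` (fixed covariates),
#'   `overrides` (physiology overrides), `condition` and `modified_renal`.
#' @param perpetrator Optional `perpetrator_model` co-administered to every
#'   subject.
#' @param options See [pbpk_options()].
#' @return A tibble with one row per subject: trial, subject, id,
#'   demographics and the steady-state metrics.
#' @export
run_virtual_trials <- function(design, drug, defaults, regimen,
                               scenario = list(), perpetrator = NULL,
                               options = pbpk_options()) {
  stopifnot(inherits(design, "trial_design"))
  grid <- tidyr::expand_grid(trial = seq_len(design$n_trials),
                             subject = seq_len(design$n_subjects))
  rows <- purrr::pmap(grid, function(trial, subject) {
    ind <- build_subject(design, trial, subject, drug, defaults, scenario)
    sim <- try(simulate_pbpk(ind, drug, regimen, defaults,
                             perpetrator = perpetrator, options = options),
               silent = TRUE)
    if (inherits(sim, "try-error")) {
      return(tibble::tibble(trial = trial, subject = subject, id = ind$id,
                            age = ind$age, sex = ind$sex, weight = ind$weight,
                            aag = ind$aag, failed = TRUE,
                            auc_0_24_ss = NA_real_, css_max = NA_real_,
                            css_min = NA_real_, cl_over_f = NA_real_))
    }
    dplyr::bind_cols(
      tibble::tibble(trial = trial, subject = subject, id = ind$id,
                     age = ind$age, sex = ind$sex, weight = ind$weight,
                     aag = ind$aag, failed = FALSE),
      sim$metrics
    )
  })
  out <- dplyr::bind_rows(rows)
  n_fail <- sum(out$failed)
  if (n_fail > 0.1 * nrow(out)) {
    abort(sprintf("virtual trial run failed for %d of %d subjects",
                  n_fail, nrow(out)), class = "imatpbpk_run_error")
  }
  if (n_fail > 0) {
    warning(sprintf("%d subject simulation(s) failed and were excluded", n_fail))
  }
  dplyr::select(dplyr::filter(out, !.data$failed), -"failed")
}

#' Geometric mean with a t confidence interval
#'
#' @param values Positive values (n >= 2).
#' @param level Confidence level (e.g. 0.95 or 0.90).
#' @return A tibble with `gm`, `lo`, `hi`, `n`.
#' @export
geomean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop_domain("need at least two values")
  if (any(values <= 0)) stop_domain("geometric mean requires positive values")
  lx <- log(values)
  n <- length(lx)
  se <- sd(lx) / sqrt(n)
  q <- qt(1 - (1 - level) / 2, df = n - 1)
  tibble::tibble(gm = exp(mean(lx)), lo = exp(mean(lx) - q * se),
                 hi = exp(mean(lx) + q * se), n = n)
}

#' Compare simulated exposure between two outcome groups
#'
#' For each metric: geometric means with confidence intervals per group, the
#' between-group geometric mean ratio, a Kruskal-Wallis rank sum test on the
#' raw metric and a two-sample t-test on the log metric (two-sided, alpha
#' 0.05).
#'
#' @param metrics Per-subject metrics tibble (e.g. from
#'   [run_virtual_trials()] or [simulate_cohort()]).
#' @param labels Logical vector aligned with `metrics` rows; `NA` rows are
#'   dropped.
#' @param metric_cols Metric columns to compare.
#' @param level Confidence level for the group geometric means.
#' @return A tibble with one row per metric (class `outcome_comparison`).
#' @export
compare_groups <- function(metrics, labels,
                           metric_cols = c("auc_0_24_ss", "css_max",
                                           "css_min", "cl_over_f"),
                           level = 0.95) {
  if (nrow(metrics) != length(labels)) {
    stop_validation("labels must align with metrics rows")
  }
  keep <- !is.na(labels)
  metrics <- metrics[keep, , drop = FALSE]
  labels <- as.logical(labels[keep])
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("each group needs at least two subjects",
          class = "imatpbpk_statistics_error")
  }
  res <- purrr::map(metric_cols, function(mc) {
    x1 <- metrics[[mc]][labels]
    x0 <- metrics[[mc]][!labels]
    g1 <- geomean_ci(x1, level); g0 <- geomean_ci(x0, level)
    kw <- kruskal.test(list(x1, x0))
    tt <- t.test(log(x1), log(x0))
    tibble::tibble(metric = mc,
                   gm_yes = g1$gm, lo_yes = g1$lo, hi_yes = g1$hi, n_yes = g1$n,
                   gm_no = g0$gm, lo_no = g0$lo, hi_no = g0$hi, n_no = g0$n,
                   gm_ratio = g1$gm / g0$gm,
                   p_kruskal_wallis = kw$p.value,
                   p_t_test = tt$p.value)
  })
  structure(dplyr::bind_rows(res), class = c("outcome_comparison",
                                             class(tibble::tibble())))
}

sweep_parameters <- c("sex", "age", "weight", "egfr_band", "cirrhosis",
                      "CYP3A4_hepatic", "CYP2C8_hepatic", "CYP3A4_gut",
                      "P-gp", "BCRP", "AAG")

sweep_scenario <- function(parameter, value) {
  switch(parameter,
    sex = list(demographics = list(sex = value)),
    age = list(demographics = list(age = value)),
    weight = list(demographics = list(weight = value)),
    egfr_band = if (identical(value, "normal")) list() else
      list(condition = value),
    cirrhosis = if (identical(value, "none")) list() else
      list(condition = value),
    CYP3A4_hepatic = list(overrides = list(enzyme_abundance = c(CYP3A4_hepatic = value))),
    CYP2C8_hepatic = list(overrides = list(enzyme_abundance = c(CYP2C8_hepatic = value))),
    CYP3A4_gut = list(overrides = list(gut_cyp3a4 = value)),
    `P-gp` = list(overrides = list(transporter_abundance = c(`P-gp` = value))),
    BCRP = list(overrides = list(transporter_abundance = c(BCRP = value))),
    AAG = list(overrides = list(aag = value)),
    stop_config(sprintf("unknown sweep parameter '%s' (supported: %s)",
                        parameter, paste(sweep_parameters, collapse = ", ")))
  )
}

#' One-at-a-time sensitivity sweep
#'
#' Simulates matched virtual subjects (identical per-subject seeds across
#' levels, so only the target parameter differs) at each level of one input
#' parameter, and summarises geometric mean metrics per level, the
#' fold-change between the extreme levels, a Kruskal-Wallis test across all
#' levels and a pairwise Wilcoxon test between the extremes.
#'
#' @param parameter One of sex, age, weight, egfr_band, cirrhosis,
#'   CYP3A4_hepatic, CYP2C8_hepatic, CYP3A4_gut, P-gp, BCRP, AAG.
#' @param values Vector of parameter levels (low to high).
#' @param design A [trial_design()].
#' @param drug,defaults,regimen,options As in [run_virtual_trials()].
#' @param modified_renal Use the modified kidney-dysfunction populations
#'   (healthy CYP abundances) for `egfr_band` sweeps.
#' @return A `sweep_result`: list with `per_subject`, `summary`,
#'   `fold_change` (per metric, extreme high vs extreme low), and p-values.
#' @export
sensitivity_sweep <- function(parameter, values, design, drug, defaults,
                              regimen, options = pbpk_options(),
                              modified_renal = FALSE) {
  if (!parameter %in% sweep_parameters) sweep_scenario(parameter, values[1])
  per_level <- purrr::map(values, function(v) {
    sc <- sweep_scenario(parameter, v)
    if (modified_renal) sc$modified_renal <- TRUE
    run_virtual_trials(design, drug, defaults, regimen, scenario = sc,
                       options = options) |>
      dplyr::mutate(level = v, .before = 1)
  })
  per_subject <- dplyr::bind_rows(per_level)
  metric_cols <- c("auc_0_24_ss", "css_max", "css_min", "cl_over_f")
  summary <- per_subject |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   ~ exp(mean(log(.x)))), .groups = "drop")
  lo <- summary[1, ]; hi <- summary[nrow(summary), ]
  fold <- purrr::map_dbl(metric_cols, ~ hi[[.x]] / lo[[.x]])
  names(fold) <- metric_cols
  stats <- purrr::map(metric_cols, function(mc) {
    x <- split(per_subject[[mc]], per_subject$level)
    p_kw <- if (length(x) > 1) kruskal.test(x)$p.value else NA_real_
    p_wx <- if (length(x) > 1) {
      wilcox.test(x[[as.character(values[1])]] %||% x[[1]],
                  x[[length(x)]])$p.value
    } else NA_real_
    tibble::tibble(metric = mc, fold_change_extremes = fold[[mc]],
                   percent_change_extremes = 100 * (fold[[mc]] - 1),
                   p_kruskal_wallis = p_kw, p_wilcoxon_extremes = p_wx)
  })
  structure(list(parameter = parameter, values = values,
                 per_subject = per_subject, summary = summary,
                 stats = dplyr::bind_rows(stats)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> parameter '%s', %d level(s)\n", x$parameter,
              length(x$values)))
  print(x$stats)
  invisible(x)
}

#' Paired perpetrator drug-drug interaction study
#'
#' Every virtual subject is simulated twice with identical physiology
#' (with and without the perpetrator); the geometric mean ratio of each
#' steady-state metric with its 90% confidence interval (t quantiles on the
#' pooled log ratios) is reported, flagged as clinically significant when
#' the interval is not contained in the conventional 0.80-1.25 no-effect
#' range.
#'
#' @param drug,defaults Model configuration objects.
#' @param regimen Victim [dose_regimen()].
#' @param perp A `perpetrator_model`.
#' @param design A [trial_design()].
#' @param options See [pbpk_options()].
#' @param level Confidence level for the GMR interval.
#' @return A `ddi_result`: list with `summary` (metric, gmr, lo, hi, flag)
#'   and `ratios` (per-subject metric ratios).
#' @export
ddi_study <- function(drug, defaults, regimen, perp, design,
                      options = pbpk_options(), level = 0.90) {
  stopifnot(inherits(perp, "perpetrator_model"), inherits(design, "trial_design"))
  grid <- tidyr::expand_grid(trial = seq_len(design$n_trials),
                             subject = seq_len(design$n_subjects))
  metric_cols <- c("auc_0_24_ss", "css_max", "css_min", "cl_over_f")
  ratios <- purrr::pmap(grid, function(trial, subject) {
    ind <- build_subject(design, trial, subject, drug, defaults)
    base <- simulate_pbpk(ind, drug, regimen, defaults, options = options)
    with <- simulate_pbpk(ind, drug, regimen, defaults, perpetrator = perp,
                          options = options)
    r <- purrr::map_dbl(metric_cols,
                        ~ with$metrics[[.x]] / base$metrics[[.x]])
    tibble::tibble(trial = trial, subject = subject,
                   metric = metric_cols, ratio = r)
  }) |> dplyr::bind_rows()
  summary <- ratios |>
    dplyr::group_by(.data$metric) |>
    dplyr::reframe(dplyr::rename(geomean_ci(.data$ratio, level = level),
                                 gmr = "gm")) |>
    dplyr::mutate(clinically_significant = !(.data$lo >= 0.80 & .data$hi <= 1.25))
  structure(list(perpetrator = perp$name, summary = summary, ratios = ratios,
                 level = level),
            class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> perpetrator '%s' (%d%% CI)\n", x$perpetrator,
              round(100 * x$level)))
  print(x$summary)
  invisible(x)
}
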