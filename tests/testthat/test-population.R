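test_that("CKD-EPI equation matches an independent evaluation", {
  # independent oracle: direct transcription of the published 2009 equation
  ckd_oracle <- function(sex, age, scr_umol) {
    scr <- scr_umol / 88.4
    k <- if (sex == "female") 0.7 else 0.9
    a <- if (sex == "female") -0.329 else -0.411
    141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age *
      (if (sex == "female") 1.018 else 1)
  }
  expect_equal(egfr_ckd_epi("female", 50, 61.9), ckd_oracle("female", 50, 61.9))
  expect_equal(egfr_ckd_epi("female", 50, 61.9), 100.99, tolerance = 1e-4)
  # randomised agreement over the domain
  withr::with_seed(31, {
    for (i in 1:20) {
      sx <- sample(c("male", "female"), 1)
      ag <- runif(1, 20, 90); sc <- runif(1, 40, 400)
      expect_equal(egfr_ckd_epi(sx, ag, sc), ckd_oracle(sx, ag, sc))
    }
  })
  # monotone decreasing in creatinine; sex coefficient acts as published
  expect_lt(egfr_ckd_epi("female", 50, 123.8), egfr_ckd_epi("female", 50, 61.9))
  expect_false(isTRUE(all.equal(egfr_ckd_epi("male", 50, 80),
                                egfr_ckd_epi("female", 50, 80))))
  expect_error(egfr_ckd_epi("male", 50, -1), class = "imatpbpk_domain_error")
})

test_that("Du Bois BSA matches an independent evaluation on random inputs", {
  withr::with_seed(7, {
    w <- runif(20, 40, 130); h <- runif(20, 145, 200)
  })
  expect_equal(bsa_dubois(w, h), 0.007184 * w^0.425 * h^0.725)
})

test_that("individual sampling is deterministic and respects truncation bounds", {
  demo <- list(age = 60, sex = "female", ancestry = "European")
  a <- sample_individual(sysdef, drug, demo, seed = 77)
  b <- sample_individual(sysdef, drug, demo, seed = 77)
  expect_identical(a, b)
  expect_error(sample_individual(sysdef, drug,
                                 list(age = 60, sex = "male", ancestry = "Martian"),
                                 seed = 1),
               class = "imatpbpk_config_error")

  for (s in 1:400) {
    ind <- sample_individual(sysdef, drug,
                             list(age = 40, sex = "male", ancestry = "Chinese"),
                             seed = s)
    expect_true(ind$enzyme_abundance[["CYP3A4_hepatic"]] >= 0 &&
                  ind$enzyme_abundance[["CYP3A4_hepatic"]] <= 600)
    expect_true(ind$enzyme_abundance[["CYP2C8_hepatic"]] >= 0 &&
                  ind$enzyme_abundance[["CYP2C8_hepatic"]] <= 85)
    expect_true(ind$aag >= 0.36 && ind$aag <= 1.46)
    expect_true(all(unlist(ind[c("weight", "height", "liver_weight", "qh",
                                 "mppgl", "egfr")]) > 0))
  }
})

test_that("copula sampling preserves marginals and the rank correlation", {
  n <- 1e4
  draws <- vapply(seq_len(n), function(s) {
    ind <- sample_individual(sysdef, drug,
                             list(age = 50, sex = "male", ancestry = "European"),
                             seed = s)
    c(ind$enzyme_abundance[["CYP3A4_hepatic"]],
      ind$enzyme_abundance[["CYP2C8_hepatic"]])
  }, numeric(2))
  m34 <- mean(draws[1, ]); m28 <- mean(draws[2, ])
  expect_lt(abs(m34 - 93) / 93, 0.05)
  expect_lt(abs(m28 - 22.4) / 22.4, 0.05)
  expect_lt(abs(sd(draws[1, ]) / m34 - 0.4), 0.05)
  rs <- cor(draws[1, ], draws[2, ], method = "spearman")
  expect_lt(abs(rs - 0.68), 0.05)
})

test_that("aging monotonically lowers liver weight, hepatic flow and eGFR", {
  ages <- seq(20, 90, by = 10)
  inds <- lapply(ages, function(a) {
    sample_individual(sysdef, drug,
                      list(age = a, sex = "male", ancestry = "European",
                           weight = 80, height = 176, serum_creatinine = 80),
                      seed = 55)
  })
  lw <- vapply(inds, `[[`, 1, "liver_weight")
  qh <- vapply(inds, `[[`, 1, "qh")
  gfr <- vapply(inds, `[[`, 1, "egfr")
  expect_true(all(diff(lw) < 0))
  expect_true(all(diff(qh) < 0))
  expect_true(all(diff(gfr) < 0))
})

test_that("special-population multipliers act as configured", {
  ind <- ref_individual(seed = 9)
  for (cls in c("A", "B", "C")) {
    m <- sysdef$cirrhosis_multipliers[[cls]]
    ci <- apply_special_population(ind, drug, sysdef, cls)
    expect_equal(ci$liver_weight, ind$liver_weight * m$liver_weight)
    expect_equal(ci$qh, ind$qh * m$qh)
    expect_equal(unname(ci$enzyme_abundance[["CYP3A4_hepatic"]]),
                 unname(ind$enzyme_abundance[["CYP3A4_hepatic"]] * m$cyp))
    expect_equal(ci$aag, ind$aag * m$aag)
    expect_equal(ci$cirrhosis_class, cls)
  }
  # severity grading A < B < C on CYP abundance reduction
  ab <- vapply(c("A", "B", "C"), function(cls) {
    apply_special_population(ind, drug, sysdef, cls)$enzyme_abundance[["CYP2C8_hepatic"]]
  }, 1)
  expect_true(all(diff(ab) < 0))

  ri <- apply_special_population(ind, drug, sysdef, "lt30")
  expect_equal(ri$aag, ind$aag * 1.5)
  expect_equal(ri$egfr, 25)
  expect_lt(ri$enzyme_abundance[["CYP3A4_hepatic"]],
            ind$enzyme_abundance[["CYP3A4_hepatic"]])
  # modified mode restores healthy CYP abundances
  rm_ <- apply_special_population(ind, drug, sysdef, "lt30", modified_renal = TRUE)
  expect_equal(rm_$enzyme_abundance, ind$enzyme_abundance)

  # identity multipliers leave the individual unchanged
  sys1 <- sysdef
  sys1$cirrhosis_multipliers$A <- list(liver_weight = 1, qh = 1, cyp = 1, aag = 1)
  id <- apply_special_population(ind, drug, sys1, "A")
  expect_equal(id$liver_weight, ind$liver_weight)
  expect_equal(id$aag, ind$aag)
  expect_equal(id$fu_baseline, ind$fu_baseline)

  expect_error(apply_special_population(ri, drug, sysdef, "A"),
               "stacking", class = "imatpbpk_validation_error")
  expect_error(apply_special_population(ind, drug, sysdef, "D"),
               class = "imatpbpk_config_error")
})

test_that("virtual twins fix observed covariates and impute the rest", {
  rec <- list(id = "P1", age = 62, sex = "female", ancestry = "European",
              weight = 45, height = 160, serum_creatinine = 70,
              cirrhosis_class = "none", dose_mg_per_day = 400)
  tw <- make_virtual_twin(rec, sysdef, drug, seed = 5)
  expect_equal(tw$weight, 45)
  expect_equal(tw$age, 62)
  expect_equal(tw$egfr, egfr_ckd_epi("female", 62, 70))

  heavy <- make_virtual_twin(modifyList(rec, list(weight = 125)), sysdef, drug, 5)
  expect_lt(tw$liver_weight, heavy$liver_weight)
  expect_lt(tw$qh, heavy$qh)

  # identical record and seed give the identical twin
  expect_identical(tw, make_virtual_twin(rec, sysdef, drug, seed = 5))

  # missing weight/height imputed from ancestry/sex centres
  imp <- make_virtual_twin(rec[setdiff(names(rec), c("weight", "height"))],
                           sysdef, drug, seed = 5)
  expect_equal(imp$weight, sysdef$body_size$European$weight_female_kg[1])
  expect_equal(imp$height, sysdef$body_size$European$height_female_cm[1])

  # cirrhosis class composes with the special-population operation
  cb <- make_virtual_twin(modifyList(rec, list(cirrhosis_class = "B")),
                          sysdef, drug, seed = 5)
  expect_equal(cb$cirrhosis_class, "B")
  expect_equal(cb$liver_weight,
               tw$liver_weight * sysdef$cirrhosis_multipliers$B$liver_weight)

  expect_error(make_virtual_twin(rec[-2], sysdef, drug, 1),
               "age", class = "imatpbpk_validation_error")
})
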