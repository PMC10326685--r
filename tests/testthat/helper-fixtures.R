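# shared fixtures: load the shipped configuration once per test run
cfg <- load_model_config()
drug <- cfg$drug
sysdef <- cfg$system
perps <- cfg$perpetrators

std_regimen <- dose_regimen(400, 24, 14)

# a fixed healthy adult used wherever one deterministic subject suffices
ref_individual <- function(seed = 101, age = 50, sex = "male",
                           weight = NULL, overrides = list()) {
  demo <- list(age = age, sex = sex, ancestry = "European")
  if (!is.null(weight)) demo$weight <- weight
  sample_individual(sysdef, drug, demo, seed = seed, overrides = overrides)
}

# fast solver settings for tests that do not probe solver accuracy
fast_opts <- function(...) pbpk_options(rtol = 1e-7, atol = 1e-9, ...)

# modify one perpetrator field functionally
perp_with <- function(perp, ...) {
  mods <- list(...)
  for (nm in names(mods)) perp[[nm]] <- mods[[nm]]
  perp
}
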