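# shared fixtures: packaged defaults loaded once, and a generator of random
# valid parameter sets for property-style tests

base_params <- function() {
  if (is.null(.helper_env$params)) .helper_env$params <- load_parameters()
  .helper_env$params
}
.helper_env <- new.env()

# random but valid parameter set (direct field perturbation; registry and
# background mortality stay at defaults)
random_params <- function(seed) {
  set.seed(seed)
  p <- base_params()
  p$p_fall_year1 <- runif(1, 0.05, 0.9)
  p$p_fall_recurrent <- runif(1, 0.05, 0.95)
  p$rr_fall_exercise <- runif(1, 0.4, 1.2)
  p$p_fracture <- runif(1, 0.02, 0.5)
  p$rr_fracture_exercise <- runif(1, 0.2, min(1.5, p$rr_fall_exercise / p$p_fracture))
  p$p_fx_major <- runif(1, 0.1, 0.9); p$p_fx_minor <- 1 - p$p_fx_major
  p$p_nonfx_injury <- runif(1, 0.3, 0.95)
  p$rr_injury_exercise <- runif(1, 0.3, min(1.5, p$rr_fall_exercise / p$p_nonfx_injury))
  p$p_inj_major <- runif(1, 0.01, 0.5); p$p_inj_minor <- 1 - p$p_inj_major
  for (nm in c("p_death_fall_60_64", "p_death_fall_65_69", "p_death_fall_70_74"))
    p[[nm]] <- runif(1, 0, 0.3)
  for (nm in c("c_fx_major", "c_fx_minor", "c_inj_major", "c_inj_minor",
               "c_intervention"))
    p[[nm]] <- runif(1, 100, 30000)
  for (nm in c("u_baseline", "u_fx_major", "u_fx_minor", "u_inj_major",
               "u_inj_minor", "u_recurrent_control", "u_recurrent_exercise"))
    p[[nm]] <- runif(1, 0.2, 1)
  p$discount_annual <- runif(1, 0, 0.1)
  validate_parameters(p)
}

# parameter set with a field replaced (keeping splits consistent)
with_value <- function(p, name, value) {
  p[[name]] <- value
  if (name == "p_fx_major") p$p_fx_minor <- 1 - value
  if (name == "p_inj_major") p$p_inj_minor <- 1 - value
  p
}
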