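# Shared fixtures: small designs and parameter sets for fast tests.

# the bundled reference calibration (also the constructor defaults)
ref_params <- athero_params()
ref_factors <- athero_factors()

# a minimal two-scenario lesion+LDL design, cheap to simulate (<= 28 weeks)
toy_design <- function(cv = 0, n = 4) {
  synth_design(
    scenario_id = rep(c(1, 4), each = 4),
    observable = rep(c("LDL_blood", "LDL_blood",
                       "lesion_area_pct", "lesion_area_pct"), 2),
    time_weeks = rep(c(20, 28), 4),
    n = n, cv = cv
  )
}

# noise-free measurements from the reference truth on the toy design
toy_data <- function(cv = 0, n = 4, seed = 1) {
  generate_measurements(ref_params, ref_factors, toy_design(cv, n),
                        seed = seed)
}
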