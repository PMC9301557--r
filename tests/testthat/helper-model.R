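# Shared fixtures: the packaged base case and its calibrated detection
# hazards. Calibration is deterministic, so computing it once here keeps the
# suite fast without hiding anything.
base_params <- default_parameters()
base_cal <- calibrate_detection(base_params)
cal_params <- set_detection(base_params, base_cal$probabilities)

# a zero-mortality, unit-utility, undiscounted configuration used by the
# limit-identity tests
inert_params <- local({
  p <- base_params
  p$mortality$all_cause$value <- rep(0, nrow(p$mortality$all_cause))
  p$transitions$lc_death[] <- 0
  p$utilities[] <- 1
  p$economics$discount_rate <- 0
  set_detection(p, rep(0, 5))
})

table1_rates <- c(81.0559, 89.6626, 162.0833, 112.4574, 256.0943, 154.6871,
                  373.6808, 190.2521, 498.0681, 242.6310)
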