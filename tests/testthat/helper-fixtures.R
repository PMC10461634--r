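# shared fixtures: reference parameters and small, fast protocols

ref_params <- islet_params()
ref_basal <- basal_state()

# perifusion protocol with a glucose step, 15 islets, 1 mL at 1 mL/min
step_protocol <- function(g0 = 3, g1 = 16.7, t_step = 8, duration = 60,
                          n_islets = 15, ...) {
  islet_protocol(
    "perifusion", n_islets = n_islets, duration_min = duration,
    glucose_inlet = if (t_step > 0) inlet_steps(c(0, t_step), c(g0, g1))
                    else inlet_steps(0, g1),
    ...
  )
}

# basal-held perifusion protocol (everything flowing in at basal)
basal_protocol <- function(n_islets = 15, duration = 30, ...) {
  islet_protocol("perifusion", n_islets = n_islets, duration_min = duration, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel diff %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
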