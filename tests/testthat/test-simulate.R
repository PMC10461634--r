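test_that("a basal-held perifusion stays at its initial steady state", {
  sim <- simulate_islets(basal_protocol(duration = 30), ref_params)
  tr <- sim$trajectory
  for (col in c("X_gB", "X_I", "insulin_pg_per_ml", "glucagon_pg_per_ml",
                "insulin_flux_pg_per_min", "glucagon_flux_pg_per_min")) {
    expect_rel_equal(tr[[col]], tr[[col]][1], tol = 1e-6)
  }
})

test_that("glucose signal matches the closed-form exponential after a step", {
  proto <- step_protocol(g0 = 3, g1 = 16.7, t_step = 8)
  sim <- simulate_islets(proto, ref_params, grid_dt = 0.1,
                         rtol = 1e-12, atol = 1e-14)
  tr <- sim$trajectory
  b <- proto$basal
  u0 <- 3 / b$g_ba; u1 <- 16.7 / b$g_ba
  pred <- ifelse(tr$time_min < 8, u0,
                 u1 + (u0 - u1) * exp(-ref_params$k_gB * (tr$time_min - 8)))
  expect_lt(max(abs(tr$X_gB - pred) / pred), 1e-8)
  # first-order kinetics: after one time constant the gap closes by 1 - 1/e
  t1 <- 8 + 1 / ref_params$k_gB
  x_t1 <- stats::approx(tr$time_min, tr$X_gB, t1)$y
  # linear interpolation between 0.1-min grid points limits the precision
  expect_equal((x_t1 - u0) / (u1 - u0), 1 - exp(-1), tolerance = 1e-4)
})

test_that("steady state agrees with long-horizon integration and refuses batch", {
  proto <- basal_protocol()
  ss <- steady_state_islets(proto, ref_params)
  expect_lt(ss$residual, 1e-10)
  # start well away from the fixed point and integrate far out
  y0 <- isletsim:::adapted_state(3, ref_basal$I_ba, ref_basal$G_ba,
                                 ref_params, ref_basal)
  proto_long <- proto
  proto_long$duration_min <- 5000
  sim <- simulate_islets(proto_long, ref_params, init = y0, grid_dt = 25)
  last <- sim$trajectory[nrow(sim$trajectory), ]
  yv <- as.numeric(last[c("X_gB", "X_G", "X_gA", "X_I", "I1_pg", "I2_pg",
                          "G1_pg", "G2_pg", "glucose_mM", "insulin_pg_per_ml",
                          "glucagon_pg_per_ml")])
  expect_lt(max(abs(yv - ss$state) / pmax(abs(ss$state), 1e-9)), 1e-3)
  expect_error(steady_state_islets(islet_protocol("batch"), ref_params),
               "no finite steady state")
})

test_that("perifusion chamber satisfies the CSTR balance at steady state", {
  ss <- steady_state_islets(basal_protocol(), ref_params)
  # [H] = [H]_in + r_H / Q for both hormones
  expect_equal(ss$concentrations[["insulin_pg_per_ml"]],
               ref_basal$I_ba + ss$fluxes[["insulin_pg_per_min"]] / 1,
               tolerance = 1e-9)
  expect_equal(ss$concentrations[["glucagon_pg_per_ml"]],
               ref_basal$G_ba + ss$fluxes[["glucagon_pg_per_min"]] / 1,
               tolerance = 1e-9)
})

test_that("hormone mass is conserved in a secretion-free perifusion wash-in", {
  p0 <- islet_params(m_I = 0, m_G = 0)
  proto <- islet_protocol(
    "perifusion", volume_ml = 2, flow_ml_min = 0.5, n_islets = 15,
    duration_min = 40,
    insulin_inlet = inlet_steps(c(0, 10), c(50, 400)),
    glucagon_inlet = inlet_steps(0, 70)
  )
  sim <- simulate_islets(proto, p0, grid_dt = 0.05)
  tr <- sim$trajectory
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  inflow <- 0.5 * trap(tr$time_min,
                       isletsim:::inlet_value(proto$insulin_inlet, tr$time_min))
  outflow <- 0.5 * trap(tr$time_min, tr$insulin_pg_per_ml)
  accum <- 2 * (tr$insulin_pg_per_ml[nrow(tr)] - tr$insulin_pg_per_ml[1])
  expect_lt(abs(inflow - outflow - accum) / inflow, 1e-3)
})

test_that("batch mode clamps glucose and accumulates hormones", {
  proto <- islet_protocol("batch", n_islets = 10, duration_min = 30,
                          glucose_inlet = inlet_steps(c(0, 10), c(1, 15)))
  sim <- simulate_islets(proto, ref_params)
  tr <- sim$trajectory
  expect_equal(unique(tr$glucose_mM[tr$time_min < 10]), 1)
  expect_equal(unique(tr$glucose_mM[tr$time_min >= 10]), 15)
  # hormones only accumulate (no outflow)
  expect_true(all(diff(tr$insulin_pg_per_ml) >= -1e-9))
  expect_true(all(diff(tr$glucagon_pg_per_ml) >= -1e-9))
  # zero secretion => concentrations constant
  sim0 <- simulate_islets(proto, islet_params(m_I = 0, m_G = 0))
  expect_equal(diff(range(sim0$trajectory$insulin_pg_per_ml)), 0, tolerance = 1e-9)
})

test_that("chamber insulin rise is linear in islet number when decoupled", {
  p0 <- islet_params(m_G = 0)  # no glucagon feedback onto beta-cells
  rise <- sapply(c(15, 30), function(n) {
    proto <- basal_protocol(n_islets = n)
    ss <- steady_state_islets(proto, p0)
    ss$concentrations[["insulin_pg_per_ml"]] - ref_basal$I_ba
  })
  expect_equal(rise[2], 2 * rise[1], tolerance = 1e-6)
})

test_that("total secretion integrates fluxes over the requested window", {
  sim <- simulate_islets(basal_protocol(duration = 60), ref_params)
  tr <- sim$trajectory
  tot <- total_secretion(sim)
  # constant flux S over 60 min -> 60 S
  expect_equal(tot$total_pg[tot$hormone == "insulin"],
               60 * tr$insulin_flux_pg_per_min[1], tolerance = 1e-5)
  # zero-length window -> 0
  z <- total_secretion(sim, c(10, 10))
  expect_equal(z$total_pg, c(0, 0))
  # additivity over subwindows
  a <- total_secretion(sim, c(0, 22.35))$total_pg
  b <- total_secretion(sim, c(22.35, 60))$total_pg
  expect_equal(a + b, tot$total_pg, tolerance = 1e-9)
  expect_error(total_secretion(sim, c(-1, 10)), "inside the simulated span")
  expect_error(total_secretion(sim, c(50, 70)), "inside the simulated span")
})

test_that("hour-long batch glucagon at constant low glucose is bracketed by the
           endpoint secretion rates", {
  # insulin accumulation drifts R_G downward over the hour, so the integral
  # lies between 60 * R_G(end) and 60 * R_G(start)
  proto <- islet_protocol("batch", n_islets = 10, duration_min = 60,
                          glucose_inlet = inlet_steps(0, 1))
  sim <- simulate_islets(proto, ref_params)
  tr <- sim$trajectory
  tot <- total_secretion(sim)$total_pg[2]
  hi <- 60 * tr$glucagon_flux_pg_per_min[1]
  lo <- 60 * tr$glucagon_flux_pg_per_min[nrow(tr)]
  expect_true(tot <= hi && tot >= lo)
  expect_lt(lo, hi)  # the drift is real at 10 islets
})

test_that("halving the output grid changes hour totals by far less than 0.1%", {
  proto <- step_protocol(g0 = 1, g1 = 15, t_step = 0, duration = 60)
  y0 <- isletsim:::adapted_state(1, ref_basal$I_ba, ref_basal$G_ba,
                                 ref_params, ref_basal)
  t1 <- total_secretion(simulate_islets(proto, ref_params, init = y0,
                                        grid_dt = 0.1))$total_pg
  t2 <- total_secretion(simulate_islets(proto, ref_params, init = y0,
                                        grid_dt = 0.05))$total_pg
  expect_lt(max(abs(t1 - t2) / t1), 1e-4)
})

test_that("simulation rejects malformed initial states", {
  expect_error(simulate_islets(basal_protocol(), ref_params, init = c(a = 1)),
               "named state vector")
  expect_error(simulate_islets(basal_protocol(), ref_params, init = "nonsense"),
               "basal_steady_state")
})
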