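test_that("normalized SSE matches hand arithmetic and validates inputs", {
  expect_equal(normalized_sse(c(3, 3), c(2, 4)), 0.5^2 + 0.25^2)
  expect_equal(normalized_sse(c(2, 4), c(2, 4)), 0)
  expect_error(normalized_sse(c(1, 2), c(1, 0)), "positive")
  expect_error(normalized_sse(1, c(1, 2)), "equal length")
  # per-trajectory weights, keyed by condition, as in the human workflow
  w <- c(g6 = 1 / 15, g9 = 2 / 15, g12 = 3 / 15, g15 = 4 / 15, g30 = 5 / 15)
  cond <- c("g6", "g6", "g30")
  expect_equal(normalized_sse(c(2, 2, 2), c(1, 1, 1), weights = w,
                              condition = cond),
               (1 / 15) * 2 + 5 / 15)
  expect_error(normalized_sse(1, 1, weights = w, condition = "g99"),
               "no weight")
})

test_that("the reduced kinetics path agrees with the full simulator", {
  # feedback-off conditions: no glucagon secretion, (near-)zero glucagon
  # inlet so the beta-cell glucagon term vanishes
  p <- islet_params(m_G = 0)
  proto <- islet_protocol(
    "perifusion", n_islets = 15, duration_min = 60,
    glucose_inlet = inlet_steps(c(0, 8), c(3, 15)),
    glucagon_inlet = inlet_steps(0, 1e-9)
  )
  sim <- simulate_islets(proto, p)
  ts <- seq(0, 60, 2)
  full <- stats::approx(sim$trajectory$time_min,
                        sim$trajectory$insulin_flux_pg_per_min, ts)$y
  red <- isletsim:::kinetic_flux(p, ts, g0_mM = 3, g1_mM = 15, t_step_min = 8)
  expect_lt(max(abs(full - red) / full), 1e-4)
})

test_that("objective plumbing: zero-noise self-generated data give SSE ~ 0 at truth", {
  truth <- islet_params()
  conds <- tibble::tibble(condition_id = c("a", "b"), g0_mM = 3,
                          g1_mM = c(9, 15), t_step_min = 8, n_islets = 15)
  ts <- seq(0, 40, 2)
  data <- purrr::pmap_dfr(conds, function(condition_id, g0_mM, g1_mM,
                                          t_step_min, n_islets) {
    tibble::tibble(
      condition_id = condition_id, time_min = ts,
      insulin_pg_per_min = isletsim:::kinetic_flux(
        truth, ts, g0_mM = g0_mM, g1_mM = g1_mM, t_step_min = t_step_min,
        n_islets = n_islets)
    )
  })
  pr <- fit_problem(data, conds, free = "m_I", lower = c(m_I = 50),
                    upper = c(m_I = 200), n_starts = 1)
  fit <- fit_secretion(pr, truth)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$estimates[["m_I"]], truth$m_I, tolerance = 1e-4)
})

test_that("a single steady observation determines the secretion scale in closed form", {
  truth <- islet_params()
  b <- basal_state()
  # long after a step the flux equals R_I at the settled signal
  X_B_end <- 15 / b$g_ba + truth$X_B0
  frac <- hill(X_B_end, 1, truth$h_I, truth$n_I)
  obs <- 77  # pg/min, an arbitrary single measurement
  data <- tibble::tibble(condition_id = "a", time_min = 300,
                         insulin_pg_per_min = obs)
  conds <- tibble::tibble(condition_id = "a", g0_mM = 15, g1_mM = 15,
                          t_step_min = 0, n_islets = 15)
  pr <- fit_problem(data, conds, free = "m_I", lower = c(m_I = 1),
                    upper = c(m_I = 500), n_starts = 4, seed = 7)
  fit <- fit_secretion(pr, truth)
  expect_equal(fit$estimates[["m_I"]], obs / frac, tolerance = 1e-6)
})

test_that("multistart fits are ranked, bounded and seed-deterministic", {
  truth <- islet_params()
  d <- generate_perifusion_dataset(truth, glucose_mM = c(9, 15),
                                   duration_min = 40, sample_dt_min = 4,
                                   noise = noise_model(0.05, 0, seed = 3))
  conds <- attr(d, "conditions")
  pr <- function(seed) fit_problem(
    d, conds, free = c("m_I", "h_I"),
    lower = c(m_I = 50, h_I = 2), upper = c(m_I = 80, h_I = 6),
    n_starts = 4, seed = seed)
  f1 <- fit_secretion(pr(11), truth)
  f2 <- fit_secretion(pr(11), truth)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$starts$sse, f2$starts$sse)
  # best solution first; every start's SSE is >= the best
  expect_true(all(diff(f1$starts$sse) >= 0))
  # the m_I bound excludes the truth (103): the estimate must sit inside
  est <- f1$estimates[["m_I"]]
  expect_true(est >= 50 && est <= 80)
})

test_that("grouped fits free a kinetic parameter per condition", {
  truth <- islet_params()
  conds <- tibble::tibble(condition_id = c("lo", "hi"), g0_mM = 3,
                          g1_mM = c(9, 25), t_step_min = 8, n_islets = 15)
  ts <- seq(0, 40, 2)
  # generate with a different h_I1 per condition (per-glucose kinetics)
  h_true <- c(lo = 3.4, hi = 4.2)
  data <- purrr::pmap_dfr(conds, function(condition_id, g0_mM, g1_mM,
                                          t_step_min, n_islets) {
    p_c <- update_params(truth, list(h_I1 = h_true[[condition_id]]))
    tibble::tibble(
      condition_id = condition_id, time_min = ts,
      insulin_pg_per_min = isletsim:::kinetic_flux(
        p_c, ts, g0_mM = g0_mM, g1_mM = g1_mM, t_step_min = t_step_min,
        n_islets = n_islets))
  })
  pr <- fit_problem(data, conds, free = "h_I1",
                    lower = c(h_I1 = 2), upper = c(h_I1 = 6),
                    per_condition = "h_I1", n_starts = 4, seed = 5)
  expect_setequal(pr$theta_names, c("h_I1@lo", "h_I1@hi"))
  fit <- fit_secretion(pr, truth)
  expect_equal(fit$estimates[["h_I1@lo"]], 3.4, tolerance = 0.01)
  expect_equal(fit$estimates[["h_I1@hi"]], 4.2, tolerance = 0.01)
})

test_that("fit problems validate their inputs", {
  d <- tibble::tibble(condition_id = "a", time_min = 0, insulin_pg_per_min = 1)
  conds <- tibble::tibble(condition_id = "a", g0_mM = 3, g1_mM = 9,
                          t_step_min = 0, n_islets = 15)
  expect_error(fit_problem(d, conds, free = "zzz", lower = 1, upper = 2),
               "not model parameters")
  expect_error(fit_problem(d, conds, free = "m_I", lower = c(m_I = 5),
                           upper = c(m_I = 2)), "lower < upper")
  expect_error(fit_problem(d[0, ], conds, free = "m_I", lower = c(m_I = 1),
                           upper = c(m_I = 2)), "no usable")
  d2 <- dplyr::mutate(d, condition_id = "b")
  expect_error(fit_problem(d2, conds, free = "m_I", lower = c(m_I = 1),
                           upper = c(m_I = 2)), "lacks")
})

test_that("identity sensitivity rows equal the baseline readout", {
  scan <- sensitivity_scan(ref_params, parameters = c("m_I", "h_G1"),
                           factors = 1)
  expect_equal(scan$insulin_total_pg[1], scan$insulin_total_pg[2],
               tolerance = 1e-9)
  expect_equal(scan$glucagon_total_pg[1], scan$glucagon_total_pg[2],
               tolerance = 1e-9)
  expect_error(sensitivity_scan(ref_params, parameters = "bogus"),
               "not model parameters")
  expect_error(sensitivity_scan(ref_params, factors = c(0, 1)), "> 0")
})

test_that("out-of-domain perturbations are reported as missing, not errors", {
  # m_g * 1.75 > 1 leaves the valid domain
  scan <- sensitivity_scan(ref_params, parameters = "m_g",
                           factors = c(1, 1.75))
  expect_true(is.na(scan$insulin_total_pg[scan$factor == 1.75]))
  expect_false(is.na(scan$insulin_total_pg[scan$factor == 1]))
})
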