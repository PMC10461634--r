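test_that("hill obeys its closed form, limits and identities", {
  # half-maximal at x = h, for the secretion-law parameter sets
  expect_equal(hill(3.97, 103, 3.97, 4.84), 103 / 2)
  expect_equal(hill(1.06, 2.24, 1.06, 3.5), 2.24 / 2)
  expect_equal(hill(0, 2.24, 1.06, 3.5), 0)
  # frozen closed-form evaluation (checked at high precision)
  expect_equal(hill(5.40, 2.24, 1.06, 3.5), 2.2325187, tolerance = 1e-7)
  # saturation and monotonicity
  x <- sort(stats::runif(50, 0, 20))
  y <- hill(x, 103, 3.97, 4.84)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y <= 103))
  expect_lt(abs(hill(1e8, 103, 3.97, 4.84) - 103), 1e-6)
})

test_that("hill stays finite at large exponents and large inputs", {
  # n ~ 10 with big signals would overflow x^n in a naive evaluation
  expect_equal(hill(1e30, 0.336, 3.75, 9.97), 0.336)
  expect_true(is.finite(hill(1e6, 0.360, 0.968, 6.68)))
})

test_that("hill rejects invalid domains", {
  expect_error(hill(1, 1, -1, 2), "h > 0")
  expect_error(hill(1, 1, 1, 0), "n > 0")
  expect_error(hill(-0.1, 1, 1, 2), "non-negative")
})

test_that("secretion laws are bounded Hill responses of the net signals", {
  p <- ref_params
  expect_equal(insulin_secretion_rate(p$h_I, p), p$m_I / 2)
  expect_equal(glucagon_secretion_rate(p$h_G, p), p$m_G / 2)
  expect_equal(insulin_secretion_rate(0, p), 0)
  # frozen value at the whole-pancreas operating point
  expect_equal(insulin_secretion_rate(3.713007, p), 43.23142, tolerance = 1e-6)
  # linearity of the rate in the maximal secretion (mass-scale homogeneity)
  p2 <- update_params(p, list(m_I = p$m_I * 3))
  xs <- c(0.5, 2, 3.7, 8)
  expect_equal(insulin_secretion_rate(xs, p2), 3 * insulin_secretion_rate(xs, p))
})

test_that("beta-cell net signal combines glucose and glucagon as specified", {
  p <- ref_params
  expect_equal(beta_net_signal(0, 0, p), p$X_B0)
  expect_equal(beta_net_signal(1, 0, p), 1 + p$X_B0)  # glucagon term off at X_G = 0
  # frozen hand evaluation with the reference interaction parameters
  expect_equal(beta_net_signal(1, 59, p), 3.713007, tolerance = 1e-6)
  # monotone non-decreasing in both inputs
  g <- seq(0, 6, length.out = 25)
  expect_true(all(diff(beta_net_signal(g, 10, p)) >= 0))
  xg <- seq(0, 500, length.out = 25)
  expect_true(all(diff(beta_net_signal(1, xg, p)) >= 0))
})

test_that("alpha-cell net signal is insulin-dampened within its bounds", {
  p <- ref_params
  expect_equal(alpha_net_signal(1, 0, p), 1 + p$X_A0)
  expect_equal(alpha_net_signal(0, 0, p), p$X_A0)
  # insulin saturation removes at most m_g of the glucose signal
  expect_equal(alpha_net_signal(1, 1e12, p), 1 * (1 - p$m_g), tolerance = 1e-6)
  xi <- seq(0, 200, length.out = 40)
  xa <- alpha_net_signal(2, xi, p)
  expect_true(all(diff(xa) <= 0))
  expect_true(all(xa >= 2 * (1 - p$m_g) - 1e-12 & xa <= 2 + p$X_A0 + 1e-12))
})

test_that("signal transduction is first-order relaxation to normalized inputs", {
  p <- ref_params
  s <- list(X_gB = 1, X_G = 1, X_gA = 1, X_I = 1)
  u <- list(g_B = 1, G = 1, g_A = 1, I = 1)
  expect_equal(unname(signal_rhs(s, u, p)), rep(0, 4))  # fixed point
  d <- signal_rhs(list(X_gB = 1, X_G = 0, X_gA = 2, X_I = 0.5),
                  list(g_B = 3, G = 1, g_A = 3, I = 1), p)
  expect_equal(unname(d["X_gB"]), p$k_gB * 2)
  expect_equal(unname(d["X_gA"]), p$k_gA * 1)
  expect_equal(unname(d["X_I"]), p$k_I * 0.5)
})

test_that("pool kinetics conserve flux at fixed points and freeze at zero signal", {
  p <- ref_params
  X_B <- 3.713; X_A <- 4.2
  # frozen transfer coefficient at the operating point
  expect_equal(pool_transfer_rates(X_B, p, "insulin")$k1, 0.1597026,
               tolerance = 1e-6)
  ki <- pool_transfer_rates(X_B, p, "insulin")
  kg <- pool_transfer_rates(X_A, p, "glucagon")
  pools <- c(I1 = insulin_secretion_rate(X_B, p) / ki$k1,
             I2 = insulin_secretion_rate(X_B, p) / ki$k2,
             G1 = glucagon_secretion_rate(X_A, p) / kg$k1,
             G2 = glucagon_secretion_rate(X_A, p) / kg$k2)
  out <- pool_rhs(pools, X_B, X_A, p)
  expect_equal(unname(out$derivatives), rep(0, 4), tolerance = 1e-12)
  expect_equal(out$efflux[["insulin"]], insulin_secretion_rate(X_B, p))
  expect_equal(out$efflux[["glucagon"]], glucagon_secretion_rate(X_A, p))
  # zero signal: all transfer coefficients vanish, pools frozen
  frozen <- pool_rhs(c(I1 = 5, I2 = 5, G1 = 5, G2 = 5), 0, 0, p)
  expect_equal(unname(frozen$derivatives), rep(0, 4))
  expect_equal(unname(frozen$efflux), c(0, 0))
})

test_that("the hormone-mass subsystem is linear in the secretion scale", {
  p <- ref_params
  c_scale <- 2.5
  p2 <- update_params(p, list(m_I = p$m_I * c_scale))
  X_B <- 3.2
  ki <- pool_transfer_rates(X_B, p, "insulin")
  r1 <- insulin_secretion_rate(X_B, p)
  r2 <- insulin_secretion_rate(X_B, p2)
  expect_equal(r2, c_scale * r1)
  # steady pools and efflux scale identically (transfer rates unchanged)
  expect_equal(pool_transfer_rates(X_B, p2, "insulin")$k1, ki$k1)
  out <- pool_rhs(c(I1 = r2 / ki$k1, I2 = r2 / ki$k2, G1 = 0, G2 = 0),
                  X_B, 0, p2)
  expect_equal(out$efflux[["insulin"]], c_scale * r1)
})

test_that("parameter validation enforces the model's domain", {
  expect_error(islet_params(m_g = 1.2), "m_g")
  expect_error(islet_params(h_I = -1), "invalid parameter")
  expect_error(islet_params(k_gB = 0), "invalid parameter")
  expect_error(islet_params(nope = 1), "unknown parameter")
  expect_error(update_params(ref_params, list(n_I1 = 0)), "invalid parameter")
  expect_silent(islet_params(m_I = 0))  # cell elimination is legal
})

test_that("parameter sets round-trip through YAML and JSON", {
  p <- islet_params(m_I = 99.5, h_GB = 777)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_equal(unclass(read_params(f)), unclass(p))
  }
  expect_error(write_params(p, "x.txt"), "extension")
})

test_that("cell-type elimination zeroes the right maximal secretion", {
  expect_equal(eliminate_cell_type(ref_params, "alpha")$m_G, 0)
  expect_equal(eliminate_cell_type(ref_params, "beta")$m_I, 0)
  both <- eliminate_cell_type(eliminate_cell_type(ref_params, "alpha"), "beta")
  expect_equal(both$m_G + both$m_I, 0)
})
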