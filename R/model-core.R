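#' Steady-state insulin secretion rate
#'
#' Hill secretion law of the beta-cell: `R_I = m_I X_B^n_I / (X_B^n_I + h_I^n_I)`,
#' in pg/min per 15 islets. Bounded by `[0, m_I]` and non-decreasing in the
#' net signal.
#'
#' @param X_B Beta-cell net signal (dimensionless, >= 0); vectorized.
#' @param params An [islet_params()] object.
#' @return Secretion rate(s), pg/min per 15 islets.
#' @examples
#' p <- islet_params()
#' insulin_secretion_rate(p$h_I, p) # half-maximal
#' @export
insulin_secretion_rate <- function(X_B, params = islet_params()) {
  hill(X_B, params$m_I, params$h_I, params$n_I)
}

#' Steady-state glucagon secretion rate
#'
#' Hill secretion law of the alpha-cell: `R_G = m_G X_A^n_G / (X_A^n_G + h_G^n_G)`,
#' in pg/min per 15 islets.
#'
#' @param X_A Alpha-cell net signal (dimensionless, >= 0); vectorized.
#' @inheritParams insulin_secretion_rate
#' @return Secretion rate(s), pg/min per 15 islets.
#' @export
glucagon_secretion_rate <- function(X_A, params = islet_params()) {
  hill(X_A, params$m_G, params$h_G, params$n_G)
}

#' Net stimulatory signal of the beta-cell
#'
#' Combines the glucose signal `X_gB` with a saturating glucagon
#' amplification that is itself gated by glucose, plus a constant background:
#' `X_B = X_gB + hill(X_G; m_GB, h_GB, n_GB) * hill(X_gB; 1, h_gB, n_gB) + X_B0`.
#' Monotone non-decreasing in both inputs; `X_B >= X_B0` always.
#'
#' @param X_gB Basal-normalized glucose signal in beta-cells (>= 0).
#' @param X_G Basal-normalized glucagon signal in beta-cells (>= 0).
#' @inheritParams insulin_secretion_rate
#' @return The net signal `X_B` (dimensionless).
#' @export
beta_net_signal <- function(X_gB, X_G, params = islet_params()) {
  X_gB +
    hill(X_G, params$m_GB, params$h_GB, params$n_GB) *
    hill(X_gB, 1, params$h_gB, params$n_gB) +
    params$X_B0
}

#' Net stimulatory signal of the alpha-cell
#'
#' Glucose drives the alpha-cell while insulin removes a saturating share of
#' that drive:
#' `X_A = X_gA - (m_g X_gA + X_A0) * hill(X_I; 1, h_IA, n_IA) + X_A0`.
#' Because `m_g <= 1` the result stays within
#' `[X_gA (1 - m_g), X_gA + X_A0]`; as a guard against user parameter sets
#' that violate the invariant, negative values are clamped to 0 with a
#' warning.
#'
#' @param X_gA Basal-normalized glucose signal in alpha-cells (>= 0).
#' @param X_I Basal-normalized insulin signal in alpha-cells (>= 0).
#' @inheritParams insulin_secretion_rate
#' @return The net signal `X_A` (dimensionless, >= 0).
#' @export
alpha_net_signal <- function(X_gA, X_I, params = islet_params()) {
  out <- X_gA -
    (params$m_g * X_gA + params$X_A0) * hill(X_I, 1, params$h_IA, params$n_IA) +
    params$X_A0
  if (any(out < 0)) {
    warning("alpha-cell net signal went negative and was clamped at 0; ",
            "this cannot happen for m_g <= 1 with non-negative inputs",
            call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Signal-transduction right-hand side
#'
#' Each intracellular signal relaxes linearly toward its basal-normalized
#' extracellular concentration: `dX/dt = k (c/c_ba - X)` with rate constants
#' `k_gB`, `k_G`, `k_gA`, `k_I`. For piecewise-constant inputs the solution
#' is the closed-form exponential
#' `X(t) = input + (X(0) - input) exp(-k t)`.
#'
#' @param signals Named numeric vector or list with `X_gB`, `X_G`, `X_gA`, `X_I`.
#' @param inputs Named numeric vector or list of the normalized extracellular
#'   concentrations: `g_B` and `g_A` (glucose over basal, as seen by beta-
#'   and alpha-cells), `G` (glucagon over basal) and `I` (insulin over basal).
#' @inheritParams insulin_secretion_rate
#' @return Named numeric vector of time derivatives (1/min).
#' @export
signal_rhs <- function(signals, inputs, params = islet_params()) {
  s <- as.list(signals); u <- as.list(inputs)
  c(
    X_gB = params$k_gB * (u$g_B - s$X_gB),
    X_G  = params$k_G  * (u$G   - s$X_G),
    X_gA = params$k_gA * (u$g_A - s$X_gA),
    X_I  = params$k_I  * (u$I   - s$X_I)
  )
}

#' Pool transfer coefficients
#'
#' The docked-to-releasable and releasable-to-exterior transfer coefficients
#' are Hill functions of the driving net signal, saturating at high glucose.
#'
#' @param X Driving net signal (`X_B` for insulin pools, `X_A` for glucagon).
#' @inheritParams insulin_secretion_rate
#' @param hormone `"insulin"` or `"glucagon"`.
#' @return Named list with `k1` and `k2` (1/min).
#' @export
pool_transfer_rates <- function(X, params = islet_params(),
                                hormone = c("insulin", "glucagon")) {
  hormone <- match.arg(hormone)
  if (hormone == "insulin") {
    list(k1 = hill(X, params$m_I1, params$h_I1, params$n_I1),
         k2 = hill(X, params$m_I2, params$h_I2, params$n_I2))
  } else {
    list(k1 = hill(X, params$m_G1, params$h_G1, params$n_G1),
         k2 = hill(X, params$m_G2, params$h_G2, params$n_G2))
  }
}

#' Three-pool exocytosis right-hand side
#'
#' Hormone flows forward through reserve -> docked -> readily releasable
#' pools. The reserve pool is treated as unlimited, so the inflow to the
#' docked pool is the steady-state secretion law itself (`R_I(X_B)` or
#' `R_G(X_A)`); the secreted flux is the efflux of the readily releasable
#' pool, `k2(X) * pool2`. At any fixed point the efflux therefore equals the
#' steady-state secretion rate exactly.
#'
#' @param pools Named numeric vector or list with `I1`, `I2`, `G1`, `G2`
#'   (pg per 15 islets): docked and readily releasable insulin and glucagon.
#' @param X_B Beta-cell net signal.
#' @param X_A Alpha-cell net signal.
#' @inheritParams insulin_secretion_rate
#' @return List with `derivatives` (named, pg/min per 15 islets) and
#'   `efflux` (named vector: secreted `insulin` and `glucagon` fluxes,
#'   pg/min per 15 islets).
#' @export
pool_rhs <- function(pools, X_B, X_A, params = islet_params()) {
  q <- as.list(pools)
  ki <- pool_transfer_rates(X_B, params, "insulin")
  kg <- pool_transfer_rates(X_A, params, "glucagon")
  R_I <- insulin_secretion_rate(X_B, params)
  R_G <- glucagon_secretion_rate(X_A, params)
  eff <- c(insulin = ki$k2 * q$I2, glucagon = kg$k2 * q$G2)
  list(
    derivatives = c(
      I1 = R_I - ki$k1 * q$I1,
      I2 = ki$k1 * q$I1 - eff[["insulin"]],
      G1 = R_G - kg$k1 * q$G1,
      G2 = kg$k1 * q$G1 - eff[["glucagon"]]
    ),
    efflux = eff
  )
}

# pool masses at flux balance for given net signals; 0 where transfer is 0
pool_steady_state <- function(X_B, X_A, params) {
  ki <- pool_transfer_rates(X_B, params, "insulin")
  kg <- pool_transfer_rates(X_A, params, "glucagon")
  R_I <- insulin_secretion_rate(X_B, params)
  R_G <- glucagon_secretion_rate(X_A, params)
  div <- function(r, k) if (k > 0) r / k else 0
  c(I1 = div(R_I, ki$k1), I2 = div(R_I, ki$k2),
    G1 = div(R_G, kg$k1), G2 = div(R_G, kg$k2))
}
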