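#' Whole-pancreas steady-state secretion report
#'
#' Treats the pancreas as a perifused chamber: roughly 1 dL of tissue
#' containing about a million islets, washed by the organ's blood flow
#' (1.3 mL/min/100 g for a 90 g pancreas gives 1.17 mL/min) with basal
#' glucose, insulin and glucagon flowing in. Solves the coupled steady
#' state and reports secretion rates in mg/min and chamber concentrations
#' in mg/dL.
#'
#' With `diabetic = TRUE` the type 1 diabetes limit is simulated: maximal
#' insulin secretion `m_I` and the basal insulin concentration are both set
#' to 0, which pins the insulin signal `X_I` at 0 so the alpha-cell side
#' evolves as if beta-cells were absent. The resulting loss of insulin
#' inhibition produces hyperglucagonemia: glucagon concentration roughly
#' 30-fold the normal value.
#'
#' @param params An [islet_params()] object.
#' @param diabetic Simulate the type 1 diabetes scenario?
#' @param volume_ml Pancreas volume, mL (default 100 = 1 dL).
#' @param n_islets Number of islets (default 1e6).
#' @param flow_ml_min Perifusion rate, mL/min; default [perifusion_rate()]
#'   of 1.3 mL/min/100 g over 90 g = 1.17.
#' @param basal A [basal_state()]; under `diabetic = TRUE` its `I_ba` is
#'   forced to 0.
#' @return A tibble (one row) with columns `condition`,
#'   `insulin_secretion_mg_per_min`, `glucagon_secretion_mg_per_min`,
#'   `insulin_conc_mg_per_dl`, `glucagon_conc_mg_per_dl`, plus the net
#'   signals `X_B` and `X_A`.
#' @examples
#' whole_pancreas()
#' whole_pancreas(diabetic = TRUE)
#' @export
whole_pancreas <- function(params = islet_params(), diabetic = FALSE,
                           volume_ml = 100, n_islets = 1e6,
                           flow_ml_min = perifusion_rate(1.3, 90),
                           basal = basal_state()) {
  if (diabetic) {
    params <- update_params(params, list(m_I = 0))
    basal <- basal_state(g_ba = basal$g_ba, I_ba = 0, G_ba = basal$G_ba)
  }
  proto <- islet_protocol(
    "perifusion", volume_ml = volume_ml, flow_ml_min = flow_ml_min,
    n_islets = n_islets, basal = basal
  )
  ss <- steady_state_islets(proto, params)
  # pg/min -> mg/min; pg/mL -> mg/dL (1 pg/mL = 1e-7 mg/dL)
  tibble::tibble(
    condition = if (diabetic) "t1d" else "normal",
    insulin_secretion_mg_per_min = ss$fluxes[["insulin_pg_per_min"]] / 1e9,
    glucagon_secretion_mg_per_min = ss$fluxes[["glucagon_pg_per_min"]] / 1e9,
    insulin_conc_mg_per_dl = ss$concentrations[["insulin_pg_per_ml"]] / 1e7,
    glucagon_conc_mg_per_dl = ss$concentrations[["glucagon_pg_per_ml"]] / 1e7,
    X_B = ss$net_signals[["X_B"]],
    X_A = ss$net_signals[["X_A"]]
  )
}

#' Total 1-h secretion across islet counts and glucose levels
#'
#' Reruns the standard hour-long chamber experiment over a grid of islet
#' counts and glucose levels: islets adapted at 1 mM glucose receive a step
#' to the target level at t = 0, in a 1 mL chamber, either batch (static)
#' or perifusion at 1 mL/min. Totals are trapezoidal integrals of the
#' whole-chamber secretion fluxes over the experiment.
#'
#' In batch mode this reproduces the hallmark condition dependence of the
#' glucagon readout: a U-shaped glucagon-vs-glucose curve at 8-12 islets
#' that flattens and shrinks per islet as the count (and hence accumulated
#' insulin) grows, while perifusion washes insulin out and flattens the
#' curve entirely.
#'
#' @param params An [islet_params()] object.
#' @param glucose_mM Glucose levels stepped to at t = 0 (from 1 mM).
#' @param n_islets Islet counts.
#' @param mode `"batch"` or `"perifusion"`.
#' @param duration_min Experiment length (default 60 min).
#' @param volume_ml Chamber volume (default 1 mL).
#' @param flow_ml_min Perifusion rate when `mode = "perifusion"` (default 1).
#' @param basal A [basal_state()].
#' @param start_glucose_mM Adaptation glucose before the step (default 1 mM).
#' @param grid_dt Output grid for the underlying simulations, min.
#' @return A tibble of class `islet_sweep` with one row per
#'   (mode, islet count, glucose level): total and per-islet secreted
#'   insulin and glucagon in pg.
#' @examples
#' \donttest{
#' islet_number_sweep(glucose_mM = c(1, 7, 30), n_islets = 10, mode = "batch")
#' }
#' @export
islet_number_sweep <- function(params = islet_params(),
                               glucose_mM = c(1, 4, 7, 15, 30),
                               n_islets = c(10, 100, 500),
                               mode = c("batch", "perifusion"),
                               duration_min = 60, volume_ml = 1,
                               flow_ml_min = 1, basal = basal_state(),
                               start_glucose_mM = 1, grid_dt = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(n_islets > 0), all(glucose_mM >= 0))
  grid <- tidyr::expand_grid(n_islets = n_islets, glucose_mM = glucose_mM)
  res <- purrr::pmap_dfr(grid, function(n_islets, glucose_mM) {
    steps <- if (glucose_mM == start_glucose_mM) {
      inlet_steps(0, start_glucose_mM)
    } else {
      # adapted at start_glucose_mM; step occurs at t = 0, so the inlet is
      # the target level throughout while the initial state is the 1 mM one
      inlet_steps(0, glucose_mM)
    }
    proto <- islet_protocol(
      mode, volume_ml = volume_ml,
      flow_ml_min = if (mode == "batch") 0 else flow_ml_min,
      n_islets = n_islets, duration_min = duration_min,
      glucose_inlet = steps, basal = basal
    )
    pre_proto <- proto
    pre_proto$glucose_inlet <- inlet_steps(0, start_glucose_mM)
    y0 <- if (mode == "perifusion") {
      steady_state_islets(pre_proto, params)$state
    } else {
      adapted_state(start_glucose_mM, basal$I_ba, basal$G_ba, params, basal)
    }
    sim <- simulate_islets(proto, params, init = y0, grid_dt = grid_dt)
    tot <- total_secretion(sim)
    tibble::tibble(
      mode = mode, n_islets = n_islets, glucose_mM = glucose_mM,
      insulin_total_pg = tot$total_pg[tot$hormone == "insulin"],
      glucagon_total_pg = tot$total_pg[tot$hormone == "glucagon"]
    )
  })
  res$insulin_per_islet_pg <- res$insulin_total_pg / res$n_islets
  res$glucagon_per_islet_pg <- res$glucagon_total_pg / res$n_islets
  class(res) <- c("islet_sweep", class(res))
  res
}

#' Steady-state secretion under exogenous hormone infusion
#'
#' Perifusion runs in which the inlet concentration of one hormone is
#' raised above basal, reporting the steady-state secretion of both
#' hormones across a glucose sweep. Raising inlet insulin suppresses
#' glucagon secretion at every glucose level; raising inlet glucagon
#' potentiates insulin secretion, most visibly at low glucose where glucose
#' itself is not yet the dominant drive.
#'
#' @param params An [islet_params()] object.
#' @param hormone Which inlet hormone to raise: `"insulin"` or `"glucagon"`.
#' @param inlet_pg_per_ml Inlet concentration(s) of that hormone, pg/mL;
#'   each must be >= 0. The basal value reproduces the baseline run.
#' @param glucose_mM Glucose levels to sweep.
#' @param n_islets,volume_ml,flow_ml_min Chamber setup (defaults 15 islets,
#'   1 mL, 1 mL/min).
#' @param basal A [basal_state()].
#' @return A tibble: one row per (inlet level, glucose level) with
#'   steady-state whole-chamber secretion fluxes in pg/min.
#' @examples
#' \donttest{
#' exogenous_hormone_run(hormone = "insulin", inlet_pg_per_ml = c(50, 500),
#'                       glucose_mM = c(1, 7, 15))
#' }
#' @export
exogenous_hormone_run <- function(params = islet_params(),
                                  hormone = c("insulin", "glucagon"),
                                  inlet_pg_per_ml,
                                  glucose_mM = c(1, 4, 7, 15, 30),
                                  n_islets = 15, volume_ml = 1,
                                  flow_ml_min = 1, basal = basal_state()) {
  hormone <- match.arg(hormone)
  stopifnot(all(inlet_pg_per_ml >= 0))
  grid <- tidyr::expand_grid(inlet_pg_per_ml = inlet_pg_per_ml,
                             glucose_mM = glucose_mM)
  purrr::pmap_dfr(grid, function(inlet_pg_per_ml, glucose_mM) {
    proto <- islet_protocol(
      "perifusion", volume_ml = volume_ml, flow_ml_min = flow_ml_min,
      n_islets = n_islets,
      glucose_inlet = inlet_steps(0, glucose_mM),
      insulin_inlet = inlet_steps(
        0, if (hormone == "insulin") inlet_pg_per_ml else basal$I_ba),
      glucagon_inlet = inlet_steps(
        0, if (hormone == "glucagon") inlet_pg_per_ml else basal$G_ba),
      basal = basal
    )
    ss <- steady_state_islets(proto, params)
    tibble::tibble(
      exogenous_hormone = hormone,
      inlet_pg_per_ml = inlet_pg_per_ml,
      glucose_mM = glucose_mM,
      insulin_flux_pg_per_min = ss$fluxes[["insulin_pg_per_min"]],
      glucagon_flux_pg_per_min = ss$fluxes[["glucagon_pg_per_min"]]
    )
  })
}
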