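#' Piecewise-constant inlet time course
#'
#' @param time_min Step start times (min); strictly increasing, first at 0.
#' @param value Values held from each start time until the next.
#' @return A tibble with columns `time_min` and `value`.
#' @examples
#' inlet_steps(c(0, 8), c(3, 16.7)) # 3 mM until t = 8 min, then 16.7 mM
#' @export
inlet_steps <- function(time_min, value) {
  stopifnot(length(time_min) == length(value), length(time_min) >= 1)
  if (time_min[1] != 0) {
    stop("the first inlet step must start at time 0", call. = FALSE)
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("inlet step times must be strictly increasing", call. = FALSE)
  }
  if (any(value < 0)) stop("inlet values must be non-negative", call. = FALSE)
  tibble::tibble(time_min = as.numeric(time_min), value = as.numeric(value))
}

# value of a piecewise-constant inlet at time t (vectorized over t)
inlet_value <- function(steps, t) {
  steps$value[findInterval(t, steps$time_min)]
}

#' Experiment protocol for a well-mixed islet chamber
#'
#' Describes a batch (static incubation) or perifusion (continuous-flow)
#' experiment: chamber geometry, islet load, duration, and piecewise-constant
#' inlet time courses for glucose and the two hormones. In batch mode the
#' chamber has no flow (`flow_ml_min = 0`), glucose is clamped to the
#' protocol value (islet glucose consumption is not modeled) and secreted
#' hormones accumulate; in perifusion mode species obey the continuously
#' stirred tank reactor balance
#' `d[H]/dt = r_H/V + (Q/V)([H]_in - [H])`.
#'
#' @param mode `"perifusion"` or `"batch"`.
#' @param volume_ml Chamber volume V, mL (> 0).
#' @param flow_ml_min Flow rate Q, mL/min; must be 0 in batch mode and > 0 in
#'   perifusion mode.
#' @param n_islets Number of islets in the chamber (> 0). Secretion fluxes
#'   scale by `n_islets / 15` (the model's rates are per 15 islets).
#' @param duration_min Experiment duration, min.
#' @param glucose_inlet,insulin_inlet,glucagon_inlet [inlet_steps()] time
#'   courses (glucose in mM, hormones in pg/mL). Hormone inlets default to
#'   the basal concentrations; glucose defaults to basal held constant.
#' @param basal A [basal_state()] with the reference concentrations used to
#'   normalize signals.
#' @param glucose_ideal_step If `TRUE` (default) chamber glucose follows the
#'   inlet value instantly (ideal step, matching how step protocols are
#'   usually described); if `FALSE` (perifusion only) glucose washes in with
#'   CSTR dynamics.
#' @param species_scale Multiplier applied to all inlet glucose values, for
#'   cross-species protocol translation (see
#'   [rescale_protocol_species()]); default 1.
#'
#' @return A list of class `islet_protocol`.
#' @examples
#' islet_protocol("perifusion", n_islets = 15,
#'                glucose_inlet = inlet_steps(c(0, 8), c(3, 16.7)))
#' @export
islet_protocol <- function(mode = c("perifusion", "batch"),
                           volume_ml = 1,
                           flow_ml_min = NULL,
                           n_islets = 15,
                           duration_min = 60,
                           glucose_inlet = NULL,
                           insulin_inlet = NULL,
                           glucagon_inlet = NULL,
                           basal = basal_state(),
                           glucose_ideal_step = TRUE,
                           species_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(basal, "basal_state"))
  if (is.null(flow_ml_min)) flow_ml_min <- if (mode == "batch") 0 else 1
  if (volume_ml <= 0) stop("volume_ml must be > 0", call. = FALSE)
  if (n_islets <= 0) stop("n_islets must be > 0", call. = FALSE)
  if (duration_min <= 0) stop("duration_min must be > 0", call. = FALSE)
  if (mode == "batch" && flow_ml_min != 0) {
    stop("batch mode requires flow_ml_min = 0", call. = FALSE)
  }
  if (mode == "perifusion" && flow_ml_min <= 0) {
    stop("perifusion mode requires flow_ml_min > 0", call. = FALSE)
  }
  if (species_scale <= 0) stop("species_scale must be > 0", call. = FALSE)
  if (is.null(glucose_inlet)) glucose_inlet <- inlet_steps(0, basal$g_ba)
  if (is.null(insulin_inlet)) insulin_inlet <- inlet_steps(0, basal$I_ba)
  if (is.null(glucagon_inlet)) glucagon_inlet <- inlet_steps(0, basal$G_ba)
  for (s in list(glucose_inlet, insulin_inlet, glucagon_inlet)) {
    if (!all(c("time_min", "value") %in% names(s))) {
      stop("inlet time courses must be built with inlet_steps()", call. = FALSE)
    }
    if (any(s$time_min >= duration_min & s$time_min > 0)) {
      stop("inlet step times must fall within the experiment duration",
           call. = FALSE)
    }
  }
  glucose_inlet$value <- glucose_inlet$value * species_scale
  structure(
    list(mode = mode, volume_ml = volume_ml, flow_ml_min = flow_ml_min,
         n_islets = n_islets, duration_min = duration_min,
         glucose_inlet = glucose_inlet, insulin_inlet = insulin_inlet,
         glucagon_inlet = glucagon_inlet, basal = basal,
         glucose_ideal_step = glucose_ideal_step),
    class = "islet_protocol"
  )
}

#' @export
print.islet_protocol <- function(x, ...) {
  cat(sprintf("<islet_protocol> %s, V = %g mL, Q = %g mL/min, %g islets, %g min\n",
              x$mode, x$volume_ml, x$flow_ml_min, x$n_islets, x$duration_min))
  cat(" glucose inlet (mM): ",
      paste(sprintf("%g@%gmin", x$glucose_inlet$value, x$glucose_inlet$time_min),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rescale a protocol's glucose axis between species
#'
#' Glycemic set points differ between species (mouse basal glucose is higher
#' than human), so a glucose step protocol designed for one species is
#' translated to another by multiplying all inlet glucose values by the ratio
#' of set points. The mouse-to-human factor is 0.6 (e.g. a 3 -> 12 mM mouse
#' step becomes a 1.8 -> 7.2 mM human step).
#'
#' @param protocol An [islet_protocol()].
#' @param factor Positive multiplier applied to all inlet glucose values.
#' @return The rescaled protocol.
#' @examples
#' p <- islet_protocol(glucose_inlet = inlet_steps(c(0, 8), c(3, 12)))
#' rescale_protocol_species(p, 0.6)$glucose_inlet$value
#' @export
rescale_protocol_species <- function(protocol, factor = 0.6) {
  stopifnot(inherits(protocol, "islet_protocol"))
  if (!is.numeric(factor) || factor <= 0) {
    stop("rescaling factor must be > 0", call. = FALSE)
  }
  protocol$glucose_inlet$value <- protocol$glucose_inlet$value * factor
  protocol
}

#' Perifusion rate from tissue blood flow
#'
#' Organ-scale simulations treat the vascular bed as a perifusion flow:
#' `Q = flow per 100 g x mass / 100`. With the pancreatic blood flow of
#' 1.3 mL/min/100 g and a 90 g pancreas this gives 1.17 mL/min.
#'
#' @param flow_ml_min_per_100g Tissue blood flow, mL/min per 100 g.
#' @param mass_g Organ mass, g.
#' @return Flow rate, mL/min.
#' @examples
#' perifusion_rate(1.3, 90)
#' @export
perifusion_rate <- function(flow_ml_min_per_100g = 1.3, mass_g = 90) {
  stopifnot(flow_ml_min_per_100g > 0, mass_g > 0)
  flow_ml_min_per_100g * mass_g / 100
}
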