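#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into long format
#'
#' @param x An `islet_simulation`.
#' @param ... Unused.
#' @return A long tibble with `time_min`, `variable`, `value`.
#' @export
tidy.islet_simulation <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, -"time_min",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x An `islet_simulation`.
#' @param ... Unused.
#' @return A tibble with duration, grid size, insulin peak flux and time,
#'   final fluxes and totals.
#' @export
glance.islet_simulation <- function(x, ...) {
  tr <- x$trajectory
  pk <- which.max(tr$insulin_flux_pg_per_min)
  tot <- total_secretion(x)
  tibble::tibble(
    duration_min = max(tr$time_min),
    n_time = nrow(tr),
    insulin_peak_pg_per_min = tr$insulin_flux_pg_per_min[pk],
    insulin_peak_time_min = tr$time_min[pk],
    insulin_final_pg_per_min = tr$insulin_flux_pg_per_min[nrow(tr)],
    glucagon_final_pg_per_min = tr$glucagon_flux_pg_per_min[nrow(tr)],
    insulin_total_pg = tot$total_pg[tot$hormone == "insulin"],
    glucagon_total_pg = tot$total_pg[tot$hormone == "glucagon"]
  )
}

#' Tidy a steady-state report
#'
#' @param x An `islet_steady_state`.
#' @param ... Unused.
#' @return A tibble with `quantity`, `value`, `unit`.
#' @export
tidy.islet_steady_state <- function(x, ...) {
  tibble::tibble(
    quantity = c("insulin_secretion", "glucagon_secretion",
                 "insulin_concentration", "glucagon_concentration",
                 "glucose", "X_B", "X_A"),
    value = c(x$fluxes[["insulin_pg_per_min"]],
              x$fluxes[["glucagon_pg_per_min"]],
              x$concentrations[["insulin_pg_per_ml"]],
              x$concentrations[["glucagon_pg_per_ml"]],
              x$concentrations[["glucose_mM"]],
              x$net_signals[["X_B"]], x$net_signals[["X_A"]]),
    unit = c("pg/min", "pg/min", "pg/mL", "pg/mL", "mM", "1", "1")
  )
}

#' Tidy fitted parameters
#'
#' @param x An `islet_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `lower`, `upper`,
#'   `at_bound` (whether the estimate sits on a box bound).
#' @export
tidy.islet_fit <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    term = names(est), estimate = unname(est),
    lower = unname(x$problem$lower), upper = unname(x$problem$upper),
    at_bound = est <= x$problem$lower + 1e-12 | est >= x$problem$upper - 1e-12
  )
}

#' One-row fit summary
#'
#' @param x An `islet_fit`.
#' @param ... Unused.
#' @return A tibble with the best SSE, convergence code, start counts and
#'   observation count.
#' @export
glance.islet_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse,
    convergence = x$convergence,
    n_starts = nrow(x$starts),
    n_starts_ok = sum(is.finite(x$starts$sse)),
    n_obs = nrow(x$fitted),
    n_free = length(x$estimates)
  )
}

#' Plot secretion fluxes and chamber concentrations over time
#'
#' @param object An `islet_simulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.islet_simulation <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(
    tr[, c("time_min", "insulin_flux_pg_per_min", "glucagon_flux_pg_per_min",
           "insulin_pg_per_ml", "glucagon_pg_per_ml", "glucose_mM")],
    -"time_min", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("%s, %g islets", object$protocol$mode,
                                  object$protocol$n_islets)) +
    ggplot2::theme_minimal()
}

#' Plot a glucose/islet-count secretion sweep
#'
#' @param object An `islet_sweep` from [islet_number_sweep()].
#' @param hormone Which total to plot.
#' @param per_islet Plot per-islet rather than whole-chamber totals.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.islet_sweep <- function(object, hormone = c("glucagon", "insulin"),
                                 per_islet = FALSE, ...) {
  hormone <- match.arg(hormone)
  col <- paste0(hormone, if (per_islet) "_per_islet_pg" else "_total_pg")
  ggplot2::ggplot(object, ggplot2::aes(.data$glucose_mM, .data[[col]],
                                       color = factor(.data$n_islets))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "glucose (mM)",
                  y = sprintf("%s secreted (pg%s)", hormone,
                              if (per_islet) "/islet" else ""),
                  color = "islets",
                  title = unique(object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity scan
#'
#' @param object An `islet_sensitivity` from [sensitivity_scan()].
#' @param hormone Which total to show.
#' @param ... Unused.
#' @return A ggplot: totals (relative to factor 1) across factors, one line
#'   per parameter.
#' @export
autoplot.islet_sensitivity <- function(object,
                                       hormone = c("insulin", "glucagon"),
                                       ...) {
  hormone <- match.arg(hormone)
  col <- paste0(hormone, "_total_pg")
  ref <- dplyr::filter(object, .data$factor == 1)
  ref <- stats::setNames(ref[[col]], ref$parameter)
  dat <- dplyr::mutate(object,
                       relative = .data[[col]] / ref[.data$parameter])
  ggplot2::ggplot(dat, ggplot2::aes(.data$factor, .data$relative,
                                    group = .data$parameter)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "parameter multiplier",
                  y = sprintf("total %s (relative to factor 1)", hormone)) +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted secretion time courses
#'
#' @param object An `islet_fit`.
#' @param ... Unused.
#' @return A ggplot faceted by condition.
#' @export
autoplot.islet_fit <- function(object, ...) {
  d <- object$fitted
  obs_col <- object$problem$flux_col
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[obs_col]]), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "steelblue") +
    ggplot2::facet_wrap(~condition_id, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = paste0(obs_col, " (points: data)")) +
    ggplot2::theme_minimal()
}
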