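#' Measurement-noise model for synthetic secretion datasets
#'
#' Secretion assays scale with signal, so the default noise is
#' multiplicative Gaussian; an optional additive floor (pg/min) models
#' assay background. Noisy values are clamped at 0.
#'
#' @param multiplicative_sd Fractional standard deviation (>= 0).
#' @param additive_sd Additive standard deviation, pg/min (>= 0).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sd = 0.05, additive_sd = 0, seed = 1) {
  if (multiplicative_sd < 0 || additive_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = seed),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (noise$multiplicative_sd == 0 && noise$additive_sd == 0) return(x)
  pmax(0, x * (1 + stats::rnorm(length(x), 0, noise$multiplicative_sd)) +
         stats::rnorm(length(x), 0, noise$additive_sd))
}

#' Generate a synthetic perifusion secretion dataset
#'
#' Emulates the standard dynamic glucose-step experiment: islets adapted at
#' a low glucose level are stepped to each target concentration, and the
#' secreted insulin and glucagon fluxes are sampled on a regular grid. Each
#' target level is one condition. Data come from the full coupled simulator
#' at the supplied (ground-truth) parameters, then measurement noise is
#' applied; the truth is recorded alongside so parameter-recovery tests
#' never have to re-derive it from the noisy file.
#'
#' @param params Ground-truth [islet_params()].
#' @param glucose_mM Target glucose levels (one condition each).
#' @param g0_mM Adaptation glucose before the step (default 3 mM).
#' @param t_step_min Time of the step (default 8 min).
#' @param duration_min Experiment length (default 60 min).
#' @param sample_dt_min Sampling interval (default 2 min).
#' @param n_islets,volume_ml,flow_ml_min Chamber setup (defaults 15, 1 mL,
#'   1 mL/min).
#' @param noise A [noise_model()].
#' @param basal A [basal_state()].
#' @param path Optional CSV output path; the dialect is
#'   `condition_id, time_min, insulin_pg_per_min, glucagon_pg_per_min`.
#' @param truth_path Optional sidecar JSON path for the ground truth
#'   (defaults to `paste0(path, ".truth.json")` when `path` is given).
#' @return A tibble in the dataset dialect, with attributes `conditions`
#'   (the [fit_problem()] conditions table) and `truth_params`.
#' @examples
#' \donttest{
#' d <- generate_perifusion_dataset(glucose_mM = c(9, 15),
#'                                  noise = noise_model(0, 0))
#' head(d)
#' }
#' @export
generate_perifusion_dataset <- function(params = islet_params(),
                                        glucose_mM = c(6, 9, 12, 15, 30),
                                        g0_mM = 3, t_step_min = 8,
                                        duration_min = 60, sample_dt_min = 2,
                                        n_islets = 15, volume_ml = 1,
                                        flow_ml_min = 1,
                                        noise = noise_model(),
                                        basal = basal_state(),
                                        path = NULL, truth_path = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  sample_times <- seq(0, duration_min, by = sample_dt_min)
  sims <- purrr::map(glucose_mM, function(g1) {
    proto <- islet_protocol(
      "perifusion", volume_ml = volume_ml, flow_ml_min = flow_ml_min,
      n_islets = n_islets, duration_min = duration_min,
      glucose_inlet = if (t_step_min > 0) {
        inlet_steps(c(0, t_step_min), c(g0_mM, g1))
      } else {
        inlet_steps(0, g1)
      },
      basal = basal
    )
    sim <- simulate_islets(proto, params)
    tibble::tibble(
      condition_id = sprintf("g%0.3gmM", g1),
      time_min = sample_times,
      insulin_pg_per_min = stats::approx(sim$trajectory$time_min,
                                         sim$trajectory$insulin_flux_pg_per_min,
                                         xout = sample_times)$y,
      glucagon_pg_per_min = stats::approx(sim$trajectory$time_min,
                                          sim$trajectory$glucagon_flux_pg_per_min,
                                          xout = sample_times)$y
    )
  })
  data <- dplyr::bind_rows(sims)
  data <- with_seed(noise$seed, {
    data$insulin_pg_per_min <- apply_noise(data$insulin_pg_per_min, noise)
    data$glucagon_pg_per_min <- apply_noise(data$glucagon_pg_per_min, noise)
    data
  })
  conditions <- tibble::tibble(
    condition_id = sprintf("g%0.3gmM", glucose_mM),
    g0_mM = g0_mM, g1_mM = glucose_mM, t_step_min = t_step_min,
    n_islets = n_islets
  )
  attr(data, "conditions") <- conditions
  attr(data, "truth_params") <- params
  if (!is.null(path)) {
    readr::write_csv(data, path)
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.json")
    jsonlite::write_json(
      list(parameters = lapply(unclass(params), as.numeric),
           basal = unclass(basal),
           conditions = conditions,
           noise = unclass(noise)),
      truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  data
}

#' Generate a synthetic batch (static incubation) dataset
#'
#' Emulates the static glucose-response experiment: for each glucose level,
#' islets adapted at `start_glucose_mM` are incubated for `duration_min` in
#' a closed chamber and the total secreted insulin and glucagon are
#' recorded. With reference parameters and about 10 islets the glucagon
#' totals are non-monotone in glucose (the U-shape); large islet numbers
#' accumulate enough insulin to suppress the low- and high-glucose arms.
#'
#' @inheritParams generate_perifusion_dataset
#' @param glucose_mM Incubation glucose levels.
#' @param start_glucose_mM Adaptation glucose (default 1 mM).
#' @param n_islets Islets per chamber (default 10).
#' @return A tibble: `condition_id, glucose_mM, insulin_total_pg,
#'   glucagon_total_pg`, with the same truth attributes/sidecar behavior as
#'   the perifusion generator.
#' @export
generate_batch_dataset <- function(params = islet_params(),
                                   glucose_mM = c(1, 4, 7, 15, 30),
                                   n_islets = 10, duration_min = 60,
                                   start_glucose_mM = 1, volume_ml = 1,
                                   noise = noise_model(),
                                   basal = basal_state(),
                                   path = NULL, truth_path = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  sweep_tbl <- islet_number_sweep(
    params, glucose_mM = glucose_mM, n_islets = n_islets, mode = "batch",
    duration_min = duration_min, volume_ml = volume_ml, basal = basal,
    start_glucose_mM = start_glucose_mM
  )
  data <- tibble::tibble(
    condition_id = sprintf("g%0.3gmM", sweep_tbl$glucose_mM),
    glucose_mM = sweep_tbl$glucose_mM,
    insulin_total_pg = sweep_tbl$insulin_total_pg,
    glucagon_total_pg = sweep_tbl$glucagon_total_pg
  )
  data <- with_seed(noise$seed, {
    data$insulin_total_pg <- apply_noise(data$insulin_total_pg, noise)
    data$glucagon_total_pg <- apply_noise(data$glucagon_total_pg, noise)
    data
  })
  attr(data, "truth_params") <- params
  if (!is.null(path)) {
    readr::write_csv(data, path)
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.json")
    jsonlite::write_json(
      list(parameters = lapply(unclass(params), as.numeric),
           basal = unclass(basal),
           n_islets = n_islets, duration_min = duration_min,
           start_glucose_mM = start_glucose_mM, noise = unclass(noise)),
      truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  data
}

#' Read a secretion dataset CSV
#'
#' Validates and reads the package's dataset dialect
#' (`condition_id, time_min, insulin_pg_per_min, glucagon_pg_per_min`;
#' missing fluxes allowed).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_secretion_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition_id", "time_min")
  if (!all(need %in% names(data)) ||
      !any(c("insulin_pg_per_min", "glucagon_pg_per_min") %in% names(data))) {
    stop("dataset must have columns condition_id, time_min and at least one ",
         "of insulin_pg_per_min / glucagon_pg_per_min", call. = FALSE)
  }
  data
}
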