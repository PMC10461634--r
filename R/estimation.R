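# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Normalized, weighted sum of squared errors
#'
#' Residuals are divided by the data values before squaring, so hormone
#' trajectories whose absolute scales differ by orders of magnitude
#' contribute comparably:
#' `SSE = sum_traj w_traj * sum_t ((model - data) / data)^2`.
#'
#' @param model Model predictions.
#' @param data Observed values; must be positive wherever used (they
#'   normalize the residuals).
#' @param weights Per-trajectory weights (>= 0). Either a single number, a
#'   vector along `model`, or (with `condition`) a named vector keyed by
#'   condition id.
#' @param condition Optional vector of condition/trajectory ids along
#'   `model`, used to look up named `weights`.
#' @return The scalar objective.
#' @examples
#' normalized_sse(c(3, 3), c(2, 4)) # 0.5^2 + 0.25^2
#' @export
normalized_sse <- function(model, data, weights = 1, condition = NULL) {
  if (length(model) != length(data)) {
    stop("model and data must have equal length", call. = FALSE)
  }
  if (any(data <= 0)) {
    stop("data values must be positive: they normalize the residuals",
         call. = FALSE)
  }
  if (!is.null(condition) && !is.null(names(weights))) {
    missing_w <- setdiff(unique(as.character(condition)), names(weights))
    if (length(missing_w) > 0) {
      stop("no weight supplied for condition(s): ",
           paste(missing_w, collapse = ", "), call. = FALSE)
    }
    weights <- unname(weights[as.character(condition)])
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  sum(weights * ((model - data) / data)^2)
}

# Fast secretion-kinetics evaluator used inside the fit objective.
#
# Under the standard fitting assumptions the secreting cell type decouples
# from the chamber: for insulin fits glucagon feedback is off (X_G = 0, so
# X_B = X_gB + X_B0); for glucagon fits the insulin signal is held at a
# constant level (default 0, isolated alpha-cells). The glucose signal then
# has the closed-form piecewise exponential solution and only the two pool
# masses need integrating, done here with a fixed-step RK4 on precomputed
# Hill coefficient grids. Cross-checked against the full lsoda simulator in
# the test suite.
kinetic_flux <- function(params, times, g0_mM, g1_mM, t_step_min = 0,
                         n_islets = 15, basal = basal_state(),
                         hormone = c("insulin", "glucagon"),
                         X_I_const = 0, dt = 0.1) {
  hormone <- match.arg(hormone)
  p <- params
  t_end <- max(times)
  half <- seq(0, t_end, by = dt / 2)
  if (utils::tail(half, 1) < t_end) half <- c(half, t_end)
  u0 <- g0_mM / basal$g_ba
  u1 <- g1_mM / basal$g_ba
  k_sig <- if (hormone == "insulin") p$k_gB else p$k_gA
  Xg <- ifelse(half < t_step_min, u0,
               u1 + (u0 - u1) * exp(-k_sig * (half - t_step_min)))
  if (hormone == "insulin") {
    X <- Xg + p$X_B0
    R <- hill(X, p$m_I, p$h_I, p$n_I)
    k1 <- hill(X, p$m_I1, p$h_I1, p$n_I1)
    k2 <- hill(X, p$m_I2, p$h_I2, p$n_I2)
  } else {
    damp <- hill(X_I_const, 1, p$h_IA, p$n_IA)
    X <- Xg - (p$m_g * Xg + p$X_A0) * damp + p$X_A0
    R <- hill(X, p$m_G, p$h_G, p$n_G)
    k1 <- hill(X, p$m_G1, p$h_G1, p$n_G1)
    k2 <- hill(X, p$m_G2, p$h_G2, p$n_G2)
  }
  n_step <- (length(half) - 1) %/% 2
  # adapted initial pools at the pre-step signal
  q1 <- if (k1[1] > 0) R[1] / k1[1] else 0
  q2 <- if (k2[1] > 0) R[1] / k2[1] else 0
  flux_grid <- numeric(n_step + 1)
  flux_grid[1] <- k2[1] * q2
  for (i in seq_len(n_step)) {
    ia <- 2 * i - 1; im <- 2 * i; ib <- 2 * i + 1
    h <- half[ib] - half[ia]
    Ra <- R[ia]; Rm <- R[im]; Rb <- R[ib]
    k1a <- k1[ia]; k1m <- k1[im]; k1b <- k1[ib]
    k2a <- k2[ia]; k2m <- k2[im]; k2b <- k2[ib]
    a1 <- Ra - k1a * q1
    a2 <- k1a * q1 - k2a * q2
    u1 <- q1 + h / 2 * a1; u2 <- q2 + h / 2 * a2
    b1 <- Rm - k1m * u1
    b2 <- k1m * u1 - k2m * u2
    u1 <- q1 + h / 2 * b1; u2 <- q2 + h / 2 * b2
    c1 <- Rm - k1m * u1
    c2 <- k1m * u1 - k2m * u2
    u1 <- q1 + h * c1; u2 <- q2 + h * c2
    d1 <- Rb - k1b * u1
    d2 <- k1b * u1 - k2b * u2
    q1 <- q1 + h / 6 * (a1 + 2 * b1 + 2 * c1 + d1)
    q2 <- q2 + h / 6 * (a2 + 2 * b2 + 2 * c2 + d2)
    flux_grid[i + 1] <- k2b * q2
  }
  grid_t <- half[seq(1, length(half), by = 2)]
  stats::approx(grid_t, flux_grid * n_islets / 15, xout = times)$y
}

#' Bound presets for the insulin-to-alpha-cell half-point
#'
#' Two ranges are in common use when estimating `h_IA`, the half-point of
#' insulin's inhibition of the alpha-cell signal: a broad first-pass range
#' of `[1, 100]` and the narrower `[8, 100]` used when refitting human
#' batch data. Pass e.g. `h_IA_bound_presets$human["lower"]` /
#' `["upper"]` into [fit_problem()] bounds.
#'
#' @format A named list of two `c(lower, upper)` vectors, `broad` and
#'   `human`.
#' @export
h_IA_bound_presets <- list(
  broad = c(lower = 1, upper = 100),
  human = c(lower = 8, upper = 100)
)

#' Define a constrained secretion-fitting problem
#'
#' Couples a secretion time-series dataset to the experiment conditions it
#' came from, the parameters to free (with finite bounds), per-condition
#' weights and fitting assumptions.
#'
#' @param data Tibble with columns `condition_id`, `time_min` and the
#'   observed flux column (`insulin_pg_per_min` or `glucagon_pg_per_min`,
#'   chosen by `hormone`); the dialect written by
#'   [generate_perifusion_dataset()]. Rows with missing flux are dropped.
#' @param conditions Tibble describing each condition: columns
#'   `condition_id`, `g0_mM` (adaptation glucose), `g1_mM` (step target),
#'   `t_step_min`, `n_islets`.
#' @param free Character vector of parameter names to estimate.
#' @param lower,upper Named (or positionally matching `free`) finite bounds
#'   with `lower < upper`.
#' @param fixed Named list of parameter overrides held fixed during the fit.
#' @param weights Per-condition weights: named vector keyed by
#'   `condition_id`, or a single number (default 1). The published human
#'   workflow weights the 6-30 mM trajectories 1/15 ... 5/15.
#' @param hormone Which secretion flux is fitted.
#' @param assume Assumption flags. `"glucagon_feedback_off"` (default for
#'   insulin fits) sets the glucagon contribution to the beta-cell signal to
#'   zero (`X_G = 0`, `R_G` irrelevant), the standard simplification for
#'   perifusion insulin-kinetics fits where glucagon secretion is strongly
#'   insulin-inhibited.
#' @param n_starts Number of multistart initial points (Latin hypercube in
#'   the bounds, plus the supplied initial parameter values).
#' @param seed RNG seed for the multistart design.
#' @param basal A [basal_state()].
#' @param per_condition Optional character vector of kinetic parameter names
#'   that get an independent copy per condition ("grouped fit": shared
#'   steady-state parameters, per-glucose-level kinetics).
#' @return A list of class `fit_problem`.
#' @export
fit_problem <- function(data, conditions, free, lower, upper,
                        fixed = list(), weights = 1,
                        hormone = c("insulin", "glucagon"),
                        assume = "glucagon_feedback_off",
                        n_starts = 32, seed = 1,
                        basal = basal_state(), per_condition = character()) {
  hormone <- match.arg(hormone)
  flux_col <- paste0(hormone, "_pg_per_min")
  need <- c("condition_id", "time_min", flux_col)
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  need_c <- c("condition_id", "g0_mM", "g1_mM", "t_step_min", "n_islets")
  if (!all(need_c %in% names(conditions))) {
    stop("conditions must have columns ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  data <- data[!is.na(data[[flux_col]]), c("condition_id", "time_min", flux_col)]
  if (nrow(data) == 0) stop("no usable observations", call. = FALSE)
  missing_cond <- setdiff(unique(data$condition_id), conditions$condition_id)
  if (length(missing_cond) > 0) {
    stop("conditions table lacks: ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  ref <- islet_params()
  unknown <- setdiff(c(free, per_condition, names(fixed)), names(ref))
  if (length(unknown) > 0) {
    stop("not model parameters: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  theta_names <- c(
    setdiff(free, per_condition),
    unlist(lapply(intersect(free, per_condition), function(nm)
      paste0(nm, "@", conditions$condition_id)))
  )
  expand_bound <- function(b, what) {
    if (!is.null(names(b))) {
      out <- b[sub("@.*$", "", theta_names)]
    } else if (length(b) == length(free)) {
      out <- stats::setNames(b, free)[sub("@.*$", "", theta_names)]
    } else {
      stop(what, " must be named by free parameter or match length(free)",
           call. = FALSE)
    }
    stats::setNames(as.numeric(out), theta_names)
  }
  lo <- expand_bound(lower, "lower")
  hi <- expand_bound(upper, "upper")
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  structure(
    list(data = data, conditions = conditions, flux_col = flux_col,
         free = free, per_condition = intersect(free, per_condition),
         theta_names = theta_names, lower = lo, upper = hi, fixed = fixed,
         weights = weights, hormone = hormone, assume = assume,
         n_starts = n_starts, seed = seed, basal = basal),
    class = "fit_problem"
  )
}

# objective closure over a fit_problem; returns function(theta) -> sse and
# a predictor returning fitted values
fit_objective <- function(problem, params0) {
  d <- problem$data
  conds <- problem$conditions
  split_idx <- split(seq_len(nrow(d)), d$condition_id)
  obs <- d[[problem$flux_col]]
  predict_theta <- function(theta) {
    fitted <- numeric(nrow(d))
    base <- params0
    if (length(problem$fixed) > 0) base <- update_params(base, problem$fixed)
    shared <- theta[!grepl("@", names(theta))]
    if (length(shared) > 0) base <- update_params(base, as.list(shared))
    for (cid in names(split_idx)) {
      pc <- base
      local_names <- names(theta)[endsWith(names(theta), paste0("@", cid))]
      if (length(local_names) > 0) {
        vals <- stats::setNames(theta[local_names],
                                sub("@.*$", "", local_names))
        pc <- update_params(pc, as.list(vals))
      }
      idx <- split_idx[[cid]]
      cc <- conds[conds$condition_id == cid, ]
      fitted[idx] <- kinetic_flux(
        pc, d$time_min[idx], g0_mM = cc$g0_mM, g1_mM = cc$g1_mM,
        t_step_min = cc$t_step_min, n_islets = cc$n_islets,
        basal = problem$basal, hormone = problem$hormone
      )
    }
    fitted
  }
  list(
    value = function(theta) {
      fitted <- predict_theta(theta)
      if (any(!is.finite(fitted))) return(1e12)
      normalized_sse(fitted, obs, weights = problem$weights,
                     condition = d$condition_id)
    },
    predict = predict_theta
  )
}

#' Fit secretion parameters by constrained multistart least squares
#'
#' Minimizes the normalized, weighted SSE between the model's secretion
#' fluxes and observed time courses, subject to box bounds, from multiple
#' seeded Latin-hypercube starting points; any start may fail, and the best
#' converged solution is returned. The local solver is the bounded
#' quasi-Newton method of [stats::nlminb()].
#'
#' @param problem A [fit_problem()].
#' @param params0 Initial/backbone parameter set; fixed parameters and
#'   non-free values come from here (after applying `problem$fixed`).
#' @return An object of class `islet_fit`: best estimates, SSE, all ranked
#'   starts, per-observation residuals and fitted values.
#' @export
fit_secretion <- function(problem, params0 = islet_params()) {
  stopifnot(inherits(problem, "fit_problem"))
  obj <- fit_objective(problem, params0)
  k <- length(problem$theta_names)
  lo <- problem$lower; hi <- problem$upper

  base_vals <- unlist(params0[sub("@.*$", "", problem$theta_names)])
  start0 <- pmin(pmax(base_vals, lo), hi)
  n_extra <- max(problem$n_starts - 1, 0)
  starts <- matrix(start0, nrow = 1, dimnames = list(NULL, problem$theta_names))
  if (n_extra > 0) {
    u <- with_seed(problem$seed, lhs::randomLHS(n_extra, k))
    extra <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
    colnames(extra) <- problem$theta_names
    starts <- rbind(starts, extra)
  }

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    th0 <- stats::setNames(starts[i, ], problem$theta_names)
    res <- tryCatch(
      stats::nlminb(th0, obj$value, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    runs[[i]] <- if (is.null(res)) {
      tibble::tibble(start = i, sse = Inf, convergence = NA_integer_,
                     message = "error", par = list(th0))
    } else {
      tibble::tibble(start = i, sse = res$objective,
                     convergence = res$convergence,
                     message = res$message,
                     par = list(stats::setNames(res$par, problem$theta_names)))
    }
  }
  all_starts <- dplyr::arrange(dplyr::bind_rows(runs), .data$sse)
  if (!is.finite(all_starts$sse[1])) {
    stop("all optimization starts failed; check bounds and data scaling",
         call. = FALSE)
  }
  best <- all_starts$par[[1]]
  fitted <- obj$predict(best)
  obs <- problem$data[[problem$flux_col]]
  structure(
    list(estimates = best, sse = all_starts$sse[1],
         convergence = all_starts$convergence[1],
         starts = all_starts,
         fitted = dplyr::mutate(problem$data, fitted = fitted,
                                residual = (fitted - obs) / obs),
         problem = problem, params0 = params0),
    class = "islet_fit"
  )
}

#' @export
print.islet_fit <- function(x, ...) {
  cat(sprintf("<islet_fit> %s kinetics, %d free parameter(s), %d start(s)\n",
              x$problem$hormone, length(x$estimates), nrow(x$starts)))
  cat("  best normalized SSE:", format(x$sse, digits = 6), "\n")
  print(tibble::tibble(term = names(x$estimates), estimate = x$estimates,
                       lower = x$problem$lower, upper = x$problem$upper))
  invisible(x)
}
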