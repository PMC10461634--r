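#' Model parameters for the paracrine islet secretion model
#'
#' Returns the full 32-parameter set of the coupled alpha/beta-cell secretion
#' model. Defaults are the published reference values for human islets.
#' Parameters fall into three groups:
#'
#' * **Kinetic** (`k_gB`, `k_G`, `k_gA`, `k_I`, 1/min): first-order signal
#'   transduction rate constants for glucose in beta-cells, glucagon in
#'   beta-cells, glucose in alpha-cells and insulin in alpha-cells; plus the
#'   Hill parameters of the pool transfer coefficients
#'   (`m_I1`, `h_I1`, `n_I1`, `m_I2`, `h_I2`, `n_I2` for insulin and the
#'   `*_G1`, `*_G2` mirrors for glucagon; maxima in 1/min).
#' * **Interaction** (`m_GB`, `h_GB`, `n_GB`, `h_gB`, `n_gB`, `h_IA`, `n_IA`,
#'   `m_g`, dimensionless): how glucagon amplifies the beta-cell net signal
#'   and insulin dampens the alpha-cell net signal. `m_g` bounds the fraction
#'   of the alpha-cell glucose signal that insulin can remove and cannot
#'   exceed 1.
#' * **Secretion** (`m_I`, `m_G` in pg/min per 15 islets; `h_I`, `n_I`,
#'   `h_G`, `n_G`, `X_B0`, `X_A0` dimensionless): steady-state Hill secretion
#'   laws and the background signal offsets.
#'
#' @param ... Named overrides of any default, e.g. `islet_params(m_I = 0)`.
#'
#' @return A named list of class `islet_params`.
#' @examples
#' p <- islet_params()
#' p$m_I
#' islet_params(m_G = 0)$m_G
#' @export
islet_params <- function(...) {
  p <- list(
    # kinetic: signal transduction (1/min)
    k_gB = 0.554, k_G = 0.554, k_gA = 0.022, k_I = 2.77,
    # kinetic: pool transfer coefficients (maxima 1/min)
    m_I1 = 0.336, h_I1 = 3.75, n_I1 = 9.97,
    m_I2 = 0.360, h_I2 = 0.968, n_I2 = 6.68,
    m_G1 = 0.336, h_G1 = 3.75, n_G1 = 9.97,
    m_G2 = 0.360, h_G2 = 0.968, n_G2 = 6.68,
    # interaction
    m_GB = 1.11, h_GB = 502, n_GB = 0.63,
    h_gB = 1.07, n_gB = 0.35,
    h_IA = 10.0, n_IA = 1.17, m_g = 0.60,
    # secretion
    m_I = 103, h_I = 3.97, n_I = 4.84,
    m_G = 2.24, h_G = 1.06, n_G = 3.5,
    X_B0 = 2.60, X_A0 = 4.40
  )
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    p <- update_params(structure(p, class = "islet_params"), over)
    return(p)
  }
  validate_params(structure(p, class = "islet_params"))
}

#' Update a parameter set with named overrides
#'
#' @param params An [islet_params()] object.
#' @param overrides Named list or vector of replacement values; names must be
#'   existing parameter names.
#' @return The updated, re-validated `islet_params` object.
#' @export
update_params <- function(params, overrides) {
  stopifnot(inherits(params, "islet_params"))
  overrides <- as.list(overrides)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(overrides)] <- lapply(overrides, as.numeric)
  validate_params(params)
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  nm <- names(p)
  bad <- function(idx, cond) nm[idx][cond]
  h_idx <- grepl("^h_", nm)
  n_idx <- grepl("^n_", nm)
  k_idx <- grepl("^k_", nm)
  m_idx <- grepl("^m_", nm) & nm != "m_g"
  probs <- c(
    bad(h_idx, unlist(p[h_idx]) <= 0),
    bad(n_idx, unlist(p[n_idx]) <= 0),
    bad(k_idx, unlist(p[k_idx]) <= 0),
    bad(m_idx, unlist(p[m_idx]) < 0)
  )
  if (length(probs) > 0) {
    stop("invalid parameter value(s): half-points h_* and exponents n_* must be ",
         "> 0, rate constants k_* > 0, maxima m_* >= 0 (violated: ",
         paste(probs, collapse = ", "), ")", call. = FALSE)
  }
  if (p$m_g < 0 || p$m_g > 1) {
    stop("m_g must lie in [0, 1]: it is the fraction of the alpha-cell glucose ",
         "signal that insulin can remove", call. = FALSE)
  }
  if (p$X_B0 < 0 || p$X_A0 < 0) {
    stop("background signals X_B0 and X_A0 must be non-negative", call. = FALSE)
  }
  p
}

#' @export
print.islet_params <- function(x, ...) {
  cat("<islet_params> coupled alpha/beta-cell secretion model (32 parameters)\n")
  print(tibble::tibble(parameter = names(x), value = unlist(x)), n = 32)
  invisible(x)
}

#' Zero out the secretion of one islet cell type
#'
#' Emulates a pure population of the remaining cell type by setting the
#' maximal secretion of the eliminated type to zero (`m_G = 0` removes
#' alpha-cells, `m_I = 0` removes beta-cells). Inflowing hormone
#' concentrations are left untouched; to silence the insulin signal entirely
#' (as in the type 1 diabetes scenario) also set the basal insulin
#' concentration to zero, which pins `X_I` at 0.
#'
#' @param params An [islet_params()] object.
#' @param which `"alpha"` or `"beta"`.
#' @return The modified parameter set.
#' @examples
#' eliminate_cell_type(islet_params(), "alpha")$m_G
#' @export
eliminate_cell_type <- function(params, which = c("alpha", "beta")) {
  which <- match.arg(which)
  if (which == "alpha") update_params(params, list(m_G = 0))
  else update_params(params, list(m_I = 0))
}

#' Read or write a parameter set as YAML or JSON
#'
#' The flat key-value serialization uses the model's parameter symbols
#' verbatim (`k_gB`, `m_I1`, `h_GB`, `X_B0`, ...), so files are portable
#' between implementations. Format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param params An [islet_params()] object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   an `islet_params` object (missing keys fall back to defaults).
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "islet_params"))
  vals <- lapply(unclass(params), as.numeric)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported parameter file extension (use .yaml, .yml or .json): ",
         path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension (use .yaml, .yml or .json): ",
         path, call. = FALSE)
  }
  do.call(islet_params, as.list(vals))
}

#' Basal reference concentrations
#'
#' The dimensionless signals that drive secretion are concentrations divided
#' by these basal references, so that glucose (mM) and hormones (pg/mL),
#' which differ by orders of magnitude in absolute value, enter the model on
#' comparable scales.
#'
#' Defaults are documented package choices, not published constants: basal
#' glucose 5 mM for human (the mouse glycemic set point is 5/0.6 = 8.33 mM,
#' consistent with the 0.6 cross-species glucose rescaling factor), basal
#' glucagon 70 pg/mL (about 20 pM, within the commonly cited 5-25 pM range)
#' and basal insulin 50 pg/mL (about 9 pM). The basal insulin level sets the
#' scale at which accumulated insulin suppresses glucagon; tens of pg/mL is
#' the level at which the U-shaped glucagon response of 8-12 islets in a
#' 1 mL batch chamber emerges, and whole-pancreas readouts are insensitive
#' to it because the insulin-inhibition Hill term is nearly saturated there
#' (see the methods vignette).
#'
#' @param g_ba Basal glucose, mM (> 0).
#' @param I_ba Basal insulin, pg/mL; 0 is permitted and pins the insulin
#'   signal `X_I` at 0 (type 1 diabetes scenario).
#' @param G_ba Basal glucagon, pg/mL (> 0).
#' @param species `"human"` (default) or `"mouse"`; selects the basal glucose
#'   set point unless `g_ba` is given explicitly.
#' @return A named list of class `basal_state`.
#' @examples
#' basal_state()
#' basal_state(species = "mouse")$g_ba
#' @export
basal_state <- function(g_ba = NULL, I_ba = 50, G_ba = 70,
                        species = c("human", "mouse")) {
  species <- match.arg(species)
  if (is.null(g_ba)) g_ba <- if (species == "human") 5 else 5 / 0.6
  if (!is.numeric(g_ba) || g_ba <= 0) stop("g_ba must be > 0", call. = FALSE)
  if (!is.numeric(G_ba) || G_ba <= 0) stop("G_ba must be > 0", call. = FALSE)
  if (!is.numeric(I_ba) || I_ba < 0) {
    stop("I_ba must be >= 0 (0 only for the insulin-free scenario)", call. = FALSE)
  }
  structure(list(g_ba = as.numeric(g_ba), I_ba = as.numeric(I_ba),
                 G_ba = as.numeric(G_ba)),
            class = "basal_state")
}

#' @export
print.basal_state <- function(x, ...) {
  cat(sprintf("<basal_state> glucose %.3g mM, insulin %.3g pg/mL, glucagon %.3g pg/mL\n",
              x$g_ba, x$I_ba, x$G_ba))
  invisible(x)
}
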