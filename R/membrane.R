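#' Physical constants for membrane hydrodynamic models
#'
#' Bundles the constants entering the Saffman-Delbruck and
#' Stokes-Einstein-like diffusion laws. Defaults reflect room-temperature
#' imaging of cells in buffer: `T = 294` K, solvent (water) viscosity
#' `mu_s = 9.6e-4` Pa s, membrane thickness `h = 3.8e-9` m. The
#' characteristic length `lambda` enters only the Stokes-Einstein-like
#' model and defaults to the membrane thickness.
#'
#' @param temperature absolute temperature (K).
#' @param mu_s solvent viscosity (Pa s).
#' @param h membrane thickness (m).
#' @param k_B Boltzmann constant (J/K).
#' @param gamma_euler Euler-Mascheroni constant.
#' @param lambda characteristic length (m) of the Stokes-Einstein-like
#'   model.
#' @return a `membrane_constants` list.
#' @export
membrane_constants <- function(temperature = 294, mu_s = 9.6e-4, h = 3.8e-9,
                               k_B = 1.38e-23, gamma_euler = 0.5772156649,
                               lambda = h) {
  vals <- c(temperature, mu_s, h, k_B, gamma_euler, lambda)
  if (any(!is.finite(vals)) || any(vals <= 0)) stopf("all constants must be positive")
  structure(
    list(temperature = temperature, mu_s = mu_s, h = h, k_B = k_B,
         gamma_euler = gamma_euler, lambda = lambda),
    class = "membrane_constants"
  )
}

#' Saffman-Delbruck diffusion coefficient
#'
#' `D = k_B T / (4 pi mu_m h) * (ln(mu_m h / (mu_s R)) - gamma)`, valid in
#' the regime `mu_m h / (mu_s R) > exp(gamma)` (large membrane-to-solvent
#' viscosity contrast); outside it the model is not defined and an error
#' names the offending reduced ratio.
#'
#' @param R protein radius in metres.
#' @param mu_m membrane viscosity (Pa s).
#' @param const a [membrane_constants()] bundle.
#' @return diffusion coefficient in um^2/s.
#' @export
d_saffman_delbruck <- function(R, mu_m, const = membrane_constants()) {
  if (any(R <= 0) || any(mu_m <= 0)) stopf("R and mu_m must be positive")
  ratio <- mu_m * const$h / (const$mu_s * R)
  bad <- ratio <= exp(const$gamma_euler)
  if (any(bad))
    stopf("Saffman-Delbruck validity violated: mu_m h/(mu_s R) = %.3g <= e^gamma",
          min(ratio))
  D_si <- const$k_B * const$temperature / (4 * pi * mu_m * const$h) *
    (log(ratio) - const$gamma_euler)
  D_si * 1e12   # m^2/s -> um^2/s
}

#' Stokes-Einstein-like diffusion coefficient
#'
#' `D = k_B T lambda / (4 pi mu_m h R)`: diffusion inversely proportional
#' to both the membrane viscosity and the protein radius, with the
#' characteristic length `lambda` fixed in the constants bundle (not
#' fitted).
#'
#' @inheritParams d_saffman_delbruck
#' @return diffusion coefficient in um^2/s.
#' @export
d_stokes_einstein_like <- function(R, mu_m, const = membrane_constants()) {
  if (any(R <= 0) || any(mu_m <= 0)) stopf("R and mu_m must be positive")
  D_si <- const$k_B * const$temperature * const$lambda /
    (4 * pi * mu_m * const$h * R)
  D_si * 1e12
}

#' Least-squares membrane viscosity fit
#'
#' Estimates the membrane viscosity `mu_m` by minimizing
#' `sum((D_obs - D_model(R; mu_m))^2)` over a log-scale bracket
#' `mu_m in [1e-2, 1e4]` Pa s, for either hydrodynamic model. Radii that
#' violate the Saffman-Delbruck validity condition at a candidate `mu_m`
#' make that candidate infeasible (infinite objective).
#'
#' @param R protein radii in metres (one per observation).
#' @param D observed diffusion coefficients (um^2/s).
#' @param model `"SD"` (Saffman-Delbruck) or `"SE"` (Stokes-Einstein-like).
#' @param const a [membrane_constants()] bundle.
#' @param bracket log10 search bracket for `mu_m` (Pa s).
#' @return a `viscosity_fit` list: `mu_m` (Pa s), `model`, `residual`
#'   (sum of squares at the optimum), `n`.
#' @export
fit_viscosity <- function(R, D, model = c("SD", "SE"),
                          const = membrane_constants(),
                          bracket = c(-2, 4)) {
  model <- match.arg(model)
  stopifnot(length(R) == length(D), length(R) >= 1)
  if (length(unique(R)) < 2)
    warnf("fit_viscosity: fewer than 2 distinct radii; fit is an exact interpolation")
  fn <- if (model == "SD") d_saffman_delbruck else d_stokes_einstein_like
  obj <- function(log10mu) {
    mu <- 10^log10mu
    pred <- tryCatch(fn(R, mu, const), error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    sum((D - pred)^2)
  }
  opt <- stats::optimize(obj, interval = bracket, tol = 1e-10)
  if (!is.finite(opt$objective))
    stopf("no feasible mu_m in the search bracket for model %s", model)
  edge <- min(abs(opt$minimum - bracket))
  if (edge < 1e-6)
    warnf("fit_viscosity: optimum at the edge of the search bracket")
  structure(
    list(mu_m = 10^opt$minimum, model = model, residual = opt$objective,
         n = length(R)),
    class = "viscosity_fit"
  )
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf("%s viscosity fit: mu_m = %.4g Pa s (SSE %.3g, n = %d)\n",
              x$model, x$mu_m, x$residual, x$n))
  invisible(x)
}

#' Read a protein size table
#'
#' CSV with columns `protein_id`, `R_nm` (radius, nanometres), `D_um2_s`
#' (per-state diffusion coefficient) and optionally `state`.
#'
#' @param path CSV path.
#' @return data frame with radius converted to metres in column `R_m`.
#' @export
read_size_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "R_nm", "D_um2_s")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("size table lacks column(s): %s", paste(miss, collapse = ", "))
  tab$R_m <- tab$R_nm * 1e-9
  tab
}
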