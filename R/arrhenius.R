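#' Arrhenius temperature-response parameters
#'
#' Parameter set for the Arrhenius-type developmental temperature response
#' used throughout the model. The defaults are the 18-species averages
#' (17 crops plus Arabidopsis): activation enthalpy 69350 J mol^-1,
#' half-activation temperature 305 K, exponent 3.5. The response is always
#' used normalized to 1 at the reference temperature (20 degC by default),
#' so the absolute scaling coefficient of the underlying rate law cancels
#' and is never stored.
#'
#' @param deltaH_A Activation enthalpy, J mol^-1. Must be positive.
#' @param T0 Temperature at which half of the (enzymatic) system is in the
#'   active state, K. Must exceed 273.15 K.
#' @param alpha Dimensionless exponent controlling the width of the
#'   supra-optimal decline. Must be positive.
#' @param T_ref_celsius Reference temperature in degC at which the
#'   normalized response equals 1. Default 20.
#' @return An object of class `arrhenius_params`.
#' @seealso [fav()], [fav_raw()]
#' @export
#' @examples
#' p <- arrhenius_params()
#' fav(21.2, p)  # ~1.12
arrhenius_params <- function(deltaH_A = 69350, T0 = 305, alpha = 3.5,
                             T_ref_celsius = 20) {
  stopifnot(
    is.numeric(deltaH_A), length(deltaH_A) == 1L, deltaH_A > 0,
    is.numeric(T0), length(T0) == 1L, T0 > 273.15,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0,
    is.numeric(T_ref_celsius), length(T_ref_celsius) == 1L,
    T_ref_celsius + 273.15 > 0
  )
  structure(
    list(deltaH_A = deltaH_A, T0 = T0, alpha = alpha,
         T_ref_celsius = T_ref_celsius, R_gas = 8.314),
    class = "arrhenius_params"
  )
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat("Arrhenius temperature-response parameters\n")
  cat(sprintf("  deltaH_A: %g J/mol   T0: %g K   alpha: %g   T_ref: %g degC\n",
              x$deltaH_A, x$T0, x$alpha, x$T_ref_celsius))
  invisible(x)
}

# log of the unscaled response at absolute temperature (K); the scaling
# coefficient A is taken as 1 -- it cancels in the normalized ratio.
# The denominator exponent is computed directly as x*alpha*(1 - T/T0)
# (with x = -dH/(R T)) so no underflowing power of exp(x) is ever formed.
log_fav_raw <- function(temp_K, params) {
  x <- -params$deltaH_A / (params$R_gas * temp_K)
  log(temp_K) + x - log1p(exp(x * params$alpha * (1 - temp_K / params$T0)))
}

#' Unnormalized Arrhenius response
#'
#' Evaluates `T * exp(-dH/(R*T)) / (1 + exp(-dH/(R*T))^(alpha*(1 - T/T0)))`
#' with the scaling coefficient taken as 1. The absolute scale is arbitrary;
#' only ratios of this function are meaningful (see [fav()]).
#'
#' @param temp_K Absolute temperature(s), K. Must be positive.
#' @param params An [arrhenius_params()] object.
#' @return Positive numeric vector, arbitrary scale.
#' @export
fav_raw <- function(temp_K, params = arrhenius_params()) {
  if (!is.numeric(temp_K) || any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    stop("temp_K must be finite and positive (absolute temperature in K)",
         call. = FALSE)
  }
  exp(log_fav_raw(temp_K, params))
}

#' Normalized Arrhenius temperature-response factor
#'
#' The dimensionless factor F_av(T) that multiplies developmental rates
#' (elongation rate, appearance rate) and divides durations. Normalized so
#' that F_av equals exactly 1 at the reference temperature (20 degC by
#' default). Temperatures are accepted in degC and converted internally
#' with T\[K\] = T\[degC\] + 273.15.
#'
#' A warning is issued outside the declared physiological validity range
#' (0-40 degC by default); temperatures outside the hard bounds
#' (-20 to 60 degC) are an error.
#'
#' @param temp_celsius Temperature(s), degC.
#' @param params An [arrhenius_params()] object.
#' @param valid_range Physiological validity range in degC; values outside
#'   it trigger a warning but are still evaluated.
#' @return Dimensionless positive factor(s), equal to 1 at the reference.
#' @export
#' @examples
#' fav(20)    # exactly 1
#' fav(21.2)  # ~1.12: a 12% faster elongation/appearance rate
#' fav(24)    # ~1.41
fav <- function(temp_celsius, params = arrhenius_params(),
                valid_range = c(0, 40)) {
  if (!is.numeric(temp_celsius) || any(!is.finite(temp_celsius))) {
    stop("temp_celsius must be finite numeric", call. = FALSE)
  }
  if (any(temp_celsius < -20 | temp_celsius > 60)) {
    stop("temperature outside hard bounds [-20, 60] degC", call. = FALSE)
  }
  if (any(temp_celsius < valid_range[1] | temp_celsius > valid_range[2])) {
    warning(sprintf(
      "temperature outside declared validity range [%g, %g] degC",
      valid_range[1], valid_range[2]), call. = FALSE)
  }
  temp_K <- temp_celsius + 273.15
  ref_K <- params$T_ref_celsius + 273.15
  exp(log_fav_raw(temp_K, params) - log_fav_raw(ref_K, params))
}

#' Tabulate the normalized temperature response
#'
#' @param from,to,step Temperature grid in degC.
#' @param params An [arrhenius_params()] object.
#' @return A data frame with columns `temperature_C` and `F_av`.
#' @export
fav_table <- function(from = 10, to = 30, step = 0.5,
                      params = arrhenius_params()) {
  stopifnot(from <= to, step > 0)
  grid <- seq(from, to, by = step)
  data.frame(temperature_C = grid,
             F_av = fav(grid, params, valid_range = c(-20, 60)))
}

#' Bundled species parameter table
#'
#' Only the 18-species-average entry is shipped; species-specific entries
#' (per-species activation enthalpies and half-activation temperatures) can
#' be supplied by the user through [arrhenius_params()] or the config file.
#'
#' @return Data frame with columns `species`, `deltaH_A`, `T0`, `alpha`.
#' @export
arrhenius_species <- function() {
  data.frame(
    species = "average_18_species",
    deltaH_A = 69350,
    T0 = 305,
    alpha = 3.5,
    stringsAsFactors = FALSE
  )
}
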