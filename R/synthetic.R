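#' Synthetic greenhouse climate generator configuration
#'
#' A phenomenological emulator of daily greenhouse climate: PAR follows a
#' stationary AR(1) Gaussian process (weather persistence) truncated at 0,
#' and daily mean temperature tracks PAR (sunny days are warmer) around a
#' base level, clipped between the base and slightly above the ventilation
#' ceiling. It is not a physical greenhouse model: the heating set-point /
#' ventilation mechanism is reduced to clipping, because only summary
#' statistics of the real climate are available to emulate.
#'
#' @param n_days Number of days to generate.
#' @param seed Integer seed; the series is deterministic given the seed.
#' @param par_mean,par_sd Target stationary mean and SD of daily mean PAR,
#'   umol m^-2 s^-1.
#' @param par_autocorr AR(1) lag-1 autocorrelation of PAR, in \[0, 1).
#' @param temp_base Base daily mean temperature, degC (heating set-point
#'   proxy; also the lower clip).
#' @param temp_vent Ventilation ceiling, degC; daily means are clipped at
#'   `temp_vent + 0.5`.
#' @param temp_par_coupling Warming per unit PAR anomaly, degC per
#'   umol m^-2 s^-1.
#' @param temp_noise_sd SD of the additive temperature noise, degC.
#' @return A list of class `climate_gen_config`.
#' @seealso [generate_climate()], [climate_preset()]
#' @export
climate_gen_config <- function(n_days, seed = 1L,
                               par_mean = 430, par_sd = 118,
                               par_autocorr = 0.5,
                               temp_base = 22, temp_vent = 24,
                               temp_par_coupling = 0.004,
                               temp_noise_sd = 0.5) {
  stopifnot(
    n_days >= 1, par_mean > 0, par_sd >= 0,
    par_autocorr >= 0, par_autocorr < 1,
    temp_base < temp_vent, temp_noise_sd >= 0
  )
  structure(list(
    n_days = as.integer(n_days), seed = as.integer(seed),
    par_mean = par_mean, par_sd = par_sd, par_autocorr = par_autocorr,
    temp_base = temp_base, temp_vent = temp_vent,
    temp_par_coupling = temp_par_coupling, temp_noise_sd = temp_noise_sd
  ), class = "climate_gen_config")
}

#' Named climate presets emulating the two greenhouse experiments
#'
#' `E1`: PAR 464 +/- 116 umol m^-2 s^-1, period mean temperature 21.9 degC;
#' `E2`: PAR 404 +/- 120, 22.4 degC. Both with a 24 degC ventilation
#' ceiling. Day/night set-points are not resolved because the model
#' consumes daily means only. Autocorrelation and PAR-temperature coupling
#' are assumptions of the emulator (see the methods vignette).
#'
#' @param name `"E1"` or `"E2"`.
#' @param n_days,seed Passed to [climate_gen_config()].
#' @return A `climate_gen_config`.
#' @export
climate_preset <- function(name = c("E1", "E2"), n_days = 45, seed = 1L) {
  name <- match.arg(name)
  if (name == "E1") {
    climate_gen_config(n_days, seed, par_mean = 464, par_sd = 116,
                       temp_base = 21.9, temp_vent = 24)
  } else {
    climate_gen_config(n_days, seed, par_mean = 404, par_sd = 120,
                       temp_base = 22.4, temp_vent = 24)
  }
}

#' Generate a synthetic greenhouse climate series
#'
#' PAR is drawn as a stationary AR(1) process with the configured mean, SD
#' and lag-1 autocorrelation (innovation SD scaled by sqrt(1 - phi^2) so
#' the stationary SD matches), truncated at 0. Temperature is
#' `temp_base + coupling * (PAR - par_mean) + noise`, clipped to
#' `[temp_base, temp_vent + 0.5]`. The RNG state of the caller is
#' preserved.
#'
#' @param config A [climate_gen_config()] (or [climate_preset()]).
#' @return A [climate_series()] with `n_days` rows, days 1..n.
#' @export
#' @examples
#' cl <- generate_climate(climate_preset("E1", n_days = 45, seed = 42))
#' round(c(mean(cl$par), sd(cl$par), mean(cl$temperature)), 1)
generate_climate <- function(config) {
  stopifnot(inherits(config, "climate_gen_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_days
  phi <- config$par_autocorr
  par <- numeric(n)
  par[1L] <- stats::rnorm(1L, config$par_mean, config$par_sd)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, 0, config$par_sd * sqrt(1 - phi^2))
    for (i in 2:n) {
      par[i] <- config$par_mean + phi * (par[i - 1L] - config$par_mean) +
        innov[i - 1L]
    }
  }
  par <- pmax(par, 0)

  temp <- config$temp_base +
    config$temp_par_coupling * (par - config$par_mean) +
    stats::rnorm(n, 0, config$temp_noise_sd)
  temp <- pmin(pmax(temp, config$temp_base), config$temp_vent + 0.5)

  climate_series(seq_len(n), par, temp)
}
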