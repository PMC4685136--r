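#' Internode model configuration
#'
#' All tunable parameters of the daily-step internode growth model. The
#' defaults are the published cucumber parameterization: final internode
#' length responds linearly to the 4-day PAR signal
#' (`FIL = 13.4 - 0.014 * PAR4d + f(R:FR)`, cm), elongation approaches the
#' target at relative rate `k = 0.5` per day, the reference elongation
#' duration at 20 degC is `De20 = 4.2` d (42 degC-days over a 10 degC
#' supra-base reference) and the reference appearance interval is
#' `Da20 = 1.4` d (reciprocal of the 0.7 d^-1 appearance rate at 20 degC).
#'
#' @param fil_intercept Intercept of the light response, cm.
#' @param fil_par_slope Slope of the light response, cm per umol m^-2 s^-1
#'   (applied subtractively: higher PAR gives shorter internodes).
#' @param k_elong Relative approach rate of elongation toward the target
#'   length, d^-1.
#' @param De20 Reference elongation duration at 20 degC, d.
#' @param Da20 Reference appearance interval at 20 degC, d.
#' @param initial_length Length at appearance, cm.
#' @param temperature_sensitive `TRUE` for the temperature-sensitive
#'   scenario (MA-T), `FALSE` to hold the temperature factor at 1
#'   everywhere (MA-20, the original fixed-20 degC model).
#' @param arrhenius An [arrhenius_params()] object.
#' @param rfr_function Pluggable light-quality term `f(R:FR)` in cm, called
#'   as `rfr_function(rank, day)`. Default returns 0 (no light-quality
#'   effect); supply a function backed by a piecewise-linear table to model
#'   red:far-red responses.
#' @param analysis_min_rank Lowest rank included in summary analyses
#'   (default 5: lower internodes initiate before the climate applies).
#' @param fil_floor Lower clamp on target lengths, cm (the appearance
#'   length; the light response goes negative at very high PAR).
#' @param window A [signal_window()] for the PAR4d/T4d signals.
#' @param partial_final_step `"fractional"` (default) scales the last
#'   elongation increment by the fractional remainder of the duration;
#'   `"floor"` truncates durations to whole days.
#' @return A list of class `model_config`.
#' @export
model_config <- function(fil_intercept = 13.4, fil_par_slope = 0.014,
                         k_elong = 0.5, De20 = 4.2, Da20 = 1.4,
                         initial_length = 3,
                         temperature_sensitive = TRUE,
                         arrhenius = arrhenius_params(),
                         rfr_function = function(rank, day) 0,
                         analysis_min_rank = 5, fil_floor = 3,
                         window = signal_window(),
                         partial_final_step = c("fractional", "floor")) {
  partial_final_step <- match.arg(partial_final_step)
  stopifnot(
    k_elong > 0, De20 > 0, Da20 > 0, initial_length > 0, fil_floor > 0,
    is.logical(temperature_sensitive),
    inherits(arrhenius, "arrhenius_params"),
    is.function(rfr_function),
    inherits(window, "signal_window")
  )
  structure(list(
    fil_intercept = fil_intercept, fil_par_slope = fil_par_slope,
    k_elong = k_elong, De20 = De20, Da20 = Da20,
    initial_length = initial_length,
    temperature_sensitive = temperature_sensitive,
    arrhenius = arrhenius, rfr_function = rfr_function,
    analysis_min_rank = analysis_min_rank, fil_floor = fil_floor,
    window = window, partial_final_step = partial_final_step
  ), class = "model_config")
}

# temperature factor under the configured scenario: F_av(T) when
# temperature-sensitive, identically 1 otherwise (identical code path).
scenario_fav <- function(temp_celsius, config) {
  if (config$temperature_sensitive) {
    fav(temp_celsius, config$arrhenius)
  } else {
    rep(1, length(temp_celsius))
  }
}

#' Light-determined final internode length
#'
#' The light-quantity part of the final-length response:
#' `max(fil_floor, intercept - slope * par4d + rfr_term)`.
#'
#' @param par4d Mean PAR over the internode's signal window,
#'   umol m^-2 s^-1; non-negative.
#' @param rfr_term Light-quality contribution `f(R:FR)`, cm (default 0).
#' @param config A [model_config()].
#' @return Final length from light alone, cm.
#' @export
#' @examples
#' final_length_light(383)  # ~8.0 cm
final_length_light <- function(par4d, rfr_term = 0,
                               config = model_config()) {
  stopifnot(all(par4d >= 0))
  pmax(config$fil_floor,
       config$fil_intercept - config$fil_par_slope * par4d + rfr_term)
}

#' Temperature-modulated target length
#'
#' Multiplies the light-determined length by the normalized temperature
#' factor F_av(T4d) in the temperature-sensitive scenario; leaves it
#' unchanged otherwise. Clamped below at `fil_floor`.
#'
#' @param fil_light Light-determined final length, cm.
#' @param t4d Mean temperature over the internode's signal window, degC.
#' @param config A [model_config()].
#' @return Target final length, cm.
#' @export
temperature_target <- function(fil_light, t4d, config = model_config()) {
  pmax(config$fil_floor, scenario_fav(t4d, config) * fil_light)
}

#' Temperature-modulated elongation duration
#'
#' `De(T) = De20 / F_av(T4d)` in the temperature-sensitive scenario, De20
#' otherwise. Fixed once at internode appearance and never recomputed.
#'
#' @inheritParams temperature_target
#' @return Duration, d.
#' @export
elongation_duration <- function(t4d, config = model_config()) {
  config$De20 / scenario_fav(t4d, config)
}

#' One elongation step
#'
#' First-order approach to the target:
#' `length + frac * k * (target - length)`, with negative increments
#' clamped to 0 (an internode never shrinks). `frac < 1` applies the
#' fractional final step when the elongation duration is non-integer.
#'
#' @param length Current length, cm.
#' @param target Target final length, cm.
#' @param k Relative approach rate, d^-1.
#' @param frac Fraction of a day covered by this step, in (0, 1\].
#' @return Updated length, cm.
#' @export
#' @examples
#' elongation_step(3, 10, 0.5)  # 6.5
elongation_step <- function(length, target, k, frac = 1) {
  length + pmax(0, frac * k * (target - length))
}

#' Daily development increment
#'
#' The appearance accumulator advances by `F_av(T_today) / Da20` per day
#' in the temperature-sensitive scenario (`1 / Da20` otherwise); each
#' integer threshold crossed produces one new internode.
#'
#' @param temp_celsius Today's daily mean temperature, degC.
#' @param config A [model_config()].
#' @return Dimensionless daily increment of the development stage.
#' @export
development_increment <- function(temp_celsius, config = model_config()) {
  scenario_fav(temp_celsius, config) / config$Da20
}

#' Simulate internode appearance and elongation over a climate series
#'
#' Daily time-step simulation. At step 2 the plant holds internode 1 at the
#' initial length (development stage initialized to 1). Each subsequent
#' step: (1) the development stage advances with today's temperature and
#' one internode appears per integer threshold crossed -- its PAR4d/T4d
#' signals, target length and elongation duration are computed once, at
#' appearance, and fixed; (2) every previously appeared active internode
#' takes one elongation step toward its target (the final step is scaled
#' by the fractional remainder of the duration); (3) internodes whose age
#' has reached their elongation duration are deactivated and their length
#' frozen.
#'
#' Simulation step `s` uses the `s`-th row of the climate series, so the
#' climate must cover at least `n_steps` days.
#'
#' @param climate A [climate_series()].
#' @param config A [model_config()].
#' @param n_steps Last simulation step (>= 2).
#' @param quiet Suppress appearance/truncation messages (default TRUE).
#' @return A list of class `internode_sim` with elements
#'   `trajectory` (day, rank, length_cm, active),
#'   `internodes` (rank, appearance_day, par4d, t4d, fav, fil_light,
#'   target_cm, duration_d, final_cm, completed),
#'   `daily` (day, n_internodes, mean_final_cm over completed internodes
#'   with rank >= `analysis_min_rank`), plus the `config`, `n_steps` and
#'   scenario label.
#' @export
simulate_internodes <- function(climate, config = model_config(),
                                n_steps = nrow(climate), quiet = TRUE) {
  validate_climate(climate)
  stopifnot(n_steps >= 2)
  if (n_steps > nrow(climate)) {
    stop(sprintf("climate series (%d days) shorter than n_steps = %d",
                 nrow(climate), n_steps), call. = FALSE)
  }

  # per-internode state, grown as internodes appear
  st <- new.env(parent = emptyenv())
  st$rank <- integer(0); st$app_step <- integer(0)
  st$app_day <- integer(0); st$length <- numeric(0)
  st$par4d <- numeric(0); st$t4d <- numeric(0); st$fav <- numeric(0)
  st$fil_light <- numeric(0); st$target <- numeric(0)
  st$duration <- numeric(0); st$active <- logical(0)

  appear <- function(step) {
    rank <- length(st$rank) + 1L
    day <- climate$day[step]
    p4 <- window_mean(climate, "par", day, config$window, quiet = quiet)
    t4 <- window_mean(climate, "temperature", day, config$window,
                      quiet = quiet)
    fv <- scenario_fav(t4, config)
    fl <- final_length_light(p4, config$rfr_function(rank, day), config)
    st$rank <- c(st$rank, rank)
    st$app_step <- c(st$app_step, step)
    st$app_day <- c(st$app_day, day)
    st$length <- c(st$length, config$initial_length)
    st$par4d <- c(st$par4d, p4); st$t4d <- c(st$t4d, t4)
    st$fav <- c(st$fav, fv); st$fil_light <- c(st$fil_light, fl)
    st$target <- c(st$target, max(config$fil_floor, fv * fl))
    st$duration <- c(st$duration, config$De20 / fv)
    st$active <- c(st$active, TRUE)
    if (!quiet) message(sprintf(
      "step %d (day %d): internode %d appeared (PAR4d %.1f, T4d %.2f, target %.2f cm, duration %.2f d)",
      step, day, rank, p4, t4, st$target[rank], st$duration[rank]))
  }

  stage <- 1
  appear(2L)

  traj <- vector("list", n_steps)
  daily <- vector("list", n_steps)
  record <- function(step) {
    traj[[step]] <<- data.frame(
      day = climate$day[step], rank = st$rank,
      length_cm = st$length, active = st$active)
    done <- !st$active & st$rank >= config$analysis_min_rank
    daily[[step]] <<- data.frame(
      day = climate$day[step], n_internodes = length(st$rank),
      mean_final_cm = if (any(done)) mean(st$length[done]) else NA_real_)
  }
  record(2L)

  if (n_steps > 2L) for (step in 3:n_steps) {
    # (1) development: integer crossings of the accumulator trigger
    # appearances; several crossings in one day each produce an internode
    # thresholds are detected with a 1e-9 tolerance so that exact-rational
    # increments (e.g. 1/1.4 per day at 20 degC) are not missed to
    # floating-point accumulation error
    inc <- development_increment(climate$temperature[step], config)
    n_new <- floor(stage + inc + 1e-9) - floor(stage + 1e-9)
    stage <- stage + inc
    if (n_new > 0) for (i in seq_len(n_new)) appear(step)

    # (2) elongation of internodes that appeared before today
    idx <- which(st$active & st$app_step < step)
    if (length(idx)) {
      age <- step - st$app_step[idx]           # elapsed days after this step
      dur <- if (config$partial_final_step == "floor")
        floor(st$duration[idx]) else st$duration[idx]
      frac <- pmin(1, pmax(0, dur - (age - 1)))
      st$length[idx] <- elongation_step(st$length[idx], st$target[idx],
                                        config$k_elong, frac)
      # (3) freeze internodes whose elongation time is exhausted
      done <- age >= dur
      st$active[idx[done]] <- FALSE
    }
    record(step)
  }

  internodes <- data.frame(
    rank = st$rank, appearance_day = st$app_day,
    par4d = st$par4d, t4d = st$t4d, fav = st$fav,
    fil_light = st$fil_light, target_cm = st$target,
    duration_d = st$duration, final_cm = st$length,
    completed = !st$active)

  structure(list(
    trajectory = do.call(rbind, traj[!vapply(traj, is.null, TRUE)]),
    internodes = internodes,
    daily = do.call(rbind, daily[!vapply(daily, is.null, TRUE)]),
    config = config, n_steps = n_steps,
    scenario = if (config$temperature_sensitive) "MA-T" else "MA-20"
  ), class = "internode_sim")
}

#' @export
print.internode_sim <- function(x, ...) {
  n_done <- sum(x$internodes$completed)
  cat(sprintf("Internode simulation (%s), steps 2-%d\n",
              x$scenario, x$n_steps))
  cat(sprintf("  %d internodes (%d completed elongation)\n",
              nrow(x$internodes), n_done))
  sel <- x$internodes$completed &
    x$internodes$rank >= x$config$analysis_min_rank
  if (any(sel)) {
    cat(sprintf("  mean final length (rank >= %d, completed): %.1f cm\n",
                x$config$analysis_min_rank,
                mean(x$internodes$final_cm[sel])))
  }
  invisible(x)
}

#' Plot the simulated length-by-rank pattern
#'
#' Minimal base-graphics view of final internode lengths along the main
#' stem, optionally overlaying a second simulation (e.g. the fixed-20 degC
#' scenario) for comparison.
#'
#' @param x An `internode_sim`.
#' @param other Optional second `internode_sim` to overlay.
#' @param min_rank First rank to display.
#' @param ... Passed to [plot()].
#' @export
plot.internode_sim <- function(x, other = NULL,
                               min_rank = x$config$analysis_min_rank, ...) {
  a <- x$internodes[x$internodes$rank >= min_rank, ]
  plot(a$rank, a$final_cm, type = "b", pch = 19,
       xlab = "rank", ylab = "final internode length (cm)", ...)
  if (!is.null(other)) {
    b <- other$internodes[other$internodes$rank >= min_rank, ]
    graphics::lines(b$rank, b$final_cm, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", legend = c(x$scenario, other$scenario),
                     pch = c(19, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
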