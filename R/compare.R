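#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) as a percentage of the
#' mean; used to compare variability of quantities with different units
#' (e.g. PAR and temperature).
#'
#' @param values Numeric vector with nonzero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv(c(8, 10, 12))  # 20
cv <- function(values) {
  m <- mean(values)
  if (m == 0) stop("cv undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Pearson correlation
#'
#' Product-moment correlation, used to check whether radiation and
#' temperature signals are associated over an experimental phase.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_r needs at least 3 paired values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r undefined for zero-variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Evaluation statistics for length-by-rank patterns
#'
#' Compares a simulated length-by-rank pattern against measurements:
#' root mean square deviation (RMSD), mean deviation (bias = mean of
#' simulated minus measured), and the systematic prediction error
#' (SPE = 100 * bias^2 / MSD, the share of the mean squared deviation
#' attributable to bias), plus per-pattern means and CVs. Ranks are paired
#' on the intersection of ranks present in both inputs (simulated and
#' measured internode counts can differ; intersection never invents data),
#' restricted to `rank >= min_rank`.
#'
#' @param simulated,measured Data frames with columns `rank` and
#'   `length_cm`, or named numeric vectors (names = ranks).
#' @param min_rank Lowest rank entering the comparison (default 5).
#' @return A list of class `eval_stats` with elements `rmsd`, `bias`,
#'   `spe`, `n_pairs`, `mean_sim`, `mean_meas`, `cv_sim`, `cv_meas`.
#' @export
#' @examples
#' sim <- data.frame(rank = 5:6, length_cm = c(10, 11))
#' meas <- data.frame(rank = 5:6, length_cm = c(9, 10))
#' eval_stats(sim, meas)  # bias 1, rmsd 1, spe 100
eval_stats <- function(simulated, measured, min_rank = 5) {
  as_tab <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("rank", "length_cm") %in% names(x)))
      x[c("rank", "length_cm")]
    } else {
      data.frame(rank = as.integer(names(x)), length_cm = as.numeric(x))
    }
  }
  s <- as_tab(simulated); m <- as_tab(measured)
  s <- s[s$rank >= min_rank, ]; m <- m[m$rank >= min_rank, ]
  if (nrow(s) == 0 || nrow(m) == 0) {
    stop("no data at rank >= min_rank", call. = FALSE)
  }
  ranks <- intersect(s$rank, m$rank)
  if (length(ranks) == 0) stop("no common ranks to compare", call. = FALSE)
  sv <- s$length_cm[match(ranks, s$rank)]
  mv <- m$length_cm[match(ranks, m$rank)]
  err <- sv - mv
  msd <- mean(err^2)
  bias <- mean(err)
  structure(list(
    rmsd = sqrt(msd), bias = bias,
    spe = if (msd == 0) 0 else 100 * bias^2 / msd,
    n_pairs = length(ranks),
    mean_sim = mean(sv), mean_meas = mean(mv),
    cv_sim = cv(sv), cv_meas = cv(mv)
  ), class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d pairs | RMSD %.1f cm | bias %.1f cm | SPE %.0f%%\n",
    x$n_pairs, x$rmsd, x$bias, x$spe))
  cat(sprintf("simulated %.1f cm (CV %.0f%%) vs measured %.1f cm (CV %.0f%%)\n",
              x$mean_sim, x$cv_sim, x$mean_meas, x$cv_meas))
  invisible(x)
}

#' Read measured internode lengths
#'
#' CSV with header `day,rank,length_cm` (one row per measured internode per
#' measurement day).
#'
#' @param path File path.
#' @return Data frame with columns `day`, `rank`, `length_cm`.
#' @export
read_lengths_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("day", "rank", "length_cm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("measured-lengths file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Compare the temperature-sensitive and fixed-20 degC scenarios
#'
#' Runs the simulation twice on the same climate and configuration -- once
#' temperature-sensitive (MA-T) and once with the temperature factor held
#' at 1 (MA-20) -- and attributes the per-rank final-length differences to
#' their sources: the PAR component is the light-response slope times the
#' shift in PAR4d caused by temperature-driven changes in appearance
#' timing; the temperature component is the direct Arrhenius scaling
#' `(F_av(T4d) - 1) * fil_light`; the residual collects interaction and
#' clamping effects so the three always sum to the observed difference.
#'
#' @param climate A [climate_series()].
#' @param config A [model_config()]; its `temperature_sensitive` flag is
#'   overridden for each scenario.
#' @param n_steps Last simulation step.
#' @param share_threshold `par_share` is reported only where the absolute
#'   length difference exceeds this (cm), to avoid division blow-ups.
#' @return A list of class `scenario_comparison`: `attribution` (per-rank
#'   table with `delta_fil`, `par_component`, `temp_component`,
#'   `residual`, `par_share`, `appearance_shift_d`), `summary`
#'   (per-scenario internode counts and mean completed final lengths at
#'   `rank >= analysis_min_rank`, and their difference), plus both run
#'   objects.
#' @export
compare_scenarios <- function(climate, config = model_config(),
                              n_steps = nrow(climate),
                              share_threshold = 0.1) {
  cfg_t <- config; cfg_t$temperature_sensitive <- TRUE
  cfg_20 <- config; cfg_20$temperature_sensitive <- FALSE
  run_t <- simulate_internodes(climate, cfg_t, n_steps)
  run_20 <- simulate_internodes(climate, cfg_20, n_steps)

  it <- run_t$internodes; i20 <- run_20$internodes
  ranks <- intersect(it$rank, i20$rank)
  a <- it[match(ranks, it$rank), ]
  b <- i20[match(ranks, i20$rank), ]

  delta <- a$final_cm - b$final_cm
  par_comp <- -config$fil_par_slope * (a$par4d - b$par4d)
  temp_comp <- (a$fav - 1) * a$fil_light
  attribution <- data.frame(
    rank = ranks,
    delta_fil = delta,
    par_component = par_comp,
    temp_component = temp_comp,
    residual = delta - par_comp - temp_comp,
    par_share = ifelse(abs(delta) > share_threshold,
                       100 * abs(par_comp) / abs(delta), NA_real_),
    appearance_shift_d = a$appearance_day - b$appearance_day)

  mean_fil <- function(x) {
    sel <- x$completed & x$rank >= config$analysis_min_rank
    if (any(sel)) mean(x$final_cm[sel]) else NA_real_
  }
  summary <- data.frame(
    scenario = c("MA-T", "MA-20"),
    n_internodes = c(nrow(it), nrow(i20)),
    mean_final_cm = c(mean_fil(it), mean_fil(i20)))

  structure(list(attribution = attribution, summary = summary,
                 delta_mean_fil = mean_fil(it) - mean_fil(i20),
                 run_t = run_t, run_20 = run_20),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (temperature-sensitive vs fixed 20 degC)\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("mean final-length difference (MA-T - MA-20): %.1f cm\n",
              x$delta_mean_fil))
  shifts <- x$attribution$appearance_shift_d
  if (any(shifts != 0)) {
    cat(sprintf("appearance shifted by up to %d d at higher ranks\n",
                -min(shifts)))
  }
  invisible(x)
}
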