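test_that("light response reproduces the published length contributions", {
  expect_equal(final_length_light(0), 13.4)      # intercept
  expect_equal(final_length_light(383), 8.038)   # printed E2 mean signal
  expect_equal(final_length_light(375), 8.15)
  # clamp at the appearance length for extreme PAR
  expect_equal(final_length_light(1000), 3)
  expect_error(final_length_light(-10))
})

test_that("temperature scales the target only in the sensitive scenario", {
  ma_t <- model_config(temperature_sensitive = TRUE)
  ma_20 <- model_config(temperature_sensitive = FALSE)
  expect_equal(temperature_target(10, 20, ma_t), 10)
  expect_equal(temperature_target(10, 21.2, ma_t), 10 * fav(21.2))
  expect_equal(round(temperature_target(10, 21.2, ma_t), 1), 11.2)
  expect_equal(temperature_target(10, 25, ma_20), 10)
  # low-temperature targets never drop below the appearance length
  expect_gte(temperature_target(3, 10, ma_t), 3)
})

test_that("elongation steps follow the first-order approach law", {
  expect_equal(elongation_step(3, 10, 0.5), 6.5)
  expect_equal(elongation_step(10, 10, 0.5), 10)   # fixed point
  expect_equal(elongation_step(12, 10, 0.5), 12)   # no shrinkage
  # closed-form geometric approach: 10 - 7 * 0.5^n after n steps
  len <- 3
  for (n in 1:8) {
    len <- elongation_step(len, 10, 0.5)
    expect_equal(len, 10 - 7 * 0.5^n)
  }
})

test_that("elongation duration scales inversely with the temperature factor", {
  ma_t <- model_config()
  expect_equal(elongation_duration(20, ma_t), 4.2)
  expect_equal(round(elongation_duration(21.2, ma_t), 2),
               round(4.2 / fav(21.2), 2))
  # conservation: De(T) * F_av(T) = De20 across the whole range
  for (t in seq(10, 30, by = 0.5)) {
    expect_equal(elongation_duration(t, ma_t) * fav(t), 4.2)
  }
  ma_20 <- model_config(temperature_sensitive = FALSE)
  expect_equal(elongation_duration(27, ma_20), 4.2)
})

test_that("appearance accumulator produces the reference interval at 20 degC", {
  # 14 advance days at constant 20 degC: increment 1/1.4 -> 10 appearances
  run <- simulate_internodes(const_climate(16), model_config(), 16)
  expect_equal(nrow(run$internodes), 11)  # internode 1 + 10 further
  expect_equal(development_increment(20, model_config()), 1 / 1.4)
})

test_that("several accumulator crossings in one day each yield an internode", {
  cfg <- model_config(Da20 = 0.4)  # increment 2.5/day at 20 degC
  run <- simulate_internodes(const_climate(10), cfg, 10)
  daily <- run$daily
  # count always equals the floored accumulator: 1 + 2.5 * days elapsed
  expect_equal(daily$n_internodes, floor(1 + 2.5 * (0:8)))
  expect_equal(run$internodes$rank, seq_len(nrow(run$internodes)))
})

test_that("constant-climate final lengths match the day-by-day oracle", {
  run <- simulate_internodes(const_climate(20), model_config(), 20)
  done <- run$internodes[run$internodes$completed, ]
  # at 20 degC, PAR 375: target 8.15 cm, duration 4.2 d
  expect_equal(unique(done$target_cm), 8.15)
  expect_equal(unique(done$duration_d), 4.2)
  oracle <- iterate_elongation(8.15, 4.2)
  expect_equal(unique(done$final_cm), oracle)
  # floor mode stops at whole days and never exceeds the fractional mode
  run_f <- simulate_internodes(const_climate(20),
                               model_config(partial_final_step = "floor"), 20)
  done_f <- run_f$internodes[run_f$internodes$completed, ]
  expect_equal(unique(done_f$final_cm), iterate_elongation(8.15, 4))
  expect_lt(unique(done_f$final_cm), oracle)
})

test_that("temperature-sensitive run at constant 20 degC is identical to the fixed model", {
  cl <- const_climate(25, par = 420)
  run_t <- simulate_internodes(cl, model_config(temperature_sensitive = TRUE), 25)
  run_20 <- simulate_internodes(cl, model_config(temperature_sensitive = FALSE), 25)
  expect_identical(run_t$trajectory, run_20$trajectory)
  expect_identical(run_t$internodes, run_20$internodes)
})

test_that("lengths are non-decreasing and frozen after the elongation duration", {
  cl <- generate_climate(climate_preset("E2", n_days = 40, seed = 5))
  run <- simulate_internodes(cl, model_config(), 35)
  for (r in unique(run$trajectory$rank)) {
    tr <- run$trajectory[run$trajectory$rank == r, ]
    expect_true(all(diff(tr$length_cm) >= 0))
    frozen <- tr[!tr$active, ]
    if (nrow(frozen) > 1) {
      expect_equal(length(unique(frozen$length_cm)), 1)
    }
    info <- run$internodes[run$internodes$rank == r, ]
    if (info$completed) {
      # active span never exceeds the fixed duration
      expect_lte(sum(tr$active) - 1, ceiling(info$duration_d))
    }
  }
  expect_true(all(run$trajectory$length_cm >= 3))
  expect_true(all(diff(run$daily$n_internodes) >= 0))
})

test_that("warm climates develop at least as fast as the fixed-20 model", {
  cl <- generate_climate(climate_preset("E2", n_days = 40, seed = 2))
  stopifnot(all(cl$temperature >= 20))
  run_t <- simulate_internodes(cl, model_config(), 40)
  run_20 <- simulate_internodes(cl, model_config(temperature_sensitive = FALSE), 40)
  counts <- merge(run_t$daily[c("day", "n_internodes")],
                  run_20$daily[c("day", "n_internodes")], by = "day")
  expect_true(all(counts$n_internodes.x >= counts$n_internodes.y))
})

test_that("empirical appearance interval converges to Da20 / F_av(T)", {
  for (temp in c(20, 23, 24)) {
    cl <- const_climate(100, temp = temp)
    run <- simulate_internodes(cl, model_config(), 100)
    app <- run$internodes$appearance_day
    emp <- (max(app) - min(app)) / (length(app) - 1)
    expect_equal(emp, 1.4 / fav(temp), tolerance = 0.03)
  }
})

test_that("doubling the approach rate weakly lengthens every frozen internode", {
  cl <- generate_climate(climate_preset("E1", n_days = 35, seed = 9))
  run_a <- simulate_internodes(cl, model_config(k_elong = 0.5), 30)
  run_b <- simulate_internodes(cl, model_config(k_elong = 1.0), 30)
  a <- run_a$internodes[run_a$internodes$completed, ]
  b <- run_b$internodes[run_b$internodes$completed, ]
  common <- intersect(a$rank, b$rank)
  expect_gt(length(common), 5)
  expect_true(all(b$final_cm[match(common, b$rank)] >=
                    a$final_cm[match(common, a$rank)]))
})

test_that("simulation refuses a climate shorter than the requested steps", {
  expect_error(simulate_internodes(const_climate(10), model_config(), 11),
               "shorter")
})

test_that("the pipeline is deterministic: repeated runs agree exactly", {
  cl <- generate_climate(climate_preset("E1", n_days = 30, seed = 4))
  r1 <- simulate_internodes(cl, model_config(), 30)
  r2 <- simulate_internodes(cl, model_config(), 30)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$internodes, r2$internodes)
})
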