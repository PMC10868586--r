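test_that("tolerable_time evaluates the TDT curve at its anchor points", {
  p <- tdt_params(z = 5.58, t_static = 41.4)
  # at the static limit the tolerable time is the reference duration
  expect_equal(tolerable_time(p, 41.4), 1)
  # one z below the static limit multiplies tolerable time tenfold:
  # (41.4 - 35.82)/5.58 = 1 exactly
  expect_equal(tolerable_time(p, 35.82), 10)
  # independent hand calculation: 10^((39 - 34)/4.19) = 15.6069...
  p2 <- tdt_params(z = 4.19, t_static = 39.0)
  expect_equal(tolerable_time(p2, 34), 15.6069, tolerance = 1e-4)
})

test_that("tolerable_time is strictly decreasing and scales with t_ref", {
  p <- tdt_params(z = 4.19, t_static = 39.0)
  temps <- seq(25, 45, by = 0.5)
  expect_true(all(diff(tolerable_time(p, temps)) < 0))
  p_k <- tdt_params(z = 4.19, t_static = 39.0, t_ref = 7)
  expect_equal(tolerable_time(p_k, temps), 7 * tolerable_time(p, temps))
})

test_that("parameter validation rejects nonsense and warns on implausibility", {
  expect_error(tdt_params(z = -1, t_static = 40), class = "thermotol_error_params")
  expect_error(tdt_params(z = 5, t_static = 40, t_ref = 0), class = "thermotol_error_params")
  expect_error(tdt_params(z = 5, t_static = Inf), class = "thermotol_error_params")
  expect_warning(tdt_params(z = 5, t_static = 55), "plausibility")
  expect_warning(tdt_params(z = 25, t_static = 40), "suspiciously large")
})

test_that("injury at the static limit for the reference duration is exactly 1", {
  p <- tdt_params(z = 5.58, t_static = 41.4)
  const <- data.frame(time_min = c(0, 1), temp_c = c(41.4, 41.4))
  expect_identical(injury_integral(p, const), 1)
  # one z colder tolerates ten reference durations
  colder <- data.frame(time_min = c(0, 10), temp_c = rep(41.4 - 5.58, 2))
  expect_equal(injury_integral(p, colder), 1, tolerance = 1e-12)
})

test_that("injury is additive over concatenated trajectories", {
  p <- tdt_params(z = 5.58, t_static = 41.4)
  traj <- ramp_trajectory(30, 0.42, 41, by_min = 0.25)
  k <- 11L
  a <- traj[1:k, ]
  b <- traj[k:nrow(traj), ]
  expect_equal(
    injury_integral(p, a) + injury_integral(p, b),
    injury_integral(p, traj),
    tolerance = 1e-12
  )
})

test_that("closed-form and Simpson injury agree on curved trajectories", {
  p <- tdt_params(z = 5, t_static = 42)
  tt <- seq(0, 120, by = 1)
  traj <- data.frame(time_min = tt, temp_c = 34 + 6 * sin(pi * tt / 120))
  expect_equal(
    injury_integral(p, traj, method = "simpson"),
    injury_integral(p, traj, method = "closed_form"),
    tolerance = 1e-6
  )
})

test_that("degenerate trajectories are rejected", {
  p <- tdt_params(z = 5, t_static = 40)
  expect_error(
    injury_integral(p, data.frame(time_min = 0, temp_c = 35)),
    class = "thermotol_error_trajectory"
  )
  expect_error(
    injury_integral(p, data.frame(time_min = c(0, 2, 1), temp_c = c(35, 36, 37))),
    class = "thermotol_error_trajectory"
  )
})

test_that("dynamic knockdown matches the cold-start analytic limit", {
  # starting far below the static limit with r = z / (ln10 * t_ref), the log
  # argument collapses to 1 and knockdown occurs exactly at t_static
  z <- 5.58
  p <- tdt_params(z = z, t_static = 41.4)
  r_special <- z / log(10)
  expect_equal(dynamic_knockdown(p, -200, r_special), 41.4, tolerance = 1e-10)
})

test_that("dynamic knockdown is monotone in rate and start temperature", {
  p <- tdt_params(z = 5.58, t_static = 45.6)
  rates <- c(0.003, 0.01, 0.066, 0.2, 0.42, 0.5)
  tk <- dynamic_knockdown(p, 30, rates)
  expect_true(all(diff(tk) > 0))
  starts <- c(20, 24, 26, 28, 30)
  expect_true(all(diff(dynamic_knockdown(p, starts, 0.42)) > 0))
  expect_error(dynamic_knockdown(p, 30, 0), class = "thermotol_error_rate")
  expect_error(dynamic_knockdown(p, 30, -0.1), class = "thermotol_error_rate")
})

test_that("closed-form knockdown equals the numeric injury-integration root", {
  # grid over heat sensitivity, ramp rate, start temperature
  for (z in c(2, 4, 6, 8)) {
    for (r in c(0.003, 0.066, 0.42)) {
      for (start in c(20, 28, 33)) {
        p <- tdt_params(z = z, t_static = 40)
        expect_equal(
          dynamic_knockdown(p, start, r),
          numeric_knockdown_oracle(z, 40, start, r),
          tolerance = 1e-6
        )
      }
    }
  }
})

test_that("ramp injury reaches 1 exactly at the closed-form knockdown", {
  p <- tdt_params(z = 5.58, t_static = 45.6)
  tk <- dynamic_knockdown(p, 30, 0.42)
  traj <- ramp_trajectory(30, 0.42, tk, by_min = 0.05)
  expect_equal(injury_integral(p, traj), 1, tolerance = 1e-6)
})

test_that("a warm start raises a pre-heating injury warning", {
  p <- tdt_params(z = 5, t_static = 40)
  expect_warning(dynamic_knockdown(p, 39.5, 0.42), "close to the static limit")
})

test_that("predict_ctmax_at_rate is a labelled alias of dynamic_knockdown", {
  p <- tdt_params(z = 4.19, t_static = 43)
  out <- predict_ctmax_at_rate(p,
    site_rate = c(0.003, 0.42, 0.066),
    site_start = 28, site_id = c("s1", "lab", "s2")
  )
  expect_identical(
    out$predicted_ctmax,
    dynamic_knockdown(p, rep(28, 3), c(0.003, 0.42, 0.066))
  )
  # habitat rates give lower predicted CTmax than the laboratory ramp
  expect_true(all(out$predicted_ctmax[c(1, 3)] < out$predicted_ctmax[2]))
  expect_named(out, c("site_id", "heating_rate", "start_temp", "predicted_ctmax"))
})

test_that("tolerable times decrease strictly across ascending bands", {
  p <- tdt_params(z = 5.58, t_static = 45.6)
  tab <- tolerable_times_by_band(p, 32:36)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$band_mid, c(32.5, 33.5, 34.5, 35.5))
  expect_true(all(diff(tab$tolerable_min) < 0))
})
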