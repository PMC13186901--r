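# Pulse tests run around the tube-law reference state (p_ref = operating
# pressure) so the analytic reference wave speed applies exactly.

gaussian_pulse <- function(amplitude = 4e-6, center = 0.1, width = 0.015,
                           period = 0.8, n = 1024) {
  t <- (0:(n - 1)) / n * period
  list(time = t, flow = amplitude * exp(-(t - center)^2 / (2 * width^2)),
       period = period)
}

test_that("pulse transit speed matches the Moens-Korteweg prediction", {
  net <- make_tube_network(length = 1, split = TRUE)
  num <- numerics_config(target_dx = 0.005, n_out = 1000, max_cycles = 4,
                         periodicity_tolerance = 1e-4, p_ref = 0,
                         venous_pressure = 0)
  sw <- simulate_subject(net, gaussian_pulse(), num,
                         locations = c("tube_a", "tube_b"))
  fa <- phase_features(sw$time, sw$waves$tube_a$pressure)
  fb <- phase_features(sw$time, sw$waves$tube_b$pressure)
  c_transit <- 0.5 / (fb$t_b - fa$t_b) # midpoints are 0.5 m apart
  c0 <- sqrt(4e5 * 0.75e-3 / (2 * 1060 * 5e-3))
  expect_equal(c_transit, c0, tolerance = 0.02)
  # instantaneous tube-law wave speed agrees with the transit estimate
  expect_equal(max(sw$waves$tube_a$wave_speed), c_transit, tolerance = 0.02)
})

test_that("tube-law wave speed series follows its closed forms", {
  a0 <- pi * (4e-3)^2
  cs <- wave_speed_series(rep(a0, 5), 4e-3, 0.6e-3, 5e5)
  expect_equal(cs, rep(sqrt(5e5 * 0.6e-3 / (2 * 1060 * 4e-3)), 5),
               tolerance = 1e-12)
  # doubling the modulus scales c by sqrt(2) at fixed geometry
  expect_equal(wave_speed_series(a0, 4e-3, 0.6e-3, 1e6),
               sqrt(2) * wave_speed_series(a0, 4e-3, 0.6e-3, 5e5),
               tolerance = 1e-12)
  expect_error(wave_speed_series(c(a0, -a0), 4e-3, 0.6e-3, 5e5), "positive")
})

test_that("steady inflow reproduces the resistive-network pressure", {
  co <- 8.83e-5
  inf0 <- list(time = seq(0, 0.8, length.out = 257)[-257],
               flow = rep(co, 256), period = 0.8)
  tube <- make_tube_network()
  rt <- oracle_tree_resistance(tube, 3.5e-3, 9)
  p_oracle <- 666.5 + co * rt
  z0 <- characteristic_impedance(5e-3, 0.75e-3, 4e5)
  p_mid <- 666.5 + co * (z0 + 1.5e8) + 0.5 * co * (rt - z0 - 1.5e8)
  sw <- simulate_subject(tube, inf0,
                         numerics_config(target_dx = 0.005, max_cycles = 16,
                                         periodicity_tolerance = 1e-8,
                                         p_ref = p_mid),
                         locations = "tube")
  expect_equal(mean(sw$inlet_pressure), p_oracle, tolerance = 0.005)
})

test_that("matched proximal terminal resistance is nearly reflection free", {
  net <- make_tube_network(length = 1, R2 = 1e9, C = 1e-8)
  num <- numerics_config(target_dx = 0.005, n_out = 1000, max_cycles = 4,
                         periodicity_tolerance = 1e-4, p_ref = 0,
                         venous_pressure = 0)
  sw <- simulate_subject(net, gaussian_pulse(), num, locations = "tube")
  c0 <- sqrt(4e5 * 0.75e-3 / (2 * 1060 * 5e-3))
  p <- sw$waves$tube$pressure
  u <- sw$waves$tube$velocity
  # linear wave splitting around the quiescent state
  p_fwd <- (p - p[1] + 1060 * c0 * (u - u[1])) / 2
  p_bwd <- (p - p[1] - 1060 * c0 * (u - u[1])) / 2
  expect_lt(max(abs(p_bwd)) / max(abs(p_fwd)), 0.05)
})

test_that("halving the grid changes systolic inlet pressure by under 1%", {
  tube <- make_tube_network()
  sbp <- vapply(c(0.02, 0.01), function(dx) {
    sw <- simulate_subject(tube, aortic_inflow(9e-5),
                           numerics_config(target_dx = dx, max_cycles = 12,
                                           periodicity_tolerance = 1e-5),
                           locations = "tube")
    max(sw$inlet_pressure)
  }, 0)
  expect_lt(abs(sbp[2] - sbp[1]) / sbp[2], 0.01)
})

test_that("converged network run satisfies conservation, periodicity and energy decay", {
  full <- reference_network()
  path <- c("aorta_asc", "thoracic_aorta_a", "abdominal_aorta_c", "renal_r",
            "renal_r_seg1", "renal_r_seg1_il1", "renal_r_seg1_il1_arc1")
  num <- numerics_config(target_dx = 0.02, min_cells = 1, max_cycles = 25,
                         periodicity_tolerance = 1e-6)
  sw <- simulate_subject(full, aortic_inflow(8.8e-5), num,
                         locations = c(path, "abdominal_aorta_d"))
  expect_true(sw$converged)
  expect_lt(utils::tail(sw$residuals, 1), 1e-6)
  # cycle-mean junction balance at the abdominal renal take-off; bounded
  # by the ghost-cell junction closure of the scheme (measured ~1e-4)
  qp <- mean(sw$waves$abdominal_aorta_c$flow)
  qc <- mean(sw$waves$renal_r$flow) + mean(sw$waves$abdominal_aorta_d$flow)
  expect_lt(abs(qp - qc) / qp, 1e-3)
  # flow equals velocity times area pointwise (definition of velocity)
  w <- sw$waves$renal_r
  expect_equal(w$flow, w$velocity * w$area, tolerance = 1e-12)
  # time-averaged pressure decreases monotonically from inlet to terminal
  mp <- vapply(path, function(id) mean(sw$waves[[id]]$pressure), 0)
  expect_true(all(diff(mp) < 0))
})

test_that("solver failures and bad locations are reported", {
  tube <- make_tube_network()
  expect_error(
    simulate_subject(tube, aortic_inflow(9e-5), locations = "nonesuch"),
    "unknown waveform location")
})
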