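make_cycle <- function(f, n = 200, period = 0.8) {
  t <- (0:(n - 1)) / n * period
  list(time = t, values = f(t))
}

test_that("phase features recover closed-form template values", {
  # squared sine: peak 1 at T/2, cycle mean exactly one half
  w <- make_cycle(function(t) sin(pi * t / 0.8)^2)
  f <- phase_features(w$time, w$values)
  expect_equal(f$Y_PS, max(w$values))
  expect_equal(f$t_PS, 0.4, tolerance = 0.8 / 200)
  expect_equal(f$Y_mean, 0.5, tolerance = 1e-12)
  # constant series: flat flag, degenerate features
  fc <- phase_features(w$time, rep(3.2, 200))
  expect_true(fc$flat)
  expect_identical(fc$Y_PS, 3.2)
  expect_identical(fc$Y_ED, 3.2)
  expect_true(is.na(fc$t_b))
  expect_true(is.na(systolic_acceleration_slope(fc)))
  # two-Gaussian surrogate template: known peak position
  tpl <- make_cycle(function(t) 0.1 + renaltwin:::.surrogate_template(t, 0.8))
  ft <- phase_features(tpl$time, tpl$values)
  expect_equal(ft$t_PS, 0.16 * 0.8, tolerance = 1.1 * 0.8 / 200)
})

test_that("index formulas evaluate exactly and satisfy their identities", {
  expect_equal(resistive_index(1.00, 0.30), 0.70)
  expect_equal(resistive_index(0.8, 0.8), 0)
  expect_error(resistive_index(0, 0.1), "V_PSV")
  expect_equal(pulsatility_index(1.00, 0.30, 0.55), 0.7 / 0.55)
  expect_equal(pulsatility_index(0.5, 0.5, 0.4), 0)
  expect_error(pulsatility_index(1, 0.2, 0), "V_Mean")
  set.seed(7)
  for (k in 1:50) {
    v_ps <- runif(1, 0.5, 2)
    v_ed <- runif(1, 0, v_ps)
    v_mn <- runif(1, v_ed, v_ps)
    ri <- resistive_index(v_ps, v_ed)
    pi_ <- pulsatility_index(v_ps, v_ed, v_mn)
    # PI = RI * V_PSV / V_Mean, exactly
    expect_equal(pi_, ri * v_ps / v_mn, tolerance = 1e-14)
    expect_gte(ri, 0); expect_lte(ri, 1)
    expect_gte(pi_, ri)
  }
})

test_that("slope formulas are direct substitutions", {
  f <- list(Y_PS = 10, Y_b = 2, t_PS = 0.20, t_b = 0.05,
            Y_ED = 2, t_ED = 0.9, flat = FALSE)
  expect_equal(systolic_acceleration_slope(f), 8 / 0.15)
  expect_equal(diastolic_deceleration_slope(f), 8 / (0.2 - 0.9))
  f0 <- f; f0$Y_b <- 10; f0$Y_ED <- 10
  expect_equal(systolic_acceleration_slope(f0), 0)
  expect_equal(diastolic_deceleration_slope(f0), 0)
  fbad <- f; fbad$t_b <- f$t_PS
  expect_error(systolic_acceleration_slope(fbad), "degenerate")
  # deceleration slope equals the chord of a decay by construction
  w <- make_cycle(function(t) ifelse(t < 0.1, 10 * t / 0.1, exp(-3 * (t - 0.1))) * 2)
  ff <- phase_features(w$time, w$values)
  expect_equal(diastolic_deceleration_slope(ff),
               (ff$Y_PS - ff$Y_ED) / (ff$t_PS - ff$t_ED), tolerance = 1e-12)
})

test_that("panel extraction yields the full vocabulary with correct invariances", {
  surr <- generate_surrogate(surrogate_spec(n_per_class = 2, seed = 3))
  sw <- surr$subjects[[1]]
  panel <- biomarker_panel(sw)
  expect_equal(nrow(panel), 27 * 4 * 2) # 27 names x 4 locations x 2 sides
  expect_setequal(unique(panel$name), biomarker_names())
  expect_true(all(c("Diastolic PWV", "Diastolic Pressure", "Diastolic Area")
                  %in% panel$name))
  expect_true(all(is.finite(panel$value)))
  # circular shift of the cycle start leaves phase values unchanged
  shift <- function(x, k) c(x[(k + 1):length(x)], x[1:k])
  sw_s <- sw
  for (id in names(sw_s$waves)) {
    sw_s$waves[[id]] <- lapply(sw_s$waves[[id]], shift, k = 57)
  }
  p2 <- biomarker_panel(sw_s)
  phase_rows <- grepl("^(Systolic|Diastolic|Mean)|^(RI|PI)$", panel$name)
  expect_equal(p2$value[phase_rows], panel$value[phase_rows],
               tolerance = 1e-9)
  # slopes re-detect the foot; agree to one sample step's effect
  expect_equal(p2$value[!phase_rows], panel$value[!phase_rows],
               tolerance = 0.05)
  # scaling a waveform by k scales phase values and slopes by k and
  # leaves RI and PI unchanged
  sw_k <- sw
  for (id in names(sw_k$waves)) {
    sw_k$waves[[id]]$velocity <- sw_k$waves[[id]]$velocity * 3
  }
  p3 <- biomarker_panel(sw_k)
  vel <- grepl("Velocity$", panel$name)
  expect_equal(p3$value[vel], 3 * panel$value[vel], tolerance = 1e-12)
  idx <- panel$name %in% c("RI", "PI")
  expect_equal(p3$value[idx], panel$value[idx], tolerance = 1e-12)
  # constant waveform: zero indices and zero slopes in the panel
  sw_c <- sw
  for (id in names(sw_c$waves)) {
    sw_c$waves[[id]]$velocity <- rep(0.4, length(sw_c$waves[[id]]$velocity))
  }
  p4 <- biomarker_panel(sw_c)
  expect_equal(p4$value[p4$name %in% c("RI", "PI")], rep(0, 16))
  expect_equal(p4$value[p4$name %in% c("Acceleration Velocity",
                                       "Deceleration Velocity")],
               rep(0, 16))
})

test_that("missing renal generations are reported", {
  surr <- generate_surrogate(surrogate_spec(n_per_class = 2, seed = 3))
  sw <- surr$subjects[[1]]
  sw$waves <- sw$waves[!grepl("^renal_l$", names(sw$waves))]
  expect_error(biomarker_panel(sw), "left main")
})
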