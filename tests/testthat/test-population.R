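tb <- normalization_tables()

test_that("reference subjects combine sex and age factors with exact anchors", {
  m <- build_reference_subject("male", "20-29", tb)
  f <- build_reference_subject("female", "20-29", tb)
  # the renal peripheral-resistance sex anchors are exact
  expect_identical(m$factors[["pvr_renal"]], 0.85)
  expect_identical(f$factors[["pvr_renal"]], 1.15)
  # factors multiply across sex and age
  m5 <- build_reference_subject("male", "50-59", tb)
  expect_equal(m5$factors[["pvr_renal"]],
               0.85 * tb$age["50-59", "pvr_renal"], tolerance = 1e-14)
  expect_error(build_reference_subject("male", "15-19", tb), "age group")
})

test_that("subject sampling is seeded, truncated and centred", {
  net <- reference_network()
  ref <- build_reference_subject("male", "50-59", tb)
  a <- sample_virtual_subject(ref, net, tb$sds, 42)
  b <- sample_virtual_subject(ref, net, tb$sds, 42)
  expect_identical(a, b)
  c2 <- sample_virtual_subject(ref, net, tb$sds, 43)
  expect_false(identical(a$vessel_noise, c2$vessel_noise))
  # zero SDs reproduce the reference exactly
  z <- sample_virtual_subject(ref, net, tb$sds * 0, 42)
  expect_true(all(z$vessel_noise$radius == 1))
  expect_identical(z$global_noise[["cardiac_output"]], 1)
  # noise is unit-centred: per-vessel radius draws across one subject
  # (145 iid draws) stay within the CLT band
  cv <- tb$sds[["radius"]]
  expect_lt(abs(mean(a$vessel_noise$radius) - 1), 4 * cv / sqrt(145))
  # truncation floor
  wild <- sample_virtual_subject(ref, net,
                                 stats::setNames(rep(3, 9), names(tb$sds)),
                                 7)
  expect_gte(min(wild$vessel_noise$radius), 0.2)
})

test_that("disease columns multiply onto subjects along legal transitions", {
  ref <- build_reference_subject("male", "20-29", tb)
  dm <- apply_disease(ref, "dm_htn", tb)
  expect_equal(dm$factors[["cardiac_output"]],
               ref$factors[["cardiac_output"]] * 0.83, tolerance = 1e-14)
  expect_equal(dm$factors[["viscosity"]],
               ref$factors[["viscosity"]] * 1.20, tolerance = 1e-14)
  expect_equal(dm$factors[["pvr_renal"]],
               ref$factors[["pvr_renal"]] * 1.17, tolerance = 1e-14)
  # kidney-disease renal resistance: 1.17 then the extra 10% gives 1.287,
  # printed as 1.29
  hkd <- apply_disease(dm, "hkd", tb)
  expect_equal(hkd$factors[["pvr_renal"]] / ref$factors[["pvr_renal"]],
               1.29, tolerance = 1e-14)
  expect_equal(round(1.17 * 1.10, 2), 1.29)
  dkd <- apply_disease(dm, "dkd", tb)
  expect_equal(dkd$factors[["pvr_renal"]] / ref$factors[["pvr_renal"]],
               1.35, tolerance = 1e-14)
  # systemic block identical across the three disease states
  expect_equal(dkd$factors[["pvr_systemic"]], hkd$factors[["pvr_systemic"]])
  expect_error(apply_disease(ref, "dkd", tb), "illegal disease transition")
  expect_error(apply_disease(dkd, "hkd", tb), "illegal disease transition")
})

test_that("disease pairing preserves the shared sampled draws", {
  net <- reference_network()
  ref <- build_reference_subject("female", "40-49", tb)
  subj <- sample_virtual_subject(ref, net, tb$sds, 99)
  dm <- apply_disease(subj, "dm_htn", tb)
  dkd <- apply_disease(dm, "dkd", tb)
  hkd <- apply_disease(dm, "hkd", tb)
  expect_identical(dkd$vessel_noise, hkd$vessel_noise)
  expect_identical(dkd$terminal_noise, hkd$terminal_noise)
  expect_identical(dkd$global_noise, hkd$global_noise)
})

test_that("the physiological filter applies the 99% band and RI interval", {
  crit <- tb$filter
  mid <- list(sbp = crit$sbp_mean["male", "50-59"],
              dbp = crit$dbp_mean["male", "50-59"], ri = 0.65)
  expect_true(physiological_filter(mid, "male", "50-59", crit)$keep)
  hi <- mid; hi$sbp <- mid$sbp + 3 * crit$sbp_sd
  f <- physiological_filter(hi, "male", "50-59", crit)
  expect_false(f$keep)
  expect_identical(f$reasons, "SBP")
  # z = 2.5 is inside the 2.575 band
  ok <- mid; ok$sbp <- mid$sbp + 2.5 * crit$sbp_sd
  expect_true(physiological_filter(ok, "male", "50-59", crit)$keep)
  ri_hi <- mid; ri_hi$ri <- crit$ri_interval[2] + 0.01
  f2 <- physiological_filter(ri_hi, "male", "50-59", crit)
  expect_false(f2$keep)
  expect_identical(f2$reasons, "RI")
  # monotone in the threshold: widening the band never drops a kept subject
  crit_wide <- crit; crit_wide$z_threshold <- 3.5
  set.seed(3)
  for (k in 1:50) {
    s <- list(sbp = rnorm(1, 138, 30), dbp = rnorm(1, 81, 20),
              ri = runif(1, 0.4, 0.9))
    if (physiological_filter(s, "male", "50-59", crit)$keep) {
      expect_true(physiological_filter(s, "male", "50-59", crit_wide)$keep)
    }
  }
})

test_that("subject beds track the renal resistance factor and disease edits", {
  ref <- build_reference_subject("male", "20-29", tb)
  b0 <- subject_bed(ref)
  base <- bed_equivalent_resistance(microvascular_bed())
  expect_equal(bed_equivalent_resistance(b0), 0.85 * base, tolerance = 1e-10)
  dm <- apply_disease(ref, "dm_htn", tb)
  bdm <- subject_bed(dm)
  expect_equal(bed_equivalent_resistance(bdm), 0.85 * 1.17 * base,
               tolerance = 1e-10)
  # hypertensive kidney: interlobular constriction delivers +10% over the
  # systemic-disease baseline
  bh <- subject_bed(apply_disease(dm, "hkd", tb))
  expect_equal(bed_equivalent_resistance(bh) / bed_equivalent_resistance(bdm),
               1.10, tolerance = 1e-5)
  # diabetic kidney: mechanistic chain lands near the printed 1.35 column
  bd <- subject_bed(apply_disease(dm, "dkd", tb))
  expect_equal(bed_equivalent_resistance(bd) / bed_equivalent_resistance(bdm),
               1.357, tolerance = 0.01)
  # filtration fraction rises under the diabetic arteriolar changes
  g_dm <- compute_gfr(bdm, 12000)
  g_dk <- compute_gfr(bd, 12000)
  expect_gt(g_dk$filtration_fraction, g_dm$filtration_fraction)
})
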