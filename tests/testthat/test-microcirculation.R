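test_that("Hagen-Poiseuille resistance matches direct evaluation and scaling laws", {
  # interlobular arteriole geometry: frozen value from 8*mu*L/(pi*r^4)
  expect_equal(poiseuille_resistance(4.00e-3, 370e-6, 22.9e-6),
               1.3704e13, tolerance = 1e-3)
  # renal tubule (plasma viscosity)
  expect_equal(poiseuille_resistance(2.00e-3, 18000e-6, 16.4e-6),
               1.2675e15, tolerance = 1e-3)
  expect_identical(poiseuille_resistance(3e-3, 0, 1e-5), 0)
  # radius^-4: halving the radius multiplies resistance by exactly 16
  r <- 1.3e-5
  expect_identical(poiseuille_resistance(3e-3, 1e-3, r / 2),
                   16 * poiseuille_resistance(3e-3, 1e-3, r))
  expect_error(poiseuille_resistance(0, 1, 1), "viscosity")
  expect_error(poiseuille_resistance(1e-3, 1, -1), "radius")
})

test_that("nephron nodal solve conserves flow and reduces limiting cases", {
  circ <- nephron_circuit()
  sol <- solve_nephron(circ, 12000, 600)
  f <- sol$branch_flows
  # Kirchhoff at each node, relative to the inlet flow
  tol <- 1e-10 * f[["afferent"]]
  expect_lt(abs(f[["afferent"]] - f[["glomerular_capillary"]] -
                  f[["glomerular_filter"]]), tol)
  expect_lt(abs(f[["glomerular_filter"]] - f[["reabsorption"]] -
                  f[["ureter"]]), tol)
  expect_lt(abs(f[["efferent"]] + f[["reabsorption"]] -
                  f[["peritubular_capillary"]]), tol)
  expect_lt(abs(f[["afferent"]] - f[["peritubular_capillary"]] -
                  f[["ureter"]]), tol)
  # disconnected filtrate limb: pure series chain, zero filtration
  comp <- circ$components
  comp[["glomerular_filter"]] <- Inf
  comp[["reabsorption"]] <- Inf
  sol2 <- solve_nephron(nephron_circuit(comp), 1000, 0)
  expect_identical(sol2$filtration_flow, 0)
  series <- comp[["afferent"]] + comp[["glomerular_capillary"]] +
    comp[["efferent"]] + comp[["peritubular_capillary"]]
  expect_equal(sol2$equivalent_resistance, series, tolerance = 1e-12)
  # two-resistor Ohm's law through the same path
  comp3 <- comp
  comp3[c("afferent", "glomerular_capillary", "efferent",
          "peritubular_capillary")] <- c(1e12, 1, 1e12, 1)
  sol3 <- solve_nephron(nephron_circuit(comp3), 1, 0)
  expect_equal(sol3$branch_flows[["afferent"]], 5e-13, tolerance = 1e-9)
  expect_error(solve_nephron(circ, 1, 2), "exceed")
})

test_that("printed nephron-block and bed resistances are reproduced", {
  bed <- microvascular_bed()
  expect_equal(nephron_block_resistance(bed), 4.40e12, tolerance = 0.02)
  expect_equal(bed_equivalent_resistance(bed), 2.80e10, tolerance = 0.02)
  # degenerate counts: exact series sum
  bed1 <- microvascular_bed(n_interlobular_per_arcuate = 1,
                            n_nephrons_per_interlobular = 1)
  single <- solve_nephron(bed1$nephron, 1, 0)$equivalent_resistance
  expect_equal(bed_equivalent_resistance(bed1),
               bed1$interlobular_resistance + single, tolerance = 1e-12)
})

test_that("hierarchical reduction equals brute-force expanded nodal solve", {
  comp <- nephron_components()
  for (cfg in list(c(1, 1), c(3, 2), c(5, 3))) {
    bed <- microvascular_bed(n_interlobular_per_arcuate = cfg[1],
                             n_nephrons_per_interlobular = cfg[2])
    brute <- oracle_bed_resistance(comp, bed$interlobular_resistance,
                                   cfg[1], cfg[2])
    expect_equal(bed_equivalent_resistance(bed), brute, tolerance = 1e-9)
  }
})

test_that("equivalent resistance is monotone in every component resistance", {
  set.seed(42)
  base <- nephron_components()
  for (k in 1:100) {
    comp <- base * exp(stats::rnorm(length(base), 0, 0.5))
    names(comp) <- names(base)
    r0 <- solve_nephron(nephron_circuit(comp), 1, 0)$equivalent_resistance
    j <- sample(names(comp), 1)
    comp2 <- comp
    comp2[[j]] <- comp2[[j]] * 1.05
    r1 <- solve_nephron(nephron_circuit(comp2), 1, 0)$equivalent_resistance
    expect_gte(r1, r0 * (1 - 1e-12))
  }
})

test_that("diabetic arteriolar edits behave as radius^-4 rescalings", {
  bed <- microvascular_bed()
  r0 <- bed_equivalent_resistance(bed)
  # identity
  expect_equal(bed_equivalent_resistance(apply_dkd_arterioles(bed, 1, 1)),
               r0, tolerance = 1e-14)
  # afferent dilation alone strictly decreases resistance
  expect_lt(bed_equivalent_resistance(apply_dkd_arterioles(bed, 1.10, 1)), r0)
  # component changes are exactly radius^-4
  b2 <- apply_dkd_arterioles(bed, 1.10, 0.93)
  expect_equal(b2$nephron$components[["afferent"]],
               bed$nephron$components[["afferent"]] / 1.10^4,
               tolerance = 1e-14)
  expect_equal(b2$nephron$components[["efferent"]],
               bed$nephron$components[["efferent"]] / 0.93^4,
               tolerance = 1e-14)
  # commutes with nephron loss (disjoint multiplicative actions)
  a <- apply_nephron_loss(apply_dkd_arterioles(bed, 1.1, 0.93), 0.43)
  b <- apply_dkd_arterioles(apply_nephron_loss(bed, 0.43), 1.1, 0.93)
  expect_equal(bed_equivalent_resistance(a), bed_equivalent_resistance(b),
               tolerance = 1e-14)
})

test_that("nephron loss scales the parallel block reciprocally", {
  bed <- microvascular_bed()
  expect_equal(nephron_block_resistance(apply_nephron_loss(bed, 0.5)),
               2 * nephron_block_resistance(bed), tolerance = 1e-14)
  expect_equal(nephron_block_resistance(apply_nephron_loss(bed, 0.43)),
               nephron_block_resistance(bed) / 0.43, tolerance = 1e-14)
  expect_error(apply_nephron_loss(bed, 0), "surviving_fraction")
  # identity
  expect_equal(bed_equivalent_resistance(apply_nephron_loss(bed, 1)),
               bed_equivalent_resistance(bed), tolerance = 1e-14)
})

test_that("interlobular constriction solve reproduces a target PVR ratio", {
  bed <- microvascular_bed()
  expect_identical(solve_hkd_interlobular_scale(bed, 1.0), 1.0)
  s <- solve_hkd_interlobular_scale(bed, 1.10)
  expect_lt(s, 1)
  b2 <- apply_interlobular_scale(bed, s)
  expect_equal(bed_equivalent_resistance(b2) / bed_equivalent_resistance(bed),
               1.10, tolerance = 1e-6)
  # tiny interlobular share cannot deliver a doubling
  bed_small <- microvascular_bed(interlobular_resistance = 1e9)
  expect_error(solve_hkd_interlobular_scale(bed_small, 2.0), "unreachable")
})

test_that("filtration computation covers degenerate and symmetric circuits", {
  comp <- nephron_components()
  comp[["glomerular_filter"]] <- Inf
  bed0 <- microvascular_bed(nephron_circuit(comp))
  g0 <- compute_gfr(bed0, 12000)
  expect_identical(g0$gfr, 0)
  expect_identical(g0$filtration_fraction, 0)
  # symmetric branches: blood path resistance equals filtrate path, exits
  # matched, cross-branch blocked -> filtration fraction exactly one half
  comp2 <- nephron_components()
  comp2[["glomerular_capillary"]] <- 5e13
  comp2[["efferent"]] <- 5e13
  comp2[["glomerular_filter"]] <- 5e13
  comp2[["renal_tubule"]] <- 5e13
  comp2[["reabsorption"]] <- Inf
  comp2[["ureter"]] <- 2e13
  comp2[["peritubular_capillary"]] <- 2e13
  sol <- solve_nephron(nephron_circuit(comp2), 900, 0)
  expect_equal(sol$filtration_fraction, 0.5, tolerance = 1e-12)
})
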