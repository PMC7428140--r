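test_that("renal excretion law: branch values, continuity, corrected slope", {
  # sub-threshold branch on its closure at the 460 mg/dl threshold
  expect_equal(rate_kidney_glucose_excretion(460, P, branch = "sub460"), 71)
  # printed sub-branch at zero glucose: 71 (1 + tanh(-5.06))
  expect_equal(rate_kidney_glucose_excretion(0, P),
               71 * (1 + tanh(0.011 * (0 - 460))), tolerance = 1e-12)
  expect_lt(rate_kidney_glucose_excretion(0, P), 0.006)
  # linear branch by direct evaluation
  expect_equal(rate_kidney_glucose_excretion(1000, P), -330 + 0.872 * 1000)
  # corrected 0.011 factor, never 0.11: the erroneous slope saturates the
  # law far below threshold, suppressing sub-threshold excretion
  wrong <- 71 + 71 * tanh(0.11 * (400 - 460))
  expect_gt(abs(rate_kidney_glucose_excretion(400, P) - wrong), 10)
  # branch continuity across the threshold
  expect_lt(abs(rate_kidney_glucose_excretion(460 - 1e-9, P) -
                  rate_kidney_glucose_excretion(460, P)), 0.2)
  expect_error(rate_kidney_glucose_excretion(-1, P), "non-negative")
})

test_that("peripheral uptake multiplier and rate match the printed law", {
  expect_equal(m_pgu_insulin(5.82, P), 7.03)
  expect_equal(peripheral_glucose_uptake(5.82, 1, P), 7.03 * 35)
  expect_equal(peripheral_glucose_uptake(5.82, 0, P), 0)
  expect_equal(peripheral_glucose_uptake(1, 1, P),
               35 * (7.03 + 6.52 * tanh(0.338 * (1 - 5.82))),
               tolerance = 1e-12)
  expect_error(peripheral_glucose_uptake(-1, 1, P), "non-negative")
})

test_that("hepatic production/uptake midpoints and basal closure", {
  expect_equal(m_hgp_glucose(0.497, P), 1.42)
  expect_equal(m_hgu_glucose(1.48, P), 5.66)
  # production at the glucose-law center with unit insulin multiplier and
  # a glucagon term constructed to be exactly 1
  gam_n <- atanh(1 / 2.7) / 0.39   # 2.7 tanh(0.39 x) = 1
  r <- hepatic_rates(1, 0, gam_n, 0.497, 1, P)
  expect_equal(r$r_HGP, 1.42 * 155, tolerance = 1e-12)
  r2 <- hepatic_rates(1, 0, gam_n, 1.48, 1, P)
  expect_equal(r2$r_HGU, 5.66 * 20, tolerance = 1e-12)
  # all multipliers exactly 1 reproduces the basal production
  gl_n <- 0.497  # M_HGP_G = 1.42 here, so solve for M^G = 1 instead:
  gl1 <- 0.497 + atanh((1.42 - 1) / 1.41) / 0.62
  expect_equal(hepatic_rates(1, 0, gam_n, gl1, 1, P)$r_HGP, 155,
               tolerance = 1e-9)
})

test_that("regulatory relaxation targets and fixed points", {
  d <- regulatory_derivatives(1, 1, 0, I_L_N = 0.89, Gamma_N = 1, P)
  expect_equal(unname(d["dM_HGP_I"]), (1.21 - 1) / 25, tolerance = 1e-12)
  expect_equal(m_hgp_insulin_inf(0.89, P), 1.21)
  expect_equal(m_hgu_insulin_inf(0, P), 0)
  # fixed point: derivative vanishes when the state equals its target
  tgt <- m_hgp_insulin_inf(1.3, P)
  expect_equal(unname(regulatory_derivatives(tgt, 1, 0, 1.3, 1, P)["dM_HGP_I"]), 0)
  f2_star <- (m_hgp_glucagon0(1, P) - 1) / 2
  expect_equal(unname(regulatory_derivatives(1, 1, f2_star, 1, 1, P)["df2"]), 0)
})

test_that("pancreatic secretion: zero glucose, inhibitor boundary, basal ratio", {
  s0 <- pancreas_secretion(0, list(P = 0.1, I = 0.2, Q = 5), P)
  expect_equal(s0$X, 0)
  expect_equal(s0$S, 0)
  # at X = I the early-phase term vanishes
  sb <- pancreas_secretion(B$ref$G_HB, list(P = B$pancreas$P,
                                            I = B$pancreas$X,
                                            Q = B$pancreas$Q), P)
  expect_equal(sb$S, P$M1 * sb$Y * B$pancreas$Q, tolerance = 1e-12)
  # basal ratio: S(G_HB) equals the stored basal secretion
  expect_equal(sb$S, B$S_B, tolerance = 1e-12)
  expect_error(pancreas_secretion(-5, list(P = 0, I = 0, Q = 1), P), "G_H")
  # corrected labile-pool sign: at Q below Q0 the turnover term refills
  d <- pancreas_derivatives(B$ref$G_HB, B$pancreas$P, B$pancreas$X,
                            P$Q0 / 2, P)
  expect_gt(P$K * (P$Q0 - P$Q0 / 2), 0)
  expect_gt(d$dQ, pancreas_derivatives(B$ref$G_HB, B$pancreas$P,
                                       B$pancreas$X, P$Q0, P)$dQ)
})

test_that("insulin clearances use the corrected arterial kidney term", {
  cl <- insulin_clearances(I_H = 10, I_J = 0, I_PI = 0, r_PIR = 0, P)
  expect_equal(cl$r_KIC, 0.30 * 0.72 * 10)
  expect_equal(insulin_clearances(0, 0, 0, 0, P)$r_LIC, 0)
  # peripheral clearance balances basal peripheral insulin delivery
  clb <- insulin_clearances(B$ref$I_HB, B$ref$I_JB, B$ref$I_PIB,
                            B$r_PIRB, P)
  expect_equal(clb$r_PIC, P$Q_PI * (B$ref$I_HB - B$ref$I_PVB),
               tolerance = 1e-10)
})

test_that("glucagon multipliers and basal equilibrium closure", {
  expect_equal(m_pgr_glucose(0.61, P), 2.93)
  expect_equal(m_pgr_insulin(0.47, P), 1.31)
  g <- glucagon_rates(1, 1, 1, P)
  expect_equal(g$release, g$clearance, tolerance = 1e-12)
})

test_that("tanh multiplier laws are bounded and monotone as specified", {
  grid <- seq(0, 10, by = 0.01)
  expect_true(all(m_pgu_insulin(grid, P) >= 7.03 - 6.52 - 1e-12))
  expect_true(all(m_pgu_insulin(grid, P) <= 7.03 + 6.52 + 1e-12))
  expect_true(all(m_hgp_glucose(grid, P) >= 1.42 - 1.41 - 1e-12))
  expect_true(all(m_hgp_glucose(grid, P) <= 1.42 + 1.41 + 1e-12))
  expect_true(all(m_hgu_glucose(grid, P) <= 5.66 + 5.66 + 1e-12))
  expect_true(all(m_pgr_glucose(grid, P) <= 2.93 + 2.10 + 1e-12))
  expect_true(all(m_pgr_insulin(grid, P) >= 1.31 - 0.61 - 1e-12))
  # monotonicity on the grid
  expect_true(all(diff(m_pgu_insulin(grid, P)) >= 0))
  expect_true(all(diff(m_hgp_glucose(grid, P)) <= 0))
  expect_true(all(diff(m_pgr_glucose(grid, P)) <= 0))
})
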