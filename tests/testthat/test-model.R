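test_that("full derivative vector matches the term-by-term oracle", {
  set.seed(11)
  simo <- SP_FIT
  for (i in 1:100) {
    y <- random_feasible_state()
    ivg <- sample(c(0, 500), 1)
    ivi <- sample(c(0, 50), 1)
    d_pkg <- full_derivatives(y, P, B, simo, iv_glucose = ivg,
                              iv_insulin = ivi)
    d_or <- oracle_derivs(y, B$ref, B$S_B, B$r_PIRB, simo,
                          ivg = ivg, ivi = ivi)
    denom <- pmax(abs(d_or), 1e-6)
    expect_lt(max(abs(d_pkg - d_or[names(d_pkg)]) / denom), 1e-12)
  }
})

test_that("basal initialization: exact equilibrium and printed cascade", {
  expect_lt(B$max_abs_deriv, 1e-6)
  d <- full_derivatives(B$state, P, B, SP_FIT)
  expect_lt(max(abs(d)), 1e-6)
  # printed-IC mode reproduces the summary relations exactly
  expect_equal(B_paper$ref$G_KB, B_paper$ref$G_HB)
  expect_equal(unname(B_paper$state["f2"]), 0)
  expect_equal(unname(B_paper$state[c("M_HGP_I", "M_HGU_I")]), c(1, 1))
  # corrected heart insulin relation I_HB = I_PVB / (1 - F_PIC)
  expect_equal(B$ref$I_HB, 12.8 / 0.85, tolerance = 1e-12)
  # corrected peripheral glucose gradient uses peripheral (not brain) uptake
  expect_equal(B$ref$G_PIB, 89 - 35 * 5.0 / 67.4, tolerance = 1e-12)
  expect_equal(B$ref$G_HB, 89 + 35 / 15.1, tolerance = 1e-12)
})

test_that("erroneous summary forms diverge from the corrected ones", {
  ## regression fixtures proving the corrections matter
  # (C) kidney clearance driven by I_K instead of I_H breaks the cascade:
  # with the erroneous form the kidney balance would need
  # I_K = I_H/(1+F_KIC) rather than I_H (1-F_KIC)
  expect_gt(abs(B$ref$I_KB - B$ref$I_HB / (1 + P$F_KIC)), 0.1)
  # (E) brain-uptake-driven interstitial gradient differs from the
  # corrected peripheral-uptake-driven one
  wrong_GPIB <- 89 - 70 * 5.0 / 67.4
  expect_gt(abs(B$ref$G_PIB - wrong_GPIB), 2)
  # (D) the erroneous labile-pool sign K(Q - Q0) makes the basal pancreas
  # unstable: perturbing Q upward would grow Q without bound
  dq_wrong <- function(Q) P$K * (Q - P$Q0) + P$gamma * B$pancreas$P -
    (P$M1 * B$pancreas$Y) * Q
  expect_gt(dq_wrong(40), 0)        # runaway
  dq_right <- function(Q) P$K * (P$Q0 - Q) + P$gamma * B$pancreas$P -
    (P$M1 * B$pancreas$Y) * Q
  expect_lt(dq_right(40), 0)        # restoring
})

test_that("infeasible basal inputs raise named errors", {
  expect_error(basal_state(P, G_PVB = -1), "positive")
  # a tiny peripheral flow makes the computed interstitial insulin negative
  p_bad <- sorensen_params(V_PII = 0.5)
  expect_error(basal_state(p_bad), "I_PIB")
})

test_that("state validation identifies non-finite components", {
  y <- B$state
  y[["G_L"]] <- NaN
  expect_error(full_derivatives(y, P, B, SP_FIT), "G_L")
})

test_that("pure flow-balance compartments scale inversely with volume", {
  y <- random_feasible_state()
  d1 <- full_derivatives(y, P, B, SP_FIT)
  p2 <- sorensen_params(V_HG = 2 * P$V_HG, V_KG = 2 * P$V_KG)
  d2 <- full_derivatives(y, p2, B, SP_FIT)
  expect_equal(unname(d2[c("G_H", "G_K")]), unname(d1[c("G_H", "G_K")]) / 2,
               tolerance = 1e-12)
})

test_that("a 180-minute unperturbed run holds the basal state", {
  sim <- run_protocol(protocol("none", duration = 180), P, SP_FIT, basal = B)
  for (nm in sorensen_state_names()[1:22]) {
    ref <- B$state[[nm]]
    expect_lt(max(abs(sim[[nm]] - ref)) / max(abs(ref), 1e-9), 0.01)
  }
})
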