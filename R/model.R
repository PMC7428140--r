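## Full coupled right-hand side of the whole-body model: 8 glucose + 7
## insulin + 1 glucagon + 3 regulatory + 3 pancreas + 4 gut states.

.state_names <- c("G_BV", "G_BI", "G_H", "G_J", "G_L", "G_K", "G_PV", "G_PI",
                  "I_B", "I_H", "I_J", "I_L", "I_K", "I_PV", "I_PI",
                  "Gamma", "M_HGP_I", "M_HGU_I", "f2",
                  "P", "I_inh", "Q",
                  "S_sto", "J_jej", "R_del", "L_ile")

#' State variable names of the whole-body model
#'
#' Eight glucose compartments (mg/dl), seven insulin compartments (mU/l),
#' normalized glucagon, three slow hepatic regulatory states, three
#' pancreatic secretion states (labile insulin \code{Q} in U) and the four
#' gut transit compartments (mg).
#'
#' @return character vector of length 26.
#' @export
sorensen_state_names <- function() .state_names

## Fast closure building the RHS with all constants bound locally.
## iv_glucose in mg/min and iv_insulin in mU/min are constant over the
## closure's lifetime (piecewise-constant inputs are handled by integrating
## segment by segment).
make_rhs <- function(p, basal, simo, iv_glucose = 0, iv_insulin = 0) {
  ref <- basal$ref
  # normalization references
  G_HB <- ref$G_HB; G_LB <- ref$G_LB; G_PIB <- ref$G_PIB
  I_HB <- ref$I_HB; I_LB <- ref$I_LB; I_PIB <- ref$I_PIB
  S_B <- basal$S_B; r_PIRB <- basal$r_PIRB
  # rate-law coefficients
  cpg <- p$c_pgu_i; chi <- p$c_hgp_i; chg0 <- p$c_hgp_g0; chg <- p$c_hgp_g
  cui <- p$c_hgu_i; cug <- p$c_hgu_g; ckg <- p$c_kge
  cgg <- p$c_pgr_g; cgi <- p$c_pgr_i
  kGam <- p$r_MGammaC / p$V_Gamma
  rB_gam <- kGam / ((cgg[["a"]] + cgg[["b"]] * tanh(cgg[["c"]] * (1 - cgg[["d"]]))) *
                      (cgi[["a"]] + cgi[["b"]] * tanh(cgi[["c"]] * (1 - cgi[["d"]]))))
  rpic_den <- (1 - p$F_PIC) / (p$F_PIC * p$Q_PI) - p$T_PI / p$V_PII
  gsc <- p$pancreas_glucose_scale
  b1 <- p$beta_pir1; b2b1 <- p$beta_pir2^p$beta_pir1
  b3 <- p$beta_pir3; b4 <- p$beta_pir4; b5 <- p$beta_pir5
  # hoist every parameter field out of the list: the closure is on the
  # integrator's hot path
  V_BVG <- p$V_BVG; V_BIG <- p$V_BIG; V_HG <- p$V_HG; V_LG <- p$V_LG
  V_JG <- p$V_JG; V_KG <- p$V_KG; V_PVG <- p$V_PVG; V_PIG <- p$V_PIG
  Q_BG <- p$Q_BG; Q_HG <- p$Q_HG; Q_AG <- p$Q_AG; Q_LG <- p$Q_LG
  Q_JG <- p$Q_JG; Q_KG <- p$Q_KG; Q_PG <- p$Q_PG
  T_B <- p$T_B; T_PG <- p$T_PG
  V_BI <- p$V_BI; V_HI <- p$V_HI; V_JI <- p$V_JI; V_LI <- p$V_LI
  V_KI <- p$V_KI; V_PVI <- p$V_PVI; V_PII <- p$V_PII
  Q_BI <- p$Q_BI; Q_HI <- p$Q_HI; Q_AI <- p$Q_AI; Q_KI <- p$Q_KI
  Q_PI <- p$Q_PI; Q_JI <- p$Q_JI; Q_LI <- p$Q_LI; T_PI <- p$T_PI
  F_LIC <- p$F_LIC; F_KIC <- p$F_KIC
  r_BGU <- p$r_BGU; r_RBCU <- p$r_RBCU; r_JGU <- p$r_JGU
  r_PGU_B <- p$r_PGU_B; r_HGP_B <- p$r_HGP_B; r_HGU_B <- p$r_HGU_B
  tau_I <- p$tau_I; tau_Gamma <- p$tau_Gamma
  alpha <- p$alpha; beta_ <- p$beta; K_ <- p$K; Q0 <- p$Q0
  gamma_ <- p$gamma; M1 <- p$M1; M2 <- p$M2
  cpg_a <- cpg[["a"]]; cpg_b <- cpg[["b"]]; cpg_c <- cpg[["c"]]; cpg_d <- cpg[["d"]]
  chi_a <- chi[["a"]]; chi_b <- chi[["b"]]; chi_c <- chi[["c"]]; chi_d <- chi[["d"]]
  chg0_a <- chg0[["a"]]; chg0_c <- chg0[["c"]]
  chg_a <- chg[["a"]]; chg_b <- chg[["b"]]; chg_c <- chg[["c"]]; chg_d <- chg[["d"]]
  cui_a <- cui[["a"]]; cui_c <- cui[["c"]]
  cug_a <- cug[["a"]]; cug_b <- cug[["b"]]; cug_c <- cug[["c"]]; cug_d <- cug[["d"]]
  ckg_a <- ckg[["a"]]; ckg_b <- ckg[["b"]]; ckg_c <- ckg[["c"]]
  ckg_d <- ckg[["d"]]; ckg_e <- ckg[["e"]]; ckg_f <- ckg[["f"]]
  cgg_a <- cgg[["a"]]; cgg_b <- cgg[["b"]]; cgg_c <- cgg[["c"]]; cgg_d <- cgg[["d"]]
  cgi_a <- cgi[["a"]]; cgi_b <- cgi[["b"]]; cgi_c <- cgi[["c"]]; cgi_d <- cgi[["d"]]
  sf <- simo$f; k_js <- simo$k_js; k_gj <- simo$k_gj
  k_rj <- simo$k_rj; k_lr <- simo$k_lr; k_gl <- simo$k_gl

  function(t, y) {
    G_BV <- y[1]; G_BI <- y[2]; G_H <- y[3]; G_J <- y[4]; G_L <- y[5]
    G_K <- y[6]; G_PV <- y[7]; G_PI <- y[8]
    I_B <- y[9]; I_H <- y[10]; I_J <- y[11]; I_L <- y[12]; I_K <- y[13]
    I_PV <- y[14]; I_PI <- y[15]
    Gam <- y[16]; MHGPI <- y[17]; MHGUI <- y[18]; f2 <- y[19]
    P <- y[20]; Iinh <- y[21]; Q <- y[22]
    S_sto <- y[23]; J_jej <- y[24]; R_del <- y[25]; L_ile <- y[26]

    ## gut transit and oral absorption
    r_oga <- sf * (k_gj * J_jej + k_gl * L_ile)

    ## glucose sinks/sources
    r_PGU <- (cpg_a + cpg_b * tanh(cpg_c * (I_PI / I_PIB - cpg_d))) *
      (G_PI / G_PIB) * r_PGU_B
    mg0 <- chg0_a * tanh(chg0_c * Gam)
    r_HGP <- MHGPI * (mg0 - f2) *
      (chg_a + chg_b * tanh(chg_c * (G_L / G_LB - chg_d))) * r_HGP_B
    r_HGU <- MHGUI *
      (cug_a + cug_b * tanh(cug_c * (G_L / G_LB - cug_d))) * r_HGU_B
    r_KGE <- if (G_K < ckg_d)
      ckg_a + ckg_b * tanh(ckg_c * (G_K - ckg_d))
    else ckg_e + ckg_f * G_K

    ## pancreatic secretion (U/min) and release into liver (mU/min)
    g <- if (G_H > 0) G_H / gsc else 0
    X <- g^b1 / (b2b1 + b3 * g^b4)
    Y <- X^b5
    S <- (M1 * Y + M2 * max(0, X - Iinh)) * Q
    r_PIR <- S / S_B * r_PIRB

    ## insulin clearances (mU/min)
    r_LIC <- F_LIC * (Q_AI * I_H + Q_JI * I_J + r_PIR)
    r_KIC <- F_KIC * Q_KI * I_H
    r_PIC <- I_PI / rpic_den

    ## glucagon (normalized)
    rel <- (cgg_a + cgg_b * tanh(cgg_c * (G_H / G_HB - cgg_d))) *
      (cgi_a + cgi_b * tanh(cgi_c * (I_H / I_HB - cgi_d))) * rB_gam

    dif_B <- (V_BIG / T_B) * (G_BV - G_BI)
    dif_P <- (V_PIG / T_PG) * (G_PV - G_PI)
    dif_I <- (V_PII / T_PI) * (I_PV - I_PI)

    c(
      (Q_BG * (G_H - G_BV) - dif_B) / V_BVG,
      (dif_B - r_BGU) / V_BIG,
      (Q_BG * G_BV + Q_LG * G_L + Q_KG * G_K + Q_PG * G_PV -
         Q_HG * G_H - r_RBCU + iv_glucose) / V_HG,
      (Q_JG * (G_H - G_J) + r_oga - r_JGU) / V_JG,
      (Q_AG * G_H + Q_JG * G_J - Q_LG * G_L + r_HGP - r_HGU) / V_LG,
      (Q_KG * (G_H - G_K) - r_KGE) / V_KG,
      (Q_PG * (G_H - G_PV) - dif_P) / V_PVG,
      (dif_P - r_PGU) / V_PIG,
      Q_BI * (I_H - I_B) / V_BI,
      (Q_BI * I_B + Q_LI * I_L + Q_KI * I_K + Q_PI * I_PV -
         Q_HI * I_H + iv_insulin) / V_HI,
      Q_JI * (I_H - I_J) / V_JI,
      (Q_AI * I_H + Q_JI * I_J - Q_LI * I_L + r_PIR - r_LIC) / V_LI,
      (Q_KI * (I_H - I_K) - r_KIC) / V_KI,
      (Q_PI * (I_H - I_PV) - dif_I) / V_PVI,
      (dif_I - r_PIC) / V_PII,
      rel - kGam * Gam,
      (chi_a + chi_b * tanh(chi_c * (I_L / I_LB - chi_d)) - MHGPI) / tau_I,
      (cui_a * tanh(cui_c * (I_L / I_LB)) - MHGUI) / tau_I,
      ((mg0 - 1) / 2 - f2) / tau_Gamma,
      alpha * (Y - P),
      beta_ * (X - Iinh),
      K_ * (Q0 - Q) + gamma_ * P - S,
      -k_js * S_sto,
      k_js * S_sto - (k_gj + k_rj) * J_jej,
      k_rj * J_jej - k_lr * R_del,
      k_lr * R_del - k_gl * L_ile
    )
  }
}

#' Full model derivative vector
#'
#' Evaluates the complete right-hand side of the coupled 26-equation system
#' (22 whole-body equations plus the 4 gut transit equations) at a given
#' state. The oral absorption flux enters only the gut glucose balance;
#' intravenous inputs enter the heart/lungs balances.
#'
#' @param state named numeric vector in the order of
#'   [sorensen_state_names()].
#' @param p parameter set from [sorensen_params()].
#' @param basal basal solution from [basal_state()]; supplies the
#'   normalization references.
#' @param simo gut parameter set from [simo_params()].
#' @param iv_glucose intravenous glucose input, mg/min.
#' @param iv_insulin intravenous insulin input, mU/min.
#' @return named vector of time derivatives (native units per minute).
#' @export
full_derivatives <- function(state, p = sorensen_params(),
                             basal = basal_state(p),
                             simo = simo_params(),
                             iv_glucose = 0, iv_insulin = 0) {
  if (length(state) != 26)
    stop("state must have 26 components (see sorensen_state_names())")
  names(state) <- .state_names
  check_finite_state(state, NA_real_, "state")
  d <- make_rhs(p, basal, simo, iv_glucose, iv_insulin)(0, unname(state))
  names(d) <- .state_names
  check_finite_state(d, NA_real_, "derivative")
  d
}

#' Basal steady-state initialization
#'
#' Computes the basal solution implied by input basal peripheral-vascular
#' glycemia and insulinemia. The closed-form cascade (corrected forms: the
#' peripheral interstitial glucose gradient driven by peripheral -- not
#' brain -- uptake, heart insulin from the peripheral fractional clearance,
#' liver insulin and basal pancreatic release from direct steady-state
#' solution of the liver and heart insulin balances) gives the reference
#' basal concentrations used to normalize every multiplier argument.
#'
#' With \code{exact = TRUE} (default) the full 22-state algebraic steady
#' state is then solved by damped Newton iteration starting from the
#' cascade, so the returned state is an equilibrium of the simulated system
#' to within \code{tol}. The residual drift of the printed initial
#' conditions (rounded multiplier coefficients and the small basal renal
#' excretion) is absorbed into sub-percent shifts of the compartment
#' concentrations. \code{exact = FALSE} returns the printed initial
#' conditions unchanged (unit regulatory multipliers, \code{f2 = 0},
#' kidney glucose equal to heart glucose).
#'
#' @param p parameter set.
#' @param G_PVB basal peripheral vascular glucose, mg/dl.
#' @param I_PVB basal peripheral vascular insulin, mU/l.
#' @param Gamma_B basal normalized glucagon (1 by convention).
#' @param exact logical; solve the exact equilibrium (see above).
#' @param tol maximum absolute derivative accepted in exact mode
#'   (native units per minute).
#' @return object of class \code{sorensen_basal}: list with the full
#'   \code{state} (26 components, gut empty), the cascade references
#'   \code{ref}, basal pancreas values, \code{r_PIRB} (mU/min), \code{S_B}
#'   (U/min) and the achieved \code{max_abs_deriv}.
#' @export
#' @examples
#' b <- basal_state()
#' b$max_abs_deriv < 1e-6
basal_state <- function(p = sorensen_params(), G_PVB = p$G_PVB,
                        I_PVB = p$I_PVB, Gamma_B = p$Gamma_B,
                        exact = TRUE, tol = 1e-8) {
  if (G_PVB <= 0 || I_PVB <= 0 || Gamma_B <= 0)
    stop("basal inputs must be positive")
  ## glucose cascade
  G_HB <- G_PVB + p$r_PGU_B / p$Q_PG
  G_KB <- G_HB
  G_BVB <- G_HB - p$r_BGU / p$Q_BG
  G_JB <- G_HB - p$r_JGU / p$Q_JG
  G_LB <- (p$Q_AG * G_HB + p$Q_JG * G_JB + p$r_HGP_B - p$r_HGU_B) / p$Q_LG
  G_BIB <- G_BVB - p$r_BGU * p$T_B / p$V_BIG
  G_PIB <- G_PVB - p$r_PGU_B * p$T_PG / p$V_PIG
  ## insulin cascade
  I_HB <- I_PVB / (1 - p$F_PIC)
  I_KB <- I_HB * (1 - p$F_KIC)
  I_BB <- I_HB
  I_JB <- I_HB
  I_PIB <- I_PVB - (p$Q_PI * p$T_PI / p$V_PII) * (I_HB - I_PVB)
  I_LB <- (p$Q_HI * I_HB - p$Q_BI * I_BB - p$Q_KI * I_KB - p$Q_PI * I_PVB) / p$Q_LI
  r_PIRB <- p$Q_LI / (1 - p$F_LIC) * I_LB - p$Q_JI * I_JB - p$Q_AI * I_HB
  ref <- list(G_HB = G_HB, G_KB = G_KB, G_BVB = G_BVB, G_JB = G_JB,
              G_LB = G_LB, G_BIB = G_BIB, G_PIB = G_PIB, G_PVB = G_PVB,
              I_HB = I_HB, I_KB = I_KB, I_BB = I_BB, I_JB = I_JB,
              I_PIB = I_PIB, I_LB = I_LB, I_PVB = I_PVB, Gamma_B = Gamma_B)
  neg <- names(ref)[vapply(ref, function(v) v < 0, logical(1))]
  if (length(neg))
    stop("infeasible basal state: negative computed concentration in ",
         paste(neg, collapse = ", "))
  if (r_PIRB <= 0) stop("infeasible basal state: non-positive basal ",
                        "pancreatic release r_PIRB")
  ## basal pancreas
  g <- G_HB / p$pancreas_glucose_scale
  X_B <- g^p$beta_pir1 / (p$beta_pir2^p$beta_pir1 + p$beta_pir3 * g^p$beta_pir4)
  Y_B <- X_B^p$beta_pir5
  P_B <- Y_B
  Q_B <- (p$K * p$Q0 + p$gamma * Y_B) / (p$K + p$M1 * Y_B)
  S_B <- p$M1 * Y_B * Q_B
  pancreas <- list(X = X_B, Y = Y_B, P = P_B, I = X_B, Q = Q_B)

  state <- c(G_BVB, G_BIB, G_HB, G_JB, G_LB, G_KB, G_PVB, G_PIB,
             I_BB, I_HB, I_JB, I_LB, I_KB, I_PVB, I_PIB,
             Gamma_B, 1, 1, 0,
             P_B, X_B, Q_B,
             0, 0, 0, 0)
  names(state) <- .state_names

  out <- structure(list(state = state, ref = ref, pancreas = pancreas,
                        r_PIRB = r_PIRB, S_B = S_B,
                        input = list(G_PVB = G_PVB, I_PVB = I_PVB,
                                     Gamma_B = Gamma_B),
                        exact = exact),
                   class = "sorensen_basal")
  rhs <- make_rhs(p, out, simo_params())
  if (exact) {
    y <- unname(state)[1:22]
    fun <- function(z) rhs(0, c(z, 0, 0, 0, 0))[1:22]
    fv <- fun(y)
    for (it in 1:30) {
      if (max(abs(fv)) < tol / 10) break
      J <- fd_jacobian(fun, y, f0 = fv, rel = 1e-7, abs_ = 1e-9)
      step <- tryCatch(solve(J, fv), error = function(e)
        stop("basal equilibrium solve failed: singular Jacobian"))
      lam <- 1
      repeat {
        ynew <- y - lam * step
        fnew <- fun(ynew)
        if (max(abs(fnew)) < max(abs(fv)) || lam < 1e-4) break
        lam <- lam / 2
      }
      y <- ynew; fv <- fnew
    }
    if (max(abs(fv)) > tol)
      stop("basal equilibrium solve did not converge (max |dX/dt| = ",
           signif(max(abs(fv)), 3), ")")
    if (any(y[1:16] < 0)) {
      bad <- .state_names[which(y[1:16] < 0)]
      stop("infeasible basal state: negative equilibrium concentration in ",
           paste(bad, collapse = ", "))
    }
    out$state[1:22] <- y
  }
  d <- rhs(0, unname(out$state))
  out$max_abs_deriv <- max(abs(d))
  out
}

#' @export
print.sorensen_basal <- function(x, ...) {
  cat("Basal steady state (", if (x$exact) "exact equilibrium" else
    "printed initial conditions", ")\n", sep = "")
  cat(sprintf("  glycemia %.6g mg/dl, insulinemia %.6g mU/l (peripheral vascular)\n",
              x$input$G_PVB, x$input$I_PVB))
  cat(sprintf("  basal pancreatic release %.6g mU/min, max |dX/dt| = %.3g\n",
              x$r_PIRB, x$max_abs_deriv))
  invisible(x)
}
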