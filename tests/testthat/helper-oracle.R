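## Independent term-by-term oracle for the full derivative vector:
## a literal transcription of the mass balances with hard-coded literature
## parameter values, written without reference to the package's parameter
## structures or rate functions. Used to cross-check full_derivatives().
oracle_derivs <- function(y, ref, S_B, r_PIRB, simo, ivg = 0, ivi = 0) {
  G_BV <- y[["G_BV"]]; G_BI <- y[["G_BI"]]; G_H <- y[["G_H"]]
  G_J <- y[["G_J"]]; G_L <- y[["G_L"]]; G_K <- y[["G_K"]]
  G_PV <- y[["G_PV"]]; G_PI <- y[["G_PI"]]
  I_B <- y[["I_B"]]; I_H <- y[["I_H"]]; I_J <- y[["I_J"]]; I_L <- y[["I_L"]]
  I_K <- y[["I_K"]]; I_PV <- y[["I_PV"]]; I_PI <- y[["I_PI"]]
  Gam <- y[["Gamma"]]; MHGPI <- y[["M_HGP_I"]]; MHGUI <- y[["M_HGU_I"]]
  f2 <- y[["f2"]]; Pp <- y[["P"]]; Ii <- y[["I_inh"]]; Qq <- y[["Q"]]
  S_sto <- y[["S_sto"]]; J_jej <- y[["J_jej"]]; R_del <- y[["R_del"]]
  L_ile <- y[["L_ile"]]

  r_oga <- simo$f * (simo$k_gj * J_jej + simo$k_gl * L_ile)
  r_BGU <- 70; r_RBCU <- 10; r_JGU <- 20
  r_PGU <- (7.03 + 6.52 * tanh(0.338 * (I_PI / ref$I_PIB - 5.82))) *
    (G_PI / ref$G_PIB) * 35
  MG0 <- 2.7 * tanh(0.39 * Gam)
  r_HGP <- MHGPI * (MG0 - f2) *
    (1.42 - 1.41 * tanh(0.62 * (G_L / ref$G_LB - 0.497))) * 155
  r_HGU <- MHGUI * (5.66 + 5.66 * tanh(2.44 * (G_L / ref$G_LB - 1.48))) * 20
  r_KGE <- if (G_K < 460) 71 + 71 * tanh(0.011 * (G_K - 460)) else
    -330 + 0.872 * G_K
  X <- G_H^3.27 / (132^3.27 + 5.93 * G_H^3.02)
  Y <- X^1.11
  S <- (0.00747 * Y + 0.0958 * max(0, X - Ii)) * Qq
  r_PIR <- S / S_B * r_PIRB
  r_LIC <- 0.40 * (0.18 * I_H + 0.72 * I_J + r_PIR)
  r_KIC <- 0.30 * 0.72 * I_H
  r_PIC <- I_PI / ((1 - 0.15) / (0.15 * 1.05) - 20 / 6.74)
  kG <- 9.10 / 11310
  MGg1 <- 2.93 - 2.10 * tanh(4.18 * (1 - 0.61))
  MGi1 <- 1.31 - 0.61 * tanh(1.06 * (1 - 0.47))
  rel <- (2.93 - 2.10 * tanh(4.18 * (G_H / ref$G_HB - 0.61))) *
    (1.31 - 0.61 * tanh(1.06 * (I_H / ref$I_HB - 0.47))) * kG / (MGg1 * MGi1)

  c(G_BV = (5.9 * (G_H - G_BV) - (4.5 / 2.1) * (G_BV - G_BI)) / 3.5,
    G_BI = ((4.5 / 2.1) * (G_BV - G_BI) - r_BGU) / 4.5,
    G_H = (5.9 * G_BV + 12.6 * G_L + 10.1 * G_K + 15.1 * G_PV -
             43.7 * G_H - r_RBCU + ivg) / 13.8,
    G_J = (10.1 * (G_H - G_J) + r_oga - r_JGU) / 11.2,
    G_L = (2.5 * G_H + 10.1 * G_J - 12.6 * G_L + r_HGP - r_HGU) / 25.1,
    G_K = (10.1 * (G_H - G_K) - r_KGE) / 6.6,
    G_PV = (15.1 * (G_H - G_PV) - (67.4 / 5.0) * (G_PV - G_PI)) / 10.4,
    G_PI = ((67.4 / 5.0) * (G_PV - G_PI) - r_PGU) / 67.4,
    I_B = 0.45 * (I_H - I_B) / 0.26,
    I_H = (0.45 * I_B + 0.90 * I_L + 0.72 * I_K + 1.05 * I_PV -
             3.12 * I_H + ivi) / 0.99,
    I_J = 0.72 * (I_H - I_J) / 0.94,
    I_L = (0.18 * I_H + 0.72 * I_J - 0.90 * I_L + r_PIR - r_LIC) / 1.14,
    I_K = (0.72 * (I_H - I_K) - r_KIC) / 0.51,
    I_PV = (1.05 * (I_H - I_PV) - (6.74 / 20) * (I_PV - I_PI)) / 0.74,
    I_PI = ((6.74 / 20) * (I_PV - I_PI) - r_PIC) / 6.74,
    Gamma = rel - kG * Gam,
    M_HGP_I = (1.21 - 1.14 * tanh(1.66 * (I_L / ref$I_LB - 0.89)) - MHGPI) / 25,
    M_HGU_I = (2 * tanh(0.55 * (I_L / ref$I_LB)) - MHGUI) / 25,
    f2 = ((MG0 - 1) / 2 - f2) / 65,
    P = 0.0482 * (Y - Pp),
    I_inh = 0.931 * (X - Ii),
    Q = 0.00794 * (6.33 - Qq) + 0.575 * Pp - S,
    S_sto = -simo$k_js * S_sto,
    J_jej = simo$k_js * S_sto - (simo$k_gj + simo$k_rj) * J_jej,
    R_del = simo$k_rj * J_jej - simo$k_lr * R_del,
    L_ile = simo$k_lr * R_del - simo$k_gl * L_ile)
}
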