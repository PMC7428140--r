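## Algebraic metabolic rate laws and tanh multiplier functions.
## Superscript-N arguments are concentrations normalized by their basal
## steady-state value (basal => 1), the convention of the original model.

tanh_law <- function(x, cc) cc[["a"]] + cc[["b"]] * tanh(cc[["c"]] * (x - cc[["d"]]))

#' Renal glucose excretion rate
#'
#' Piecewise law: a saturating tanh branch below the renal threshold and a
#' linear branch above it. The corrected slope factor 0.011 (not 0.11) is
#' used in the sub-threshold branch.
#'
#' @param G_K kidney glucose concentration, mg/dl (vectorized, must be >= 0).
#' @param p parameter set from [sorensen_params()].
#' @param branch \code{"auto"} (piecewise as printed: linear branch from
#'   460 mg/dl), or force \code{"sub460"} / \code{"linear"} to evaluate one
#'   branch on its closure (used for branch-continuity analysis).
#' @return excretion rate, mg/min.
#' @export
#' @examples
#' rate_kidney_glucose_excretion(460, branch = "sub460")  # 71
rate_kidney_glucose_excretion <- function(G_K, p = sorensen_params(),
                                          branch = c("auto", "sub460", "linear")) {
  branch <- match.arg(branch)
  if (any(!is.finite(G_K)) || any(G_K < 0))
    stop("G_K must be finite and non-negative")
  cc <- p$c_kge
  sub <- cc[["a"]] + cc[["b"]] * tanh(cc[["c"]] * (G_K - cc[["d"]]))
  lin <- cc[["e"]] + cc[["f"]] * G_K
  switch(branch,
         auto = ifelse(G_K < cc[["d"]], sub, lin),
         sub460 = sub,
         linear = lin)
}

#' Insulin multiplier of peripheral glucose uptake
#' @param I_PI_N normalized peripheral interstitial insulin (basal = 1).
#' @param p parameter set.
#' @return dimensionless multiplier.
#' @export
m_pgu_insulin <- function(I_PI_N, p = sorensen_params()) tanh_law(I_PI_N, p$c_pgu_i)

#' Peripheral glucose uptake rate
#'
#' \code{r_PGU = M_I(I_PI_N) * M_G(G_PI_N) * r_PGU_B} where the glucose
#' multiplier is the normalized interstitial glucose itself.
#'
#' @param I_PI_N,G_PI_N normalized interstitial insulin and glucose (>= 0).
#' @param p parameter set.
#' @return uptake rate, mg/min.
#' @export
peripheral_glucose_uptake <- function(I_PI_N, G_PI_N, p = sorensen_params()) {
  if (any(I_PI_N < 0) || any(G_PI_N < 0))
    stop("normalized inputs must be non-negative")
  m_pgu_insulin(I_PI_N, p) * G_PI_N * p$r_PGU_B
}

#' Glucose multiplier of hepatic glucose production
#' @param G_L_N normalized liver glucose.
#' @param p parameter set.
#' @export
m_hgp_glucose <- function(G_L_N, p = sorensen_params()) tanh_law(G_L_N, p$c_hgp_g)

#' Glucose multiplier of hepatic glucose uptake
#' @param G_L_N normalized liver glucose.
#' @param p parameter set.
#' @export
m_hgu_glucose <- function(G_L_N, p = sorensen_params()) tanh_law(G_L_N, p$c_hgu_g)

#' Basal-glucagon multiplier of hepatic glucose production
#' @param Gamma_N normalized glucagon (basal = 1).
#' @param p parameter set.
#' @export
m_hgp_glucagon0 <- function(Gamma_N, p = sorensen_params())
  p$c_hgp_g0[["a"]] * tanh(p$c_hgp_g0[["c"]] * Gamma_N)

#' Steady-state insulin multiplier of hepatic glucose production
#' @param I_L_N normalized liver insulin.
#' @param p parameter set.
#' @export
m_hgp_insulin_inf <- function(I_L_N, p = sorensen_params()) tanh_law(I_L_N, p$c_hgp_i)

#' Steady-state insulin multiplier of hepatic glucose uptake
#' @param I_L_N normalized liver insulin.
#' @param p parameter set.
#' @export
m_hgu_insulin_inf <- function(I_L_N, p = sorensen_params())
  p$c_hgu_i[["a"]] * tanh(p$c_hgu_i[["c"]] * I_L_N)

#' Glucose multiplier of pancreatic glucagon release
#' @param G_H_N normalized heart/lungs glucose.
#' @param p parameter set.
#' @export
m_pgr_glucose <- function(G_H_N, p = sorensen_params()) tanh_law(G_H_N, p$c_pgr_g)

#' Insulin multiplier of pancreatic glucagon release
#' @param I_H_N normalized heart/lungs insulin.
#' @param p parameter set.
#' @export
m_pgr_insulin <- function(I_H_N, p = sorensen_params()) tanh_law(I_H_N, p$c_pgr_i)

#' Hepatic glucose production and uptake rates
#'
#' \code{r_HGP = M_HGP_I * (M_HGP_Gamma0 - f2) * M_HGP_G * r_HGP_B} and
#' \code{r_HGU = M_HGU_I * M_HGU_G * r_HGU_B}. The slow insulin multipliers
#' \code{M_HGP_I}, \code{M_HGU_I} and the glucagon offset \code{f2} are
#' dynamic states relaxing toward their steady-state laws (see
#' [regulatory_derivatives()]).
#'
#' @param M_HGP_I,M_HGU_I current dynamic insulin multipliers (dimensionless).
#' @param f2 current glucagon-effect offset state.
#' @param Gamma_N,G_L_N normalized glucagon and liver glucose.
#' @param p parameter set.
#' @return list with \code{r_HGP} and \code{r_HGU} (mg/min).
#' @export
hepatic_rates <- function(M_HGP_I, f2, Gamma_N, G_L_N, M_HGU_I,
                          p = sorensen_params()) {
  if (any(c(M_HGP_I, M_HGU_I, Gamma_N, G_L_N) < 0))
    stop("inputs must be non-negative")
  list(r_HGP = M_HGP_I * (m_hgp_glucagon0(Gamma_N, p) - f2) *
         m_hgp_glucose(G_L_N, p) * p$r_HGP_B,
       r_HGU = M_HGU_I * m_hgu_glucose(G_L_N, p) * p$r_HGU_B)
}

#' Derivatives of the slow hepatic regulatory states
#'
#' First-order relaxations: \code{M_HGP_I} and \code{M_HGU_I} relax toward
#' their insulin-dependent steady-state laws with time constant
#' \code{tau_I}; \code{f2} relaxes toward \code{(M_HGP_Gamma0 - 1)/2} with
#' time constant \code{tau_Gamma}.
#'
#' @param M_HGP_I,M_HGU_I,f2 current state values.
#' @param I_L_N,Gamma_N normalized liver insulin and glucagon.
#' @param p parameter set.
#' @return named vector of the three time derivatives (1/min).
#' @export
regulatory_derivatives <- function(M_HGP_I, M_HGU_I, f2, I_L_N, Gamma_N,
                                   p = sorensen_params()) {
  c(dM_HGP_I = (m_hgp_insulin_inf(I_L_N, p) - M_HGP_I) / p$tau_I,
    dM_HGU_I = (m_hgu_insulin_inf(I_L_N, p) - M_HGU_I) / p$tau_I,
    df2 = ((m_hgp_glucagon0(Gamma_N, p) - 1) / 2 - f2) / p$tau_Gamma)
}

#' Pancreatic insulin secretion submodel
#'
#' Glucose-driven instantaneous release signal
#' \code{X = g^b1 / (b2^b1 + b3 g^b4)} (with \code{g} the heart/lungs
#' glucose in the preset's pancreatic unit system), late-phase signal
#' \code{P_inf = Y = X^b5}, and secretion
#' \code{S = [M1 Y + M2 max(0, X - I)] Q} from the labile compartment
#' \code{Q}. The corrected labile-compartment balance sign
#' \code{dQ/dt = K (Q0 - Q) + gamma P - S} is used throughout.
#'
#' @param G_H heart/lungs glucose concentration, mg/dl (>= 0).
#' @param pstate list or named vector with \code{P} (potentiator),
#'   \code{I} (inhibitor) and \code{Q} (labile insulin, U).
#' @param p parameter set.
#' @return list with \code{X}, \code{Y}, \code{P_inf}, \code{S} (U/min) and
#'   the labile-compartment derivative inputs.
#' @export
#' @examples
#' b <- basal_state()
#' s <- pancreas_secretion(b$ref$G_HB, b$pancreas)
#' all.equal(s$S, b$S_B)
pancreas_secretion <- function(G_H, pstate, p = sorensen_params()) {
  if (!is.finite(G_H) || G_H < 0) stop("G_H must be finite and non-negative")
  if (pstate[["Q"]] < 0) stop("labile insulin Q must be non-negative")
  g <- G_H / p$pancreas_glucose_scale
  X <- g^p$beta_pir1 / (p$beta_pir2^p$beta_pir1 + p$beta_pir3 * g^p$beta_pir4)
  Y <- X^p$beta_pir5
  S <- (p$M1 * Y + p$M2 * max(0, X - pstate[["I"]])) * pstate[["Q"]]
  list(X = X, Y = Y, P_inf = Y, S = S)
}

#' Pancreatic state derivatives and secretion
#'
#' @param G_H heart/lungs glucose, mg/dl.
#' @param P,I,Q potentiator, inhibitor and labile insulin (U) states.
#' @param p parameter set.
#' @return list with \code{S} (U/min) and derivatives \code{dP}, \code{dI},
#'   \code{dQ}.
#' @export
pancreas_derivatives <- function(G_H, P, I, Q, p = sorensen_params()) {
  sec <- pancreas_secretion(G_H, list(P = P, I = I, Q = Q), p)
  list(S = sec$S,
       dP = p$alpha * (sec$P_inf - P),
       dI = p$beta * (sec$X - I),
       dQ = p$K * (p$Q0 - Q) + p$gamma * P - sec$S)
}

#' Insulin clearance rates
#'
#' Liver: \code{r_LIC = F_LIC (Q_AI I_H + Q_JI I_J + r_PIR)}; kidney uses
#' the corrected arterial driving concentration,
#' \code{r_KIC = F_KIC Q_KI I_H}; periphery
#' \code{r_PIC = I_PI / [((1-F_PIC)/F_PIC)/Q_PI - T_PI/V_PII]}.
#'
#' @param I_H,I_J,I_PI heart, gut and peripheral interstitial insulin, mU/l.
#' @param r_PIR pancreatic insulin release, mU/min.
#' @param p parameter set.
#' @return list with \code{r_LIC}, \code{r_KIC}, \code{r_PIC} (mU/min).
#' @export
insulin_clearances <- function(I_H, I_J, I_PI, r_PIR, p = sorensen_params()) {
  list(r_LIC = p$F_LIC * (p$Q_AI * I_H + p$Q_JI * I_J + r_PIR),
       r_KIC = p$F_KIC * p$Q_KI * I_H,
       r_PIC = I_PI / ((1 - p$F_PIC) / (p$F_PIC * p$Q_PI) - p$T_PI / p$V_PII))
}

#' Glucagon release and clearance rates (normalized units)
#'
#' Glucagon is simulated as a concentration normalized to its basal value
#' (basal = 1), because no absolute basal glucagon concentration is part of
#' the parameterization. The mass balance divided through by the
#' distribution volume gives first-order clearance
#' \code{r_MGammaC/V_Gamma * Gamma} (1/min) and release
#' \code{M_G(G_H_N) M_I(I_H_N) r_B} with the basal release \code{r_B}
#' closed so that release equals clearance at basal
#' (\code{G_H_N = I_H_N = Gamma = 1}).
#'
#' @param G_H_N,I_H_N normalized heart/lungs glucose and insulin.
#' @param Gamma normalized glucagon concentration.
#' @param p parameter set.
#' @return list with \code{release} and \code{clearance} (both 1/min).
#' @export
glucagon_rates <- function(G_H_N, I_H_N, Gamma, p = sorensen_params()) {
  if (any(c(G_H_N, I_H_N, Gamma) < 0)) stop("inputs must be non-negative")
  kG <- p$r_MGammaC / p$V_Gamma
  rB <- kG / (m_pgr_glucose(1, p) * m_pgr_insulin(1, p))
  list(release = m_pgr_glucose(G_H_N, p) * m_pgr_insulin(I_H_N, p) * rB,
       clearance = kG * Gamma)
}
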