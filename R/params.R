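#' Whole-body model parameter set
#'
#' Builds the full parameter set of the corrected Sorensen whole-body
#' glucose-insulin-glucagon model: compartment volumes, blood flows,
#' transcapillary time constants, fractional clearances, constant and basal
#' metabolic rates, every hyperbolic-tangent multiplier coefficient, the
#' pancreatic secretion submodel parameters and the glucagon kinetics.
#'
#' Two presets are shipped:
#' \describe{
#'   \item{\code{"appendix_a1"}}{The corrected literature parameterization
#'     for intravenous protocols. The pancreatic glucose argument is in
#'     mg/dl (\code{beta_pir2 = 132} mg/dl). The labile-compartment turnover
#'     \code{K} defaults to 0.00794/min: the value 0.575 printed with units
#'     U/min in some summaries is dimensionally a flux and numerically equals
#'     the glucose-driven provision rate \code{gamma} (4025 pmol/min at
#'     7000 pmol/U); it is shipped as \code{K_alt_U_min} for reference.}
#'   \item{\code{"table3_after"}}{The OGTT-refitted pancreatic secretion and
#'     gut-transit parameterization. The pancreatic glucose argument is in
#'     mM (\code{beta_pir2 = 3.776} mM, conversion 18 mg/dl per mM); pmol
#'     quantities are converted at 7000 pmol/U.}
#' }
#'
#' Volumes are dl (glucose side) and l (insulin side); flows dl/min and
#' l/min; time constants min; rates mg/min (glucose), mU/min (insulin) and
#' U/min (pancreatic secretion).
#'
#' @param preset character, one of \code{"appendix_a1"}, \code{"table3_after"}.
#' @param ... named numeric overrides for any parameter field.
#' @return an object of class \code{sorensen_params} (a validated named list).
#' @export
#' @examples
#' p <- sorensen_params()
#' p$r_BGU  # constant brain glucose uptake, mg/min
sorensen_params <- function(preset = c("appendix_a1", "table3_after"), ...) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset,
    ## --- glucose side: volumes (dl), flows (dl/min), time constants (min)
    V_BVG = 3.5, V_BIG = 4.5, V_HG = 13.8, V_LG = 25.1, V_JG = 11.2,
    V_KG = 6.6, V_PVG = 10.4, V_PIG = 67.4,
    Q_BG = 5.9, Q_HG = 43.7, Q_AG = 2.5, Q_LG = 12.6, Q_JG = 10.1,
    Q_KG = 10.1, Q_PG = 15.1,
    T_B = 2.1, T_PG = 5.0,
    ## --- insulin side: volumes (l), flows (l/min), time constant (min)
    V_BI = 0.26, V_HI = 0.99, V_JI = 0.94, V_LI = 1.14, V_KI = 0.51,
    V_PVI = 0.74, V_PII = 6.74,
    Q_BI = 0.45, Q_HI = 3.12, Q_AI = 0.18, Q_KI = 0.72, Q_PI = 1.05,
    Q_JI = 0.72, Q_LI = 0.90,
    T_PI = 20,
    ## --- fractional insulin clearances
    F_LIC = 0.40, F_KIC = 0.30, F_PIC = 0.15,
    ## --- constant and basal metabolic rates (mg/min)
    r_BGU = 70, r_RBCU = 10, r_JGU = 20,
    r_PGU_B = 35, r_HGP_B = 155, r_HGU_B = 20,
    ## --- tanh multiplier coefficients (a + b*tanh[c*(x - d)])
    c_pgu_i  = c(a = 7.03, b = 6.52, c = 0.338, d = 5.82),
    c_hgp_i  = c(a = 1.21, b = -1.14, c = 1.66, d = 0.89),
    c_hgp_g0 = c(a = 2.7, c = 0.39),
    c_hgp_g  = c(a = 1.42, b = -1.41, c = 0.62, d = 0.497),
    c_hgu_i  = c(a = 2.0, c = 0.55),
    c_hgu_g  = c(a = 5.66, b = 5.66, c = 2.44, d = 1.48),
    c_kge    = c(a = 71, b = 71, c = 0.011, d = 460, e = -330, f = 0.872),
    c_pgr_g  = c(a = 2.93, b = -2.10, c = 4.18, d = 0.61),
    c_pgr_i  = c(a = 1.31, b = -0.61, c = 1.06, d = 0.47),
    tau_I = 25, tau_Gamma = 65,
    ## --- pancreatic secretion submodel
    alpha = 0.0482, beta = 0.931, K = 0.00794,
    Q0 = 6.33,           # U
    gamma = 0.575,       # U/min (= 4025 pmol/min at 7000 pmol/U)
    M1 = 0.00747, M2 = 0.0958,
    beta_pir1 = 3.27, beta_pir2 = 132, beta_pir3 = 5.93,
    beta_pir4 = 3.02, beta_pir5 = 1.11,
    # scale dividing heart glucose (mg/dl) before the secretion dose-response:
    # 1 when beta_pir2 is in mg/dl, 18 when in mM
    pancreas_glucose_scale = 1,
    K_alt_U_min = 0.575,  # flux printed as "K" in some summaries; see docs
    ## --- glucagon
    r_MGammaC = 9.10,    # ml/min, metabolic clearance rate
    V_Gamma = 11310,     # ml
    ## --- basal inputs
    G_PVB = 89, I_PVB = 12.8, Gamma_B = 1,
    ## --- unit conversions
    pmol_per_U = 7000, mgdl_per_mM = 18
  )
  if (preset == "table3_after") {
    p[c("alpha", "beta", "K", "gamma", "M1", "M2")] <-
      list(0.014, 15.558, 0.0145, 2138.76 / 7000, 0.00012, 0.2488)
    p[c("beta_pir1", "beta_pir2", "beta_pir3", "beta_pir4", "beta_pir5")] <-
      list(4.164, 3.776, 1.837, 3.577, 2.876)
    p$pancreas_glucose_scale <- p$mgdl_per_mM
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  class(p) <- "sorensen_params"
  validate_params(p)
  p
}

#' Validate a whole-body parameter set
#'
#' Checks positivity of volumes, flows and time constants, that fractional
#' clearances lie in (0,1), and flow-conservation identities (total
#' heart/lungs flow equals the sum of organ flows on both the glucose and
#' insulin sides).
#'
#' @param p a \code{sorensen_params} object.
#' @return \code{p}, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  pos <- c("V_BVG", "V_BIG", "V_HG", "V_LG", "V_JG", "V_KG", "V_PVG", "V_PIG",
           "Q_BG", "Q_HG", "Q_AG", "Q_LG", "Q_JG", "Q_KG", "Q_PG",
           "T_B", "T_PG", "V_BI", "V_HI", "V_JI", "V_LI", "V_KI", "V_PVI",
           "V_PII", "Q_BI", "Q_HI", "Q_AI", "Q_KI", "Q_PI", "Q_JI", "Q_LI",
           "T_PI", "tau_I", "tau_Gamma", "alpha", "beta", "K", "Q0", "gamma",
           "M1", "M2", "r_MGammaC", "V_Gamma", "G_PVB", "I_PVB")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter ", nm, " must be positive and finite")
  for (nm in c("F_LIC", "F_KIC", "F_PIC"))
    if (p[[nm]] <= 0 || p[[nm]] >= 1)
      stop("fractional clearance ", nm, " must lie in (0,1)")
  stopifnot(abs(p$Q_BG + p$Q_LG + p$Q_KG + p$Q_PG - p$Q_HG) < 1e-9,
            abs(p$Q_AG + p$Q_JG - p$Q_LG) < 1e-9,
            abs(p$Q_BI + p$Q_LI + p$Q_KI + p$Q_PI - p$Q_HI) < 1e-9,
            abs(p$Q_AI + p$Q_JI - p$Q_LI) < 1e-9)
  invisible(p)
}

#' Gut transit parameter set
#'
#' Rate constants of the four-compartment gastrointestinal transit chain
#' (stomach, jejunum, delay, ileum) and the bioavailable fraction \code{f}.
#'
#' Presets: \code{"ogtt_fit"} (transit rates refitted against the reference
#' oral-absorption curve; the default), \code{"simo_prior"} (the original
#' population-average values of the gut transit model), and
#' \code{"table3_after"} (the joint whole-model refit).
#'
#' @param preset character preset name.
#' @param ... named numeric overrides (\code{k_js}, \code{k_gj}, \code{k_rj},
#'   \code{k_lr}, \code{k_gl}, \code{f}).
#' @return an object of class \code{simo_params}.
#' @export
#' @examples
#' simo_params("simo_prior")$k_js
simo_params <- function(preset = c("ogtt_fit", "simo_prior", "table3_after"),
                        ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    ogtt_fit = list(k_js = 0.028237, k_gj = 0.0329673, k_rj = 0.0344046,
                    k_lr = 0.0513802, k_gl = 0.0180942, f = 1),
    simo_prior = list(k_js = 0.25, k_gj = 0.042, k_rj = 0.09,
                      k_lr = 0.06, k_gl = 0.1, f = 0.7),
    table3_after = list(k_js = 0.026, k_gj = 0.032, k_rj = 0.029,
                        k_lr = 0.026, k_gl = 0.035, f = 1))
  p$preset <- preset
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c("k_js", "k_gj", "k_rj", "k_lr", "k_gl", "f"))
    if (length(bad))
      stop("unknown gut parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  for (nm in c("k_js", "k_gj", "k_rj", "k_lr", "k_gl"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("gut rate constant ", nm, " must be positive")
  if (p$f <= 0 || p$f > 1) stop("bioavailable fraction f must lie in (0,1]")
  class(p) <- "simo_params"
  p
}

#' Serialize a parameter set to JSON
#'
#' @param p a \code{sorensen_params} or \code{simo_params} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(p, path) {
  x <- unclass(p)
  # named coefficient vectors must serialize as objects, not bare arrays
  x <- lapply(x, function(v)
    if (is.numeric(v) && length(v) > 1 && !is.null(names(v))) as.list(v)
    else v)
  x$.class <- class(p)[1]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path file written by [write_params()].
#' @return the deserialized parameter object, revalidated.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "sorensen_params")) {
    base <- sorensen_params(x$preset)
    keep <- setdiff(names(x), "preset")
    base[keep] <- lapply(x[keep], function(v)
      if (is.list(v)) unlist(v) else v)   # named vectors round-trip as objects
    validate_params(base)
    base
  } else if (identical(cls, "simo_params")) {
    do.call(simo_params, c(list(preset = x$preset),
                           x[setdiff(names(x), "preset")]))
  } else stop("unrecognized parameter file: ", path)
}
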