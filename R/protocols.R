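#' Dosing/sampling protocol description
#'
#' @param route one of \code{"iv_glucose_bolus"} (dose in g/kg),
#'   \code{"iv_insulin_bolus"} (U/kg), \code{"iv_insulin_infusion"}
#'   (mU/kg/min), \code{"oral_glucose"} (g, absolute) or \code{"none"}.
#' @param dose dose in the route's unit (>= 0).
#' @param body_weight kg; the standard-man 70 kg by default.
#' @param window administration window, min. Boluses are delivered as a
#'   constant-rate input over this window (default 3 min); for infusions it
#'   is the infusion length.
#' @param duration total simulated time, min.
#' @param grid output grid spacing, min (event times are inserted exactly).
#' @param label free-text label.
#' @return object of class \code{sorensen_protocol}.
#' @export
#' @examples
#' protocol("iv_glucose_bolus", 0.5)  # the standard 0.5 g/kg IVGTT
protocol <- function(route = c("iv_glucose_bolus", "iv_insulin_bolus",
                               "iv_insulin_infusion", "oral_glucose", "none"),
                     dose = 0, body_weight = 70, window = 3,
                     duration = 180, grid = 1, label = NULL) {
  route <- match.arg(route)
  if (!is.numeric(dose) || length(dose) != 1 || dose < 0)
    stop("dose must be a single non-negative number")
  if (duration <= 0) stop("duration must be positive")
  if (window < 0) stop("administration window must be non-negative")
  if (route == "iv_insulin_infusion" && window == 0)
    stop("an infusion needs a positive administration window")
  if (route != "none" && dose > 0 && window == 0 && route != "oral_glucose")
    stop("an intravenous dose needs a positive administration window")
  if (window > duration) stop("administration window exceeds duration")
  structure(list(route = route, dose = dose, body_weight = body_weight,
                 window = window, duration = duration, grid = grid,
                 label = label %||%
                   sprintf("%s %g", route, dose)),
            class = "sorensen_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## dose -> (iv_glucose mg/min, iv_insulin mU/min, oral mg) over the window
protocol_inputs <- function(proto) {
  bw <- proto$body_weight
  w <- proto$window
  switch(proto$route,
    iv_glucose_bolus = list(iv_glucose = proto$dose * bw * 1000 / w,
                            iv_insulin = 0, oral = 0),
    iv_insulin_bolus = list(iv_glucose = 0,
                            iv_insulin = proto$dose * bw * 1000 / w, oral = 0),
    iv_insulin_infusion = list(iv_glucose = 0,
                               iv_insulin = proto$dose * bw, oral = 0),
    oral_glucose = list(iv_glucose = 0, iv_insulin = 0,
                        oral = proto$dose * 1000),
    none = list(iv_glucose = 0, iv_insulin = 0, oral = 0))
}

#' Simulate a dosing protocol
#'
#' Integrates the whole-body model from its basal steady state under the
#' protocol's exogenous inputs. Intravenous doses are delivered as
#' constant-rate inputs into the heart/lungs balances over the
#' administration window; oral doses are loaded into the stomach
#' compartment at time zero. The integration is split at the window
#' boundary so the discontinuous input is never stepped across.
#'
#' @param proto a [protocol()].
#' @param p parameter set.
#' @param simo gut parameter set (used by the transit chain; inert for
#'   intravenous routes).
#' @param basal basal solution; computed from \code{p} when \code{NULL}.
#' @param times optional explicit output times (overrides the protocol
#'   grid); must start at 0.
#' @param rtol,atol integrator tolerances.
#' @return object of class \code{sorensen_sim}: data.frame with
#'   \code{time}, the 26 state variables, and derived observable channels
#'   \code{glucose_blood} (0.84 G_PV, peripheral venous blood),
#'   \code{glucose_plasma} (0.925 G_PV, venous plasma), \code{insulin}
#'   (I_PV), \code{r_oga} (mg/min) and \code{r_PIR} (mU/min).
#' @export
#' @examples
#' s <- run_protocol(protocol("iv_glucose_bolus", 0.5, duration = 120))
#' max(s$glucose_blood)
run_protocol <- function(proto, p = sorensen_params(), simo = simo_params(),
                         basal = NULL, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(proto, "sorensen_protocol"))
  if (is.null(basal)) basal <- basal_state(p)
  if (is.null(times))
    times <- sort(unique(c(seq(0, proto$duration, by = proto$grid),
                           proto$duration, proto$window)))
  else {
    stopifnot(times[1] == 0, all(diff(times) > 0))
    if (proto$window > 0 && proto$window < max(times))
      times <- sort(unique(c(times, proto$window)))
  }
  inp <- protocol_inputs(proto)
  y0 <- basal$state
  y0[["S_sto"]] <- y0[["S_sto"]] + inp$oral

  segs <- if (inp$iv_glucose > 0 || inp$iv_insulin > 0)
    list(c(0, proto$window), c(proto$window, max(times)))
  else list(c(0, max(times)))

  rows <- NULL
  y <- y0
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s[2] <= s[1]) next
    on_seg <- times[times >= s[1] & times <= s[2]]
    if (length(on_seg) < 2 || on_seg[1] > s[1])
      on_seg <- sort(unique(c(s[1], on_seg)))
    if (on_seg[length(on_seg)] < s[2]) on_seg <- c(on_seg, s[2])
    dosing <- i == 1 && (inp$iv_glucose > 0 || inp$iv_insulin > 0)
    rhs <- make_rhs(p, basal, simo,
                    iv_glucose = if (dosing) inp$iv_glucose else 0,
                    iv_insulin = if (dosing) inp$iv_insulin else 0)
    sol <- ode_rk45(rhs, y, on_seg, rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    names(y) <- .state_names
    rows <- rbind(rows, if (is.null(rows)) sol else sol[-1, , drop = FALSE])
  }
  out <- as.data.frame(rows)
  out <- out[out$time %in% times, , drop = FALSE]
  rownames(out) <- NULL
  neg <- vapply(out[.state_names[1:16]], function(v) any(v < -1e-8), logical(1))
  if (any(neg))
    warning("negative concentration excursion in ",
            paste(names(neg)[neg], collapse = ", "))
  ## derived observable channels
  out$glucose_blood <- 0.84 * out$G_PV
  out$glucose_plasma <- 0.925 * out$G_PV
  out$insulin <- out$I_PV
  out$r_oga <- simo$f * (simo$k_gj * out$J_jej + simo$k_gl * out$L_ile)
  Xr <- with(out, {
    g <- G_H / p$pancreas_glucose_scale
    g^p$beta_pir1 / (p$beta_pir2^p$beta_pir1 + p$beta_pir3 * g^p$beta_pir4)
  })
  S <- (p$M1 * Xr^p$beta_pir5 + p$M2 * pmax(0, Xr - out$I_inh)) * out$Q
  out$r_PIR <- S / basal$S_B * basal$r_PIRB
  attr(out, "protocol") <- proto
  attr(out, "basal") <- basal
  class(out) <- c("sorensen_sim", "data.frame")
  out
}

#' Extract an observable channel
#'
#' Applies the venous conversion factors: 0.84 maps peripheral vascular
#' glucose to peripheral venous blood glucose, 0.925 to venous plasma
#' glucose; insulin channels are reported as simulated.
#'
#' @param series a \code{sorensen_sim} from [run_protocol()].
#' @param channel one of \code{"glucose_blood"}, \code{"glucose_plasma"},
#'   \code{"insulin"}, \code{"r_oga"}, \code{"r_PIR"}, or any raw state
#'   variable name.
#' @return data.frame with \code{time}, \code{channel}, \code{value}.
#' @export
to_observed <- function(series, channel) {
  valid <- c("glucose_blood", "glucose_plasma", "insulin", "r_oga", "r_PIR",
             sorensen_state_names())
  if (!channel %in% valid)
    stop("unknown channel '", channel, "'; valid channels: ",
         paste(valid[1:5], collapse = ", "), ", or a state variable name")
  data.frame(time = series$time, channel = channel,
             value = series[[channel]])
}
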