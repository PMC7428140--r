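## Synthetic observation generation. The observation sets used by the
## estimation and MCMC machinery stand in for experiment recordings that
## are not distributable; every generated set is labelled STANDIN in its
## metadata and is a pure function of (parameters, times, seed).

#' Generate noisy observations from a simulated series
#'
#' Samples the requested channels of a simulation at the requested times
#' and applies the mean-proportional error model
#' \code{y = f (1 + sigma z)}, \code{z} iid standard normal -- the same
#' constant-CV structure assumed by the WLS weighting and the Bayesian
#' error model. Deterministic under a fixed seed.
#'
#' @param series a \code{sorensen_sim} from [run_protocol()] whose grid
#'   contains \code{times}.
#' @param channels character vector of observable channel names.
#' @param times sampling times (subset of the series grid).
#' @param sigma noise coefficient of variation (0 = exact model curve).
#' @param seed RNG seed.
#' @return an [observation_set()] with attribute \code{standin = TRUE}.
#' @export
generate_observations <- function(series, channels, times, sigma = 0.05,
                                  seed = 1) {
  stopifnot(sigma >= 0)
  miss <- setdiff(times, series$time)
  if (length(miss))
    stop("requested times not on the simulation grid: ",
         paste(utils::head(miss, 5), collapse = ", "))
  rows <- do.call(rbind, lapply(channels, function(ch) {
    f <- to_observed(series, ch)
    f <- f[f$time %in% times, , drop = FALSE]
    if (any(f$value < 0))
      stop("channel ", ch, " is negative at a requested time")
    f
  }))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  z <- stats::rnorm(nrow(rows))
  rows$value <- rows$value * (1 + sigma * z)
  rows$value <- pmax(rows$value, 0)
  out <- observation_set(rows, sigma = max(sigma, 0.05))
  attr(out, "standin") <- TRUE
  attr(out, "seed") <- seed
  attr(out, "noise_sigma") <- sigma
  out
}

## declared stand-in sampling grids: dense early (5-min spacing), sparse
## late (20-min spacing), the usual oral-test practice
standin_grid <- function(n_points) {
  if (n_points == 27) return(c(seq(0, 70, 5), seq(90, 290, 20), 300))
  if (n_points == 25) return(c(seq(0, 60, 5), seq(80, 300, 20)))
  seq(0, 300, length.out = n_points)
}

#' Stand-in oral absorption-rate observations
#'
#' Simulates the gut transit chain for a 100 g oral dose and samples the
#' absorption rate \code{r_oga} on the declared stand-in grid (27 points
#' by default, dense to 70 min then every 20 min to 300 min). The first
#' record is the structural zero at dose time.
#'
#' @param sp gut parameter set generating the curve.
#' @param n_points number of records (>= 2; 2 gives the endpoints only).
#' @param dose oral dose, mg.
#' @param sigma noise CV (0 = noiseless).
#' @param seed RNG seed.
#' @return an [observation_set()] of channel \code{r_oga}, labelled
#'   STANDIN.
#' @export
#' @examples
#' obs <- generate_roga_standin()
#' nrow(obs$data)  # 27
generate_roga_standin <- function(sp = simo_params("ogtt_fit"),
                                  n_points = 27, dose = 1e5, sigma = 0,
                                  seed = 1) {
  stopifnot(n_points >= 2)
  times <- standin_grid(n_points)
  s <- simo_simulate(dose, sp, times = times)
  dat <- data.frame(time = times, channel = "r_oga", value = s$r_oga)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  dat$value <- pmax(dat$value * (1 + sigma * stats::rnorm(nrow(dat))), 0)
  out <- observation_set(dat, sigma = max(sigma, 0.05))
  attr(out, "standin") <- TRUE
  attr(out, "seed") <- seed
  attr(out, "noise_sigma") <- sigma
  attr(out, "generator") <- unlist(sp[c("k_js", "k_gj", "k_rj", "k_lr",
                                        "k_gl", "f")])
  out
}

#' Stand-in pancreatic release and oral-test observations
#'
#' Simulates a 100 g oral test with the refitted ("after") secretion and
#' transit parameterization and samples the pancreatic insulin release
#' rate (25 points by default) and optionally the venous plasma glucose
#' and insulin channels, standing in for the recordings used by the
#' staged identification.
#'
#' @param p whole-body parameter set generating the curves.
#' @param sp gut parameter set.
#' @param n_points number of release-rate records.
#' @param channels additional observed channels to include.
#' @param sigma noise CV.
#' @param seed RNG seed.
#' @return an [observation_set()] labelled STANDIN.
#' @export
generate_ogtt_standin <- function(p = sorensen_params("table3_after"),
                                  sp = simo_params("table3_after"),
                                  n_points = 25,
                                  channels = c("glucose_plasma", "insulin"),
                                  sigma = 0, seed = 1) {
  times <- standin_grid(n_points)
  sim <- run_protocol(protocol("oral_glucose", 100, duration = max(times)),
                      p, sp, times = sort(unique(c(0, times))))
  out <- generate_observations(sim, c("r_PIR", channels), times,
                               sigma = sigma, seed = seed)
  attr(out, "standin") <- TRUE
  out
}
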