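#' Observation set for weighted least-squares fitting
#'
#' Timestamped observations of the observable channels with the
#' constant-coefficient-of-variation error model: observation variances are
#' proportional to the squared model expectation, so residuals are weighted
#' by the inverse squared predictions.
#'
#' @param data data.frame with columns \code{time}, \code{channel},
#'   \code{value}; channels from \code{glucose_blood}, \code{glucose_plasma},
#'   \code{insulin}, \code{r_oga}, \code{r_PIR}.
#' @param sigma scale parameter (coefficient of variation) of the error
#'   model.
#' @param weights optional named per-channel relative weight multipliers
#'   (default 1 for every channel; the loss stays a plain inverse-squared-
#'   expectation sum when all weights are equal).
#' @return object of class \code{observation_set}.
#' @export
observation_set <- function(data, sigma = 0.05, weights = NULL) {
  need <- c("time", "channel", "value")
  if (!all(need %in% names(data)))
    stop("observations need columns time, channel, value")
  if (nrow(data) == 0) stop("empty observation set")
  valid <- c("glucose_blood", "glucose_plasma", "insulin", "r_oga", "r_PIR")
  bad <- setdiff(unique(data$channel), valid)
  if (length(bad))
    stop("unknown channel(s) ", paste(bad, collapse = ", "),
         "; valid channels: ", paste(valid, collapse = ", "))
  for (ch in unique(data$channel)) {
    tt <- data$time[data$channel == ch]
    if (is.unsorted(tt)) stop("times must be nondecreasing within channel ", ch)
  }
  if (any(!is.finite(data$value)) || any(data$value < 0))
    stop("observation values must be finite and non-negative")
  w <- rep(1, nrow(data))
  if (!is.null(weights)) {
    miss <- setdiff(unique(data$channel), names(weights))
    if (length(miss)) weights[miss] <- 1
    w <- unname(weights[data$channel])
  }
  structure(list(data = data[need], sigma = sigma, w = w),
            class = "observation_set")
}

#' Weighted least-squares loss
#'
#' \code{sum_j (y_j - f_j)^2 / f_j^2}: squared residuals weighted by the
#' inverse squared model expectations, summed over all channels. A
#' simulation failure (error, non-finite or non-positive prediction) is
#' absorbed as a large finite penalty so a multistart never aborts.
#'
#' @param theta named parameter vector.
#' @param obs an [observation_set()].
#' @param predict_fn function \code{theta -> predictions} aligned with the
#'   rows of \code{obs$data}.
#' @param penalty loss returned on simulation failure.
#' @return scalar loss (>= 0).
#' @export
wls_loss <- function(theta, obs, predict_fn, penalty = 1e9) {
  f <- tryCatch(predict_fn(theta), error = function(e) NULL)
  if (is.null(f) || length(f) != nrow(obs$data) ||
      any(!is.finite(f)) || any(f < 0))
    return(penalty)
  y <- obs$data$value
  ## a structurally zero expectation (e.g. the absorption rate at dose
  ## time) carries zero variance: it contributes nothing when matched by a
  ## zero observation and is otherwise unattainable
  zero <- f == 0
  if (any(zero & y != 0)) return(penalty)
  ok <- !zero
  sum(obs$w[ok] * ((y[ok] - f[ok]) / f[ok])^2)
}

#' Multi-start weighted least-squares fit
#'
#' Each start perturbs every free parameter with a Normal draw centered on
#' its center value with standard deviation \code{cv} times that value
#' (truncated at a small positivity floor), then runs a local minimizer in
#' log-parameter space. Returns the best-loss estimate together with the
#' full cloud of per-start estimates and losses, from which means, SDs,
#' CVs and pairwise correlations of the estimates are summarized.
#'
#' @param predict_fn prediction function as in [wls_loss()].
#' @param obs an [observation_set()].
#' @param center named vector of center values for the free parameters
#'   (all > 0).
#' @param n_starts number of optimization starts (>= 1).
#' @param cv start-perturbation coefficient of variation (0.15 by default).
#' @param seed master seed; per-start draws are derived deterministically.
#' @param method \code{"nlminb"} (default: quasi-Newton with a simplex
#'   polish and a second quasi-Newton pass, markedly the most reliable on
#'   this loss surface) or any method name accepted by [stats::optim()]
#'   (e.g. \code{"Nelder-Mead"} for a purely derivative-free search).
#' @param maxit iteration cap per start.
#' @param reltol convergence tolerance per start.
#' @return object of class \code{sorensen_fit}.
#' @export
multistart_fit <- function(predict_fn, obs, center, n_starts = 100,
                           cv = 0.15, seed = 1, method = "nlminb",
                           maxit = 500, reltol = 1e-10) {
  stopifnot(n_starts >= 1, all(center > 0), !is.null(names(center)))
  pnames <- names(center)
  objective <- function(lt) {
    th <- exp(lt); names(th) <- pnames
    wls_loss(th, obs, predict_fn)
  }
  starts <- matrix(NA_real_, n_starts, length(center),
                   dimnames = list(NULL, pnames))
  ests <- starts
  losses <- numeric(n_starts)
  init_losses <- numeric(n_starts)
  conv <- integer(n_starts)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (i in seq_len(n_starts)) {
    th0 <- if (cv > 0)
      pmax(center + stats::rnorm(length(center)) * cv * center, 1e-8 * center)
    else center
    starts[i, ] <- th0
    init_losses[i] <- objective(log(th0))
    if (method == "nlminb") {
      r <- stats::nlminb(log(th0), objective,
                         control = list(iter.max = maxit,
                                        eval.max = 4 * maxit))
      # quasi-Newton can stall on the penalty plateau; a short simplex
      # polish plus a second quasi-Newton pass is markedly more robust
      r2 <- stats::optim(r$par, objective,
                         method = if (length(th0) == 1) "BFGS"
                         else "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
      r3 <- stats::nlminb(r2$par, objective,
                          control = list(iter.max = maxit,
                                         eval.max = 4 * maxit))
      best_r <- list(r, r2, r3)[[which.min(c(r$objective, r2$value,
                                             r3$objective))]]
      ests[i, ] <- exp(best_r$par)
      losses[i] <- best_r$objective %||% best_r$value
      conv[i] <- best_r$convergence
    } else {
      fit <- stats::optim(log(th0), objective, method = method,
                          control = list(maxit = maxit, reltol = reltol))
      ests[i, ] <- exp(fit$par)
      losses[i] <- fit$value
      conv[i] <- fit$convergence
    }
  }
  if (all(losses >= 1e9)) stop("all optimization starts failed")
  best <- which.min(losses)
  summ <- list(mean = colMeans(ests), sd = apply(ests, 2, stats::sd),
               cor = if (n_starts >= 3) stats::cor(ests) else NULL)
  summ$cv <- 100 * summ$sd / summ$mean
  structure(list(par = ests[best, ], loss = losses[best], best = best,
                 estimates = ests, losses = losses, starts = starts,
                 initial_losses = init_losses, convergence = conv,
                 summary = summ, seed = seed, method = method),
            class = "sorensen_fit")
}

#' @export
print.sorensen_fit <- function(x, ...) {
  cat("Multi-start WLS fit:", nrow(x$estimates), "start(s), best loss",
      signif(x$loss, 6), "\n")
  print(signif(x$par, 6))
  invisible(x)
}

#' Asymptotic covariance of a WLS estimate
#'
#' Central finite-difference Jacobian \code{J} of the model predictions
#' with respect to the free parameters at the optimum; observation
#' covariance \code{S = sigma^2 F} with \code{F = diag(f^2)}; parameter
#' covariance \code{[J^T S^-1 J]^-1 = sigma^2 [J^T F^-1 J]^-1}. Percent CVs
#' are \code{100 sqrt(cov_ii)/theta_i}. A singular information matrix
#' (e.g. a parameter without effect on the predictions) falls back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param theta_hat named estimate vector.
#' @param predict_fn prediction function.
#' @param obs an [observation_set()].
#' @param sigma scale parameter (CV) of the error model; estimated from the
#'   residuals as \code{sqrt(loss/(n - p))} when \code{NULL}.
#' @param rel_step relative finite-difference step.
#' @return list with \code{cov}, \code{cv} (percent), \code{cor},
#'   \code{sd}, \code{sigma2}, \code{J} and \code{singular} flag.
#' @export
asymptotic_covariance <- function(theta_hat, predict_fn, obs, sigma = NULL,
                                  rel_step = 1e-4) {
  f0 <- predict_fn(theta_hat)
  stopifnot(length(f0) == nrow(obs$data), all(f0 >= 0))
  keep <- f0 > 0      # zero-variance rows carry no information
  obs <- observation_set(obs$data[keep, , drop = FALSE], sigma = obs$sigma)
  f0 <- f0[keep]
  predict_all <- predict_fn
  predict_fn <- function(th) predict_all(th)[keep]
  n <- length(f0); p_ <- length(theta_hat)
  if (n <= p_ && is.null(sigma))
    stop("no residual degrees of freedom to estimate sigma")
  J <- fd_jacobian(function(th) {
    names(th) <- names(theta_hat); predict_fn(th)
  }, theta_hat, f0 = f0, rel = rel_step, abs_ = 0)
  sigma2 <- if (is.null(sigma))
    sum(((obs$data$value - f0) / f0)^2) / (n - p_)
  else sigma^2
  info <- crossprod(J / f0)            # J' F^-1 J
  singular <- FALSE
  covm <- tryCatch({
    if (qr(info)$rank < p_) stop("rank deficient")
    sigma2 * solve(info)
  }, error = function(e) {
    singular <<- TRUE
    warning("singular information matrix; using pseudo-inverse ",
            "(a parameter may have no effect on the predictions)")
    s <- svd(info)
    pos <- s$d > max(s$d) * 1e-12
    sigma2 * s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })
  sdv <- sqrt(pmax(diag(covm), 0))
  dimnames(covm) <- list(names(theta_hat), names(theta_hat))
  corm <- covm / outer(sdv, sdv)
  diag(corm) <- 1
  list(cov = covm, sd = stats::setNames(sdv, names(theta_hat)),
       cv = 100 * sdv / abs(theta_hat), cor = corm, sigma2 = sigma2,
       J = J, singular = singular)
}

## ---- predictors -----------------------------------------------------------

#' Prediction function for gut-transit (absorption-curve) fitting
#'
#' Closes over an observation set whose rows are all \code{r_oga} and
#' returns a function mapping the named transit rate constants to the
#' model absorption curve at the observation times (closed-form linear
#' solution; the bioavailable fraction stays at the base value).
#'
#' @param obs an [observation_set()] with channel \code{r_oga} only.
#' @param dose oral dose, mg.
#' @param sp_base base gut parameter set supplying any parameter not in
#'   \code{theta}.
#' @return function \code{theta -> r_oga predictions}.
#' @export
simo_predictor <- function(obs, dose = 1e5, sp_base = simo_params()) {
  stopifnot(all(obs$data$channel == "r_oga"))
  times <- obs$data$time
  function(theta) {
    sp <- sp_base
    sp[names(theta)] <- theta
    A <- simo_matrix(sp)
    st <- vapply(times, function(tt)
      as.vector(Matrix::expm(A * tt) %*% c(dose, 0, 0, 0)), numeric(4))
    sp$f * (sp$k_gj * st[2, ] + sp$k_gl * st[4, ])
  }
}

#' Prediction function for whole-model fitting
#'
#' Returns a function mapping free parameters (whole-body pancreatic
#' secretion parameters and/or gut transit rate constants, by name) to the
#' simulated observable channels at the observation times. The basal
#' steady state is re-solved for every parameter vector, since the
#' secretion parameters enter the basal pancreas.
#'
#' @param obs an [observation_set()] (any mix of channels).
#' @param proto the dosing [protocol()] that generated the observations.
#' @param p_base base whole-body parameter set.
#' @param simo_base base gut parameter set.
#' @param rtol,atol integrator tolerances for the fitting simulations
#'   (defaults relaxed relative to reporting runs; fit objectives are
#'   smooth at 1e-6).
#' @return function \code{theta -> predictions}.
#' @export
sorensen_predictor <- function(obs, proto, p_base = sorensen_params(),
                               simo_base = simo_params(),
                               rtol = 1e-6, atol = 1e-8) {
  dat <- obs$data
  times <- sort(unique(c(0, dat$time)))
  simo_names <- c("k_js", "k_gj", "k_rj", "k_lr", "k_gl", "f")
  function(theta) {
    p <- p_base; sp <- simo_base
    for (nm in names(theta)) {
      if (nm %in% simo_names) sp[[nm]] <- theta[[nm]]
      else if (nm %in% names(p)) p[[nm]] <- theta[[nm]]
      else stop("unknown free parameter ", nm)
    }
    b <- basal_state(p)
    sim <- run_protocol(proto, p, sp, basal = b, times = times,
                        rtol = rtol, atol = atol)
    idx <- match(dat$time, sim$time)
    vapply(seq_len(nrow(dat)),
           function(i) sim[[dat$channel[i]]][idx[i]], numeric(1))
  }
}

## ---- the four-step identification pipeline --------------------------------

#' Staged identification pipeline
#'
#' The staged protocol for identifying the oral-dosing model on absorption,
#' secretion, glucose and insulin observations:
#' \describe{
#'   \item{STEP 1}{fit the 5 gut transit rate constants (bioavailable
#'     fraction fixed at 1) to an absorption-rate curve.}
#'   \item{STEP 2}{fix the gut chain, run a multistart (100 starts by
#'     default) over the 11 free pancreatic secretion parameters
#'     (\code{Q0} stays fixed), against glucose, insulin and
#'     secretion-rate observations.}
#'   \item{STEP 3}{free all 16 parameters; single fit started from the
#'     STEP 1 optimum plus the best STEP 2 optimum.}
#'   \item{STEP 4}{200 perturbed restarts (15% CV) about the STEP 3
#'     optimum; summarizes the estimate distributions (mean, SD, CV,
#'     pairwise correlations) and the loss distribution, plus the
#'     asymptotic covariance at the STEP 3 optimum.}
#' }
#'
#' Stage outputs chain: pass the returned object of the previous stage via
#' \code{prev}. Defaults reproduce the published stage sizes; \code{n_starts}
#' and \code{maxit} can be scaled down for quick runs.
#'
#' @param step integer 1-4.
#' @param obs an [observation_set()]; STEP 1 wants \code{r_oga} rows only,
#'   STEPs 2-4 the multi-channel set.
#' @param prev output of the previous step (list of stage results so far).
#' @param proto dosing protocol for STEPs 2-4 (oral dose by default).
#' @param p_base,simo_base base parameter sets (centers for the perturbed
#'   starts).
#' @param n_starts multistart size override (NULL = published default).
#' @param seed master seed.
#' @param maxit per-start iteration cap.
#' @param rtol integrator tolerance used inside the fits.
#' @param method local minimizer, as in [multistart_fit()].
#' @return list of stage results, extended by the new stage.
#' @export
run_identification_pipeline <- function(step, obs, prev = NULL,
                               proto = protocol("oral_glucose", 100,
                                                duration = 300),
                               p_base = sorensen_params(),
                               simo_base = simo_params("simo_prior"),
                               n_starts = NULL, seed = 1, maxit = 500,
                               rtol = 1e-6, method = "nlminb") {
  stopifnot(step %in% 1:4)
  out <- prev %||% list()
  pancreas_free <- c("alpha", "beta", "K", "gamma", "M1", "M2",
                     "beta_pir1", "beta_pir2", "beta_pir3", "beta_pir4",
                     "beta_pir5")
  simo_free <- c("k_js", "k_gj", "k_rj", "k_lr", "k_gl")
  if (step == 1) {
    pf <- simo_predictor(obs, sp_base = simo_params("simo_prior", f = 1))
    center <- unlist(simo_base[simo_free])
    out$step1 <- multistart_fit(pf, obs, center,
                                n_starts = n_starts %||% 3, seed = seed,
                                maxit = maxit, method = method)
  } else if (step == 2) {
    if (is.null(out$step1)) stop("STEP 2 needs the STEP 1 result (prev)")
    sp_fix <- simo_params("simo_prior", f = 1)
    sp_fix[simo_free] <- as.list(out$step1$par[simo_free])
    pf <- sorensen_predictor(obs, proto, p_base, sp_fix, rtol = rtol)
    center <- unlist(p_base[pancreas_free])
    out$step2 <- multistart_fit(pf, obs, center,
                                n_starts = n_starts %||% 100, seed = seed,
                                maxit = maxit, method = method)
  } else if (step == 3) {
    if (is.null(out$step2)) stop("STEP 3 needs the STEP 2 result (prev)")
    pf <- sorensen_predictor(obs, proto, p_base,
                             simo_params("simo_prior", f = 1), rtol = rtol)
    center <- c(out$step1$par[simo_free], out$step2$par[pancreas_free])
    out$step3 <- multistart_fit(pf, obs, center, n_starts = 1, cv = 0,
                                seed = seed, maxit = maxit, method = method)
    out$step3$covariance <- tryCatch(
      asymptotic_covariance(out$step3$par, pf, obs),
      error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (is.null(out$step3)) stop("STEP 4 needs the STEP 3 result (prev)")
    pf <- sorensen_predictor(obs, proto, p_base,
                             simo_params("simo_prior", f = 1), rtol = rtol)
    fit <- multistart_fit(pf, obs, out$step3$par,
                          n_starts = n_starts %||% 200, seed = seed,
                          maxit = maxit, method = method)
    fit$loss_distribution <- c(min = min(fit$losses), max = max(fit$losses),
                               mean = mean(fit$losses),
                               sd = stats::sd(fit$losses))
    out$step4 <- fit
  }
  out
}
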