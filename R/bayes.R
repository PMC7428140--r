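## Metropolis-within-Gibbs a-posteriori identifiability analysis.
## The inference target is xi = (eta, sigma^2) with eta = log(theta):
## sigma^2 carries an inverse-gamma prior and is drawn exactly from its
## inverse-gamma full conditional; eta carries a uniform prior on a box D
## in log space and is updated by a random-walk Metropolis step with a
## fixed multinormal proposal whose covariance comes from the asymptotic
## CVs (Var(log theta) ~ CV^2 by the delta method).

#' MCMC configuration
#'
#' @param log_opt named vector: the log of the optimum parameter values
#'   (the center of the prior box and of the starting lattice).
#' @param cv_percent percent coefficients of variation (from
#'   [asymptotic_covariance()]); the proposal covariance is
#'   \code{diag((cv_percent/100)^2)} unless \code{proposal_cov} is given.
#' @param D 2 x p matrix of lower/upper prior-box bounds in log space;
#'   default is \code{log_opt} plus/minus 100% of its own value per axis.
#' @param nu,tau inverse-gamma hyperparameters of the sigma^2 prior
#'   (weakly informative 0.01/0.01 defaults).
#' @param chains,iterations,burnin chain layout (9 x 10000, burn-in 1000
#'   by default).
#' @param proposal_cov optional full proposal covariance matrix for eta.
#' @param proposal_scale multiplier applied to the proposal standard
#'   deviations (1 = use the asymptotic CVs as printed).
#' @param seed master seed; per-chain substreams are derived
#'   deterministically from it.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(log_opt, cv_percent, D = NULL, nu = 0.01, tau = 0.01,
                        chains = 9, iterations = 10000, burnin = 1000,
                        proposal_cov = NULL, proposal_scale = 1, seed = 1) {
  stopifnot(length(log_opt) >= 1, length(cv_percent) == length(log_opt),
            iterations > burnin, chains >= 1)
  p <- length(log_opt)
  if (is.null(D)) {
    half <- abs(log_opt)
    if (any(half == 0)) stop("log-optimum exactly 0: supply D explicitly")
    D <- rbind(lower = log_opt - half, upper = log_opt + half)
  }
  stopifnot(nrow(D) == 2, ncol(D) == p, all(D[2, ] > D[1, ]))
  if (is.null(proposal_cov))
    proposal_cov <- diag((proposal_scale * cv_percent / 100)^2, p)
  structure(list(log_opt = log_opt, cv_percent = cv_percent, D = D,
                 nu = nu, tau = tau, chains = chains,
                 iterations = iterations, burnin = burnin,
                 proposal_cov = proposal_cov, seed = seed,
                 par_names = names(log_opt)),
            class = "mcmc_config")
}

#' Gibbs draw of the error-model scale parameter
#'
#' One exact draw from the inverse-gamma full conditional of sigma^2 under
#' the proportional-error model: shape \code{(n + nu)/2}, scale
#' \code{[(y-f)^T F^-1 (y-f) + tau]/2} with \code{F = diag(f^2)}.
#'
#' @param y observation vector.
#' @param f model predictions at the current parameters (all non-zero).
#' @param nu,tau inverse-gamma hyperparameters.
#' @return one sigma^2 draw.
#' @export
sample_sigma2 <- function(y, f, nu = 0.01, tau = 0.01) {
  stopifnot(length(y) == length(f), length(y) >= 1)
  if (any(f == 0)) stop("degenerate weight: a model prediction is zero")
  shape <- (length(y) + nu) / 2
  scale <- (sum(((y - f) / f)^2) + tau) / 2
  scale / stats::rgamma(1, shape = shape)
}

#' Log full conditional of the log-parameters
#'
#' Builds the un-normalized log full conditional of \code{eta = log(theta)}
#' under the proportional-error likelihood:
#' \code{-1/2 log|S| - 1/2 (y-f)^T S^-1 (y-f)} with
#' \code{S = sigma^2 diag(f^2)}, restricted to the prior box \code{D}.
#'
#' @param obs an [observation_set()].
#' @param predict_fn function \code{theta -> predictions}.
#' @return function \code{(eta, sigma2) -> list(lp, f)}.
#' @export
make_log_conditional <- function(obs, predict_fn) {
  y <- obs$data$value
  function(eta, sigma2) {
    th <- exp(eta)
    f <- tryCatch(predict_fn(th), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f)) || any(f <= 0))
      return(list(lp = -Inf, f = NULL))
    s2 <- sigma2 * f^2
    list(lp = -0.5 * sum(log(s2)) - 0.5 * sum((y - f)^2 / s2), f = f)
  }
}

in_box <- function(eta, D) all(eta >= D[1, ]) && all(eta <= D[2, ])

#' One Metropolis step for the log-parameters
#'
#' Random-walk proposal \code{eta_new = eta + L z} (with \code{L} the lower
#' Cholesky factor of the fixed proposal covariance, centered on the
#' current point), rejected outright outside the prior box; otherwise
#' Metropolis acceptance on the log full conditional. The proposal is
#' symmetric, so the Hastings correction cancels and only the two
#' posterior densities enter the ratio.
#'
#' @param eta current point (in the box).
#' @param lp current log full conditional value (must be finite).
#' @param log_cond function \code{(eta, sigma2) -> list(lp, f)}.
#' @param sigma2 current scale parameter.
#' @param prop_chol lower-triangular Cholesky factor of the proposal
#'   covariance.
#' @param D prior box (2 x p).
#' @return list with \code{eta}, \code{lp}, \code{f}, \code{accepted}.
#' @export
mh_step <- function(eta, lp, log_cond, sigma2, prop_chol, D) {
  if (!is.finite(lp)) stop("non-finite log-posterior at the current point")
  prop <- eta + as.vector(prop_chol %*% stats::rnorm(length(eta)))
  if (!in_box(prop, D))
    return(list(eta = eta, lp = lp, f = NULL, accepted = FALSE))
  cand <- log_cond(prop, sigma2)
  if (is.finite(cand$lp) && log(stats::runif(1)) < cand$lp - lp)
    list(eta = prop, lp = cand$lp, f = cand$f, accepted = TRUE)
  else
    list(eta = eta, lp = lp, f = NULL, accepted = FALSE)
}

#' Starting lattice on the prior box
#'
#' For two parameters: the four vertices of the box, the four edge
#' midpoints and the center (nine points). For other dimensions, the
#' center plus uniformly drawn points.
#'
#' @param cfg an [mcmc_config()].
#' @return matrix chains x p of starting points.
#' @export
chain_starts <- function(cfg) {
  p <- ncol(cfg$D)
  if (p == 2) {
    lev1 <- c(cfg$D[1, 1], mean(cfg$D[, 1]), cfg$D[2, 1])
    lev2 <- c(cfg$D[1, 2], mean(cfg$D[, 2]), cfg$D[2, 2])
    g <- as.matrix(expand.grid(lev1, lev2))
  } else {
    old <- local_seed(cfg$seed)
    on.exit(restore_seed(old))
    g <- rbind(colMeans(cfg$D),
               matrix(stats::runif((cfg$chains - 1) * p, cfg$D[1, ],
                                   cfg$D[2, ]), ncol = p, byrow = TRUE))
  }
  g <- g[rep(seq_len(nrow(g)), length.out = cfg$chains), , drop = FALSE]
  dimnames(g) <- list(NULL, cfg$par_names)
  g
}

#' Run the Metropolis-within-Gibbs chains
#'
#' Independent chains started on the prior-box lattice, each alternating
#' an exact inverse-gamma Gibbs draw of sigma^2 (when an observation set
#' and predictor are supplied) with a Metropolis update of the
#' log-parameters. Each chain runs on its own deterministically derived
#' RNG substream.
#'
#' @param cfg an [mcmc_config()].
#' @param obs,predict_fn observation set and predictor for the
#'   proportional-error model; alternatively supply \code{log_conditional}
#'   directly (a function \code{(eta, sigma2) -> list(lp, f)}) for custom
#'   targets, with \code{sigma2_fixed} if sigma^2 is not to be sampled.
#' @param log_conditional optional custom log full conditional.
#' @param sigma2_fixed when not NULL, sigma^2 is held at this value and
#'   the Gibbs draw is skipped.
#' @return object of class \code{sorensen_chains}: list with \code{draws}
#'   (iterations x p x chains), \code{sigma2} (iterations x chains),
#'   \code{acceptance} per chain, \code{starts} and the config.
#' @export
run_chains <- function(cfg, obs = NULL, predict_fn = NULL,
                       log_conditional = NULL, sigma2_fixed = NULL) {
  log_cond <- log_conditional %||% {
    if (is.null(obs) || is.null(predict_fn))
      stop("supply either (obs, predict_fn) or log_conditional")
    make_log_conditional(obs, predict_fn)
  }
  sample_s2 <- is.null(sigma2_fixed) && !is.null(obs)
  y <- if (!is.null(obs)) obs$data$value
  p <- length(cfg$log_opt)
  L <- t(chol(cfg$proposal_cov))
  starts <- chain_starts(cfg)
  draws <- array(NA_real_, c(cfg$iterations, p, cfg$chains),
                 dimnames = list(NULL, cfg$par_names, NULL))
  s2mat <- matrix(NA_real_, cfg$iterations, cfg$chains)
  acc <- numeric(cfg$chains)
  seeds <- derive_seeds(cfg$seed, cfg$chains)
  for (ch in seq_len(cfg$chains)) {
    old <- local_seed(seeds[ch])
    eta <- stats::setNames(starts[ch, ], cfg$par_names)
    sigma2 <- sigma2_fixed %||% 1
    cur <- log_cond(eta, sigma2)
    if (!is.finite(cur$lp))
      stop("chain ", ch, ": non-finite posterior at its starting point")
    f <- cur$f
    nacc <- 0L
    lp_of_f <- function(f, sigma2) {
      s2 <- sigma2 * f^2
      -0.5 * sum(log(s2)) - 0.5 * sum((y - f)^2 / s2)
    }
    for (it in seq_len(cfg$iterations)) {
      if (sample_s2) {
        sigma2 <- sample_sigma2(y, f, cfg$nu, cfg$tau)
        # predictions are unchanged by the sigma^2 move: update lp in place
        cur <- if (is.null(log_conditional)) list(lp = lp_of_f(f, sigma2), f = f)
        else log_cond(eta, sigma2)
      }
      st <- mh_step(eta, cur$lp, log_cond, sigma2, L, cfg$D)
      if (st$accepted) {
        eta <- st$eta
        cur <- list(lp = st$lp, f = st$f)
        if (!is.null(st$f)) f <- st$f
        nacc <- nacc + 1L
      }
      draws[it, , ch] <- eta
      s2mat[it, ch] <- sigma2
    }
    acc[ch] <- nacc / cfg$iterations
    restore_seed(old)
  }
  if (any(acc == 0))
    warning("chain(s) ", paste(which(acc == 0), collapse = ", "),
            " accepted no proposal: diagnostic failure, inspect the ",
            "proposal scale and the prior box")
  structure(list(draws = draws, sigma2 = s2mat, acceptance = acc,
                 starts = starts, config = cfg),
            class = "sorensen_chains")
}

#' Pooled post-burn-in draws
#'
#' @param chains a \code{sorensen_chains} object.
#' @param burnin burn-in length per chain (default from the config).
#' @return matrix (pooled draws x parameters).
#' @export
pooled_draws <- function(chains, burnin = chains$config$burnin) {
  keep <- (burnin + 1):chains$config$iterations
  p <- dim(chains$draws)[2]
  out <- do.call(rbind, lapply(seq_len(chains$config$chains), function(ch)
    matrix(chains$draws[keep, , ch], ncol = p)))
  colnames(out) <- chains$config$par_names
  out
}

#' Empirical 95% credibility region from pooled draws
#'
#' Builds a bins x bins relative-frequency histogram on the bounding box of
#' the pooled draws of two parameters and selects the smallest superlevel
#' set of cells whose total frequency reaches the requested level. Ties at
#' the threshold frequency are broken in deterministic cell order, which
#' keeps the selected mass within one maximal cell frequency of the level.
#'
#' @param draws matrix with two columns (pooled post-burn-in draws).
#' @param bins histogram resolution per axis (20 by default).
#' @param level target credibility mass (0.95).
#' @return object of class \code{credibility_region}: list with
#'   \code{freq}, \code{xbreaks}, \code{ybreaks}, \code{level_threshold},
#'   \code{cells} (selected cell indices), \code{mass}.
#' @export
credibility_region <- function(draws, bins = 20, level = 0.95) {
  draws <- as.matrix(draws)
  stopifnot(ncol(draws) == 2)
  if (nrow(draws) < 400) stop("need at least 400 pooled draws")
  if (any(apply(draws, 2, stats::sd) == 0))
    stop("degenerate draws: zero variance in a parameter")
  xb <- seq(min(draws[, 1]), max(draws[, 1]), length.out = bins + 1)
  yb <- seq(min(draws[, 2]), max(draws[, 2]), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(draws[, 1], xb, rightmost.closed = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(draws[, 2], yb, rightmost.closed = TRUE), 1), bins)
  freq <- matrix(0, bins, bins)
  for (k in seq_len(nrow(draws)))
    freq[ix[k], iy[k]] <- freq[ix[k], iy[k]] + 1
  freq <- freq / nrow(draws)
  ord <- order(freq, decreasing = TRUE)
  cum <- cumsum(freq[ord])
  k <- which(cum >= level)[1]
  sel <- ord[seq_len(k)]
  cells <- cbind(row = (sel - 1) %% bins + 1,
                 col = (sel - 1) %/% bins + 1)
  structure(list(freq = freq, xbreaks = xb, ybreaks = yb,
                 level_threshold = freq[ord[k]], cells = cells,
                 mass = cum[k], level = level),
            class = "credibility_region")
}
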