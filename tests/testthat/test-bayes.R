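test_that("sigma^2 Gibbs draw follows the closed-form inverse gamma", {
  # zero residuals, tau = 2, nu = 0: scale exactly 1, shape n/2
  y <- rep(5, 10); f <- y
  old <- sorensen:::local_seed(101)
  draws <- replicate(1e5, sample_sigma2(y, f, nu = 0, tau = 2))
  sorensen:::restore_seed(old)
  shape <- 5  # n/2
  expect_equal(mean(draws), 1 / (shape - 1), tolerance = 0.02)
  expect_equal(stats::var(draws), 1 / ((shape - 1)^2 * (shape - 2)),
               tolerance = 0.05)
  # fixed nonzero residuals: distributional test against the closed form
  set.seed(7)
  y2 <- stats::rnorm(20, 100, 5); f2 <- rep(100, 20)
  old <- sorensen:::local_seed(13)
  d2 <- replicate(1e4, sample_sigma2(y2, f2, nu = 0.01, tau = 0.01))
  sorensen:::restore_seed(old)
  sh <- (20 + 0.01) / 2
  sc <- (sum(((y2 - f2) / f2)^2) + 0.01) / 2
  ks <- stats::ks.test(d2, function(q) stats::pgamma(sc / q, sh,
                                                     lower.tail = FALSE))
  expect_gt(ks$p.value, 0.01)
  # doubling tau shifts the inverse-gamma scale by exactly tau/2: with an
  # identical gamma stream the draws scale proportionally
  old <- sorensen:::local_seed(5)
  a <- sample_sigma2(y2, f2, nu = 0, tau = 1)
  sorensen:::restore_seed(old)
  old <- sorensen:::local_seed(5)
  b <- sample_sigma2(y2, f2, nu = 0, tau = 3)
  sorensen:::restore_seed(old)
  s1 <- (sum(((y2 - f2) / f2)^2) + 1) / 2
  expect_equal(b / a, (s1 + 1) / s1, tolerance = 1e-12)
  expect_error(sample_sigma2(c(1, 2), c(1, 0)), "zero")
})

test_that("Metropolis step: identity proposal always accepts; box rejects", {
  lc <- function(eta, s2) list(lp = -sum(eta^2), f = NULL)
  D <- rbind(c(-5, -5), c(5, 5))
  zeroL <- matrix(0, 2, 2)  # degenerate proposal: eta' = eta, ratio 1
  set.seed(1)
  st <- mh_step(c(1, 1), -2, lc, 1, zeroL, D)
  expect_true(st$accepted)
  expect_equal(st$eta, c(1, 1))
  # a proposal far outside the box is rejected through the prior support
  bigL <- diag(1e6, 2)
  set.seed(2)
  st2 <- mh_step(c(0, 0), 0, lc, 1, bigL, D)
  expect_false(st2$accepted)
  expect_error(mh_step(c(0, 0), -Inf, lc, 1, zeroL, D), "non-finite")
})

test_that("chains start on the 3x3 lattice of the prior box", {
  cfg <- mcmc_config(c(a = log(2), b = log(3)), c(10, 10),
                     chains = 9, iterations = 10, burnin = 1)
  g <- chain_starts(cfg)
  expect_equal(nrow(g), 9)
  expect_equal(nrow(unique(g)), 9)
  for (j in 1:2) {
    lv <- sort(unique(g[, j]))
    expect_equal(lv, c(cfg$D[1, j], mean(cfg$D[, j]), cfg$D[2, j]))
  }
})

test_that("flat target: draws cover the box uniformly; seeds reproduce", {
  lc <- function(eta, s2) list(lp = 0, f = NULL)
  cfg <- mcmc_config(c(a = 1, b = 1), c(10, 10),
                     D = rbind(c(0, 0), c(2, 2)),
                     proposal_cov = diag(0.5^2, 2),
                     chains = 9, iterations = 1500, burnin = 300, seed = 4)
  ch <- run_chains(cfg, log_conditional = lc, sigma2_fixed = 1)
  pd <- pooled_draws(ch)
  expect_equal(nrow(pd), 9 * 1200)
  # Kolmogorov distance to uniform on each axis (dependent draws: use a
  # generous bound rather than a formal test)
  for (j in 1:2) {
    dist <- max(abs(sort(pd[, j]) / 2 - (seq_len(nrow(pd)) / nrow(pd))))
    expect_lt(dist, 0.05)
  }
  ch2 <- run_chains(cfg, log_conditional = lc, sigma2_fixed = 1)
  expect_identical(ch$draws, ch2$draws)
})

test_that("conjugate toy: pooled posterior matches the analytic solution", {
  set.seed(1)
  tt <- seq(1, 10, length.out = 15)
  ab <- c(2, 0.5); sig <- 0.3
  yy <- ab[1] + ab[2] * tt + stats::rnorm(15, 0, sig)
  X <- cbind(1, tt)
  post_mean <- as.vector(solve(crossprod(X), crossprod(X, yy)))
  post_cov <- sig^2 * solve(crossprod(X))
  lc <- function(eta, s2) list(lp = -0.5 * sum((yy - eta[1] - eta[2] * tt)^2) /
                                 sig^2, f = NULL)
  cfg <- mcmc_config(c(a = log(2), b = log(0.5)), c(10, 10),
                     D = rbind(c(0, -2), c(4, 2)),
                     proposal_cov = 1.5 * post_cov,
                     chains = 9, iterations = 3000, burnin = 500, seed = 3)
  ch <- run_chains(cfg, log_conditional = lc, sigma2_fixed = sig^2)
  pd <- pooled_draws(ch)
  # Monte-Carlo SE from the spread of independent per-chain means
  nchain <- cfg$chains
  keep <- (cfg$burnin + 1):cfg$iterations
  for (j in 1:2) {
    cmeans <- vapply(seq_len(nchain), function(k) mean(ch$draws[keep, j, k]),
                     numeric(1))
    se <- stats::sd(cmeans) / sqrt(nchain)
    expect_lt(abs(mean(pd[, j]) - post_mean[j]), 3 * se)
  }
  # covariance entries within 3 chain-level SEs
  ccovs <- vapply(seq_len(nchain), function(k)
    stats::cov(ch$draws[keep, 1, k], ch$draws[keep, 2, k]), numeric(1))
  se12 <- stats::sd(ccovs) / sqrt(nchain)
  expect_lt(abs(stats::cov(pd)[1, 2] - post_cov[1, 2]), 3 * se12)
})

test_that("Gibbs-within-Metropolis on a model target recovers sigma", {
  # proportional-error linear model: the sigma^2 Gibbs chain should
  # concentrate near the generating CV^2
  times <- 1:25
  truth <- c(a = 3)
  set.seed(8)
  yv <- 3 * times * (1 + 0.05 * stats::rnorm(25))
  obs <- observation_set(data.frame(time = times, channel = "insulin",
                                    value = yv), sigma = 0.05)
  pf <- function(th) th[["a"]] * times
  cfg <- mcmc_config(c(a = log(3)), cv_percent = 2,
                     D = rbind(log(3) - 1, log(3) + 1),
                     chains = 3, iterations = 2000, burnin = 500, seed = 2)
  ch <- run_chains(cfg, obs = obs, predict_fn = pf)
  s2 <- as.vector(ch$sigma2[501:2000, ])
  expect_equal(mean(sqrt(s2)), 0.05, tolerance = 0.35)
  expect_equal(mean(exp(pooled_draws(ch))), 3, tolerance = 0.02)
})

test_that("credibility region: uniform coverage, mode inclusion, mass bound", {
  set.seed(5)
  u <- cbind(stats::runif(5000), stats::runif(5000))
  cr <- credibility_region(u)
  expect_gte(cr$mass, 0.95)
  expect_lte(cr$mass, 0.95 + max(cr$freq))
  expect_gt(nrow(cr$cells) / 400, 0.9)   # ~95% of cells on a flat target
  # tight bivariate normal: the modal cell is selected
  z <- matrix(stats::rnorm(20000), ncol = 2)
  crz <- credibility_region(z)
  mode_cell <- which(crz$freq == max(crz$freq), arr.ind = TRUE)[1, ]
  expect_true(any(crz$cells[, 1] == mode_cell[1] &
                    crz$cells[, 2] == mode_cell[2]))
  expect_lt(nrow(crz$cells), 400)
  # nearly all mass concentrated in a single cell selects just that cell
  conc <- rbind(matrix(0.5 + stats::rnorm(1980, 0, 1e-4), ncol = 2),
                cbind(stats::runif(10), stats::runif(10)))
  crc <- credibility_region(conc)
  expect_equal(nrow(crc$cells), 1)
  expect_error(credibility_region(cbind(rep(1, 500), rep(2, 500))),
               "degenerate")
  expect_error(credibility_region(z[1:100, ]), "400")
})
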