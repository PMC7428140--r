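## Adaptive explicit Runge-Kutta integrator (Dormand-Prince 5(4), FSAL).
## The model is non-stiff at physiological parameter values (fastest local
## time constant ~0.5 min against output grids of minutes), so an embedded
## explicit pair with PI step-size control is adequate at the default
## tolerances; no stiff solver is available in the supported dependency set.

.dp5 <- local({
  c_ <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
  A <- matrix(0, 7, 7)
  A[2, 1] <- 1/5
  A[3, 1:2] <- c(3/40, 9/40)
  A[4, 1:3] <- c(44/45, -56/15, 32/9)
  A[5, 1:4] <- c(19372/6561, -25360/2187, 64448/6561, -212/729)
  A[6, 1:5] <- c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656)
  A[7, 1:6] <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
  b5 <- A[7, ]
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  list(c = c_, A = A, b5 = b5, e = b5 - b4)
})

#' Adaptive Runge-Kutta (Dormand-Prince 5(4)) integration
#'
#' Integrates \code{dy/dt = rhs(t, y, ...)} and returns the solution on the
#' requested output grid. Steps are clamped so every output time is hit
#' exactly (no interpolation error on the reported grid).
#'
#' @param rhs function \code{(t, y, ...) -> dy/dt} returning a numeric
#'   vector of the same length as \code{y}.
#' @param y0 initial state (named vector recommended).
#' @param times strictly increasing numeric output times; \code{times[1]}
#'   is the initial time.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param hmax maximum step size.
#' @param max_steps guard on the number of accepted + rejected steps.
#' @param ... passed to \code{rhs}.
#' @return matrix with one row per output time; first column \code{time},
#'   remaining columns the state variables.
#' @export
ode_rk45 <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                     hmax = Inf, max_steps = 1e6, ...) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  tab <- .dp5
  cn <- c("time", if (is.null(names(y0))) paste0("y", seq_len(n))
          else names(y0))
  out <- matrix(NA_real_, length(times), n + 1,
                dimnames = list(NULL, cn))
  out[1, ] <- c(times[1], y0)
  t <- times[1]; y <- y0
  f1 <- rhs(t, y, ...)
  check_finite_state(f1, t, "derivative")
  h <- min(hmax, max((times[2] - times[1]) / 10, 1e-6), 1)
  k <- matrix(0, n, 7)
  iout <- 2L; nstep <- 0L
  while (iout <= length(times)) {
    nstep <- nstep + 1L
    if (nstep > max_steps)
      stop("ode_rk45: step limit exceeded at t = ", signif(t, 8))
    h <- min(h, hmax, times[iout] - t)
    k[, 1] <- f1
    for (s in 2:7) {
      ys <- y + h * as.vector(k[, 1:(s - 1), drop = FALSE] %*%
                                tab$A[s, 1:(s - 1)])
      k[, s] <- rhs(t + tab$c[s] * h, ys, ...)
    }
    ynew <- y + h * as.vector(k %*% tab$b5)
    errv <- h * as.vector(k %*% tab$e)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    err <- sqrt(mean((errv / sc)^2))
    if (!is.finite(err)) {
      bad <- which(!is.finite(ynew) | !is.finite(errv))[1]
      stop("ode_rk45: non-finite solution component '",
           colnames(out)[bad + 1], "' at t = ", signif(t, 8))
    }
    if (err <= 1) {            # accept
      t <- t + h
      y <- ynew
      f1 <- k[, 7]             # FSAL
      while (iout <= length(times) && abs(t - times[iout]) < 1e-10 * max(1, abs(t))) {
        out[iout, ] <- c(times[iout], y)
        t <- times[iout]
        iout <- iout + 1L
      }
    }
    fac <- 0.9 * if (err > 0) err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    if (h <= 1e-12)
      stop("ode_rk45: step size underflow at t = ", signif(t, 8))
  }
  out
}

check_finite_state <- function(x, t, what) {
  if (any(!is.finite(x))) {
    nm <- names(x)[which(!is.finite(x))[1]]
    stop("non-finite ", what, if (!is.null(nm) && nzchar(nm))
      paste0(" in variable '", nm, "'"), " at t = ", signif(t, 8))
  }
  invisible(TRUE)
}

## small dense finite-difference Jacobian (central differences)
fd_jacobian <- function(f, x, f0 = NULL, rel = 1e-6, abs_ = 1e-8, ...) {
  m <- length(if (is.null(f0)) f(x, ...) else f0)
  J <- matrix(0, m, length(x))
  for (j in seq_along(x)) {
    h <- abs_ + rel * abs(x[j])
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp, ...) - f(xm, ...)) / (2 * h)
  }
  J
}
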