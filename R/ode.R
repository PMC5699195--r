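## Stiff ODE machinery.
##
## The kinetic system couples association rates of order k_on*[ATP] ~ 3e3 s^-1
## to passive-exchange and dissociation rates of order 1e-3 s^-1, a stiffness
## ratio of ~1e6, and steady states are approached over up to 1e6 s. The
## stepper below is the modified Rosenbrock pair of Shampine & Reichelt
## (MATLAB's ode23s): L-stable, order 2(3), one Jacobian evaluation and three
## right-hand-side evaluations per step, well suited to low-accuracy stiff
## integration of small systems. Steady states are finished off with a damped
## Newton iteration on the algebraic system f(y) = 0, with the pump
## conservation law substituted for one redundant equation.

.ode23s_d <- 1 / (2 + sqrt(2))
.ode23s_e32 <- 6 + sqrt(2)

## One trial step of size h from (t, y); J = jacobian at y (autonomous system).
## Returns list(y, err_ratio) where err_ratio <= 1 means acceptable.
.ode23s_step <- function(rhs, y, f0, J, h, rtol, atol) {
  n <- length(y)
  W <- diag(n) - (h * .ode23s_d) * J
  k1 <- tryCatch(solve(W, f0), error = function(e) NULL)
  if (is.null(k1)) return(list(ok = FALSE))
  f1 <- rhs(y + 0.5 * h * k1)
  k2 <- solve(W, f1 - k1) + k1
  ynew <- y + h * k2
  f2 <- rhs(ynew)
  k3 <- solve(W, f2 - .ode23s_e32 * (k2 - f1) - 2 * (k1 - f0))
  err <- (h / 6) * (k1 - 2 * k2 + k3)
  sc <- atol + rtol * pmax(abs(y), abs(ynew))
  list(ok = TRUE, y = ynew, f = f2, err_ratio = max(abs(err) / sc))
}

.initial_h <- function(y, f, rtol, atol) {
  sc <- atol + rtol * abs(y)
  d0 <- max(abs(y) / sc)
  d1 <- max(abs(f) / sc)
  h <- if (d1 > 0) 0.01 * d0 / d1 else 1e-6
  max(min(h, 1), 1e-12)
}

#' Integrate a stiff autonomous ODE system
#'
#' Adaptive modified-Rosenbrock (order 2(3), L-stable) integration of
#' `dy/dt = rhs(y)` with analytic Jacobian, returning the solution at the
#' requested output times.
#'
#' @param rhs Function of `y` returning the derivative vector.
#' @param jac Function of `y` returning the dense Jacobian matrix.
#' @param y0 Initial state vector.
#' @param times Increasing output times; the first element is the initial
#'   time (state reported as given).
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param max_steps Step-count guard.
#' @return Matrix with one row per output time; column 1 is `time`, the rest
#'   the state variables (named as `y0`).
#' @keywords internal
#' @export
ode_integrate <- function(rhs, jac, y0, times, rtol = 1e-8, atol = 1e-12,
                          max_steps = 2e5) {
  stopifnot(length(times) >= 2L, !is.unsorted(times, strictly = TRUE))
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n,
                dimnames = list(NULL, names(y0)))
  out[1L, ] <- y0
  y <- y0
  t <- times[1L]
  f <- rhs(y)
  h <- .initial_h(y, f, rtol, atol)
  nextout <- 2L
  steps <- 0L
  while (nextout <= length(times)) {
    if (steps >= max_steps) {
      stop(sprintf("ode_integrate: step limit reached at t = %g", t),
           call. = FALSE)
    }
    h <- min(h, times[length(times)] - t)
    hitting <- FALSE
    if (t + h >= times[nextout] - 1e-12 * max(1, abs(times[nextout]))) {
      h <- times[nextout] - t
      hitting <- TRUE
    }
    J <- jac(y)
    repeat {
      st <- .ode23s_step(rhs, y, f, J, h, rtol, atol)
      steps <- steps + 1L
      if (st$ok && st$err_ratio <= 1) break
      fac <- if (st$ok) max(0.1, 0.8 * st$err_ratio^(-1 / 3)) else 0.2
      h <- h * fac
      hitting <- FALSE
      if (h < 1e-14 * max(1, abs(t))) {
        stop(sprintf("ode_integrate: step size underflow at t = %g", t),
             call. = FALSE)
      }
      if (steps >= max_steps) {
        stop(sprintf("ode_integrate: step limit reached at t = %g", t),
             call. = FALSE)
      }
    }
    t <- t + h
    y <- st$y
    ## damp solver-noise negatives (concentrations cannot be < 0)
    neg <- y < 0
    if (any(neg)) y[neg & y > -1e3 * atol] <- 0
    f <- rhs(y)
    if (hitting) {
      out[nextout, ] <- y
      nextout <- nextout + 1L
    }
    h <- h * min(5, max(0.2, 0.8 * max(st$err_ratio, 1e-10)^(-1 / 3)))
  }
  cbind(time = times, out)
}

## Damped Newton for f(y) = 0 with clamped entries held fixed and an optional
## conservation constraint replacing one redundant row:
##   g[row] <- sum(y[idx]) - total
.newton_steady <- function(rhs, jac, y, clamped = integer(0),
                           conservation = NULL, floor = 1e-15,
                           tol = 1e-9, maxit = 30L) {
  n <- length(y)
  free <- setdiff(seq_len(n), clamped)
  gfun <- function(y) {
    g <- rhs(y)
    if (!is.null(conservation)) {
      g[conservation$row] <- sum(y[conservation$idx]) - conservation$total
    }
    g
  }
  fix_rows <- function(J) {
    if (!is.null(conservation)) {
      J[conservation$row, ] <- 0
      J[conservation$row, conservation$idx] <- 1
    }
    J
  }
  ## Convergence: net rate small relative to the gross flux through each
  ## equation, |g_i| <= tol * (|J| |y|)_i. States carrying large opposing
  ## fluxes have a roundoff floor on g far above tol * |y_i|, so scaling by
  ## the state value alone would never terminate for near-empty states.
  converged_at <- function(g, J, y) {
    scale <- as.vector(abs(J) %*% abs(y))
    if (!is.null(conservation)) {
      scale[conservation$row] <- sum(abs(y[conservation$idx])) +
        abs(conservation$total)
    }
    all(abs(g[free]) <= tol * scale[free] + 1e-300)
  }
  g <- gfun(y)
  for (it in seq_len(maxit)) {
    J <- fix_rows(jac(y))
    if (converged_at(g, J, y)) {
      y[y < 0] <- 0
      return(list(y = y, converged = TRUE))
    }
    step <- tryCatch(solve(J[free, free, drop = FALSE], -g[free]),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(y = y, converged = FALSE))
    }
    lambda <- 1
    base <- max(abs(g[free]))
    ok <- FALSE
    for (tries in 1:8) {
      ytry <- y
      ytry[free] <- y[free] + lambda * step
      ## concentrations must stay (essentially) non-negative
      if (min(ytry) < -1e-9) { lambda <- lambda / 2; next }
      ytry[ytry < 0] <- 0
      gtry <- gfun(ytry)
      if (all(is.finite(gtry)) && max(abs(gtry[free])) < base * (1 - 0.1 * lambda) + 1e-300) {
        y <- ytry; g <- gtry; ok <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!ok) {
      ## stalled at the roundoff floor: accept iff already at steady state
      return(list(y = y, converged = converged_at(g, fix_rows(jac(y)), y)))
    }
  }
  list(y = y, converged = converged_at(g, fix_rows(jac(y)), y))
}

#' Drive a stiff system to steady state
#'
#' Integrates with the Rosenbrock stepper until the largest relative
#' derivative max_i |f_i| / max(|y_i|, floor) over non-clamped variables
#' falls below `ss_rtol` (default 1e-8 s^-1), with a hard cap of `t_max`
#' simulated seconds. Once the trajectory is near-stationary a damped Newton
#' iteration (with the conservation law for the pump states substituted for
#' one redundant equation) polishes the root of `f(y) = 0` to machine-level
#' accuracy, which is both faster and tighter than integrating out the
#' slowest eigenmode.
#'
#' @param rhs,jac Right-hand side and Jacobian functions of `y`.
#' @param y0 Initial state.
#' @param clamped Integer indices of clamped (held-constant) variables.
#' @param conservation Optional `list(row =, idx =, total =)` describing a
#'   linear conservation law `sum(y[idx]) == total` whose row replaces
#'   equation `row` during the Newton polish.
#' @param ss_rtol Steady-state declaration threshold on the relative
#'   derivative, s^-1.
#' @param floor Concentration floor (molar) in the relative-derivative norm.
#' @param t_max Maximum simulated time, seconds.
#' @param rtol,atol Local error tolerances for the integration phase.
#' @return `list(y, t, converged, newton)` — the steady state, the simulated
#'   time at which it was declared, whether the threshold was met, and
#'   whether the Newton polish converged.
#' @keywords internal
#' @export
ode_steady_state <- function(rhs, jac, y0, clamped = integer(0),
                             conservation = NULL, ss_rtol = 1e-8,
                             floor = 1e-15, t_max = 1e6,
                             rtol = 1e-6, atol = 1e-14) {
  n <- length(y0)
  free <- setdiff(seq_len(n), clamped)
  relderiv <- function(f, y) max(abs(f[free]) / pmax(abs(y[free]), floor))
  y <- y0
  t <- 0
  f <- rhs(y)
  if (relderiv(f, y) < ss_rtol) {
    return(list(y = y, t = t, converged = TRUE, newton = FALSE))
  }
  h <- .initial_h(y, f, rtol, atol)
  steps <- 0L
  last_newton <- -10L
  newton_trigger <- 1e-2
  while (t < t_max) {
    steps <- steps + 1L
    if (steps > 2e5) {
      stop("ode_steady_state: step limit reached", call. = FALSE)
    }
    J <- jac(y)
    repeat {
      st <- .ode23s_step(rhs, y, f, J, min(h, t_max - t), rtol, atol)
      if (st$ok && st$err_ratio <= 1) break
      fac <- if (st$ok) max(0.1, 0.8 * st$err_ratio^(-1 / 3)) else 0.2
      h <- h * fac
      if (h < 1e-14 * max(1, t)) {
        stop(sprintf("ode_steady_state: step size underflow at t = %g", t),
             call. = FALSE)
      }
    }
    t <- t + min(h, t_max - t)
    y <- st$y
    neg <- y < 0
    if (any(neg)) y[neg & y > -1e3 * atol] <- 0
    f <- rhs(y)
    rd <- relderiv(f, y)
    if (rd < ss_rtol) {
      ns <- .newton_steady(rhs, jac, y, clamped, conservation, floor)
      if (ns$converged) return(list(y = ns$y, t = t, converged = TRUE, newton = TRUE))
      return(list(y = y, t = t, converged = TRUE, newton = FALSE))
    }
    if (rd < newton_trigger && steps - last_newton >= 10L) {
      last_newton <- steps
      ns <- .newton_steady(rhs, jac, y, clamped, conservation, floor)
      if (ns$converged) {
        ## the Newton criterion certifies f(y*) = 0 to numerical precision
        return(list(y = ns$y, t = t, converged = TRUE, newton = TRUE))
      }
    }
    h <- h * min(5, max(0.2, 0.8 * max(st$err_ratio, 1e-10)^(-1 / 3)))
  }
  ## time cap reached: one last polish attempt before reporting failure
  ns <- .newton_steady(rhs, jac, y, clamped, conservation, floor)
  if (ns$converged) {
    return(list(y = ns$y, t = t, converged = TRUE, newton = TRUE))
  }
  list(y = y, t = t, converged = FALSE, newton = FALSE)
}
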