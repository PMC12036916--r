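#' Reputation trajectory under constant effort
#'
#' The reputation stock follows the linear decay-accumulation equation
#' \eqn{\dot x = a_{eff} F - \delta x}. Under constant effort its solution
#' is \eqn{x(t) = a_{eff}F/\delta + (x_0 - a_{eff}F/\delta) e^{-\delta t}},
#' converging monotonically to the steady state \eqn{a_{eff}F/\delta}.
#'
#' @param x0 Initial reputation, \code{>= 0}.
#' @param F Constant effort, \code{>= 0}.
#' @param a_eff Per-unit-effort reputation gain, \code{> 0}.
#' @param delta Decay rate, \code{> 0}.
#' @param times Increasing time grid starting at 0.
#' @return An object of class \code{trajectory}: data.frame with columns
#'   \code{time} and \code{x}.
#' @export
reputation_trajectory <- function(x0, F, a_eff, delta, times) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (F < 0) stop("F must be >= 0", call. = FALSE)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0) ||
      times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be a strictly increasing grid starting at 0",
         call. = FALSE)
  xss <- a_eff * F / delta
  out <- data.frame(time = times, x = xss + (x0 - xss) * exp(-delta * times))
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Numerically discounted payoff of a constant-effort policy
#'
#' Independent oracle for the closed-form values: integrates
#' \eqn{\int_0^T e^{-\rho t} [g F - (c_{eff}/2) F^2 + k + l\, x(t)]\, dt}
#' by composite trapezoid on a uniform grid, using the analytic
#' \eqn{x(t)} of [reputation_trajectory()]. Because the trapezoid rule is
#' linear in the integrand and the integrand is linear in the two basis
#' functions \eqn{e^{-\rho t}} and \eqn{e^{-(\rho+\delta) t}}, the rule is
#' applied to those bases once and combined — identical result, and cheap
#' enough to vectorise over many efforts for the grid oracle.
#'
#' @param p An [reduce_mode()] \code{effort_problem}.
#' @param b The player's own gain parameter.
#' @param x0 Initial reputation.
#' @param F Constant effort (vectorised).
#' @param params A validated [game_parameters()] object.
#' @param T Truncation horizon; default \code{50 / rho}, making
#'   \eqn{e^{-\rho T} \approx 2\times 10^{-22}}.
#' @param dt Quadrature step; must satisfy \code{dt < 1/(rho + delta)}.
#' @return Numeric vector of discounted payoffs, with attribute
#'   \code{truncation_bound} = \eqn{(|gF| + |k| + l\,x_{max}) e^{-\rho T}/\rho},
#'   a bound on the discarded tail.
#' @export
discounted_payoff <- function(p, b, x0, F, params, T = 50 / params$rho,
                              dt = 1e-3) {
  stopifnot(inherits(p, "effort_problem"))
  rho <- params$rho; delta <- params$delta; l <- params$l
  if (!is.finite(T) || T <= 0) stop("T must be positive", call. = FALSE)
  if (!is.finite(dt) || dt <= 0 || dt >= 1 / (rho + delta))
    stop("dt must be positive and well below 1/(rho + delta)",
         call. = FALSE)
  times <- seq(0, T, by = dt)
  if (times[length(times)] < T) times <- c(times, T)
  trap <- function(y) {
    h <- diff(times)
    sum(h * (y[-length(y)] + y[-1]) / 2)
  }
  I_rho  <- trap(exp(-rho * times))            # integral of e^{-rho t}
  I_both <- trap(exp(-(rho + delta) * times))  # integral of e^{-(rho+delta) t}
  g <- p$w * b + p$u0
  xss <- p$a_eff * F / delta
  flow <- g * F - p$c_eff / 2 * F^2 + p$k
  # x(t) = xss + (x0 - xss) e^{-delta t}
  J <- flow * I_rho + l * (xss * I_rho + (x0 - xss) * I_both)
  xmax <- pmax(x0, xss)
  attr(J, "truncation_bound") <-
    (abs(g * F) + abs(p$k) + l * xmax) * exp(-rho * T) / rho
  J
}

#' Brute-force constant-effort optimiser
#'
#' Grid search over constant-effort policies using [discounted_payoff()];
#' the independent check that the closed-form \code{F_star} maximises the
#' discounted objective. Only constant policies are searched: the HJB
#' solution is state-independent, so the restriction is without loss here.
#'
#' @param p An [reduce_mode()] \code{effort_problem}.
#' @param b The player's own gain parameter.
#' @param x0 Initial reputation.
#' @param params A validated [game_parameters()] object.
#' @param grid Effort grid; default 201 points on \code{[0, 2 F*]}.
#' @param ... Passed to [discounted_payoff()] (\code{T}, \code{dt}).
#' @return The grid effort with the largest discounted payoff, with
#'   attributes \code{payoff} and \code{grid_step}.
#' @export
best_constant_effort_grid <- function(p, b, x0, params, grid = NULL, ...) {
  stopifnot(inherits(p, "effort_problem"))
  if (is.null(grid)) {
    Fs <- optimal_effort(p, b, params)
    grid <- seq(0, 2 * Fs, length.out = 201L)
  }
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  J <- discounted_payoff(p, b, x0, grid, params, ...)
  i <- which.max(J)
  out <- grid[i]
  attr(out, "payoff") <- J[i]
  attr(out, "grid_step") <- if (length(grid) > 1L) max(diff(grid)) else NA_real_
  out
}

#' Simulate a full trajectory with cumulative discounted payoff
#'
#' Convenience wrapper combining [reputation_trajectory()] with the running
#' discounted-payoff integral, e.g. for CSV export of a scenario run.
#'
#' @inheritParams discounted_payoff
#' @param times Increasing time grid starting at 0.
#' @return A \code{trajectory} data.frame with columns \code{time},
#'   \code{x}, \code{discounted_payoff} (cumulative trapezoid of
#'   \eqn{e^{-\rho t}} times the instantaneous payoff).
#' @export
simulate_trajectory <- function(p, b, x0, F, params, times) {
  tr <- reputation_trajectory(x0, F, p$a_eff, params$delta, times)
  integrand <- exp(-params$rho * times) *
    instant_payoff(p, F, tr$x, b, params)
  h <- diff(times)
  inc <- h * (integrand[-length(integrand)] + integrand[-1]) / 2
  tr$discounted_payoff <- c(0, cumsum(inc))
  tr
}
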