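#' Slope of the value function in reputation
#'
#' With a payoff linear in the state and linear dynamics, the stationary
#' HJB equation admits a value function linear in reputation,
#' \eqn{V(x) = m x + n}. Matching the x-coefficient of
#' \eqn{\rho V = \max_F [\dots + V'(x)(a_{eff} F - \delta x)]} gives
#' \eqn{\rho m = l - m \delta}, hence \eqn{m = l / (\rho + \delta)} for
#' every mode and player.
#'
#' @param params A validated [game_parameters()] object.
#' @return The scalar slope \code{l / (rho + delta)}.
#' @export
value_slope <- function(params) {
  params <- validate_parameters(params)
  params$l / (params$rho + params$delta)
}

#' Optimal constant effort of a reduced problem
#'
#' The HJB maximand is strictly concave in effort (coefficient
#' \code{-c_eff/2 < 0}); the first-order condition with the linear value
#' ansatz gives the state-independent optimum
#' \deqn{F^* = \frac{w b + u_0}{c_{eff}} + \frac{a_{eff}\, l}{c_{eff} (\rho + \delta)}.}
#'
#' @param p An [reduce_mode()] \code{effort_problem}.
#' @param b The player's own gain parameter (defaults to the value stored
#'   in \code{p}).
#' @param params A validated [game_parameters()] object.
#' @return Optimal effort level (scalar; vectorised over \code{b}).
#' @export
optimal_effort <- function(p, b = p$b, params) {
  stopifnot(inherits(p, "effort_problem"))
  m <- value_slope(params)
  (p$w * b + p$u0) / p$c_eff + p$a_eff * m / p$c_eff
}

#' Solve the stationary HJB equation of a reduced problem
#'
#' Returns the closed-form feedback equilibrium of one (mode, player)
#' problem: constant optimal effort \code{F_star}, value slope \code{m} and
#' intercept \code{n} with \eqn{V(x) = m x + n}, and the decomposition of
#' the value as a quadratic in the player's own gain parameter,
#' \deqn{V = K + Q (w b + u)^2, \qquad K = m x + k/\rho,\quad
#'   Q = \frac{1}{2 \rho c_{eff}},\quad u = u_0 + \frac{a_{eff} l}{\rho + \delta}.}
#' The identity \eqn{m x + n = K + Q (w b + u)^2} holds for every \code{b};
#' the decomposition is how the numerical-analysis section of the model
#' prints its results.
#'
#' @param p An [reduce_mode()] \code{effort_problem}.
#' @param b The player's own gain parameter (default from \code{p}).
#' @param x Reputation at which the value is reported (default \code{p$x0}).
#' @param params A validated [game_parameters()] object.
#' @return An object of class \code{equilibrium_solution}: list with
#'   \code{mode}, \code{player}, \code{b}, \code{x}, \code{F_star},
#'   \code{m}, \code{n}, \code{K}, \code{Q}, \code{w}, \code{u} and
#'   \code{value} (\eqn{= m x + n}).
#' @examples
#' p <- baseline_scenario()$params
#' sol <- solve_value(reduce_mode("A", "government", p), b = 2, x = 1,
#'                    params = p)
#' sol$K  # -10.111...
#' @export
solve_value <- function(p, b = p$b, x = p$x0, params) {
  stopifnot(inherits(p, "effort_problem"))
  params <- validate_parameters(params)
  rho <- params$rho
  m <- value_slope(params)
  Fs <- optimal_effort(p, b, params)
  g <- p$w * b + p$u0
  # rho * n = g F - c/2 F^2 + k + m a_eff F; at F = F* this simplifies to
  # c_eff F*^2 / 2 + k (both routes are exposed for the residual checks)
  n <- (g * Fs - p$c_eff / 2 * Fs^2 + p$k + m * p$a_eff * Fs) / rho
  K <- m * x + p$k / rho
  Q <- 1 / (2 * rho * p$c_eff)
  u <- p$u0 + p$a_eff * m
  sol <- list(mode = p$mode, player = p$player, b = b, x = x,
              F_star = Fs, m = m, n = n, K = K, Q = Q, w = p$w, u = u,
              value = m * x + n)
  class(sol) <- "equilibrium_solution"
  sol
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat(sprintf("<equilibrium_solution mode=%s player=%s b=%.6g x=%.6g>\n",
              x$mode, x$player, x$b, x$x))
  cat(sprintf("  F* = %.6g;  V(x) = %.6g x + %.6g = %.6g\n",
              x$F_star, x$m, x$n, x$value))
  cat(sprintf("  V = %.4f + %.4f (%.2f b + %.4g)^2\n",
              x$K, x$Q, x$w, x$u))
  invisible(x)
}

#' HJB residuals of a candidate solution
#'
#' For a candidate value function \eqn{V = m x + n} and effort \code{F},
#' the stationary HJB equation splits into an x-coefficient and a constant
#' part. Both residuals vanish simultaneously exactly at the solved
#' equilibrium; they are the algebraic check that the closed forms solve
#' the optimality condition.
#'
#' @param p An [reduce_mode()] \code{effort_problem}.
#' @param b The player's own gain parameter.
#' @param m,n Candidate value slope and intercept.
#' @param F Candidate (constant) effort.
#' @param params A validated [game_parameters()] object.
#' @return List with \code{slope_residual} \eqn{= m(\rho+\delta) - l} and
#'   \code{const_residual} \eqn{= \rho n - [g F - (c_{eff}/2)F^2 + k + m a_{eff} F]}.
#' @export
hjb_residual <- function(p, b, m, n, F, params) {
  stopifnot(inherits(p, "effort_problem"))
  g <- p$w * b + p$u0
  list(slope_residual = m * (params$rho + params$delta) - params$l,
       const_residual = params$rho * n -
         (g * F - p$c_eff / 2 * F^2 + p$k + m * p$a_eff * F))
}
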