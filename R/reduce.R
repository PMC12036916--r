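#' Reduce a (mode, player) pair to its canonical effort problem
#'
#' Every combination of cooperation mode and player is an instance of the
#' same linear-state, concave-effort control problem
#' \deqn{\max_F \int_0^\infty e^{-\rho t}\big[(w b + u_0) F - \tfrac{c_{eff}}{2} F^2
#'   + k + l\, x(t)\big] dt, \qquad \dot x = a_{eff} F - \delta x,}
#' where \eqn{b} is the player's own per-unit gain parameter. The reduction
#' collects the mode-specific composites: the government under
#' scarce-resource sharing pays cost \code{c1 + cS} and earns reputation
#' \code{a1 + aS}; the enterprise's gain is scaled by \code{log(e + betaS)};
#' information sharing shifts both gains by \code{bI} and both payoffs by
#' the flow \code{-CI}. The carbon offset \code{CO} is a flow from
#' government (\code{k} negative) to enterprise (\code{k} positive).
#'
#' @param mode Cooperation mode, \code{"A"}, \code{"S"} or \code{"I"}.
#' @param player \code{"government"} or \code{"enterprise"}.
#' @param params A validated [game_parameters()] object.
#' @return An object of class \code{effort_problem}: list with fields
#'   \code{w} (gain multiplier), \code{u0} (additive gain offset),
#'   \code{c_eff}, \code{a_eff}, \code{k} (net fixed transfer flow, sign
#'   carries direction), plus \code{mode}, \code{player}, \code{b} (the
#'   player's own gain parameter value) and \code{x0}.
#' @examples
#' p <- baseline_scenario()$params
#' reduce_mode("S", "government", p)  # c_eff = c1 + cS, a_eff = a1 + aS
#' @export
reduce_mode <- function(mode, player, params) {
  mp <- mode_player(mode, player)
  params <- validate_parameters(params)
  gov <- mp$player == "government"
  pr <- switch(paste(mp$mode, if (gov) "g" else "e", sep = ""),
    Ag = list(w = 1, u0 = 0, c_eff = params$c1, a_eff = params$a1,
              k = -params$CO),
    Ae = list(w = 1, u0 = 0, c_eff = params$c2, a_eff = params$a2,
              k = +params$CO),
    Sg = list(w = 1, u0 = 0, c_eff = params$c1 + params$cS,
              a_eff = params$a1 + params$aS, k = -params$CO),
    Se = list(w = log(exp(1) + params$betaS), u0 = 0, c_eff = params$c2,
              a_eff = params$a2, k = +params$CO),
    Ig = list(w = 1, u0 = params$bI, c_eff = params$c1, a_eff = params$a1,
              k = -params$CI - params$CO),
    Ie = list(w = 1, u0 = params$bI, c_eff = params$c2, a_eff = params$a2,
              k = -params$CI + params$CO))
  pr$mode <- mp$mode
  pr$player <- mp$player
  pr$b <- if (gov) params$b1 else params$b2
  pr$x0 <- if (gov) params$x0_gov else params$x0_ent
  class(pr) <- "effort_problem"
  pr
}

#' Instantaneous payoff of a reduced effort problem
#'
#' Evaluates \eqn{(w b + u_0) F - (c_{eff}/2) F^2 + k + l x} — the integrand
#' of the discounted objective. Used by the numerical oracle and by the
#' payoff-equivalence checks against the mode-specific functionals.
#'
#' @param p An [reduce_mode()] \code{effort_problem}.
#' @param F Effort level (vectorised).
#' @param x Reputation level (vectorised).
#' @param b The player's own gain parameter.
#' @param params A validated [game_parameters()] object (supplies \code{l}).
#' @return Numeric vector of instantaneous payoffs.
#' @export
instant_payoff <- function(p, F, x, b, params) {
  (p$w * b + p$u0) * F - p$c_eff / 2 * F^2 + p$k + params$l * x
}

#' @export
print.effort_problem <- function(x, ...) {
  cat(sprintf("<effort_problem mode=%s player=%s>\n", x$mode, x$player))
  cat(sprintf("  gain      (w*b + u0): %.6g * b + %.6g\n", x$w, x$u0))
  cat(sprintf("  cost      c_eff/2 F^2 with c_eff = %.6g\n", x$c_eff))
  cat(sprintf("  dynamics  xdot = %.6g F - delta x\n", x$a_eff))
  cat(sprintf("  transfer  k = %.6g\n", x$k))
  invisible(x)
}
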