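# Mode-comparison analytics: value rankings, crossover roots, dominance
# maps and comparative statics. Values are exact evaluations of the
# solve_value() decomposition, never re-fitted.

.own_gain_field <- function(player) if (player == "government") "b1" else "b2"
.own_cost_field <- function(player) if (player == "government") "c1" else "c2"

# relative tolerance for declaring two mode values an exact tie
.tie_tol <- 1e-12

#' Rank the three modes for one player at a given gain
#'
#' Evaluates the closed-form value of each cooperation mode at the same
#' gain parameter \code{b} and reputation \code{x} and ranks them. Exact
#' ties (to relative tolerance 1e-12) are reported, not broken: mode choice
#' at a tie is policy, not mathematics.
#'
#' @param player \code{"government"} or \code{"enterprise"}.
#' @param params A validated [game_parameters()] object.
#' @param b The player's own gain parameter.
#' @param x Reputation at which values are compared.
#' @return A data.frame with columns \code{mode}, \code{value}, \code{rank}
#'   and \code{tied} (logical: shares its value with another mode), sorted
#'   by decreasing value.
#' @examples
#' p <- baseline_scenario()$params
#' compare_modes("government", p, b = 5, x = 1)
#' @export
compare_modes <- function(player, params, b, x = 1) {
  player <- mode_player("A", player)$player
  vals <- vapply(c("A", "S", "I"), function(md) {
    solve_value(reduce_mode(md, player, params), b = b, x = x,
                params = params)$value
  }, numeric(1))
  ord <- order(vals, decreasing = TRUE)
  out <- data.frame(mode = names(vals)[ord], value = unname(vals[ord]))
  scale <- 1 + abs(out$value)
  out$tied <- vapply(seq_len(3L), function(i) {
    any(abs(out$value[i] - out$value[-i]) <= .tie_tol * scale[i])
  }, logical(1))
  out$rank <- cumsum(c(TRUE, abs(diff(out$value)) > .tie_tol * scale[-1]))
  out[, c("mode", "value", "rank", "tied")]
}

# quadratic coefficients of V_modeX(b) - V_modeY(b)
.mode_diff_quadratic <- function(player, params, modeX, modeY, x) {
  sol <- function(md) solve_value(reduce_mode(md, player, params),
                                  b = 0, x = x, params = params)
  sX <- sol(modeX); sY <- sol(modeY)
  list(a2 = sX$Q * sX$w^2 - sY$Q * sY$w^2,
       a1 = 2 * (sX$Q * sX$w * sX$u - sY$Q * sY$w * sY$u),
       a0 = (sX$K + sX$Q * sX$u^2) - (sY$K + sY$Q * sY$u^2))
}

#' Gains at which two modes yield equal value
#'
#' The difference of two mode values is a quadratic in the player's own
#' gain parameter, so crossovers are found by the quadratic formula (at
#' most two roots) and filtered to the search interval. Each analytic root
#' is cross-checked by bisection on the difference function.
#'
#' @param player \code{"government"} or \code{"enterprise"}.
#' @param params A validated [game_parameters()] object.
#' @param modeX,modeY Two distinct modes from \code{"A","S","I"}.
#' @param interval Search interval for the gain, default \code{c(0, 10)};
#'   must lie in \code{b >= 0}.
#' @param x Reputation at which values are compared.
#' @return A data.frame with columns \code{root} and \code{multiplicity}
#'   (2 for a tangency). Zero rows if the modes never cross on the
#'   interval. If the two value functions are identical, the attribute
#'   \code{identical} is \code{TRUE} and no roots are returned.
#' @examples
#' p <- baseline_scenario()$params
#' crossover_gain("government", p, "A", "S")  # root near 0.065
#' @export
crossover_gain <- function(player, params, modeX, modeY,
                           interval = c(0, 10), x = 1) {
  player <- mode_player(modeX, player)$player
  mode_player(modeY, "government")
  if (modeX == modeY) stop("modes must differ", call. = FALSE)
  if (length(interval) != 2L || interval[1] < 0 || diff(interval) <= 0)
    stop("interval must be increasing and within b >= 0", call. = FALSE)
  q <- .mode_diff_quadratic(player, params, modeX, modeY, x)
  tol <- 1e-12 * max(1, abs(q$a2), abs(q$a1), abs(q$a0))
  empty <- data.frame(root = numeric(0), multiplicity = integer(0))
  if (abs(q$a2) <= tol && abs(q$a1) <= tol && abs(q$a0) <= tol) {
    attr(empty, "identical") <- TRUE
    return(empty)
  }
  if (abs(q$a2) <= tol) {
    roots <- if (abs(q$a1) <= tol) numeric(0) else -q$a0 / q$a1
    mult <- rep(1L, length(roots))
  } else {
    disc <- q$a1^2 - 4 * q$a2 * q$a0
    if (disc < -tol) {
      roots <- numeric(0); mult <- integer(0)
    } else if (abs(disc) <= tol) {
      roots <- -q$a1 / (2 * q$a2); mult <- 2L
    } else {
      roots <- sort((-q$a1 + c(-1, 1) * sqrt(disc)) / (2 * q$a2))
      mult <- c(1L, 1L)
    }
  }
  keep <- roots >= interval[1] - 1e-12 & roots <= interval[2] + 1e-12
  roots <- roots[keep]; mult <- mult[keep]
  diff_fn <- function(b) q$a0 + q$a1 * b + q$a2 * b^2
  refined <- vapply(seq_along(roots), function(i) {
    if (mult[i] == 2L) return(roots[i])  # tangency: no sign change
    .bisect_check(diff_fn, roots[i], interval)
  }, numeric(1))
  out <- data.frame(root = refined, multiplicity = mult)
  attr(out, "identical") <- FALSE
  out
}

# bisection confirmation of a simple analytic root; returns the bisected
# root (agrees with the analytic one to ~1e-12) or errors on mismatch
.bisect_check <- function(f, r, interval, width = 1e-3) {
  lo <- max(interval[1], r - width); hi <- min(interval[2], r + width)
  # widen until the sign changes (the root is simple)
  while (sign(f(lo)) == sign(f(hi)) && (lo > interval[1] || hi < interval[2])) {
    width <- width * 4
    lo <- max(interval[1], r - width); hi <- min(interval[2], r + width)
  }
  if (sign(f(lo)) == sign(f(hi))) return(r)  # boundary root (e.g. b = 0)
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Best-mode map over gain and cost grids
#'
#' Labels each (gain, cost) cell with the value-maximising mode for the
#' given player, the cost being applied to the player's own quadratic cost
#' parameter (by convention the model sweeps both costs jointly, but only
#' the player's own cost enters their value). Ties are labelled with all
#' tied modes joined by \code{"/"}.
#'
#' @param player \code{"government"} or \code{"enterprise"}.
#' @param params A validated [game_parameters()] object.
#' @param b_grid Gain grid (non-negative, finite).
#' @param c_grid Cost grid (positive, finite).
#' @param x Reputation at which values are compared.
#' @return A data.frame with columns \code{b}, \code{c}, \code{V_A},
#'   \code{V_S}, \code{V_I}, \code{best_mode}.
#' @export
dominance_region <- function(player, params, b_grid = seq(0, 10, 0.5),
                             c_grid = c(2, 4), x = 1) {
  player <- mode_player("A", player)$player
  if (any(!is.finite(b_grid)) || any(b_grid < 0))
    stop("b_grid must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(c_grid)) || any(c_grid <= 0))
    stop("c_grid must be finite and positive", call. = FALSE)
  cf <- .own_cost_field(player)
  rows <- lapply(c_grid, function(cc) {
    pp <- unclass(params); pp[[cf]] <- cc
    pp <- validate_parameters(pp)
    sols <- lapply(c(A = "A", S = "S", I = "I"), function(md)
      solve_value(reduce_mode(md, player, pp), b = 0, x = x, params = pp))
    vals <- sapply(sols, function(s) s$K + s$Q * (s$w * b_grid + s$u)^2)
    if (length(b_grid) == 1L) vals <- matrix(vals, nrow = 1L,
                                             dimnames = list(NULL, c("A", "S", "I")))
    best <- apply(vals, 1L, function(v) {
      top <- max(v)
      paste(names(v)[v >= top - .tie_tol * (1 + abs(top))], collapse = "/")
    })
    data.frame(b = b_grid, c = cc, V_A = vals[, "A"], V_S = vals[, "S"],
               V_I = vals[, "I"], best_mode = best)
  })
  do.call(rbind, rows)
}

# closed-form partial derivatives of F* w.r.t. each parameter it contains.
# F* = (w b + u0)/c_eff + a_eff l / (c_eff (rho + delta)), with the
# mode-specific composites spelled out per case.
.effort_derivative <- function(mode, player, target, b, params) {
  gov <- player == "government"
  pr <- reduce_mode(mode, player, params)
  rho <- params$rho; delta <- params$delta; l <- params$l
  m <- l / (rho + delta)
  g <- pr$w * b + pr$u0
  own_b <- .own_gain_field(player); own_c <- .own_cost_field(player)
  zero <- list(value = 0, depends = FALSE)
  dep <- function(v) list(value = v, depends = TRUE)
  switch(target,
    b1 = if (gov) dep(pr$w / pr$c_eff) else zero,
    b2 = if (!gov) dep(pr$w / pr$c_eff) else zero,
    c1 = if (gov) dep(-(g + pr$a_eff * m) / pr$c_eff^2) else zero,
    c2 = if (!gov) dep(-(g + pr$a_eff * m) / pr$c_eff^2) else zero,
    cS = if (gov && mode == "S") dep(-(g + pr$a_eff * m) / pr$c_eff^2)
         else zero,
    aS = if (gov && mode == "S") dep(m / pr$c_eff) else zero,
    a1 = if (gov) dep(m / pr$c_eff) else zero,
    a2 = if (!gov) dep(m / pr$c_eff) else zero,
    bI = if (mode == "I") dep(1 / pr$c_eff) else zero,
    betaS = if (!gov && mode == "S")
      dep(b / (pr$c_eff * (exp(1) + params$betaS))) else zero,
    l = dep(pr$a_eff / (pr$c_eff * (rho + delta))),
    rho = dep(-pr$a_eff * l / (pr$c_eff * (rho + delta)^2)),
    delta = dep(-pr$a_eff * l / (pr$c_eff * (rho + delta)^2)),
    CO = zero, CI = zero, x0_gov = zero, x0_ent = zero,
    stop("unknown target parameter: ", target, call. = FALSE))
}

#' Comparative statics of the optimal effort
#'
#' Closed-form partial derivative of the equilibrium effort \code{F_star}
#' with respect to one model parameter, with its sign and a central
#' finite-difference cross-check. Parameters that do not enter
#' \code{F_star} (the transfers \code{CO}, \code{CI}, the initial
#' reputations, and the other player's parameters) return 0 with
#' \code{depends = FALSE}.
#'
#' @param mode Cooperation mode, \code{"A"}, \code{"S"} or \code{"I"}.
#' @param player \code{"government"} or \code{"enterprise"}.
#' @param target Name of a [game_parameters()] field.
#' @param params A validated [game_parameters()] object.
#' @param b The player's own gain parameter (needed when the derivative
#'   depends on it, e.g. for cost parameters). Defaults to the stored
#'   value.
#' @param h Relative step of the finite-difference check.
#' @return A list with \code{value} (the derivative), \code{sign},
#'   \code{depends} (FALSE when the parameter does not enter
#'   \code{F_star}) and \code{fd} (the central finite-difference estimate).
#' @examples
#' p <- baseline_scenario()$params
#' comparative_statics("S", "government", "aS", p)$value  # l/((c1+cS)(rho+delta))
#' @export
comparative_statics <- function(mode, player, target, params, b = NULL,
                                h = 1e-6) {
  mp <- mode_player(mode, player)
  params <- validate_parameters(params)
  if (is.null(b)) b <- params[[.own_gain_field(mp$player)]]
  an <- .effort_derivative(mp$mode, mp$player, target, b, params)
  # central finite difference on the same closed-form effort map
  effort_at <- function(v) {
    pp <- unclass(params)
    pp[[target]] <- v
    if (target %in% c("b1", "b2") && .own_gain_field(mp$player) == target) {
      pr <- reduce_mode(mp$mode, mp$player, validate_parameters(pp))
      return(optimal_effort(pr, b = v, params = validate_parameters(pp)))
    }
    pp <- validate_parameters(pp)
    optimal_effort(reduce_mode(mp$mode, mp$player, pp), b = b, params = pp)
  }
  v0 <- params[[target]]
  step <- h * max(1, abs(v0))
  # perturbing rho may step just past the soft rho <= 1 band; that warning
  # is not informative for a derivative check
  fd <- suppressWarnings(
    (effort_at(v0 + step) - effort_at(v0 - step)) / (2 * step))
  list(value = an$value, sign = sign(an$value), depends = an$depends,
       fd = fd)
}
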