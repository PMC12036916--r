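#' Construct a validated set of game parameters
#'
#' Bundles all constants of the government-enterprise pest-management game:
#' discounting, reputation dynamics, per-unit gains and costs, the carbon
#' offset flow, and the mode-specific sharing parameters. All parameters are
#' flows or rates per unit time; reputation is a stock.
#'
#' @param rho Discount rate (per unit time). Must satisfy \code{0 < rho};
#'   values above 1 trigger a warning (the model is stated for
#'   \code{rho <= 1}) but are not rejected.
#' @param delta Reputation decay rate, \code{> 0}.
#' @param l Marginal long-run benefit of one unit of reputation, \code{> 0}.
#' @param b1,b2 Per-unit-effort governance gains of government and
#'   enterprise, \code{> 0} (0 allowed only where a gain grid starts at 0).
#' @param c1,c2 Quadratic effort-cost coefficients, \code{> 0}.
#' @param CO Carbon-offset flow paid by the government to the enterprise,
#'   \code{> 0}.
#' @param a1,a2 Per-unit-effort reputation gains, \code{> 0}.
#' @param cS Extra government cost coefficient under scarce-resource
#'   sharing, \code{> 0}.
#' @param betaS Helpfulness of shared scarce resources to the enterprise,
#'   \code{> 0}; enters the enterprise gain as the multiplier
#'   \code{log(e + betaS)}.
#' @param aS Extra government reputation gain from resource sharing,
#'   \code{> 0}.
#' @param bI Gain increment from information sharing, \code{> 0}.
#' @param CI Information-sharing cost flow, \code{> 0}.
#' @param x0_gov,x0_ent Initial reputations, \code{>= 0}.
#' @return An object of class \code{game_parameters} (a named list).
#' @seealso [validate_parameters()], [baseline_scenario()]
#' @examples
#' p <- game_parameters(rho = 0.9, delta = 0.1, l = 1, b1 = 2, b2 = 2,
#'                      c1 = 2, c2 = 2, CO = 10, a1 = 2, a2 = 2, cS = 3,
#'                      betaS = 1.5, aS = 1.2, bI = 2.5, CI = 3)
#' p$rho
#' @export
game_parameters <- function(rho, delta, l, b1, b2, c1, c2, CO, a1, a2,
                            cS, betaS, aS, bI, CI,
                            x0_gov = 1, x0_ent = 1) {
  p <- list(rho = rho, delta = delta, l = l, b1 = b1, b2 = b2,
            c1 = c1, c2 = c2, CO = CO, a1 = a1, a2 = a2,
            cS = cS, betaS = betaS, aS = aS, bI = bI, CI = CI,
            x0_gov = x0_gov, x0_ent = x0_ent)
  class(p) <- "game_parameters"
  validate_parameters(p)
}

.param_fields <- c("rho", "delta", "l", "b1", "b2", "c1", "c2", "CO",
                   "a1", "a2", "cS", "betaS", "aS", "bI", "CI",
                   "x0_gov", "x0_ent")

# fields that must be strictly positive (b1/b2 may sit at 0 on a gain grid)
.strict_pos <- c("rho", "delta", "l", "c1", "c2", "CO", "a1", "a2",
                 "cS", "betaS", "aS", "bI", "CI")

#' Validate a game-parameter set
#'
#' Checks every sign and range constraint of the model and either returns
#' the parameters unchanged or aborts with a message naming every violated
#' constraint. \code{rho > 1} is a warning, not an error: discounted
#' integrals still converge, but the model is stated on \code{(0, 1]}.
#'
#' @param p A \code{game_parameters} object or a bare named list with the
#'   same fields.
#' @return The validated \code{game_parameters} object.
#' @export
validate_parameters <- function(p) {
  if (!is.list(p)) stop("parameters must be a list", call. = FALSE)
  missing <- setdiff(.param_fields, names(p))
  if (length(missing) > 0L)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(p), .param_fields)
  if (length(unknown) > 0L)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  errs <- character(0)
  for (f in .param_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errs <- c(errs, sprintf("%s must be a finite numeric scalar", f))
      next
    }
    if (f %in% .strict_pos && v <= 0)
      errs <- c(errs, sprintf("%s must be > 0", f))
    if (f %in% c("b1", "b2") && v < 0)
      errs <- c(errs, sprintf("%s must be >= 0", f))
    if (f %in% c("x0_gov", "x0_ent") && v < 0)
      errs <- c(errs, sprintf("%s must be >= 0", f))
  }
  if (length(errs) > 0L)
    stop("invalid parameters:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  if (p$rho > 1)
    warning("rho = ", p$rho, " exceeds 1; the model is stated for rho in (0, 1]",
            call. = FALSE)
  p <- p[.param_fields]
  class(p) <- "game_parameters"
  p
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("<game_parameters>\n")
  v <- unlist(x, use.names = TRUE)
  cat(paste0("  ", format(names(v), width = 7), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

.modes <- c("A", "S", "I")
.players <- c("government", "enterprise")

#' Normalise mode and player labels
#'
#' Modes are \code{"A"} (individual action), \code{"S"} (scarce-resource
#' sharing) and \code{"I"} (information sharing). Players are
#' \code{"government"} and \code{"enterprise"} (abbreviations accepted).
#'
#' @param mode One of \code{"A"}, \code{"S"}, \code{"I"}.
#' @param player \code{"government"} or \code{"enterprise"}.
#' @return A list with canonical \code{mode} and \code{player} strings.
#' @export
mode_player <- function(mode, player) {
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% .modes))
    stop("mode must be one of ", paste(.modes, collapse = ", "),
         call. = FALSE)
  if (!is.character(player) || length(player) != 1L)
    stop("player must be a single string", call. = FALSE)
  pl <- .players[pmatch(player, .players)]
  if (is.na(pl))
    stop("player must be one of ", paste(.players, collapse = ", "),
         call. = FALSE)
  list(mode = mode, player = pl)
}
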