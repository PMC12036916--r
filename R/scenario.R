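# Scenarios: named parameter sets with optional sweeps, JSON (de)serialisation,
# seeded random generation, and the batch report used by the CLI.

#' The baseline numerical scenario
#'
#' The parameter set of the model's numerical-analysis section:
#' discount rate 0.9, reputation decay 0.1, reputation benefit l = 1,
#' unit reputation gains a1 = a2 = 2, sharing reputation gain aS = 1.2,
#' sharing cost cS = 3, information-sharing cost CI = 3, information gain
#' increment bI = 2.5, resource helpfulness betaS = 1.5, carbon offset
#' CO = 10, and unit initial reputation. The governance costs are swept
#' over c in {2, 4} (applied to c1 and c2 jointly); the returned scenario
#' carries the first as the default and the full sweep in \code{$sweep}.
#'
#' @param c_unit Governance cost assigned to both \code{c1} and \code{c2};
#'   default 2 (the other printed variant is 4).
#' @param b1,b2 Gains; the numerical section treats them as the swept
#'   abscissa, so they default to 1 and are usually overridden.
#' @return A \code{scenario} object: list with \code{name}, \code{params}
#'   (a [game_parameters()] object) and \code{sweep} (list with the cost
#'   variants).
#' @export
baseline_scenario <- function(c_unit = 2, b1 = 1, b2 = 1) {
  params <- game_parameters(
    rho = 0.9, delta = 0.1, l = 1, b1 = b1, b2 = b2,
    c1 = c_unit, c2 = c_unit, CO = 10, a1 = 2, a2 = 2,
    cS = 3, betaS = 1.5, aS = 1.2, bI = 2.5, CI = 3,
    x0_gov = 1, x0_ent = 1)
  sc <- list(name = sprintf("baseline_c%g", c_unit), params = params,
             sweep = list(c_unit = c(2, 4)))
  class(sc) <- "scenario"
  sc
}

#' Read or write a scenario as JSON
#'
#' Strict schema: the JSON object must contain \code{name} and
#' \code{params} (with exactly the [game_parameters()] fields); unknown
#' keys are rejected. \code{sweep} is optional.
#'
#' @param path File path.
#' @return \code{read_scenario} returns a \code{scenario};
#'   \code{write_scenario} returns \code{path} invisibly.
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("name", "params", "sweep")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L)
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$name) || is.null(raw$params))
    stop("scenario JSON must contain 'name' and 'params'", call. = FALSE)
  sc <- list(name = as.character(raw$name),
             params = validate_parameters(as.list(raw$params)),
             sweep = raw$sweep)
  class(sc) <- "scenario"
  sc
}

#' @rdname read_scenario
#' @param scenario A \code{scenario} object.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(
    list(name = scenario$name, params = unclass(scenario$params),
         sweep = scenario$sweep),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# default sampling ranges: each parameter in [0.5x, 2x] its baseline value,
# rho capped at 1 to stay inside the model's stated band
.default_ranges <- function() {
  base <- unclass(baseline_scenario()$params)
  rng <- lapply(base, function(v) c(0.5 * v, 2 * v))
  rng$rho[2] <- 1
  rng
}

#' Generate a seeded batch of random scenarios
#'
#' Samples each parameter uniformly and independently from its range.
#' Default ranges bracket the baseline (half to double each value, with
#' the discount rate capped at 1). Identical \code{(seed, n, ranges)}
#' yield an identical batch; every generated scenario validates. Scenarios
#' in which the information gain \code{bI} is not below the sharing cost
#' \code{CI} are annotated (\code{bI_exceeds_CI}), not rejected: the model
#' motivates \code{bI < CI} but does not impose it.
#'
#' @param n Number of scenarios.
#' @param seed Integer seed.
#' @param ranges Named list of \code{c(lo, hi)} sampling intervals; must
#'   respect the sign constraints of [game_parameters()].
#' @return List of \code{scenario} objects named \code{scenario_<i>}.
#' @export
generate_scenarios <- function(n, seed = 1L, ranges = .default_ranges()) {
  stopifnot(is.numeric(n), n >= 1)
  missing <- setdiff(.param_fields, names(ranges))
  if (length(missing) > 0L)
    stop("ranges missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (f in .param_fields) {
    r <- ranges[[f]]
    if (length(r) != 2L || r[1] > r[2])
      stop("range for ", f, " must be c(lo, hi)", call. = FALSE)
    if (f %in% .strict_pos && r[1] <= 0)
      stop("range for ", f, " must have a positive lower bound",
           call. = FALSE)
    if (f %in% c("b1", "b2", "x0_gov", "x0_ent") && r[1] < 0)
      stop("range for ", f, " must be non-negative", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    p <- lapply(ranges[.param_fields], function(r) stats::runif(1, r[1], r[2]))
    sc <- list(name = sprintf("scenario_%d", i),
               params = validate_parameters(p),
               seed = seed,
               bI_exceeds_CI = p$bI >= p$CI)
    class(sc) <- "scenario"
    sc
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Solve all six (mode, player) equilibria of a scenario
#'
#' @param params A validated [game_parameters()] object.
#' @param x Reputation at which values are reported; defaults to each
#'   player's initial reputation.
#' @return A data.frame with one row per (mode, player): the effort
#'   \code{F_star}, value slope/intercept \code{m}, \code{n}, the value,
#'   and the quadratic-in-gain decomposition \code{K}, \code{Q}, \code{w},
#'   \code{u}.
#' @export
solve_all <- function(params, x = NULL) {
  rows <- lapply(c("A", "S", "I"), function(md) {
    lapply(c("government", "enterprise"), function(pl) {
      pr <- reduce_mode(md, pl, params)
      s <- solve_value(pr, x = if (is.null(x)) pr$x0 else x,
                       params = params)
      data.frame(mode = md, player = pl, b = s$b, x = s$x,
                 F_star = s$F_star, m = s$m, n = s$n, value = s$value,
                 K = s$K, Q = s$Q, w = s$w, u = s$u)
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

#' Run a scenario and write a machine-readable report bundle
#'
#' Solves all six (mode, player) equilibria, runs the internal checks
#' (HJB residuals at every solution; closed form vs quadrature oracle),
#' writes per-player mode-comparison tables over a gain grid, and a JSON
#' summary with the decompositions, the checks, the parameters and the
#' package version. A report whose checks fail is marked
#' \code{passed = FALSE}.
#'
#' @param scenario A \code{scenario} object (e.g. [baseline_scenario()]).
#' @param out_dir Output directory; created if absent.
#' @param b_grid Gain grid for the comparison tables.
#' @param trajectories If TRUE, also writes a reputation/payoff trajectory
#'   CSV per (mode, player) at the equilibrium effort.
#' @param oracle_T,oracle_dt Quadrature horizon and step of the oracle
#'   check.
#' @return Invisibly, the summary list (with \code{passed}).
#' @export
run_report <- function(scenario, out_dir, b_grid = seq(0, 10, length.out = 101),
                       trajectories = FALSE,
                       oracle_T = 50 / scenario$params$rho,
                       oracle_dt = 1e-3) {
  stopifnot(inherits(scenario, "scenario"))
  params <- validate_parameters(scenario$params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  eq <- solve_all(params)
  # internal checks: HJB residuals and oracle equivalence at every pair
  checks <- lapply(seq_len(nrow(eq)), function(i) {
    pr <- reduce_mode(eq$mode[i], eq$player[i], params)
    res <- hjb_residual(pr, eq$b[i], eq$m[i], eq$n[i], eq$F_star[i], params)
    J <- discounted_payoff(pr, eq$b[i], pr$x0, eq$F_star[i], params,
                           T = oracle_T, dt = oracle_dt)
    rel <- abs(as.numeric(J) - eq$value[i]) / (1 + abs(eq$value[i]))
    list(mode = eq$mode[i], player = eq$player[i],
         slope_residual = res$slope_residual,
         const_residual = res$const_residual,
         oracle_rel_err = rel,
         ok = abs(res$slope_residual) < 1e-10 &&
              abs(res$const_residual) < 1e-10 && rel < 1e-3)
  })
  passed <- all(vapply(checks, `[[`, logical(1), "ok"))

  utils::write.csv(.round_mirror(eq), file.path(out_dir, "equilibria.csv"),
                   row.names = FALSE)
  for (pl in c("government", "enterprise")) {
    tab <- do.call(rbind, lapply(b_grid, function(bb) {
      cm <- compare_modes(pl, params, b = bb,
                          x = if (pl == "government") params$x0_gov else params$x0_ent)
      data.frame(b = bb,
                 V_A = cm$value[cm$mode == "A"],
                 V_S = cm$value[cm$mode == "S"],
                 V_I = cm$value[cm$mode == "I"],
                 best_mode = paste(cm$mode[cm$rank == 1], collapse = "/"))
    }))
    utils::write.csv(.round_mirror(tab),
                     file.path(out_dir, paste0("comparison_", pl, ".csv")),
                     row.names = FALSE)
  }
  if (isTRUE(trajectories)) {
    times <- seq(0, oracle_T, by = 0.01)
    for (i in seq_len(nrow(eq))) {
      pr <- reduce_mode(eq$mode[i], eq$player[i], params)
      tr <- simulate_trajectory(pr, eq$b[i], pr$x0, eq$F_star[i], params,
                                times)
      utils::write.csv(tr, file.path(out_dir,
        sprintf("trajectory_%s_%s.csv", eq$mode[i], eq$player[i])),
        row.names = FALSE)
    }
  }
  summary <- list(
    scenario = scenario$name,
    version = as.character(utils::packageVersion("pestgame")),
    seed = scenario$seed,
    params = unclass(params),
    equilibria = eq,
    checks = checks,
    passed = passed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}

# full-precision table plus display-rounded twins of the numeric columns,
# mirroring the model's 3-decimal print style
.round_mirror <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[paste0(cn, "_display")]] <- round(df[[cn]], 3)
  df
}
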