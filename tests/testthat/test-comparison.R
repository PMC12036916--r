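test_that("mode rankings reproduce the printed-parameter comparisons", {
  # government, cost 4, no direct gain: resource sharing wins
  p4 <- baseline_scenario(c_unit = 4)$params
  cm <- compare_modes("government", p4, b = 0, x = 1)
  expect_identical(cm$mode[1], "S")
  expect_equal(cm$value[cm$mode == "S"], -9.29841, tolerance = 1e-5)
  expect_equal(cm$value[cm$mode == "A"], -9.55556, tolerance = 1e-5)
  expect_equal(cm$value[cm$mode == "I"], -10.63194, tolerance = 1e-5)
  # government, cost 2, high gain: information sharing wins
  p2 <- baseline_scenario(c_unit = 2)$params
  cm <- compare_modes("government", p2, b = 5, x = 1)
  expect_identical(cm$mode[1], "I")
  # enterprise at zero gain: I best, A and S exactly tied
  cm <- compare_modes("enterprise", p2, b = 0, x = 1)
  expect_identical(cm$mode[1], "I")
  tied <- cm[cm$mode %in% c("A", "S"), ]
  expect_true(all(tied$tied))
  expect_identical(tied$rank[1], tied$rank[2])
  expect_equal(diff(tied$value), 0)
})

test_that("crossover roots match their frozen values and the bisection oracle", {
  p2 <- baseline_scenario(c_unit = 2)$params
  r <- crossover_gain("government", p2, "A", "S")
  expect_equal(nrow(r), 1L)
  expect_equal(r$root, 0.06491106, tolerance = 1e-6)
  p4 <- baseline_scenario(c_unit = 4)$params
  r4 <- crossover_gain("government", p4, "A", "S")
  expect_equal(r4$root, 1.716594, tolerance = 1e-5)
  # enterprise A vs S meet exactly at the boundary b = 0
  re <- crossover_gain("enterprise", p2, "A", "S")
  expect_equal(re$root, 0, tolerance = 1e-9)
  expect_error(crossover_gain("government", p2, "A", "A"), "must differ")
  expect_error(crossover_gain("government", p2, "A", "S", interval = c(-1, 5)),
               "within b >= 0")
})

test_that("analytic crossovers agree with direct bisection on random scenarios", {
  for (sc in draw_scenarios(10)) {
    p <- sc$params
    for (pair in list(c("A", "S"), c("A", "I"), c("S", "I"))) {
      roots <- crossover_gain("government", p, pair[1], pair[2],
                              interval = c(0, 50))
      vdiff <- function(b) {
        vx <- solve_value(reduce_mode(pair[1], "government", p), b = b,
                          x = 1, params = p)$value
        vy <- solve_value(reduce_mode(pair[2], "government", p), b = b,
                          x = 1, params = p)$value
        vx - vy
      }
      for (j in seq_len(nrow(roots))) {
        r <- roots$root[j]
        if (roots$multiplicity[j] == 2L || r < 1e-6) next
        # bracket inside the gap to any other root so bisection cannot
        # jump to a neighbour
        gap <- min(0.5, abs(roots$root[-j] - r) / 2, r)
        lo <- r - gap; hi <- r + gap
        while (sign(vdiff(lo)) == sign(vdiff(hi)) && gap > 1e-12) {
          gap <- gap / 4; lo <- r - gap; hi <- r + gap
        }
        if (sign(vdiff(lo)) == sign(vdiff(hi))) next
        bis <- stats::uniroot(vdiff, c(lo, hi), tol = 1e-13)$root
        expect_lt(abs(bis - r), 1e-9)
      }
    }
  }
})

test_that("information sharing strictly dominates individual action for the cost-2 government", {
  # V_I - V_A = 1.18056 + 1.38889 b1, a positive affine function of b1
  p2 <- baseline_scenario(c_unit = 2)$params
  vdiff <- function(b) {
    vi <- solve_value(reduce_mode("I", "government", p2), b = b, x = 1,
                      params = p2)$value
    va <- solve_value(reduce_mode("A", "government", p2), b = b, x = 1,
                      params = p2)$value
    vi - va
  }
  d0 <- vdiff(0); d1 <- vdiff(1); d2 <- vdiff(2)
  expect_equal(d0, 1.180556, tolerance = 1e-6)          # intercept
  expect_equal(d1 - d0, 1.388889, tolerance = 1e-6)     # slope
  expect_equal(d2 - d1, d1 - d0, tolerance = 1e-9)      # affine in b
  expect_true(all(vapply(seq(0, 10, 0.5), vdiff, numeric(1)) > 0))
})

test_that("dominance maps reproduce the qualitative mode regions", {
  p <- baseline_scenario()$params
  gov <- dominance_region("government", p, b_grid = c(0, 5), c_grid = c(2, 4))
  expect_identical(gov$best_mode[gov$b == 0 & gov$c == 4], "S")
  expect_identical(gov$best_mode[gov$b == 5 & gov$c == 2], "I")
  ent <- dominance_region("enterprise", p, b_grid = c(0, 8), c_grid = 2)
  expect_identical(ent$best_mode[ent$b == 0], "I")
  expect_identical(ent$best_mode[ent$b == 8], "S")
  # pointwise computation: invariant to grid order
  shuffled <- dominance_region("government", p, b_grid = c(5, 0),
                               c_grid = c(4, 2))
  for (i in seq_len(nrow(gov))) {
    j <- which(shuffled$b == gov$b[i] & shuffled$c == gov$c[i])
    expect_identical(shuffled$best_mode[j], gov$best_mode[i])
  }
  expect_error(dominance_region("government", p, b_grid = -1), "b_grid")
  expect_error(dominance_region("government", p, c_grid = 0), "c_grid")
})

test_that("comparative statics: frozen baseline derivatives, signs, and no-dependence flags", {
  p <- baseline_scenario()$params  # c1 = 2
  d <- comparative_statics("S", "government", "aS", p)
  expect_equal(d$value, 0.2)
  expect_true(d$depends)
  d <- comparative_statics("I", "government", "bI", p)
  expect_equal(d$value, 0.5)
  d <- comparative_statics("A", "government", "CO", p)
  expect_identical(d$value, 0)
  expect_false(d$depends)
  # the other player's parameters never enter
  expect_false(comparative_statics("A", "government", "b2", p)$depends)
})

test_that("closed-form derivatives agree with central finite differences", {
  targets <- c("b1", "c1", "a1", "cS", "aS", "bI", "betaS", "l", "rho",
               "delta", "CO", "CI", "b2", "c2", "a2")
  for (sc in draw_scenarios(5)) {
    p <- sc$params
    for (i in seq_len(nrow(all_pairs))) {
      for (tg in targets) {
        d <- comparative_statics(all_pairs$mode[i], all_pairs$player[i],
                                 tg, p)
        expect_equal(d$value, d$fd, tolerance = 1e-6,
                     label = sprintf("d F*(%s,%s)/d %s analytic",
                                     all_pairs$mode[i], all_pairs$player[i], tg))
      }
    }
  }
})
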