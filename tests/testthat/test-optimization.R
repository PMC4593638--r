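test_that("fitness value matches direct evaluation and is affine in f", {
  ## pure spine economy at the tabulated optimum: F = -s / u_bar^gamma2
  spec0 <- principle_spec(f = 0, gamma2 = 0.45, theta = 0.321)
  comp <- complete_composition(0.397, 0.397, 0.678, "exponential", 0.321)
  expect_equal(fitness_value(spec0, 0.397, 0.397, 0.678),
               -comp$fractions[["spines"]] / 0.678^0.45,
               tolerance = 1e-12)
  expect_near(fitness_value(spec0, 0.397, 0.397, 0.678), -0.1167, 1e-3)

  ## pure wire volume: F = r*x + y independent of u_bar
  spec1 <- principle_spec(f = 1, gamma1 = 0, r = 0.9, theta = 0.321)
  expect_equal(fitness_value(spec1, 0.4, 0.35, 0.7), 0.9 * 0.4 + 0.35)
  expect_equal(fitness_value(spec1, 0.4, 0.35, 2.4), 0.9 * 0.4 + 0.35)

  ## linearity of the meta principle in the mixing ratio
  mk <- function(f) principle_spec(f = f, gamma1 = 1 / 3, gamma2 = 0.6,
                                   r = 0.95, theta = 0.321)
  F0 <- fitness_value(mk(0), 0.4, 0.38, 0.8)
  F1 <- fitness_value(mk(1), 0.4, 0.38, 0.8)
  Fh <- fitness_value(mk(0.5), 0.4, 0.38, 0.8)
  expect_equal(Fh, (F0 + F1) / 2, tolerance = 1e-12)
})

test_that("published reduced systems hold at the tabulated rows", {
  ## spine economy, exponential: the u_bar equation balances at ~0.336
  spec0 <- principle_spec(f = 0, gamma2 = 0.45, theta = 0.321)
  red0 <- reduced_residuals(spec0, row_spine_econ$x, row_spine_econ$y,
                            row_spine_econ$u_bar)
  expect_lt(abs(red0[["u"]]), 5e-3)
  expect_lt(abs(red0[["constraint"]]), 5e-3)
  lhs <- row_spine_econ$u_bar^(2 / 3) *
    spine_exceedance_deriv(
      spine_distribution("exponential", row_spine_econ$u_bar), 0.321)
  expect_near(lhs, 0.336, 1e-3)

  ## wire volume, exponential, r = 0.96: asymmetry equation LHS ~ 0.041
  ## against RHS 1 - r = 0.040 (table rounding)
  spec1 <- principle_spec(f = 1, gamma1 = 0, r = 0.96, theta = 0.321)
  red1 <- reduced_residuals(spec1, row_wire_asym$x, row_wire_asym$y,
                            row_wire_asym$u_bar)
  expect_lt(abs(red1[["asym"]]), 5e-3)
  expect_lt(abs(red1[["u"]]), 5e-3)
  expect_lt(abs(red1[["constraint"]]), 5e-3)

  ## no reduced form exists for mixed principles
  spec_mix <- principle_spec(f = 0.5, gamma1 = 0, gamma2 = 0.5)
  expect_error(reduced_residuals(spec_mix, 0.4, 0.4, 0.7), "mixed")
})

test_that("derivation-based and published residuals vanish together", {
  cases <- list(
    principle_spec(f = 0, gamma2 = 0.45, theta = 0.321),
    principle_spec(f = 0, gamma2 = 0.35, theta = 0.321,
                   family = "lognormal", shape = 0.25),
    principle_spec(f = 1, gamma1 = 0, r = 0.96, theta = 0.321),
    principle_spec(f = 1, gamma1 = 0, r = 0.95, theta = 0.100,
                   family = "gamma_n2")
  )
  for (spec in cases) {
    sol <- solve_principle(spec)
    expect_true(sol$converged)
    red <- reduced_residuals(spec, sol$x, sol$y, sol$u_bar)
    expect_lt(max(abs(red)), 1e-7)
  }
  ## a random feasible but non-stationary point has a clear residual
  spec <- cases[[1]]
  expect_gt(sqrt(sum(stationarity_residuals(spec, 0.30, 0.45, 1.3)^2)),
            0.01)
})

test_that("spine-economy solutions match the tabulated optimum", {
  spec <- principle_spec(f = 0, gamma2 = 0.45, theta = 0.321)
  sol <- solve_principle(spec)
  expect_true(sol$converged)
  expect_equal(sol$branch, "stationary")
  expect_lt(sol$residual_norm, 1e-8)
  expect_lt(abs(sol$constraint_residual), 1e-9)
  expect_near(unname(sol$fractions),
              c(0.397, 0.397, 0.098, 0.097, 0.010), 1e-3)
  expect_near(sol$u_bar, 0.678, 1e-3)
  expect_near(sol$P, 0.623, 1e-3)
  ## the optimum is symmetric in axons and dendrites
  expect_equal(sol$x, sol$y, tolerance = 1e-9)
})

test_that("wire-volume solutions match the tabulated optimum", {
  spec <- principle_spec(f = 1, gamma1 = 0, r = 1.00, theta = 0.321)
  sol <- solve_principle(spec)
  expect_true(sol$converged)
  expect_near(unname(sol$fractions[c(1, 3)]), c(0.397, 0.112), 1e-3)
  expect_near(sol$u_bar, 0.936, 1.5e-3)
  expect_near(sol$P, 0.710, 1e-3)
})

test_that("positive wire exponents drive the mean spine volume to infinity", {
  for (fam in c("exponential", "lognormal")) {
    spec <- principle_spec(f = 1, gamma1 = 0.65, r = 0.95, theta = 0.321,
                           family = fam,
                           shape = if (fam == "lognormal") 0.3 else NULL)
    sol <- solve_principle(spec)
    expect_equal(sol$branch, "divergent-limit")
    expect_equal(sol$P, 1)
    expect_equal(sol$u_bar, Inf)
    expect_equal(unname(sol$fractions[4:5]), c(0, 0))
    expect_equal(sol$fractions[["spines"]], sol$x * sol$y)
  }
})

test_that("the analytic wire limit solves the quadratic exactly", {
  lim <- wire_limit_solution(1)
  expect_equal(lim$x, sqrt(2) - 1, tolerance = 1e-12)
  expect_equal(lim$fractions[["spines"]], 3 - 2 * sqrt(2),
               tolerance = 1e-12)
  lim95 <- wire_limit_solution(0.95)
  expect_near(c(lim95$x, lim95$y, lim95$fractions[["spines"]]),
              c(0.4510, 0.3785, 0.1707), 1e-4)
  ## the limit composition satisfies the normalization constraint
  expect_lt(abs(lim95$constraint_residual), 1e-12)
  expect_error(wire_limit_solution(0.4), "no limit root")
})

test_that("stationarity solve agrees with the brute-force oracle", {
  cases <- list(
    principle_spec(f = 0, gamma2 = 0.45, theta = 0.321),
    principle_spec(f = 0, gamma2 = 0.35, theta = 0.321,
                   family = "lognormal", shape = 0.25),
    principle_spec(f = 0, gamma2 = 0.60, theta = 0.100,
                   family = "loglogistic", shape = 4),
    principle_spec(f = 1, gamma1 = 0, r = 1.00, theta = 0.321),
    principle_spec(f = 1, gamma1 = 0, r = 0.95, theta = 0.321,
                   family = "lognormal", shape = 0.3),
    principle_spec(f = 0.5, gamma1 = 0, gamma2 = 0.6, r = 0.95,
                   theta = 0.321, family = "gamma_n2"),
    principle_spec(f = 0.1, gamma1 = 2 / 3, gamma2 = 1.0, r = 0.99,
                   theta = 0.321)
  )
  for (spec in cases) {
    sol <- solve_principle(spec)
    orc <- oracle_optimize(spec)
    expect_true(sol$converged)
    expect_false(orc$boundary)
    expect_lt(max(abs(sol$fractions - orc$fractions)), 1e-3)
  }
})

test_that("the oracle detects the divergent wire-minimization regime", {
  spec <- principle_spec(f = 1, gamma1 = 2 / 3, r = 1, theta = 0.321)
  orc <- oracle_optimize(spec)
  expect_true(orc$boundary)
  ## pushing the cap outward keeps lowering the objective
  orc2 <- oracle_optimize(spec, u_range = c(0.02, 2000))
  expect_lt(orc2$objective, orc$objective)
})

test_that("the Lagrange multiplier is consistent across all conditions", {
  specs <- list(
    principle_spec(f = 0, gamma2 = 0.45, theta = 0.321),
    principle_spec(f = 1, gamma1 = 0, r = 0.96, theta = 0.321),
    principle_spec(f = 0.5, gamma1 = 5 / 6, gamma2 = 3.4, r = 1,
                   theta = 0.321)
  )
  for (spec in specs) {
    sol <- solve_principle(spec)
    gr <- cortexcomp:::principle_gradients(spec, sol$x, sol$y, sol$u_bar)
    lam <- -gr$Fx / gr$hx
    ## the single multiplier annihilates every first-order condition
    expect_near(gr$Fy + lam * gr$hy, 0, 1e-6)
    expect_near(gr$Fu + lam * gr$hu, 0, 1e-6)
    expect_equal(sol$lambda, lam, tolerance = 1e-10)
  }
})

test_that("extremum classes match the principle type", {
  ## spine-economy optima are maxima of the spine-economy function
  sol0 <- solve_principle(principle_spec(f = 0, gamma2 = 0.45,
                                         theta = 0.321))
  expect_equal(sol0$extremum_class, "max")
  ## wire-volume optima are minima of the wire cost
  sol1 <- solve_principle(principle_spec(f = 1, gamma1 = 0, r = 1,
                                         theta = 0.321))
  expect_equal(sol1$extremum_class, "min")
  ## mixed optima are minima of the meta fitness
  solm <- solve_principle(principle_spec(f = 0.5, gamma1 = 5 / 6,
                                         gamma2 = 3.4, r = 1,
                                         theta = 0.321))
  expect_equal(solm$extremum_class, "min")
})

test_that("every converged solution re-derives its couplings exactly", {
  specs <- list(
    principle_spec(f = 0, gamma2 = 0.25, theta = 0.100),
    principle_spec(f = 1, gamma1 = 0, r = 0.93, theta = 0.321,
                   family = "rayleigh"),
    principle_spec(f = 0.9, gamma1 = 0, gamma2 = 1.1, r = 1,
                   theta = 0.321)
  )
  for (spec in specs) {
    sol <- solve_principle(spec)
    expect_true(sol$converged)
    fr <- sol$fractions
    expect_equal(fr[["spines"]], sol$P * sol$x * sol$y, tolerance = 1e-12)
    expect_equal(fr[["glia"]],
                 glia_fraction(fr[["spines"]], sol$u_bar, spec$a),
                 tolerance = 1e-12)
    expect_equal(fr[["capillaries"]],
                 capillary_fraction(fr[["glia"]], fr[["spines"]]),
                 tolerance = 1e-12)
    expect_lt(abs(sum(fr) - 1), 1e-9)
    expect_lt(sol$residual_norm, 1e-8)
  }
})
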