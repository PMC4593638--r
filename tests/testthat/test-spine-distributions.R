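test_that("mean calibration sets the scale parameters in closed form", {
  expect_equal(spine_distribution("exponential", 0.5)$alpha, 2)
  expect_equal(spine_distribution("gamma_n2", 1)$alpha, 3)
  expect_equal(spine_distribution("gamma_n1", 0.5)$alpha, 4)
  expect_equal(spine_distribution("loglogistic", 1, shape = 2)$alpha, 2 / pi)
  expect_equal(spine_distribution("rayleigh", 1)$sigma_R, sqrt(2 / pi))
  expect_equal(spine_distribution("lognormal", 2, shape = 0.5)$mu,
               log(2) - 0.125)
})

test_that("invalid parameters are rejected with informative messages", {
  expect_error(spine_distribution("loglogistic", 1, shape = 1), "beta")
  expect_error(spine_distribution("lognormal", 1, shape = 0), "sigma")
  expect_error(spine_distribution("exponential", -1), "positive")
  expect_error(spine_distribution("exponential", 1, shape = 2), "no `shape`")
  d <- spine_distribution("exponential", 1)
  expect_error(spine_pdf(d, -0.1), "nonnegative")
  expect_error(spine_exceedance(d, -0.1), "nonnegative")
  expect_error(spine_sample(d, 0, seed = 1), "positive integer")
  expect_error(spine_sample(d, 10), "seed")
})

test_that("pdf values match the closed forms", {
  expect_equal(spine_pdf(spine_distribution("exponential", 1), 0), 1)
  expect_equal(spine_pdf(spine_distribution("gamma_n1", 1), 0.5),
               4 * 0.5 * exp(-1))
  ray <- spine_distribution("rayleigh", sqrt(pi / 2))  # sigma_R = 1
  expect_equal(spine_pdf(ray, 1), exp(-0.5))
})

test_that("every family integrates to 1 with the requested mean", {
  for (cs in family_cases()) {
    for (ub in c(0.3, 0.7, 1.5)) {
      d <- spine_distribution(cs$family, ub, cs$shape)
      total <- integrate(function(u) spine_pdf(d, u), 0, Inf,
                         rel.tol = 1e-10)$value
      expect_equal(total, 1, tolerance = 1e-6,
                   info = paste(cs$family, ub))
      m <- integrate(function(u) u * spine_pdf(d, u), 0, Inf,
                     rel.tol = 1e-10)$value
      expect_equal(m, ub, tolerance = 1e-5, info = paste(cs$family, ub))
    }
  }
})

test_that("closed-form exceedance equals quadrature of the pdf", {
  for (cs in family_cases()) {
    for (ub in c(0.4, 0.8, 1.6)) {
      for (theta in c(0.1, 0.321, 0.9)) {
        d <- spine_distribution(cs$family, ub, cs$shape)
        quad <- integrate(function(u) spine_pdf(d, u), theta, Inf,
                          rel.tol = 1e-12)$value
        expect_equal(spine_exceedance(d, theta), quad, tolerance = 1e-8,
                     info = paste(cs$family, ub, theta))
      }
    }
  }
})

test_that("gamma exceedance matches the regularized upper incomplete gamma", {
  ## The incomplete-gamma route (upper tail of the gamma CDF) is the
  ## independent oracle for the explicit first/second-order polynomials.
  for (fam in c("gamma_n1", "gamma_n2")) {
    n <- if (fam == "gamma_n1") 1 else 2
    for (ub in c(0.4, 1.1)) {
      d <- spine_distribution(fam, ub)
      for (theta in c(0.15, 0.6)) {
        expect_equal(spine_exceedance(d, theta),
                     pgamma(theta, shape = n + 1, rate = (n + 1) / ub,
                            lower.tail = FALSE),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("exceedance is a probability, increasing in the mean volume", {
  theta <- 0.321
  ubs <- seq(0.05, 6, by = 0.05)
  for (cs in family_cases()) {
    P <- vapply(ubs, function(ub) {
      spine_exceedance(spine_distribution(cs$family, ub, cs$shape), theta)
    }, 0)
    expect_true(all(P > 0 & P <= 1), info = cs$family)
    expect_true(all(diff(P) > 0), info = cs$family)
    big <- spine_exceedance(spine_distribution(cs$family, 500, cs$shape),
                            theta)
    expect_gt(big, 0.97)
    tiny <- spine_exceedance(spine_distribution(cs$family, 0.01, cs$shape),
                             theta)
    expect_lt(tiny, 0.05)
    ## theta = 0 means every potential spine forms
    expect_equal(spine_exceedance(
      spine_distribution(cs$family, 0.7, cs$shape), 0), 1)
  }
})

test_that("log-logistic exceedance sharpens to a threshold step at large beta", {
  theta <- 0.321
  beta <- 50
  theta_tilde <- theta * (pi / beta) / sin(pi / beta)
  lo <- spine_exceedance(
    spine_distribution("loglogistic", 0.5 * theta_tilde, beta), theta)
  hi <- spine_exceedance(
    spine_distribution("loglogistic", 2 * theta_tilde, beta), theta)
  expect_lt(lo, 0.01)
  expect_gt(hi, 0.99)
})

test_that("exceedance derivative matches central finite differences", {
  theta <- 0.321
  for (cs in family_cases()) {
    for (ub in c(0.45, 0.678, 1.3)) {
      d <- spine_distribution(cs$family, ub, cs$shape)
      h <- 1e-6 * ub
      fd <- (spine_exceedance(spine_distribution(cs$family, ub + h,
                                                 cs$shape), theta) -
             spine_exceedance(spine_distribution(cs$family, ub - h,
                                                 cs$shape), theta)) / (2 * h)
      expect_equal(spine_exceedance_deriv(d, theta), fd, tolerance = 1e-5,
                   info = paste(cs$family, ub))
      expect_gte(spine_exceedance_deriv(d, theta), 0)
    }
    expect_equal(spine_exceedance_deriv(
      spine_distribution(cs$family, 0.7, cs$shape), 0), 0)
  }
})

test_that("sampling reproduces the mean and exceedance to Monte-Carlo accuracy", {
  n <- 1e5
  theta <- 0.321
  for (cs in family_cases()) {
    d <- spine_distribution(cs$family, 0.7, cs$shape)
    u <- spine_sample(d, n, seed = 42)
    expect_true(all(u >= 0))
    se_mean <- sd(u) / sqrt(n)
    expect_lt(abs(mean(u) - 0.7), 3 * se_mean)
    P <- spine_exceedance(d, theta)
    se_p <- sqrt(P * (1 - P) / n)
    expect_lt(abs(mean(u > theta) - P), 3 * se_p)
  }
})

test_that("sampling is reproducible by seed and leaves the RNG state alone", {
  d <- spine_distribution("lognormal", 0.5, shape = 0.6)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- spine_sample(d, 100, seed = 7)
  b <- spine_sample(d, 100, seed = 7)
  after <- runif(1)
  expect_identical(a, b)
  expect_identical(before, after)
  expect_false(identical(a, spine_sample(d, 100, seed = 8)))
})
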