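#' Specify an optimization principle
#'
#' Bundles the parameters of the meta fitness function
#' `F = f * (r*x + y) / u_bar^gamma1 - (1 - f) * s / u_bar^gamma2`,
#' minimized subject to `x + y + s + g + c = 1`, where `s`, `g`, `c` follow
#' from `(x, y, u_bar)` through the coupling laws. `f = 1` is pure wire
#' minimization (`gamma1` = 0 wire volume, 1/3 surface area, 2/3 length,
#' 5/6 conduction delays); `f = 0` is pure spine-economy maximization
#' (maximize `s / u_bar^gamma2`); intermediate `f` mixes the two.
#'
#' @param f Mixing ratio in \[0, 1\]: weight of the wire-cost term.
#' @param gamma1 Wire exponent, >= 0.
#' @param gamma2 Spine-economy exponent, > 0 (ignored when `f = 1`).
#' @param r Axon/dendrite asymmetry, > 0.
#' @param theta Spine-formation threshold, um^3.
#' @param family Spine-size distribution family (see [spine_distribution()]).
#' @param shape Shape parameter for the log-logistic / log-normal families.
#' @param a Astrocyte coupling constant, um^2.
#' @return An object of class `"principle_spec"`.
#' @export
principle_spec <- function(f, gamma1 = 0, gamma2 = 0.5, r = 1,
                           theta = 0.321,
                           family = "exponential", shape = NULL,
                           a = cortex_a()) {
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  if (gamma1 < 0) stop("`gamma1` must be >= 0", call. = FALSE)
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  if (theta < 0) stop("`theta` must be nonnegative", call. = FALSE)
  family <- match.arg(family, spine_families())
  spine_distribution(family, 1, shape)  # validates family/shape pairing
  structure(list(f = f, gamma1 = gamma1, gamma2 = gamma2, r = r,
                 theta = theta, family = family, shape = shape, a = a),
            class = "principle_spec")
}

#' @export
print.principle_spec <- function(x, ...) {
  cat(sprintf(paste0("<principle_spec> f = %g, gamma1 = %g, gamma2 = %g, ",
                     "r = %g, theta = %g, %s%s\n"),
              x$f, x$gamma1, x$gamma2, x$r, x$theta, x$family,
              if (is.null(x$shape)) "" else sprintf(" (shape %g)", x$shape)))
  invisible(x)
}

## Exceedance P and dP/du_bar for a principle spec.
spec_P <- function(spec, u_bar) {
  exceedance_closed(spec$family, u_bar, spec$theta, spec$shape)
}
spec_dP <- function(spec, u_bar) {
  exceedance_deriv_closed(spec$family, u_bar, spec$theta, spec$shape)
}

#' Meta fitness value on the constraint surface
#'
#' Evaluates `F = f * (r*x + y) / u_bar^gamma1 - (1 - f) * s / u_bar^gamma2`
#' with `s = P(u_bar; theta) * x * y`. The Lagrange term is omitted: `F` is
#' evaluated at the point as given, whether or not the normalization
#' constraint holds there.
#'
#' @param spec A [principle_spec()].
#' @param x,y Axon and dendrite fractions in (0, 1).
#' @param u_bar Mean spine volume, um^3.
#' @return Fitness value (to be minimized).
#' @export
fitness_value <- function(spec, x, y, u_bar) {
  stopifnot(inherits(spec, "principle_spec"))
  P <- spec_P(spec, u_bar)
  spec$f * (spec$r * x + y) / u_bar^spec$gamma1 -
    (1 - spec$f) * P * x * y / u_bar^spec$gamma2
}

## Gradients of the fitness F and the constraint h = x+y+s+g+c-1 with
## respect to (x, y, u_bar); all closed-form. Requires s > 0.
principle_gradients <- function(spec, x, y, u_bar) {
  f <- spec$f; g1 <- spec$gamma1; g2 <- spec$gamma2; r <- spec$r; a <- spec$a
  P <- spec_P(spec, u_bar)
  Pu <- spec_dP(spec, u_bar)
  s <- P * x * y
  g <- a * (s / u_bar)^(2 / 3)
  g_s <- (2 / 3) * g / s
  g_u <- -(2 / 3) * g / u_bar
  psi <- 1 + g_s * (1 + s) + g     # d(s+g+c)/ds including c = g*s
  list(
    P = P, Pu = Pu, s = s, g = g, c = g * s,
    h = x + y + s + g * (1 + s) - 1,
    Fx = f * r / u_bar^g1 - (1 - f) * P * y / u_bar^g2,
    Fy = f / u_bar^g1 - (1 - f) * P * x / u_bar^g2,
    Fu = -f * g1 * (r * x + y) / u_bar^(g1 + 1) -
      (1 - f) * (Pu * x * y / u_bar^g2 - g2 * s / u_bar^(g2 + 1)),
    hx = 1 + P * y * psi,
    hy = 1 + P * x * psi,
    hu = Pu * x * y * psi + g_u * (1 + s)
  )
}

#' Stationarity residuals of the constrained optimization
#'
#' First-order conditions of the Lagrangian `F + lambda * h` with the
#' multiplier eliminated: the returned 3-vector is
#' `c(Fx*hy - Fy*hx, Fx*hu - Fu*hx, h)`, where subscripts denote partial
#' derivatives with respect to `x`, `y` and `u_bar`, and
#' `h = x + y + s + g + c - 1`. All three components vanish exactly at a
#' constrained stationary point; they agree with the published reduced
#' systems for pure wire minimization and pure spine-economy maximization
#' (see [reduced_residuals()]).
#'
#' @inheritParams fitness_value
#' @return Numeric 3-vector of residuals.
#' @export
stationarity_residuals <- function(spec, x, y, u_bar) {
  stopifnot(inherits(spec, "principle_spec"))
  gr <- principle_gradients(spec, x, y, u_bar)
  c(xy = gr$Fx * gr$hy - gr$Fy * gr$hx,
    u = gr$Fx * gr$hu - gr$Fu * gr$hx,
    constraint = gr$h)
}

#' Published reduced stationarity systems (left minus right)
#'
#' For pure wire minimization (`f = 1`) the stationarity conditions reduce
#' to the asymmetry equation
#' `(r*x - y) * [P + (a/3) * (P^2/(x*y*u_bar^2))^(1/3) * (2 + 5*P*x*y)] = 1 - r`
#' together with the normalization constraint and a `u_bar` equation; for
#' pure spine-economy maximization (`f = 0`, where `x = y`) they reduce to
#' `u_bar^(2/3) * dP/du_bar = (P/u_bar) * (gamma2 * u_bar^(2/3) * (1 + P*x)`
#' `+ (a/3) * P^(2/3) * x^(1/3) * [2*(gamma2 - 1) + (5*gamma2 - 2) * P*x^2])`
#' plus the constraint. This function evaluates those published forms
#' directly (left-hand side minus right-hand side); it is the cross-check
#' for the derivation-based [stationarity_residuals()].
#'
#' @inheritParams fitness_value
#' @return For `f = 1`, a 3-vector (asymmetry, `u_bar` condition,
#'   constraint); for `f = 0`, a 3-vector (`u_bar` condition, constraint,
#'   symmetry `y - x`). Errors for intermediate `f`, for which no reduced
#'   form is published.
#' @export
reduced_residuals <- function(spec, x, y, u_bar) {
  stopifnot(inherits(spec, "principle_spec"))
  a <- spec$a; r <- spec$r; g1 <- spec$gamma1; g2 <- spec$gamma2
  P <- spec_P(spec, u_bar)
  Pu <- spec_dP(spec, u_bar)
  s <- P * x * y
  constraint <- x + y + s +
    a * s^(2 / 3) / u_bar^(2 / 3) + a * s^(5 / 3) / u_bar^(2 / 3) - 1
  if (spec$f == 1) {
    asym <- (r * x - y) *
      (P + (a / 3) * (P^2 / (x * y * u_bar^2))^(1 / 3) * (2 + 5 * s)) -
      (1 - r)
    ueq <- (2 / 3) * a * P * x^(2 / 3) * y * (1 + s) -
      g1 * (r * x + y) * P^(1 / 3) *
        (u_bar^(2 / 3) * y^(1 / 3) * (1 + P * x) +
           (a / 3) * (P * x)^(2 / 3) * (2 + 5 * s)) -
      u_bar * Pu * (P^(1 / 3) * u_bar^(2 / 3) * x * y^(4 / 3) +
                      (a / 3) * x^(2 / 3) * y * (2 + 5 * s))
    c(asym = asym, u = ueq, constraint = constraint)
  } else if (spec$f == 0) {
    ueq <- u_bar^(2 / 3) * Pu -
      (P / u_bar) * (g2 * u_bar^(2 / 3) * (1 + P * x) +
                       (a / 3) * P^(2 / 3) * x^(1 / 3) *
                         (2 * (g2 - 1) + (5 * g2 - 2) * P * x^2))
    c(u = ueq, constraint = constraint, symmetry = y - x)
  } else {
    stop("reduced systems are published only for f = 0 and f = 1; use ",
         "stationarity_residuals() for mixed principles", call. = FALSE)
  }
}

#' Wire-minimization limit solution for positive wire exponents
#'
#' For any `gamma1 > 0` the wire cost `(r*x + y) / u_bar^gamma1` is driven
#' to zero by `u_bar -> Inf`, so the optimal mean spine volume diverges,
#' `P -> 1`, and the glia and capillary fractions vanish. The remaining
#' fractions solve `r*x - y = 1 - r` with `x + y + x*y = 1`, a quadratic
#' with the closed form `x = sqrt(2/r) - 1`, `y = r*x - (1 - r)`.
#'
#' @param r Axon/dendrite asymmetry; must exceed 1/2 for a feasible root.
#' @return A `"principle_solution"` on the divergent-limit branch.
#' @examples
#' wire_limit_solution(1)$fractions   # x = y = sqrt(2) - 1, s = 3 - 2*sqrt(2)
#' @export
wire_limit_solution <- function(r = 1) {
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  x <- sqrt(2 / r) - 1
  y <- r * x - (1 - r)
  if (x <= 0 || x >= 1 || y <= 0 || y >= 1) {
    stop(sprintf("no limit root in (0,1)^2 for r = %g (need r > 1/2)", r),
         call. = FALSE)
  }
  fr <- c(axons = x, dendrites = y, spines = x * y, glia = 0, capillaries = 0)
  structure(list(x = x, y = y, u_bar = Inf, fractions = fr, P = 1,
                 lambda = NA_real_, objective = 0, residual_norm = 0,
                 constraint_residual = sum(fr) - 1,
                 extremum_class = "divergent-limit", converged = TRUE,
                 branch = "divergent-limit", n_roots = 1L, spec = NULL),
            class = "principle_solution")
}

#' Solver settings for [solve_principle()]
#'
#' @param tol Residual-norm convergence tolerance.
#' @param max_iter Newton iteration cap per start.
#' @param u_starts Mean-volume starting values, um^3.
#' @param x_starts Axon-fraction starting values.
#' @param u_cap Divergence cap on `u_bar`, um^3: iterates beyond it (with
#'   `f * gamma1 > 0`) select the analytic divergent-limit branch.
#' @param verbose Keep every distinct root in the result (`$roots`).
#' @return A list of settings.
#' @export
solver_control <- function(tol = 1e-10, max_iter = 120,
                           u_starts = c(0.08, 0.15, 0.3, 0.6, 1.0, 1.8, 4),
                           x_starts = c(0.34, 0.42, 0.48),
                           u_cap = 1e4, verbose = FALSE) {
  list(tol = tol, max_iter = max_iter, u_starts = u_starts,
       x_starts = x_starts, u_cap = u_cap, verbose = verbose)
}

## Damped Newton with numerical Jacobian on z = (x, y, log u_bar);
## returns list(z, norm) or NULL.
newton_root <- function(resid, z0, tol, max_iter) {
  z <- z0
  m <- length(z0)
  for (it in seq_len(max_iter)) {
    f0 <- tryCatch(resid(z), error = function(e) NULL)
    if (is.null(f0) || any(!is.finite(f0))) return(NULL)
    n0 <- sqrt(sum(f0^2))
    if (n0 < tol) return(list(z = z, norm = n0))
    J <- matrix(0, m, m)
    for (j in seq_len(m)) {
      hj <- 1e-7 * max(1, abs(z[j]))
      zp <- z; zp[j] <- z[j] + hj
      fj <- tryCatch(resid(zp), error = function(e) NULL)
      if (is.null(fj) || any(!is.finite(fj))) return(NULL)
      J[, j] <- (fj - f0) / hj
    }
    dz <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    step <- 1
    repeat {
      zn <- z + step * dz
      fn <- tryCatch(resid(zn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && sqrt(sum(fn^2)) < n0) break
      step <- step / 2
      if (step < 1e-9) return(NULL)
    }
    z <- zn
  }
  f0 <- resid(z)
  n0 <- sqrt(sum(f0^2))
  if (n0 < tol) list(z = z, norm = n0) else NULL
}

## Assemble a solution object from a converged interior root.
build_solution <- function(spec, x, y, u_bar, norm, n_roots,
                           roots = NULL) {
  gr <- principle_gradients(spec, x, y, u_bar)
  fr <- c(axons = x, dendrites = y, spines = gr$s, glia = gr$g,
          capillaries = gr$c)
  lambda <- -gr$Fx / gr$hx
  sol <- structure(list(x = x, y = y, u_bar = u_bar, fractions = fr,
                        P = gr$P, lambda = lambda,
                        objective = fitness_value(spec, x, y, u_bar),
                        residual_norm = norm,
                        constraint_residual = gr$h,
                        extremum_class = NA_character_,
                        converged = TRUE, branch = "stationary",
                        n_roots = n_roots, spec = spec),
                   class = "principle_solution")
  sol$extremum_class <- classify_extremum(spec, sol)
  if (!is.null(roots)) sol$roots <- roots
  sol
}

#' Solve the stationarity system of an optimization principle
#'
#' Multi-start damped Newton iteration on the multiplier-eliminated
#' first-order conditions ([stationarity_residuals()]) in
#' `(x, y, log u_bar)`. Distinct interior roots are collected; the root with
#' the best (lowest) meta-fitness value whose extremum class matches the
#' principle (maximum of the spine-economy function for `f = 0`, minimum of
#' the fitness otherwise) is returned.
#'
#' For pure wire minimization with `gamma1 > 0` the wire cost is strictly
#' positive and tends to zero as `u_bar -> Inf`, so no finite optimum
#' exists and the analytic divergent-limit branch
#' ([wire_limit_solution()]) is returned directly. For mixed principles
#' with `gamma1 > 0` a finite stationary local minimum is reported when one
#' exists (even though the fitness can still be lowered toward zero by
#' letting `u_bar` diverge — the finite branch is the biologically
#' meaningful one); the divergent limit is used only where the finite
#' branch disappears (small `gamma2`).
#'
#' @param spec A [principle_spec()].
#' @param control A [solver_control()].
#' @param start Optional numeric `c(x, y, u_bar)` start, tried first (used
#'   for warm starts along sweep grids).
#' @return A `"principle_solution"`: fractions, `u_bar`, `P`, the Lagrange
#'   multiplier, the objective, residual norms, the extremum class and the
#'   branch (`"stationary"` or `"divergent-limit"`). When no root is found
#'   the result has `converged = FALSE`; it is never a silent wrong answer.
#' @examples
#' spec <- principle_spec(f = 0, gamma2 = 0.45, theta = 0.321)
#' sol <- solve_principle(spec)
#' round(sol$fractions, 3)
#' @export
solve_principle <- function(spec, control = solver_control(), start = NULL) {
  stopifnot(inherits(spec, "principle_spec"))
  if (spec$f == 1 && spec$gamma1 > 0) {
    ## pure wire cost is > 0 everywhere and -> 0 as u_bar -> Inf: the
    ## optimum is the divergent limit, no root search needed
    lim <- tryCatch(wire_limit_solution(spec$r), error = function(e) NULL)
    if (!is.null(lim)) {
      lim$spec <- spec
      return(lim)
    }
    return(structure(list(x = NA_real_, y = NA_real_, u_bar = NA_real_,
                          fractions = rep(NA_real_, 5), P = NA_real_,
                          lambda = NA_real_, objective = NA_real_,
                          residual_norm = NA_real_,
                          constraint_residual = NA_real_,
                          extremum_class = NA_character_, converged = FALSE,
                          branch = "none", n_roots = 0L, spec = spec),
                     class = "principle_solution"))
  }
  resid <- function(z) {
    x <- z[1]; y <- z[2]; ub <- exp(z[3])
    if (x <= 0 || x >= 1 || y <= 0 || y >= 1) return(rep(NA_real_, 3))
    stationarity_residuals(spec, x, y, ub)
  }
  starts <- list()
  if (!is.null(start)) {
    starts[[1]] <- c(start[1], start[2], log(start[3]))
  }
  for (u0 in control$u_starts) {
    for (x0 in control$x_starts) {
      starts[[length(starts) + 1L]] <- c(x0, 0.95 * x0, log(u0))
    }
  }
  divergent_ok <- spec$f * spec$gamma1 > 0
  want <- if (spec$f == 0) "max" else "min"
  roots <- list()
  for (k in seq_along(starts)) {
    res <- newton_root(resid, starts[[k]], control$tol, control$max_iter)
    if (is.null(res)) next
    x <- res$z[1]; y <- res$z[2]; ub <- exp(res$z[3])
    if (x <= 1e-6 || x >= 1 - 1e-6 || y <= 1e-6 || y >= 1 - 1e-6) next
    if (ub > control$u_cap) next
    dup <- any(vapply(roots, function(q) {
      all(abs(c(q$x, q$y, log(q$ub)) - c(x, y, log(ub))) < 1e-6)
    }, logical(1)))
    if (!dup) {
      roots[[length(roots) + 1L]] <- list(x = x, y = y, ub = ub,
                                          norm = res$norm)
    }
    ## fast path for warm-started sweeps: accept the warm root right away,
    ## but only when its extremum class matches the principle (warm starts
    ## can slide into spurious saddles when the landscape shifts)
    if (!is.null(start) && k == 1L && length(roots) == 1L &&
        !control$verbose) {
      sol <- build_solution(spec, x, y, ub, res$norm, 1L)
      if (identical(sol$extremum_class, want)) {
        return(sol)
      }
    }
  }
  if (length(roots) > 0) {
    sols <- lapply(roots, function(q) {
      build_solution(spec, q$x, q$y, q$ub, q$norm, length(roots))
    })
    matching <- Filter(function(s) identical(s$extremum_class, want), sols)
    if (length(matching) == 0) matching <- sols
    best <- matching[[which.min(vapply(matching, `[[`, 0, "objective"))]]
    if (control$verbose) best$roots <- sols
    return(best)
  }
  if (divergent_ok) {
    lim <- tryCatch(wire_limit_solution(spec$r), error = function(e) NULL)
    if (!is.null(lim)) {
      lim$spec <- spec
      return(lim)
    }
  }
  structure(list(x = NA_real_, y = NA_real_, u_bar = NA_real_,
                 fractions = rep(NA_real_, 5), P = NA_real_,
                 lambda = NA_real_, objective = NA_real_,
                 residual_norm = NA_real_, constraint_residual = NA_real_,
                 extremum_class = NA_character_, converged = FALSE,
                 branch = "none", n_roots = 0L, spec = spec),
            class = "principle_solution")
}

#' @export
print.principle_solution <- function(x, ...) {
  if (!x$converged) {
    cat("<principle_solution> NOT CONVERGED\n")
    return(invisible(x))
  }
  cat(sprintf("<principle_solution> branch = %s, class = %s\n",
              x$branch, x$extremum_class))
  print(round(x$fractions, 4))
  cat(sprintf("u_bar = %.4g um^3, P = %.4f, F = %.6g, |resid| = %.2g\n",
              x$u_bar, x$P, x$objective, x$residual_norm))
  invisible(x)
}

#' Brute-force direct optimization (independent oracle)
#'
#' Optimizes the meta fitness directly over `(x, u_bar)` with the dendrite
#' fraction eliminated through the normalization constraint (root-finding in
#' `y`; for `f = 0` the symmetric `x = y` reduction leaves a one-dimensional
#' problem in `u_bar`), by coarse grid scan plus local polish. No use is
#' made of the stationarity equations, so this serves as an independent
#' check on [solve_principle()].
#'
#' @param spec A [principle_spec()].
#' @param n_grid Coarse-grid resolution per dimension.
#' @param u_range Search range for `u_bar`, um^3.
#' @return A list with `x`, `y`, `u_bar`, `fractions`, `P`, `objective` and
#'   `boundary` (`TRUE` when the optimum sits on the edge of `u_range`,
#'   indicating divergence).
#' @export
oracle_optimize <- function(spec, n_grid = 40,
                            u_range = c(0.02, 50)) {
  stopifnot(inherits(spec, "principle_spec"))
  a <- spec$a
  y_from_constraint <- function(x, ub) {
    P <- spec_P(spec, ub)
    con <- function(y) {
      s <- P * x * y
      x + y + s + a * (s / ub)^(2 / 3) * (1 + s) - 1
    }
    if (con(1e-12) > 0 || con(1 - x) < 0) return(NA_real_)
    stats::uniroot(con, c(1e-12, 1 - x), tol = 1e-14)$root
  }
  if (spec$f == 0) {
    ## symmetric case: maximize s / u_bar^gamma2 over u_bar alone
    neg_m <- function(lub) {
      ub <- exp(lub)
      P <- spec_P(spec, ub)
      con <- function(x) {
        s <- P * x^2
        2 * x + s + a * (s / ub)^(2 / 3) * (1 + s) - 1
      }
      x <- stats::uniroot(con, c(1e-9, 0.5), tol = 1e-14)$root
      -P * x^2 / ub^spec$gamma2
    }
    lgrid <- seq(log(u_range[1]), log(u_range[2]), length.out = n_grid * 4)
    vals <- vapply(lgrid, neg_m, 0)
    i <- which.min(vals)
    lo <- lgrid[max(1, i - 1)]; hi <- lgrid[min(length(lgrid), i + 1)]
    opt <- stats::optimize(neg_m, c(lo, hi), tol = 1e-12)
    ub <- exp(opt$minimum)
    P <- spec_P(spec, ub)
    con <- function(x) {
      s <- P * x^2
      2 * x + s + a * (s / ub)^(2 / 3) * (1 + s) - 1
    }
    x <- stats::uniroot(con, c(1e-9, 0.5), tol = 1e-14)$root
    y <- x
    boundary <- i %in% c(1L, length(lgrid))
  } else {
    obj <- function(z) {
      x <- z[1]; ub <- exp(z[2])
      if (x <= 1e-8 || x >= 1 - 1e-8) return(1e10)
      if (ub < u_range[1] || ub > u_range[2]) return(1e10)
      y <- y_from_constraint(x, ub)
      if (!is.finite(y)) return(1e10)
      fitness_value(spec, x, y, ub)
    }
    xg <- seq(0.05, 0.8, length.out = n_grid)
    lg <- seq(log(u_range[1]), log(u_range[2]), length.out = n_grid)
    grid <- as.matrix(expand.grid(xg, lg))
    vals <- apply(grid, 1, obj)
    z0 <- grid[which.min(vals), ]
    opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 4000))
    x <- opt$par[1]; ub <- exp(opt$par[2])
    y <- y_from_constraint(x, ub)
    boundary <- ub > 0.98 * u_range[2] || ub < 1.02 * u_range[1]
  }
  P <- spec_P(spec, ub)
  s <- P * x * y
  g <- a * (s / ub)^(2 / 3)
  list(x = x, y = y, u_bar = ub,
       fractions = c(axons = x, dendrites = y, spines = s, glia = g,
                     capillaries = g * s),
       P = P, objective = fitness_value(spec, x, y, ub),
       boundary = boundary)
}

#' Classify a constrained stationary point
#'
#' Numerically classifies a solution as a constrained local minimum,
#' maximum or saddle by the eigenvalue signs of the Hessian of the
#' Lagrangian projected onto the tangent space of the normalization
#' constraint at the solution. For `f = 0` the classification refers to the
#' spine-economy function `s / u_bar^gamma2` (expected: maximum); otherwise
#' to the meta fitness `F` (expected: minimum).
#'
#' @param spec A [principle_spec()].
#' @param solution A converged `"principle_solution"` on the stationary
#'   branch.
#' @return `"min"`, `"max"`, `"saddle"`, or `"indeterminate"` when the
#'   projected Hessian is numerically singular.
#' @export
classify_extremum <- function(spec, solution) {
  stopifnot(inherits(spec, "principle_spec"))
  if (!isTRUE(solution$converged) || solution$branch != "stationary") {
    return(solution$extremum_class %||% NA_character_)
  }
  v0 <- c(solution$x, solution$y, solution$u_bar)
  a <- spec$a
  hfun <- function(v) {
    s <- spec_P(spec, v[3]) * v[1] * v[2]
    v[1] + v[2] + s + a * (s / v[3])^(2 / 3) * (1 + s) - 1
  }
  if (spec$f == 0) {
    obj <- function(v) spec_P(spec, v[3]) * v[1] * v[2] / v[3]^spec$gamma2
  } else {
    obj <- function(v) fitness_value(spec, v[1], v[2], v[3])
  }
  gr <- principle_gradients(spec, solution$x, solution$y, solution$u_bar)
  grad_h <- c(gr$hx, gr$hy, gr$hu)
  grad_obj <- if (spec$f == 0) {
    ## gradient of Fs = s / u^gamma2 directly
    P <- gr$P
    c(P * solution$y, P * solution$x,
      gr$Pu * solution$x * solution$y -
        spec$gamma2 * gr$s / solution$u_bar) / solution$u_bar^spec$gamma2
  } else {
    c(gr$Fx, gr$Fy, gr$Fu)
  }
  lambda <- -grad_obj[1] / grad_h[1]
  ev <- tryCatch({
    H <- pracma::hessian(obj, v0) + lambda * pracma::hessian(hfun, v0)
    Z <- qr.Q(qr(cbind(grad_h, diag(3))))[, 2:3]
    eigen(t(Z) %*% H %*% Z, symmetric = TRUE)$values
  }, error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev)) || max(abs(ev)) == 0 ||
      min(abs(ev)) / max(abs(ev)) < 1e-8) {
    return("indeterminate")
  }
  if (all(ev > 0)) "min" else if (all(ev < 0)) "max" else "saddle"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
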