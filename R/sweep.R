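#' Sweep an optimization principle over parameter grids
#'
#' Solves the principle at every combination of the supplied grids and
#' records the optimal composition together with its Euclidean and
#' Mahalanobis distances to the empirical reference. Grid points where the
#' solver fails are kept in the output with `converged = FALSE` and excluded
#' from the argmin extraction — never silently dropped. Consecutive grid
#' points warm-start each other.
#'
#' @param spec A [principle_spec()] providing the fixed parameters.
#' @param grids Named list of grid vectors over any of `gamma2`, `r`, `f`,
#'   `gamma1`, `theta`, `shape`.
#' @param reference Empirical reference for the distances.
#' @param control A [solver_control()].
#' @return A data frame of class `"principle_sweep"`: one row per grid
#'   point with the swept parameters, `x`, `y`, `s`, `g`, `c`, `u_bar`,
#'   `P`, `objective`, `ed`, `md`, `converged`, `branch`, `class`.
#' @seealso [sweep_argmin()]
#' @export
sweep_principle <- function(spec, grids,
                            reference = normalized_reference(),
                            control = solver_control()) {
  stopifnot(inherits(spec, "principle_spec"))
  if (!is.list(grids) || length(grids) == 0 || is.null(names(grids))) {
    stop("`grids` must be a nonempty named list of parameter vectors",
         call. = FALSE)
  }
  allowed <- c("gamma2", "r", "f", "gamma1", "theta", "shape")
  bad <- setdiff(names(grids), allowed)
  if (length(bad)) {
    stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pts <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  n <- nrow(pts)
  out <- data.frame(pts,
                    x = NA_real_, y = NA_real_, s = NA_real_, g = NA_real_,
                    c = NA_real_, u_bar = NA_real_, P = NA_real_,
                    objective = NA_real_, ed = NA_real_, md = NA_real_,
                    converged = FALSE, branch = NA_character_,
                    class = NA_character_)
  warm <- NULL
  for (i in seq_len(n)) {
    sp <- spec
    for (nm in names(grids)) sp[[nm]] <- pts[i, nm]
    sol <- solve_principle(sp, control = control, start = warm)
    if (sol$converged) {
      fr <- sol$fractions
      out$x[i] <- fr[1]; out$y[i] <- fr[2]; out$s[i] <- fr[3]
      out$g[i] <- fr[4]; out$c[i] <- fr[5]
      out$u_bar[i] <- sol$u_bar; out$P[i] <- sol$P
      out$objective[i] <- sol$objective
      out$ed[i] <- euclidean_distance(fr, reference)
      out$md[i] <- mahalanobis_distance(fr, reference)
      out$converged[i] <- TRUE
      out$branch[i] <- sol$branch
      out$class[i] <- sol$extremum_class
      warm <- if (sol$branch == "stationary") {
        c(sol$x, sol$y, sol$u_bar)
      } else NULL
    } else {
      warm <- NULL
    }
  }
  class(out) <- c("principle_sweep", class(out))
  out
}

#' Extract the best-fitting row of a sweep
#'
#' @param sweep A [sweep_principle()] result.
#' @param measure `"ed"` or `"md"`.
#' @return The converged row minimizing the chosen distance.
#' @export
sweep_argmin <- function(sweep, measure = c("ed", "md")) {
  measure <- match.arg(measure)
  ok <- sweep[sweep$converged, , drop = FALSE]
  if (nrow(ok) == 0) stop("no converged grid points in sweep", call. = FALSE)
  ok[which.min(ok[[measure]]), , drop = FALSE]
}

## Default shape grids per family (the heavy-tailed families carry an
## adjustable shape parameter; the others do not).
default_shape_grid <- function(family) {
  switch(family,
    loglogistic = seq(1.5, 7, by = 0.5),
    lognormal   = seq(0.10, 1.00, by = 0.05),
    NA_real_)
}

#' Reproduce the best-fit composition tables
#'
#' Re-runs the parameter sweeps behind the published best-fit tables:
#' pure wire-volume minimization (`which = 2`; sweep over `r` and shape),
#' pure spine-economy maximization (`which = 3`; sweep over `gamma2` and
#' shape), and the mixed meta-principle at `f` = 0.1, 0.5, 0.9
#' (`which = 4, 5, 6`; four wire-cost variants
#' `gamma1 in {2/3, 1/3, 0, 5/6}`, sweep over `r`, `gamma2` and shape,
#' minimal-MD rows only). Fractions are rounded to 3 decimals,
#' half-away-from-zero, as in the source tables.
#'
#' @param which Table number, 2 to 6.
#' @param distributions Families to include.
#' @param theta Threshold grid (tables 4-6 use 0.321 only).
#' @param grids Optional named list overriding the default sweep grids
#'   (`r`, `gamma2`, and per-family `shape`).
#' @param reference Empirical reference.
#' @param control Solver settings.
#' @param file Optional path: write the table as CSV.
#' @return Data frame of best-fit rows (one per distribution, theta and
#'   criterion; tables 4-6 add a `principle` column for the wire variant).
#' @export
reproduce_table <- function(which,
                            distributions = spine_families(),
                            theta = if (which %in% 2:3) c(0.100, 0.321)
                                    else 0.321,
                            grids = list(),
                            reference = normalized_reference(),
                            control = solver_control(),
                            file = NULL) {
  stopifnot(which %in% 2:6)
  r_grid <- grids$r %||% seq(0.5, 1.2, by = 0.01)
  g2_grid <- grids$gamma2 %||% seq(0.05, 1.5, by = 0.05)
  rows <- list()
  add_row <- function(lab, fam, th, row, measure, extra = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      principle = lab, distribution = fam, theta = th, criterion = measure,
      x = round_half_up(row$x, 3), y = round_half_up(row$y, 3),
      s = round_half_up(row$s, 3), g = round_half_up(row$g, 3),
      c = round_half_up(row$c, 3),
      u_bar = round_half_up(row$u_bar, 3), P = round_half_up(row$P, 3),
      r = if ("r" %in% names(row)) row$r else NA_real_,
      gamma2 = if ("gamma2" %in% names(row)) row$gamma2 else NA_real_,
      shape = if ("shape" %in% names(row)) row$shape else NA_real_,
      ed = round_half_up(row$ed, 3), md = round_half_up(row$md, 3))
  }
  shape_grid_for <- function(fam) {
    sg <- grids$shape %||% default_shape_grid(fam)
    if (all(is.na(sg))) NA_real_ else sg
  }
  if (which %in% 2:3) {
    for (fam in distributions) {
      for (th in theta) {
        sg <- shape_grid_for(fam)
        g <- if (which == 2) list(r = r_grid) else list(gamma2 = g2_grid)
        if (!all(is.na(sg))) g$shape <- sg
        base <- principle_spec(f = as.numeric(which == 2), gamma1 = 0,
                               theta = th, family = fam,
                               shape = if (all(is.na(sg))) NULL else sg[1])
        sw <- sweep_principle(base, g, reference, control)
        add_row(if (which == 2) "wire volume min" else "spine economy max",
                fam, th, sweep_argmin(sw, "ed"), "min ED")
        add_row(if (which == 2) "wire volume min" else "spine economy max",
                fam, th, sweep_argmin(sw, "md"), "min MD")
      }
    }
  } else {
    f <- c(`4` = 0.1, `5` = 0.5, `6` = 0.9)[as.character(which)]
    variants <- c("wire length min + spine max" = 2 / 3,
                  "wire surface min + spine max" = 1 / 3,
                  "wire volume min + spine max" = 0,
                  "delays min + spine max" = 5 / 6)
    g2_wide <- grids$gamma2 %||% seq(0.1, 7, by = 0.1)
    r_coarse <- grids$r %||% seq(0.5, 1.2, by = 0.05)
    for (v in seq_along(variants)) {
      for (fam in distributions) {
        sg <- shape_grid_for(fam)
        g <- list(r = r_coarse, gamma2 = g2_wide)
        if (!all(is.na(sg))) g$shape <- sg
        base <- principle_spec(f = f, gamma1 = variants[v], theta = theta[1],
                               family = fam,
                               shape = if (all(is.na(sg))) NULL else sg[1])
        sw <- sweep_principle(base, g, reference, control)
        add_row(names(variants)[v], fam, theta[1],
                sweep_argmin(sw, "md"), "min MD")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Profile of the optimal solution along one parameter
#'
#' Tracks the optimal composition, mean spine volume, exceedance probability
#' and model-data distances along a grid of one principle parameter,
#' optionally minimizing the chosen distance over a shape-parameter grid at
#' each point (as the published profile curves do for the heavy-tailed
#' families).
#'
#' @param spec A [principle_spec()].
#' @param parameter One of `"r"`, `"gamma2"`, `"theta"`, `"f"`, `"gamma1"`.
#' @param values Grid for that parameter.
#' @param shape_grid Optional shape grid to minimize over at each point.
#' @param measure Distance minimized over `shape_grid` (`"ed"` or `"md"`).
#' @param reference Empirical reference.
#' @param control Solver settings.
#' @param file Optional CSV output path.
#' @return Data frame with one row per grid value.
#' @export
profile_curve <- function(spec, parameter, values, shape_grid = NULL,
                          measure = c("ed", "md"),
                          reference = normalized_reference(),
                          control = solver_control(), file = NULL) {
  measure <- match.arg(measure)
  parameter <- match.arg(parameter, c("r", "gamma2", "theta", "f", "gamma1"))
  grids <- stats::setNames(list(values), parameter)
  if (!is.null(shape_grid)) grids$shape <- shape_grid
  sw <- sweep_principle(spec, grids, reference, control)
  if (is.null(shape_grid)) {
    out <- sw
  } else {
    ## keep, per parameter value, the shape minimizing the chosen distance
    parts <- split(sw, sw[[parameter]])
    out <- do.call(rbind, lapply(parts, function(p) {
      ok <- p[p$converged, , drop = FALSE]
      if (nrow(ok) == 0) p[1, , drop = FALSE] else
        ok[which.min(ok[[measure]]), , drop = FALSE]
    }))
    out <- out[order(out[[parameter]]), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
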