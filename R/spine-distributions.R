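#' Spine-size distribution families
#'
#' Constructs a probability distribution for the volume `u` (in cubic microns)
#' of a potential dendritic spine. Six families are supported, three with
#' short (exponential-type) tails and two with heavy tails, plus the Rayleigh
#' family; all are parametrized by their mean `mean_volume` so that different
#' families are directly comparable at a common average spine volume.
#'
#' The internal scale parameter is derived from the mean:
#' \describe{
#'   \item{exponential}{rate `alpha = 1 / mean_volume`.}
#'   \item{gamma_n1, gamma_n2}{density `alpha^(n+1)/n! * u^n * exp(-alpha u)`
#'     of fixed order `n = 1` or `n = 2`, with `alpha = (n+1) / mean_volume`.}
#'   \item{rayleigh}{scale `sigma_R = mean_volume * sqrt(2/pi)`.}
#'   \item{loglogistic}{shape `beta > 1` (the `shape` argument) and scale
#'     `alpha = mean_volume * beta * sin(pi/beta) / pi`.}
#'   \item{lognormal}{log-scale `sigma > 0` (the `shape` argument) and
#'     location `mu = log(mean_volume) - sigma^2/2`.}
#' }
#'
#' @param family One of `"exponential"`, `"gamma_n1"`, `"gamma_n2"`,
#'   `"rayleigh"`, `"loglogistic"`, `"lognormal"`.
#' @param mean_volume Mean spine volume, um^3; must be positive.
#' @param shape Extra shape parameter: `beta > 1` for `"loglogistic"`,
#'   `sigma > 0` for `"lognormal"`; ignored (must be `NULL`) otherwise.
#'
#' @return An object of class `"spine_distribution"`: a list with fields
#'   `family`, `mean_volume`, `shape` and the derived scale parameters.
#' @seealso [spine_pdf()], [spine_exceedance()], [spine_sample()]
#' @examples
#' d <- spine_distribution("exponential", mean_volume = 0.5)
#' d$alpha                      # 2
#' spine_exceedance(d, 0.5)     # exp(-1)
#' @export
spine_distribution <- function(family = c("exponential", "gamma_n1",
                                          "gamma_n2", "rayleigh",
                                          "loglogistic", "lognormal"),
                               mean_volume, shape = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mean_volume) || length(mean_volume) != 1L ||
      !is.finite(mean_volume) || mean_volume <= 0) {
    stop("`mean_volume` must be a single positive number (um^3)",
         call. = FALSE)
  }
  needs_shape <- family %in% c("loglogistic", "lognormal")
  if (needs_shape) {
    if (is.null(shape) || !is.numeric(shape) || length(shape) != 1L ||
        !is.finite(shape)) {
      stop(sprintf("family '%s' requires a single numeric `shape` parameter",
                   family), call. = FALSE)
    }
    if (family == "loglogistic" && shape <= 1) {
      stop("log-logistic shape `beta` must be > 1 (the mean diverges otherwise)",
           call. = FALSE)
    }
    if (family == "lognormal" && shape <= 0) {
      stop("log-normal shape `sigma` must be > 0", call. = FALSE)
    }
  } else if (!is.null(shape)) {
    stop(sprintf("family '%s' takes no `shape` parameter", family),
         call. = FALSE)
  }

  d <- list(family = family, mean_volume = mean_volume, shape = shape)
  d <- c(d, switch(family,
    exponential = list(alpha = 1 / mean_volume),
    gamma_n1    = list(n = 1L, alpha = 2 / mean_volume),
    gamma_n2    = list(n = 2L, alpha = 3 / mean_volume),
    rayleigh    = list(sigma_R = mean_volume * sqrt(2 / pi)),
    loglogistic = list(beta = shape,
                       alpha = mean_volume * shape * sin(pi / shape) / pi),
    lognormal   = list(sigma = shape,
                       mu = log(mean_volume) - shape^2 / 2)
  ))
  class(d) <- "spine_distribution"
  d
}

#' @export
print.spine_distribution <- function(x, ...) {
  cat(sprintf("<spine_distribution> family = %s, mean volume = %g um^3%s\n",
              x$family, x$mean_volume,
              if (is.null(x$shape)) "" else sprintf(", shape = %g", x$shape)))
  invisible(x)
}

spine_families <- function() {
  c("exponential", "gamma_n1", "gamma_n2", "rayleigh",
    "loglogistic", "lognormal")
}

#' Spine-volume probability density
#'
#' @param dist A [spine_distribution()].
#' @param u Spine volumes, um^3; must be nonnegative.
#' @return Density values (per um^3).
#' @export
spine_pdf <- function(dist, u) {
  stopifnot(inherits(dist, "spine_distribution"))
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("`u` must be nonnegative and finite", call. = FALSE)
  }
  switch(dist$family,
    exponential = stats::dexp(u, rate = dist$alpha),
    gamma_n1    = stats::dgamma(u, shape = 2, rate = dist$alpha),
    gamma_n2    = stats::dgamma(u, shape = 3, rate = dist$alpha),
    rayleigh    = u / dist$sigma_R^2 * exp(-u^2 / (2 * dist$sigma_R^2)),
    loglogistic = {
      b <- dist$beta; a <- dist$alpha
      ifelse(u == 0 & b > 1, if (b > 1 && b < 2) Inf else if (b == 2) 1 / a else 0,
             (b / a) * (u / a)^(b - 1) / (1 + (u / a)^b)^2)
    },
    lognormal   = stats::dlnorm(u, meanlog = dist$mu, sdlog = dist$sigma)
  )
}

## Fast internal path used by the optimizer: exceedance probability
## P(mean_volume; theta) as a closed form per family, without constructing a
## distribution object per call. `shape` is beta (log-logistic), sigma
## (log-normal) or ignored.
exceedance_closed <- function(family, u_bar, theta, shape = NULL) {
  if (theta == 0) return(rep(1, length(u_bar)))
  t <- theta / u_bar
  switch(family,
    exponential = exp(-t),
    gamma_n1    = (1 + 2 * t) * exp(-2 * t),
    gamma_n2    = (1 + 3 * t + 4.5 * t^2) * exp(-3 * t),
    rayleigh    = exp(-(pi / 4) * t^2),
    loglogistic = {
      tt <- theta * pi / (shape * sin(pi / shape))  # renormalized threshold
      u_bar^shape / (u_bar^shape + tt^shape)
    },
    lognormal   = stats::pnorm((log(u_bar / theta) - shape^2 / 2) / shape)
  )
}

## d/d(u_bar) of exceedance_closed, closed form per family.
exceedance_deriv_closed <- function(family, u_bar, theta, shape = NULL) {
  if (theta == 0) return(rep(0, length(u_bar)))
  t <- theta / u_bar
  switch(family,
    exponential = exp(-t) * theta / u_bar^2,
    gamma_n1    = 4 * t * exp(-2 * t) * theta / u_bar^2,
    gamma_n2    = 13.5 * t^2 * exp(-3 * t) * theta / u_bar^2,
    rayleigh    = (pi / 2) * t * exp(-(pi / 4) * t^2) * theta / u_bar^2,
    loglogistic = {
      tt <- theta * pi / (shape * sin(pi / shape))
      shape * tt^shape * u_bar^(shape - 1) / (u_bar^shape + tt^shape)^2
    },
    lognormal   = stats::dnorm((log(u_bar / theta) - shape^2 / 2) / shape) /
                    (shape * u_bar)
  )
}

#' Probability that a spine exceeds the formation threshold
#'
#' The conditional probability of spine formation `P` is the probability that
#' a potential spine volume drawn from `dist` exceeds the threshold `theta`.
#' Each family admits a closed form in terms of the mean volume; for the
#' log-logistic family this is a Hill function of the mean with renormalized
#' threshold `theta * (pi/beta) / sin(pi/beta)`.
#'
#' @inheritParams spine_pdf
#' @param theta Spine-formation threshold, um^3; nonnegative.
#' @return Probability in (0, 1].
#' @examples
#' d <- spine_distribution("exponential", 0.678)
#' spine_exceedance(d, 0.321)   # 0.623
#' @export
spine_exceedance <- function(dist, theta) {
  stopifnot(inherits(dist, "spine_distribution"))
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be nonnegative and finite", call. = FALSE)
  }
  exceedance_closed(dist$family, dist$mean_volume, theta, dist$shape)
}

#' Sensitivity of the exceedance probability to the mean spine volume
#'
#' Returns `dP/d(u_bar)` at the distribution's mean volume, holding `theta`
#' fixed. This derivative enters the stationarity conditions of every
#' optimization principle through the term `u_bar * dP/d(u_bar)`.
#'
#' @inheritParams spine_exceedance
#' @return Nonnegative derivative (per um^3).
#' @export
spine_exceedance_deriv <- function(dist, theta) {
  stopifnot(inherits(dist, "spine_distribution"))
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be nonnegative and finite", call. = FALSE)
  }
  exceedance_deriv_closed(dist$family, dist$mean_volume, theta, dist$shape)
}

#' Draw random spine volumes
#'
#' Sampling is by inverse CDF for the families with a closed-form quantile
#' function (exponential, Rayleigh, log-logistic) and by the standard
#' generators for the gamma and log-normal families. The seed is a mandatory
#' argument; the caller's random state is left untouched.
#'
#' @inheritParams spine_pdf
#' @param n Number of samples; positive integer.
#' @param seed Integer seed; required for reproducibility.
#' @return Numeric vector of `n` nonnegative spine volumes.
#' @export
spine_sample <- function(dist, n, seed) {
  stopifnot(inherits(dist, "spine_distribution"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be supplied as a single integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    switch(dist$family,
      exponential = -dist$mean_volume * log(stats::runif(n)),
      gamma_n1    = stats::rgamma(n, shape = 2, rate = dist$alpha),
      gamma_n2    = stats::rgamma(n, shape = 3, rate = dist$alpha),
      rayleigh    = dist$sigma_R * sqrt(-2 * log(stats::runif(n))),
      loglogistic = {
        p <- stats::runif(n)
        dist$alpha * (p / (1 - p))^(1 / dist$beta)
      },
      lognormal   = stats::rlnorm(n, meanlog = dist$mu, sdlog = dist$sigma)
    )
  })
}
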