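#' Physical coupling constants of the astrocyte/capillary model
#'
#' Astrocytes are modelled as minimal spanning trees over the spines they
#' serve: the total process length of one astrocyte connecting `N_s` spines
#' inside a domain of volume `V` is `L = b * N_s^(2/3) * V^(1/3)` with the
#' universal transport prefactor `b = (3/(4*pi))^(1/3)`. With cylindrical
#' processes of mean diameter `d_as`, the glia fraction becomes
#' `g = a * rho_s^(2/3)` where `a = (pi/4) * b * d_as^2` and `rho_s` is the
#' spine number density. The process diameter is estimated from measured
#' process volume and surface area via `d_as = 4 * V_pr / S_pr`.
#'
#' Defaults (`V_pr` = 350 um^3, `S_pr` = 1650 um^2) give `d_as` = 0.85 um and
#' `a` = 0.352 um^2 — the single fixed physical constant of the model.
#'
#' @param V_pr Total astrocyte process volume (soma excluded), um^3.
#' @param S_pr Total astrocyte process surface area, um^2.
#' @param d_as Optional override of the mean process diameter, um. When
#'   given, `V_pr`/`S_pr` are ignored.
#' @return A list with `d_as` (um), `b`, `a` (um^2), `V_pr`, `S_pr`.
#' @examples
#' coupling_constants()$a   # 0.352
#' @export
coupling_constants <- function(V_pr = 350, S_pr = 1650, d_as = NULL) {
  if (is.null(d_as)) {
    if (!is.numeric(V_pr) || !is.numeric(S_pr) || V_pr <= 0 || S_pr <= 0) {
      stop("`V_pr` and `S_pr` must be positive", call. = FALSE)
    }
    d_as <- 4 * V_pr / S_pr
  } else {
    if (!is.numeric(d_as) || d_as <= 0) {
      stop("`d_as` must be positive", call. = FALSE)
    }
    V_pr <- NA_real_
    S_pr <- NA_real_
  }
  b <- (3 / (4 * pi))^(1 / 3)
  list(d_as = d_as, b = b, a = (pi / 4) * b * d_as^2, V_pr = V_pr, S_pr = S_pr)
}

## Default astrocyte coupling constant a (um^2), d_as = 0.85 um.
cortex_a <- function() {
  (pi / 4) * (3 / (4 * pi))^(1 / 3) * 0.85^2
}

#' Spine volume fraction from geometric probability
#'
#' A spine occupies a location when an axon and a dendrite are both present
#' there (probability `x * y` under geometric probability, where the volume
#' fractions double as occurrence probabilities) and the potential spine
#' exceeds the formation threshold (probability `P`). Hence `s = P * x * y`.
#'
#' @param x,y Axon and dendrite volume fractions, in \[0, 1\].
#' @param P Conditional probability of spine formation, in \[0, 1\].
#' @return Spine volume fraction `s`.
#' @export
spine_fraction <- function(x, y, P) {
  if (any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("`x` and `y` must lie in [0, 1]", call. = FALSE)
  }
  if (any(P < 0 | P > 1)) stop("`P` must lie in [0, 1]", call. = FALSE)
  P * x * y
}

#' Glia/astrocyte volume fraction from the minimal-tree coupling
#'
#' `g = a * (s / u_bar)^(2/3)`: the ratio `s / u_bar` is the spine number
#' density `rho_s` (per um^3), and the glia fraction follows from the
#' minimal-spanning-tree scaling of astrocyte process length over its
#' spine targets.
#'
#' @param s Spine volume fraction, nonnegative.
#' @param u_bar Mean spine volume, um^3; positive.
#' @param a Astrocyte coupling constant, um^2.
#' @return Glia/astrocyte volume fraction `g`.
#' @examples
#' glia_fraction(0.098, 0.678)   # 0.097
#' @export
glia_fraction <- function(s, u_bar, a = cortex_a()) {
  if (any(s < 0)) stop("`s` must be nonnegative", call. = FALSE)
  if (any(u_bar <= 0)) stop("`u_bar` must be positive", call. = FALSE)
  a * (s / u_bar)^(2 / 3)
}

#' Capillary volume fraction as a glia-spine product law
#'
#' Capillaries cluster where astrocytes and spines are both dense, so the
#' probability of finding a capillary — its volume fraction — is the product
#' `c = g * s`. When `g` comes from [glia_fraction()], this is identical to
#' `c = a * s^(5/3) / u_bar^(2/3)`, implying the strong nonlinearity
#' `c ~ g^(5/2)`.
#'
#' @param g Glia/astrocyte volume fraction, in \[0, 1\].
#' @param s Spine volume fraction, in \[0, 1\].
#' @return Capillary volume fraction `c`.
#' @export
capillary_fraction <- function(g, s) {
  if (any(g < 0 | g > 1) || any(s < 0 | s > 1)) {
    stop("`g` and `s` must lie in [0, 1]", call. = FALSE)
  }
  g * s
}

#' Complete the five-component composition from (x, y, u_bar)
#'
#' Chains the coupling laws: `s = P(u_bar; theta) * x * y`,
#' `g = a * (s/u_bar)^(2/3)`, `c = g * s`, and reports the normalization
#' residual `x + y + s + g + c - 1`. The residual is returned, not forced to
#' zero: only optimal compositions satisfy the constraint.
#'
#' @param x,y Axon and dendrite volume fractions, in (0, 1).
#' @param u_bar Mean spine volume, um^3.
#' @param dist A [spine_distribution()] family name or object; when an
#'   object, its family and shape are used and the mean is taken from
#'   `u_bar`.
#' @param theta Spine-formation threshold, um^3.
#' @param shape Shape parameter when `dist` is given as a family name.
#' @param a Astrocyte coupling constant, um^2.
#' @return A list of class `"composition_fractions"` with `fractions` (named
#'   vector: axons, dendrites, spines, glia, capillaries), `P`, `rho_s`
#'   (spine density, per um^3), `u_bar` and `residual`.
#' @examples
#' comp <- complete_composition(0.397, 0.397, 0.678, "exponential", 0.321)
#' round(comp$fractions, 3)
#' @export
complete_composition <- function(x, y, u_bar, dist, theta, shape = NULL,
                                 a = cortex_a()) {
  if (inherits(dist, "spine_distribution")) {
    family <- dist$family
    shape <- dist$shape
  } else {
    family <- match.arg(dist, spine_families())
    if (family %in% c("loglogistic", "lognormal")) {
      spine_distribution(family, u_bar, shape)  # validates shape
    }
  }
  if (any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("`x` and `y` must lie in [0, 1]", call. = FALSE)
  }
  if (u_bar <= 0) stop("`u_bar` must be positive", call. = FALSE)
  if (theta < 0) stop("`theta` must be nonnegative", call. = FALSE)

  P <- exceedance_closed(family, u_bar, theta, shape)
  s <- P * x * y
  g <- if (s > 0) a * (s / u_bar)^(2 / 3) else 0
  cc <- g * s
  fr <- c(axons = x, dendrites = y, spines = s, glia = g, capillaries = cc)
  structure(list(fractions = fr, P = P, rho_s = s / u_bar, u_bar = u_bar,
                 residual = sum(fr) - 1),
            class = "composition_fractions")
}

#' @export
print.composition_fractions <- function(x, ...) {
  cat("<composition_fractions>\n")
  print(round(x$fractions, 4))
  cat(sprintf("P = %.4f, u_bar = %.4g um^3, sum - 1 = %.2e\n",
              x$P, x$u_bar, x$residual))
  invisible(x)
}
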