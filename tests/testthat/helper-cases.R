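## Shared fixtures: distribution parameter grids and published best-fit
## rows used for spot checks.

## One representative parametrization per family at a common mean volume.
family_cases <- function(u_bar = 0.7) {
  list(
    list(family = "exponential", shape = NULL),
    list(family = "gamma_n1",    shape = NULL),
    list(family = "gamma_n2",    shape = NULL),
    list(family = "rayleigh",    shape = NULL),
    list(family = "loglogistic", shape = 3),
    list(family = "lognormal",   shape = 0.5)
  )
}

## Spine-economy optimum, exponential family, theta = 0.321, gamma2 = 0.45
## (tabulated minimal-MD row: fractions to 3 d.p.).
row_spine_econ <- list(x = 0.397, y = 0.397, s = 0.098, g = 0.097,
                       c = 0.010, u_bar = 0.678, P = 0.623, gamma2 = 0.45,
                       md = 5.883)

## Wire-volume-minimization optimum, exponential family, theta = 0.321,
## r = 1.00 (tabulated minimal-MD row).
row_wire_sym <- list(x = 0.397, y = 0.397, s = 0.112, g = 0.085,
                     c = 0.010, u_bar = 0.936, P = 0.710, r = 1.00)

## Same principle at r = 0.96 (tabulated minimal-ED row).
row_wire_asym <- list(x = 0.423, y = 0.371, u_bar = 0.935, r = 0.96)

## Absolute-tolerance comparison (expect_equal's `tolerance` is relative,
## which is too strict for table values rounded to 3 d.p.).
expect_near <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
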