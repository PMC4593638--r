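## Components in canonical order.
cortex_components <- function() {
  c("axons", "dendrites", "spines", "glia", "capillaries")
}

## Round half away from zero (the tables' rounding convention; base round()
## rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-species cortical composition table
#'
#' Measured volume fractions (percent of gray-matter volume) of the five
#' major cortical components in six mammals, with stated uncertainties where
#' the sources give them, plus the gray-matter volume (both hemispheres) of
#' each species. Missing entries (`NA`) are components not measured in that
#' species; the mouse, rat and rabbit glia entries refer to unspecified glia
#' rather than astrocytes specifically.
#'
#' @return A data frame with columns `species`, `component`, `fraction_pct`,
#'   `sd_pct`, `volume_cm3` (long format, 30 rows).
#' @export
cortical_composition_table <- function() {
  path <- system.file("extdata", "cortical_composition.csv",
                      package = "cortexcomp", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$component <- factor(tab$component, levels = cortex_components())
  tab
}

#' Per-component species means of the composition table
#'
#' Unweighted means over the species with data for each component, in
#' percent. Reproduces the table's species-mean row (39.0, 34.0, 9.6, 11.7,
#' 1.4) at one decimal place.
#'
#' @param table A composition table as from [cortical_composition_table()].
#' @return Named numeric vector of five means (percent).
#' @export
species_means <- function(table = cortical_composition_table()) {
  out <- tapply(table$fraction_pct, table$component,
                function(v) mean(v, na.rm = TRUE))
  out <- as.numeric(out)
  names(out) <- cortex_components()
  out
}

#' Normalized empirical reference composition
#'
#' The empirical reference used by the model-data distance measures: the
#' per-component species means, rounded to one decimal place (the precision
#' at which the source tabulates them), rescaled so the five components sum
#' to 100%, rounded again to one decimal place, and returned as unitless
#' fractions (40.8, 35.5, 10.0, 12.2, 1.5)%. Working at the tabulated
#' precision matters: the Mahalanobis distance divides the capillary
#' deviation by sd = 0.001, so its third decimal is influential. The
#' per-component standard deviations are the tabulated values of the
#' normalized row (2.4, 5.5, 2.1, 1.2, 0.1)%, stored verbatim because their
#' derivation is not reconstructible from the raw table.
#'
#' @inheritParams species_means
#' @return A list of class `"empirical_reference"` with `mean` and `sd`,
#'   named numeric vectors of unitless fractions.
#' @examples
#' ref <- normalized_reference()
#' round(100 * ref$mean, 1)   # 40.8 35.5 10.0 12.2 1.5
#' @export
normalized_reference <- function(table = cortical_composition_table()) {
  m <- round_half_up(species_means(table), 1)
  m <- round_half_up(100 * m / sum(m), 1) / 100
  sd <- c(axons = 2.4, dendrites = 5.5, spines = 2.1, glia = 1.2,
          capillaries = 0.1) / 100
  structure(list(mean = m, sd = sd), class = "empirical_reference")
}

#' @export
print.empirical_reference <- function(x, ...) {
  cat("<empirical_reference> (unitless fractions)\n")
  print(rbind(mean = round(x$mean, 4), sd = x$sd))
  invisible(x)
}

#' The "powers of 1/3" compositional hierarchy
#'
#' Axons and dendrites each occupy about 1/3 of cortical volume, spines and
#' glia each about (1/3)^2, and capillaries about (1/3)^4. Returns the rule's
#' predicted fractions in percent at one decimal place. The rule is a
#' hierarchy, not a partition: the five values sum to 90.1%, not 100%.
#'
#' @return Named numeric vector (percent): 33.3, 33.3, 11.1, 11.1, 1.2.
#' @export
powers_rule <- function() {
  p <- c(1, 1, 2, 2, 4)
  out <- round_half_up(100 * (1 / 3)^p, 1)
  names(out) <- cortex_components()
  out
}

#' Allometric scaling of a component fraction with gray-matter volume
#'
#' Ordinary least squares of `log10(fraction %)` on `log10(volume cm^3)`
#' across species, dropping species without data for the component. A slope
#' near zero means the fraction is conserved across brain sizes.
#'
#' @param component One of `"axons"`, `"dendrites"`, `"spines"`, `"glia"`,
#'   `"capillaries"`.
#' @inheritParams species_means
#' @return A list with `component`, `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided t-test on the slope) and `n` (species used).
#' @examples
#' fit <- allometric_fit("glia")
#' round(c(fit$slope, fit$r_squared), 3)   # 0.031 0.180
#' @export
allometric_fit <- function(component, table = cortical_composition_table()) {
  component <- match.arg(component, cortex_components())
  sub <- table[table$component == component & !is.na(table$fraction_pct), ]
  if (nrow(sub) < 3) {
    stop(sprintf("need at least 3 species with data for '%s' (have %d)",
                 component, nrow(sub)), call. = FALSE)
  }
  fit <- stats::lm(log10(fraction_pct) ~ log10(volume_cm3), data = sub)
  sm <- summary(fit)
  list(component = component,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = nrow(sub))
}
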