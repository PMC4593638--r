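## Extract a named five-vector of fractions from the accepted input types.
as_fraction_vector <- function(fractions) {
  if (inherits(fractions, "principle_solution") ||
      inherits(fractions, "composition_fractions")) {
    fractions <- fractions$fractions
  }
  if (!is.numeric(fractions) || length(fractions) != 5L) {
    stop("`fractions` must be a numeric vector of the 5 component fractions",
         call. = FALSE)
  }
  unname(fractions)
}

#' Euclidean distance between a model composition and the data
#'
#' `ED = sqrt(sum_i (x_i - x_ex,i)^2)` over the five unitless component
#' fractions, against the empirical reference means.
#'
#' @param fractions Numeric 5-vector of fractions (axons, dendrites, spines,
#'   glia, capillaries), or a `"principle_solution"` /
#'   `"composition_fractions"` object.
#' @param reference An [normalized_reference()]-style list with `mean` (and
#'   for [mahalanobis_distance()] also `sd`), unitless fractions.
#' @return Nonnegative distance.
#' @examples
#' euclidean_distance(rep(0.2, 5))   # 0.343: a uniform composition is far
#' @export
euclidean_distance <- function(fractions, reference = normalized_reference()) {
  fr <- as_fraction_vector(fractions)
  m <- unname(reference$mean)
  if (length(m) != 5L) stop("reference must have 5 component means",
                            call. = FALSE)
  sqrt(sum((fr - m)^2))
}

#' Mahalanobis (variance-normalized) distance to the data
#'
#' `MD = sqrt(sum_i ((x_i - x_ex,i) / sd_ex,i)^2)`: each component deviation
#' is scaled by the empirical standard deviation of that component, so
#' tightly-determined components (capillaries, sd 0.001) weigh heavily.
#' With all `sd = 1`, MD reduces to ED.
#'
#' @inheritParams euclidean_distance
#' @return Nonnegative distance.
#' @export
mahalanobis_distance <- function(fractions,
                                 reference = normalized_reference()) {
  fr <- as_fraction_vector(fractions)
  m <- unname(reference$mean)
  sd <- unname(reference$sd)
  if (length(m) != 5L || length(sd) != 5L) {
    stop("reference must have 5 component means and sds", call. = FALSE)
  }
  if (any(sd <= 0)) stop("reference sds must all be positive", call. = FALSE)
  sqrt(sum(((fr - m) / sd)^2))
}
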