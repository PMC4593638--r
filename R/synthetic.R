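#' Generate a synthetic cross-species composition table
#'
#' Emulates the statistical structure of the empirical composition table:
#' per-component fractions follow a log-log allometric law in gray-matter
#' volume, `log10(fraction_pct) = intercept + slope * log10(volume) + noise`,
#' with Gaussian noise on the log10 scale (so fractions stay positive by
#' construction and the log-log OLS model of [allometric_fit()] is exactly
#' well-specified under the generator). The default mimics the real table's
#' scale: 6 species with volumes log-uniform over 0.1-600 cm^3 and the
#' powers-of-1/3-like true fractions.
#'
#' @param n_species Number of synthetic species.
#' @param fractions Named true fractions (unitless, at 1 cm^3) for the five
#'   components.
#' @param slopes Imposed allometric slope per component (recycled).
#' @param noise_sd Gaussian noise sd on `log10(fraction_pct)` (recycled).
#' @param log10_volume_range Range of `log10(volume cm^3)` to draw from.
#' @param seed Integer seed (mandatory; recorded in the output attributes).
#' @return A data frame in the same long schema as
#'   [cortical_composition_table()] (`sd_pct` is `NA`), with attributes
#'   `seed`, `slopes`, `noise_sd`.
#' @examples
#' tab <- synth_composition_table(slopes = 0, noise_sd = 0, seed = 1)
#' allometric_fit("axons", tab)$slope   # 0
#'
#' ## parameter recovery with an imposed positive slope (small base
#' ## fraction keeps the steep component inside (0, 100)%)
#' tab2 <- synth_composition_table(
#'   n_species = 20,
#'   fractions = c(axons = 0.35, dendrites = 0.34, spines = 0.02,
#'                 glia = 0.12, capillaries = 0.013),
#'   slopes = c(0, 0, 0.25, 0, 0), noise_sd = 0.02, seed = 7)
#' allometric_fit("spines", tab2)$slope   # close to 0.25
#' @export
synth_composition_table <- function(n_species = 6,
                                    fractions = c(axons = 0.35,
                                                  dendrites = 0.34,
                                                  spines = 0.10,
                                                  glia = 0.12,
                                                  capillaries = 0.013),
                                    slopes = 0, noise_sd = 0.02,
                                    log10_volume_range = c(log10(0.1),
                                                           log10(600)),
                                    seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_species < 2) stop("`n_species` must be >= 2", call. = FALSE)
  comps <- cortex_components()
  if (!all(comps %in% names(fractions))) {
    stop("`fractions` must be named with all five components", call. = FALSE)
  }
  slopes <- rep_len(slopes, 5)
  noise_sd <- rep_len(noise_sd, 5)
  tab <- withr::with_seed(as.integer(seed), {
    lv <- sort(stats::runif(n_species, log10_volume_range[1],
                            log10_volume_range[2]))
    rows <- lapply(seq_along(comps), function(k) {
      lf <- log10(100 * fractions[comps[k]]) + slopes[k] * lv +
        stats::rnorm(n_species, 0, noise_sd[k])
      data.frame(species = sprintf("synth%02d", seq_len(n_species)),
                 component = comps[k], fraction_pct = 10^lf,
                 sd_pct = NA_real_, volume_cm3 = 10^lv)
    })
    do.call(rbind, rows)
  })
  if (any(tab$fraction_pct <= 0) || any(tab$fraction_pct >= 100)) {
    bad <- tab[tab$fraction_pct <= 0 | tab$fraction_pct >= 100, ]
    stop(sprintf(paste0("generator parameters produce fractions outside ",
                        "(0, 100)%%: e.g. %s %s = %.3g%%"),
                 bad$species[1], bad$component[1], bad$fraction_pct[1]),
         call. = FALSE)
  }
  tab$component <- factor(tab$component, levels = comps)
  rownames(tab) <- NULL
  attr(tab, "seed") <- as.integer(seed)
  attr(tab, "slopes") <- slopes
  attr(tab, "noise_sd") <- noise_sd
  tab
}

#' Monte-Carlo spine-volume samples with empirical summaries
#'
#' Draws `n` spine volumes from the chosen family calibrated to mean
#' `u_bar`, and summarizes them against the closed forms: the empirical
#' mean (vs `u_bar`) and the empirical fraction of samples above the
#' threshold `theta` (vs the closed-form exceedance probability).
#'
#' @param family Distribution family (see [spine_distribution()]).
#' @param u_bar Mean spine volume, um^3.
#' @param shape Shape parameter where the family needs one.
#' @param theta Spine-formation threshold, um^3.
#' @param n Number of samples.
#' @param seed Integer seed (mandatory).
#' @return A list with `samples`, `empirical_mean`, `empirical_exceedance`,
#'   `closed_form_exceedance`, `theta`, `n`, `seed`.
#' @export
synth_spine_samples <- function(family, u_bar, shape = NULL, theta, n,
                                seed) {
  dist <- spine_distribution(family, u_bar, shape)
  u <- spine_sample(dist, n, seed)
  list(samples = u,
       empirical_mean = mean(u),
       empirical_exceedance = mean(u > theta),
       closed_form_exceedance = spine_exceedance(dist, theta),
       theta = theta, n = n, seed = as.integer(seed))
}
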