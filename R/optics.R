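#' Optical properties of one medium
#'
#' Absorption and scattering coefficients are given in cm^-1 (the unit optical
#' coefficients of coral tissue are reported in); supply either the scattering
#' coefficient `mus` or the reduced scattering coefficient `musp` — the other
#' is derived through `musp = mus * (1 - g)`.
#'
#' @param mua Absorption coefficient, cm^-1 (>= 0).
#' @param mus Scattering coefficient, cm^-1 (>= 0); exactly one of `mus`,
#'   `musp` must be given.
#' @param musp Reduced scattering coefficient, cm^-1.
#' @param g Scattering anisotropy (mean cosine), in (-1, 1).
#' @return A `medium_optics` list with fields `mua`, `mus`, `musp`, `g`.
#' @export
medium_optics <- function(mua, mus = NULL, musp = NULL, g = 0.9) {
  if (is.null(mus) == is.null(musp)) {
    abort("supply exactly one of `mus` or `musp`")
  }
  stopifnot(mua >= 0, g > -1, g < 1)
  if (is.null(mus)) {
    stopifnot(musp >= 0)
    mus <- musp / (1 - g)
  } else {
    stopifnot(mus >= 0)
    musp <- mus * (1 - g)
  }
  structure(list(mua = mua, mus = mus, musp = musp, g = g),
            class = "medium_optics")
}

#' Optical property set for the three media
#'
#' Bundles water, tissue and skeleton optics for transport. The default is the
#' baseline bio-optical scenario: high skeletal scattering (reduced scattering
#' 15 cm^-1), intermediate tissue scattering (10 cm^-1), moderate tissue
#' pigmentation (absorption 1.18 cm^-1), low skeletal absorption (0.01 cm^-1),
#' anisotropy 0.9 in tissue and skeleton. Water optics are nearly transparent
#' placeholders (assumed, not measured).
#'
#' @param water,tissue,skeleton [medium_optics()] objects.
#' @return An `optical_properties` object.
#' @export
optical_properties <- function(
    water = medium_optics(mua = 0.001, mus = 0.1, g = 0.9),
    tissue = medium_optics(mua = 1.18, musp = 10, g = 0.9),
    skeleton = medium_optics(mua = 0.01, musp = 15, g = 0.9)) {
  stopifnot(inherits(water, "medium_optics"), inherits(tissue, "medium_optics"),
            inherits(skeleton, "medium_optics"))
  structure(list(water = water, tissue = tissue, skeleton = skeleton),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("<optical_properties> (cm^-1)\n")
  for (m in c("water", "tissue", "skeleton")) {
    cat(sprintf("  %-8s mua %-8.4g mus %-8.4g musp %-8.4g g %.3g\n",
                m, x[[m]]$mua, x[[m]]$mus, x[[m]]$musp, x[[m]]$g))
  }
  invisible(x)
}

#' Bio-optical scenario ledger
#'
#' Returns the optical property set of one of the six scenarios varied one
#' property at a time from the default: 1 default; 2 reduced pigmentation
#' (tissue absorption halved); 3 enhanced pigmentation (tissue absorption
#' x10); 4 tissue reduced scattering lowered x10; 5 high skeletal absorption
#' (1.0 cm^-1, an assumed value — no measured figure exists); 6 skeletal
#' reduced scattering lowered x5.
#'
#' @param scenario Integer 1-6.
#' @param base The scenario-1 [optical_properties()] to perturb.
#' @param high_skeleton_mua Absorption used by scenario 5, cm^-1.
#' @return An `optical_properties` object.
#' @export
optics_for_scenario <- function(scenario, base = optical_properties(),
                                high_skeleton_mua = 1.0) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:6) abort("optical scenario must be an integer in 1..6")
  t <- base$tissue; s <- base$skeleton
  switch(scenario,
    base,
    optical_properties(base$water,
                       medium_optics(mua = t$mua / 2, musp = t$musp, g = t$g), s),
    optical_properties(base$water,
                       medium_optics(mua = t$mua * 10, musp = t$musp, g = t$g), s),
    optical_properties(base$water,
                       medium_optics(mua = t$mua, musp = t$musp / 10, g = t$g), s),
    optical_properties(base$water, t,
                       medium_optics(mua = high_skeleton_mua, musp = s$musp, g = s$g)),
    optical_properties(base$water, t,
                       medium_optics(mua = s$mua, musp = s$musp / 5, g = s$g))
  )
}

#' Scenario descriptions
#'
#' @return A tibble with `optical_scenario` (1-6) and `description`.
#' @export
optical_scenarios <- function() {
  tibble::tibble(
    optical_scenario = 1:6,
    description = c(
      "default optics",
      "reduced pigmentation (tissue mua x0.5)",
      "enhanced pigmentation (tissue mua x10)",
      "low tissue scattering (tissue musp /10)",
      "high skeletal absorption",
      "low skeletal scattering (skeleton musp /5)"
    )
  )
}

#' Photon transport configuration
#'
#' @param n_photons Photon packets to launch (>= 1000).
#' @param seed Integer seed; every photon derives its own counter-based random
#'   stream from `(seed, photon index)`, so runs are order-independent and
#'   exactly reproducible.
#' @param lateral_boundary `"periodic"` (default; exploits tile periodicity)
#'   or `"absorbing"`.
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played (0 disables roulette).
#' @param roulette_survival Survival probability of the roulette.
#' @param estimator `"path_length"` (track-length fluence estimator; valid in
#'   non-absorbing media) or `"absorbed_weight"` (deposition-based; only
#'   defined where absorption is non-zero, falls back to the track-length
#'   value elsewhere).
#' @return A `transport_config` object.
#' @export
transport_config <- function(n_photons = 1e6, seed = 1L,
                             lateral_boundary = c("periodic", "absorbing"),
                             roulette_threshold = 1e-4,
                             roulette_survival = 0.1,
                             estimator = c("path_length", "absorbed_weight")) {
  lateral_boundary <- match.arg(lateral_boundary)
  estimator <- match.arg(estimator)
  if (n_photons < 1e3) abort("n_photons must be at least 1000")
  stopifnot(roulette_threshold >= 0, roulette_threshold < 1,
            roulette_survival > 0, roulette_survival < 1)
  structure(list(n_photons = as.numeric(n_photons), seed = as.numeric(seed),
                 lateral_boundary = lateral_boundary,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 estimator = estimator),
            class = "transport_config")
}
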