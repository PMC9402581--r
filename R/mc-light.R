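#' Sample the Henyey-Greenstein phase function
#'
#' Inverse-CDF sampling of the scattering deflection cosine for anisotropy
#' `g`. For `g = 0` the distribution is isotropic and `cos(theta) = 2u - 1`;
#' otherwise
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g u))^2) / (2 g)`,
#' which maps `u = 0` to `-1` and `u = 1` to `+1` exactly.
#'
#' @param g Anisotropy in (-1, 1).
#' @param u Uniform deviates in `[0, 1]` (vectorized).
#' @return Deflection cosines in `[-1, 1]`.
#' @export
sample_hg <- function(g, u) {
  stopifnot(g > -1, g < 1, all(u >= 0), all(u <= 1))
  if (abs(g) < 1e-12) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  ct <- (1 + g^2 - f^2) / (2 * g)
  ct <- pmin(1, pmax(-1, ct))
  # the inverse CDF maps the endpoints exactly; remove floating-point residue
  ct[u == 0] <- -1
  ct[u == 1] <- 1
  ct
}

#' Run voxel Monte Carlo photon transport
#'
#' Launches collimated photon packets uniformly over the top face of the
#' volume travelling straight down, propagates them with exponentially sampled
#' free paths against the local interaction coefficient (exact voxel-by-voxel
#' media crossings), deposits the fraction `mua/(mua+mus)` of the packet
#' weight at each interaction and scatters the remainder through a
#' Henyey-Greenstein deflection with uniform azimuth. Packet weight below the
#' roulette threshold plays Russian roulette. The returned fluence is relative:
#' a non-interacting medium yields `phi = 1` throughout the beam.
#'
#' @param volume A [label_volume()].
#' @param optics An [optical_properties()] set (cm^-1; converted internally).
#' @param config A [transport_config()].
#' @return A `fluence_volume`: `phi` (3D array of relative fluence rate),
#'   escape fractions `escaped_top`/`escaped_other`, per-medium `absorbed`
#'   fractions, `roulette_net` (weight injected/removed by roulette so the
#'   energy ledger closes exactly), and metadata.
#' @export
run_mc <- function(volume, optics, config = transport_config()) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(optics, "optical_properties"),
            inherits(config, "transport_config"))
  d <- dim(volume$labels)
  dx <- volume$resolution
  media <- c("water", "tissue", "skeleton")
  mua <- vapply(media, function(m) optics[[m]]$mua, 1) / 10  # cm^-1 -> mm^-1
  mus <- vapply(media, function(m) optics[[m]]$mus, 1) / 10
  g <- vapply(media, function(m) optics[[m]]$g, 1)

  res <- .mc_transport_cpp(
    labels = as.integer(volume$labels), dims = as.integer(d), dx = dx,
    mua = mua, mus = mus, g = g,
    n_photons = config$n_photons, seed = config$seed,
    periodic = identical(config$lateral_boundary, "periodic"),
    roulette_threshold = config$roulette_threshold,
    roulette_survival = config$roulette_survival,
    tally_absorbed = identical(config$estimator, "absorbed_weight"))

  norm <- d[1] * d[2] / (dx * config$n_photons)
  phi <- array(res$track * norm, dim = d)
  if (identical(config$estimator, "absorbed_weight")) {
    mua_vox <- mua[as.integer(volume$labels) + 1L]
    adep <- res$absorbed_voxel * (d[1] * d[2]) / (dx * config$n_photons)
    ok <- mua_vox > 0
    phi_abs <- as.numeric(phi)
    phi_abs[ok] <- adep[ok] / mua_vox[ok]
    phi <- array(phi_abs, dim = d)
  }

  structure(list(
    phi = phi,
    escaped_top = res$escaped_top,
    escaped_other = res$escaped_other,
    absorbed = setNames(as.numeric(res$absorbed_by_label), media),
    roulette_net = res$roulette_net,
    lost = res$lost,
    resolution = dx,
    optics = optics,
    config = config
  ), class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<fluence_volume> %d x %d x %d @ %.4g mm, %g photons (seed %g)\n",
              d[1], d[2], d[3], x$resolution, x$config$n_photons, x$config$seed))
  cat(sprintf("  escaped: top %.4f other %.4f | absorbed: %s | roulette net %.2e\n",
              x$escaped_top, x$escaped_other,
              paste(sprintf("%s %.4f", names(x$absorbed), x$absorbed),
                    collapse = ", "),
              x$roulette_net))
  invisible(x)
}

#' Energy ledger of a transport run
#'
#' @param fluence A `fluence_volume`.
#' @return A one-row tibble with the escape/absorption fractions, the roulette
#'   net term, and `closure` = their sum, which equals 1 (the launched weight)
#'   up to floating-point accumulation.
#' @export
energy_ledger <- function(fluence) {
  stopifnot(inherits(fluence, "fluence_volume"))
  tot_abs <- sum(fluence$absorbed)
  tibble::tibble(
    escaped_top = fluence$escaped_top,
    escaped_other = fluence$escaped_other,
    absorbed_total = tot_abs,
    roulette_net = fluence$roulette_net,
    lost = fluence$lost,
    closure = fluence$escaped_top + fluence$escaped_other + tot_abs +
      fluence$roulette_net + fluence$lost
  )
}

#' Relative fluence rate just above the tissue surface
#'
#' For each lateral position, the relative fluence in the first water voxel
#' above the local tissue-water interface — the escaping-flux enhancement map.
#'
#' @param fluence A `fluence_volume` from [run_mc()].
#' @param volume The [label_volume()] the run used.
#' @return A numeric matrix with the lateral grid dimensions; `NA` where a
#'   column has no tissue or no water above it.
#' @export
surface_escape_profile <- function(fluence, volume) {
  stopifnot(inherits(fluence, "fluence_volume"), inherits(volume, "label_volume"))
  if (!identical(dim(fluence$phi), dim(volume$labels))) {
    abort("fluence and label volume grids do not match")
  }
  labels <- volume$labels
  d <- dim(labels)
  out <- matrix(NA_real_, d[1], d[2])
  top <- apply(labels == LABEL_TISSUE, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  ok <- !is.na(top) & top > 1L
  idx <- which(ok)
  ij <- arrayInd(idx, d[1:2])
  above <- top[idx] - 1L
  water_ok <- labels[cbind(ij, above)] == LABEL_WATER
  sel <- idx[water_ok]
  out[sel] <- fluence$phi[cbind(ij[water_ok, , drop = FALSE], above[water_ok])]
  out
}

#' Mean relative fluence rate over tissue voxels
#'
#' @param fluence A `fluence_volume`.
#' @param volume The matching [label_volume()].
#' @return A single number.
#' @export
mean_tissue_phi <- function(fluence, volume) {
  stopifnot(identical(dim(fluence$phi), dim(volume$labels)))
  mean(fluence$phi[volume$labels == LABEL_TISSUE])
}
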