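#' Voxel label volume (water / tissue / skeleton)
#'
#' Lightweight container for a 3D voxel grid at fixed isotropic resolution.
#' Labels are `0` (seawater), `1` (tissue), `2` (skeleton). The z axis points
#' downward into the coral: slice `z = 1` is the top of the water column.
#' Voxels are classified by their centers; all interfaces are half-open
#' `[lo, hi)` in mm.
#'
#' @param labels Integer 3D array with values in `{0, 1, 2}`.
#' @param resolution Voxel edge length, mm.
#' @param meta Named list of provenance (z planes, source params, ...).
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, resolution, meta = list()) {
  stopifnot(is.array(labels), length(dim(labels)) == 3, resolution > 0)
  vals <- unique(as.integer(labels))
  if (!all(vals %in% 0:2)) abort("labels must be 0 (water), 1 (tissue) or 2 (skeleton)")
  structure(list(labels = labels, resolution = resolution, meta = meta),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  counts <- tabulate(as.integer(x$labels) + 1L, nbins = 3L)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.4g mm (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$resolution,
              d[1] * x$resolution, d[2] * x$resolution, d[3] * x$resolution))
  cat(sprintf("  water %.1f%% | tissue %.1f%% | skeleton %.1f%%\n",
              100 * counts[1] / sum(counts), 100 * counts[2] / sum(counts),
              100 * counts[3] / sum(counts)))
  invisible(x)
}

LABEL_WATER <- 0L
LABEL_TISSUE <- 1L
LABEL_SKELETON <- 2L

#' Build a voxelized corallite-lattice tile
#'
#' Constructs the representative corallite-scale architecture of a morphotype:
#' a square lattice of corallites at pitch `CSC`, each a cylindrical calyx of
#' diameter `CD` recessed `TH` below the coenosteum plane, with `n_septa`
#' radial septal ridges and a central columella; the coenosteum between
#' corallites is studded with conical spines (pitch `SS`, height `SPL`, basal
#' width `SPW`). Contracted tissue drapes the coenosteum up to the spine tips
#' and fills the calyx cavity up to `polyp_recess * TH` below the rim. Water
#' lies above, a solid skeleton slab below. The tile is laterally periodic by
#' construction (spine pitch is snapped to divide the corallite pitch).
#'
#' @param params A [morphotype_params()] blueprint. If it carries the
#'   `conserve_tissue` attribute set by [knockout()] for the corallite
#'   knock-out, the tissue layer is thickened and trimmed so the tissue voxel
#'   count matches the unmodified tile.
#' @param resolution Voxel edge length, mm. Must be at most `CD / 10` so the
#'   calyx is resolved (checked only when `CD > 0`).
#' @param tile_corallites Corallites per tile side (default 2).
#' @param water_mm Water column thickness above the tissue surface, mm.
#' @param slab_mm Solid skeleton thickness below the deepest calyx floor, mm.
#'   The default (1 mm, about 1.5 transport mean free paths of the default
#'   skeleton optics) stands in for the thick aragonite branch interior of
#'   this imperforate species; the plane below it absorbs.
#' @return A [label_volume()].
#' @export
build_tile <- function(params, resolution = 0.02, tile_corallites = 2L,
                       water_mm = 0.3, slab_mm = 1.0) {
  stopifnot(inherits(params, "morphotype_params"))
  conserve_from <- attr(params, "conserve_tissue", exact = TRUE)
  if (!is.null(conserve_from)) {
    ref <- build_tile(conserve_from, resolution = resolution,
                      tile_corallites = tile_corallites,
                      water_mm = water_mm, slab_mm = slab_mm)
    target <- sum(ref$labels == LABEL_TISSUE)
    # thicken the draped layer enough to exceed the target, then trim exactly
    p2 <- params
    attr(p2, "conserve_tissue") <- NULL
    t0 <- tissue_thickness_of(p2)
    side <- tile_corallites * p2$CSC
    t_need <- max(t0, target * resolution^3 / side^2 + 2 * resolution)
    p2$tissue_thickness <- t_need
    vol <- build_tile(p2, resolution = resolution,
                      tile_corallites = tile_corallites,
                      water_mm = water_mm + max(0, t_need - t0), slab_mm = slab_mm)
    return(conserve_tissue_volume(vol, target))
  }

  dx <- resolution
  if (params$CD > 0 && dx > params$CD / 10 + 1e-12) {
    abort(sprintf("resolution %.4g mm too coarse: must be <= CD/10 = %.4g mm",
                  dx, params$CD / 10), class = "corallux_resolution_error")
  }
  k <- as.integer(tile_corallites)
  stopifnot(k >= 1)

  # snap the corallite pitch to a whole number of voxels so the lattice is
  # exactly periodic at voxel resolution (distortion < half a voxel)
  cell <- max(2L, as.integer(round(params$CSC / dx)))
  nx <- k * cell
  ny <- nx
  side_eff <- nx * dx
  pitch <- cell * dx

  t_tissue <- tissue_thickness_of(params)
  z_surface <- water_mm            # tissue top over the coenosteum
  z_coeno <- water_mm + t_tissue   # coenosteum skeleton plane
  z_floor <- z_coeno + params$TH   # calyx floor
  Lz <- z_floor + slab_mm
  nz <- max(2L, as.integer(ceiling(Lz / dx)))

  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dx
  # local coordinates within the corallite cell, centered on the corallite
  ux <- (xc %% pitch) - pitch / 2
  uy <- (yc %% pitch) - pitch / 2
  U <- matrix(ux, nx, ny)
  V <- matrix(uy, nx, ny, byrow = TRUE)
  Rcal <- sqrt(U^2 + V^2)

  in_calyx <- if (params$CD > 0) Rcal <= params$CD / 2 else matrix(FALSE, nx, ny)

  # septa: radial ridges from the theca wall inward by SL
  septa <- matrix(FALSE, nx, ny)
  if (params$CD > 0 && params$n_septa > 0 && params$SL > 0 && params$SW > 0) {
    ang <- 2 * pi * (seq_len(params$n_septa) - 1) / params$n_septa
    r_in <- max(0, params$CD / 2 - params$SL)
    for (th in ang) {
      perp <- abs(-U * sin(th) + V * cos(th))
      along <- U * cos(th) + V * sin(th)
      septa <- septa | (perp <= params$SW / 2 & along > 0 &
                          Rcal >= r_in & Rcal <= params$CD / 2)
    }
  }
  columella <- if (params$CD > 0 && params$columella_diameter > 0 && params$CH > 0) {
    Rcal <= params$columella_diameter / 2
  } else matrix(FALSE, nx, ny)

  # coenosteal spine lattice, pitch snapped so the pattern tiles each cell
  has_spines <- params$SPL > 0 && params$SPW > 0 && params$SS > 0
  if (has_spines) {
    m <- max(1L, as.integer(round(pitch / params$SS)))
    ss <- pitch / m
    sx <- (xc %% ss) - ss / 2
    sy <- (yc %% ss) - ss / 2
    Rsp <- sqrt(matrix(sx, nx, ny)^2 + matrix(sy, nx, ny, byrow = TRUE)^2)
  }

  fill_top <- z_coeno + params$polyp_recess * params$TH
  col_top <- z_floor - params$CH

  labels <- array(LABEL_WATER, dim = c(nx, ny, nz))
  zc <- (seq_len(nz) - 0.5) * dx
  for (j in seq_len(nz)) {
    z <- zc[j]
    if (z >= z_coeno) {
      slice <- matrix(LABEL_SKELETON, nx, ny)
      if (z < z_floor) {
        # inside the calyx recess
        cav <- in_calyx
        slice[cav] <- if (z >= fill_top) LABEL_TISSUE else LABEL_WATER
        if (any(septa)) slice[septa & cav] <- LABEL_SKELETON
        if (z >= col_top && any(columella)) slice[columella & cav] <- LABEL_SKELETON
      }
    } else {
      slice <- matrix(LABEL_WATER, nx, ny)
      h <- z_coeno - z  # height above the coenosteum plane
      if (h <= t_tissue && t_tissue > 0) slice[!in_calyx] <- LABEL_TISSUE
      if (has_spines && h <= params$SPL) {
        r_cone <- (params$SPW / 2) * (1 - h / params$SPL)
        slice[Rsp <= r_cone & !in_calyx] <- LABEL_SKELETON
      }
    }
    labels[, , j] <- slice
  }

  label_volume(labels, dx, meta = list(
    params = params, tile_corallites = k, pitch = pitch,
    z_surface = z_surface, z_coeno = z_coeno, z_floor = z_floor,
    water_mm = water_mm, slab_mm = slab_mm,
    planar_area = side_eff^2
  ))
}

tissue_thickness_of <- function(params) {
  if (identical(params$tissue_thickness, "max_spine_length")) params$SPL
  else params$tissue_thickness
}

# Adjust the tissue voxel count to `target` by adding/removing voxels at the
# tissue-water surface, lowest columns first, in fixed raster order —
# deterministic and exact.
conserve_tissue_volume <- function(vol, target) {
  labels <- vol$labels
  d <- dim(labels)
  count <- sum(labels == LABEL_TISSUE)
  guard <- 0L
  while (count != target) {
    guard <- guard + 1L
    if (guard > 10000L) abort("tissue volume adjustment failed to converge")
    # per-column index of the topmost tissue voxel (0 if none)
    top <- apply(labels == LABEL_TISSUE, c(1, 2), function(col) {
      w <- which(col)
      if (length(w)) w[1] else 0L
    })
    if (count < target) {
      # grow: water voxel directly above an existing tissue top
      cand <- which(top > 1L)
      cand <- cand[labels[cbind(arrayInd(cand, d[1:2]), top[cand] - 1L)] == LABEL_WATER]
      if (!length(cand)) abort("no room to grow tissue layer")
      ord <- cand[order(-top[cand], cand)]   # deepest surface first -> flattens
      take <- head(ord, target - count)
      labels[cbind(arrayInd(take, d[1:2]), top[take] - 1L)] <- LABEL_TISSUE
      count <- count + length(take)
    } else {
      cand <- which(top > 0L)
      ord <- cand[order(top[cand], cand)]    # shallowest surface first
      take <- head(ord, count - target)
      labels[cbind(arrayInd(take, d[1:2]), top[take])] <- LABEL_WATER
      count <- count - length(take)
    }
  }
  vol$labels <- labels
  vol$meta$tissue_conserved_to <- target
  vol
}

#' Remove a skeletal feature from a morphotype blueprint
#'
#' Implements the knock-out scenarios: `"spines"` removes the coenosteal
#' spines (the draped tissue keeps its original thickness), `"columella"`
#' removes the columella, and `"corallite"` removes the calyx entirely,
#' flagging the returned blueprint so that [build_tile()] redistributes the
#' displaced polyp tissue over the coenosteum, conserving total tissue volume.
#'
#' @param params A [morphotype_params()] object.
#' @param feature One of `"corallite"`, `"columella"`, `"spines"`.
#' @return A modified `morphotype_params` object.
#' @export
knockout <- function(params, feature = c("corallite", "columella", "spines")) {
  stopifnot(inherits(params, "morphotype_params"))
  feature <- match.arg(feature)
  present <- switch(feature,
    corallite = params$CD > 0,
    columella = params$CH > 0 && params$columella_diameter > 0,
    spines = params$SPL > 0
  )
  if (!present) abort(sprintf("feature '%s' is not present in the blueprint", feature))
  out <- unclass(params)
  if (feature == "spines") {
    if (identical(out$tissue_thickness, "max_spine_length")) {
      out$tissue_thickness <- out$SPL
    }
    out$SPL <- 0
    out$SPW <- 0
  } else if (feature == "columella") {
    out$CH <- 0
  } else {
    out$CD <- 0; out$TH <- 0; out$SL <- 0; out$SW <- 0; out$CH <- 0
    out$CSM <- min(out$CSM, out$CSC)
  }
  res <- morphotype_params(CD = out$CD, TH = out$TH, SL = out$SL, SW = out$SW,
                           CH = out$CH, SS = out$SS, SPL = out$SPL,
                           SPW = out$SPW, CSC = out$CSC, CSM = out$CSM,
                           n_septa = out$n_septa,
                           tissue_thickness = out$tissue_thickness,
                           polyp_recess = out$polyp_recess,
                           columella_diameter = out$columella_diameter,
                           label = paste0(params$label, "-", feature))
  if (feature == "corallite") attr(res, "conserve_tissue") <- params
  res
}

#' Surface metrics of a label volume
#'
#' Computes the tissue-water interface area by triangulating the tissue
#' surface height field (the top face of the topmost tissue voxel in each
#' lateral column, with periodic lateral wrap), the surface rugosity as the
#' ratio of that real area to the planar tile area (>= 1, exactly 1 for a flat
#' slab), the tissue volume, and the apparent porosity of the skeleton slab
#' (water fraction below the deepest calyx floor).
#'
#' @param volume A [label_volume()].
#' @return A one-row tibble: `surface_area` (mm^2), `rugosity`,
#'   `tissue_volume` (mm^3), `porosity`.
#' @export
surface_metrics <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  labels <- volume$labels
  dx <- volume$resolution
  d <- dim(labels)
  tis <- labels == LABEL_TISSUE
  n_tissue <- sum(tis)
  if (n_tissue == 0) abort("volume contains no tissue voxels")

  # height of the tissue surface (top face of topmost tissue voxel), mm
  top <- apply(tis, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  if (anyNA(top)) {
    # columns without tissue (possible after aggressive knock-outs): use the
    # topmost non-water voxel so the surface stays defined
    solid <- apply(labels != LABEL_WATER, c(1, 2), function(col) {
      w <- which(col)
      if (length(w)) w[1] else d[3] + 1L
    })
    top[is.na(top)] <- solid[is.na(top)]
  }
  h <- (top - 1L) * dx  # z of the surface, mm (depth downward)

  area <- heightfield_area(h, dx)
  planar <- d[1] * d[2] * dx^2

  porosity <- NA_real_
  zf <- volume$meta$z_floor
  if (!is.null(zf)) {
    j0 <- min(d[3], max(1L, as.integer(ceiling(zf / dx)) + 1L))
    if (j0 <= d[3]) {
      slab <- labels[, , j0:d[3], drop = FALSE]
      porosity <- sum(slab == LABEL_WATER) / length(slab)
    }
  }

  tibble::tibble(
    surface_area = area,
    rugosity = area / planar,
    tissue_volume = n_tissue * dx^3,
    porosity = porosity
  )
}

# triangulated area of a periodic height field sampled at voxel centers
heightfield_area <- function(h, dx) {
  nx <- nrow(h); ny <- ncol(h)
  i2 <- c(2:nx, 1L)
  j2 <- c(2:ny, 1L)
  h00 <- h
  h10 <- h[i2, , drop = FALSE]
  h01 <- h[, j2, drop = FALSE]
  h11 <- h[i2, j2, drop = FALSE]
  # two triangles per cell: (00,10,11) and (00,11,01); cross-product areas
  tri_area <- function(dz1x, dz1y, dz1, dz2x, dz2y, dz2) {
    cx <- dz1y * dz2 - dz1 * dz2y
    cy <- dz1 * dz2x - dz1x * dz2
    cz <- dz1x * dz2y - dz1y * dz2x
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  a1 <- tri_area(dx, 0, h10 - h00, dx, dx, h11 - h00)
  a2 <- tri_area(dx, dx, h11 - h00, 0, dx, h01 - h00)
  sum(a1) + sum(a2)
}

#' Inject stochastic pores into the skeleton slab
#'
#' Converts a random fraction of skeleton voxels below the calyx floor to
#' water so the apparent-porosity metric can be exercised. Transport treats
#' the skeleton as optically homogeneous regardless; this is a reporting aid,
#' not a micro-structural model.
#'
#' @param volume A [label_volume()] built by [build_tile()].
#' @param porosity Target pore fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The modified `label_volume`.
#' @export
add_skeletal_pores <- function(volume, porosity, seed = 1L) {
  stopifnot(inherits(volume, "label_volume"), porosity >= 0, porosity < 1)
  zf <- volume$meta$z_floor
  if (is.null(zf)) abort("volume lacks z_floor metadata; build it with build_tile()")
  d <- dim(volume$labels)
  dx <- volume$resolution
  j0 <- max(1L, as.integer(ceiling(zf / dx)) + 1L)
  idx <- which(volume$labels == LABEL_SKELETON &
                 slice.index(volume$labels, 3) >= j0)
  n_slab <- d[1] * d[2] * (d[3] - j0 + 1L)
  n_water0 <- n_slab - length(idx)  # pre-existing void in the slab region
  n_pore <- max(0L, round(porosity * n_slab) - n_water0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  pores <- sample(idx, size = min(length(idx), n_pore))
  volume$labels[pores] <- LABEL_WATER
  volume
}
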