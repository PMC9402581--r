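# shared fixtures and independent oracles ------------------------------------

# a homogeneous slab of one medium (default tissue) for transport checks
make_slab <- function(nx = 40, ny = 40, nz = 60, dx = 0.02, label = 1L) {
  label_volume(array(as.integer(label), dim = c(nx, ny, nz)), dx)
}

# optics with a single non-trivial medium; all three media share the values so
# the slab is homogeneous regardless of label
uniform_optics <- function(mua, mus, g = 0) {
  m <- medium_optics(mua = mua, mus = mus, g = g)
  optical_properties(water = m, tissue = m, skeleton = m)
}

# zero-noise trait table with explicit per-group colony means
constant_trait_table <- function(means_shallow, means_mesophotic,
                                 n_colonies = 5L, n_reps = 2L) {
  gm <- tibble::tibble(trait = names(means_shallow),
                       shallow = unname(means_shallow),
                       mesophotic = unname(means_mesophotic[names(means_shallow)]))
  spec <- trait_generator_spec(group_means = gm, colony_sd = 0,
                               replicate_cv = 0,
                               n_colonies_per_group = n_colonies,
                               n_replicates = n_reps, seed = 1)
  generate_trait_table(spec)
}

# Independent 1-D layered-medium Monte Carlo reference (laterally infinite,
# depth-binned track-length fluence). Deliberately a separate code path from
# the voxel kernel: base-R RNG, analytic layer crossings, no voxel grid.
ref_mc_layered <- function(layers, n_photons = 2e4, seed = 1,
                           dz = 0.02, zmax = NULL) {
  stopifnot(all(c("z0", "z1", "mua", "mus", "g") %in% names(layers)))
  if (is.null(zmax)) zmax <- max(layers$z1)
  nbin <- ceiling(zmax / dz)
  track <- numeric(nbin)
  set.seed(seed)
  hg <- function(g, u) {
    if (abs(g) < 1e-12) return(2 * u - 1)
    f <- (1 - g^2) / (1 - g + 2 * g * u)
    max(-1, min(1, (1 + g^2 - f^2) / (2 * g)))
  }
  tally <- function(za, zb, uz) {
    lo <- min(za, zb); hi <- max(za, zb)
    if (hi <= 0 || lo >= zmax) return(invisible())
    lo <- max(lo, 0); hi <- min(hi, zmax)
    b0 <- floor(lo / dz); b1 <- min(nbin - 1, floor((hi - 1e-12) / dz))
    for (b in b0:b1) {
      seg <- min(hi, (b + 1) * dz) - max(lo, b * dz)
      if (seg > 0) track[b + 1] <<- track[b + 1] + w * seg / abs(uz)
    }
  }
  for (i in seq_len(n_photons)) {
    z <- 0; uz <- 1; w <- 1
    repeat {
      lay <- which(layers$z0 <= z & z < layers$z1)[1]
      if (is.na(lay)) break
      mua <- layers$mua[lay]; mus <- layers$mus[lay]; g <- layers$g[lay]
      mut <- mua + mus
      zb <- if (uz > 0) layers$z1[lay] else layers$z0[lay]
      db <- (zb - z) / uz
      dint <- if (mut > 0) -log(runif(1)) / mut else Inf
      if (dint < db) {
        z2 <- z + uz * dint
        tally(z, z2, uz)
        z <- z2
        w_abs <- w * mua / mut
        w <- w - w_abs
        if (w <= 1e-6) break
        ct <- hg(g, runif(1))
        st <- sqrt(max(0, 1 - ct^2))
        phi <- 2 * pi * runif(1)
        uz <- uz * ct + sqrt(max(0, 1 - uz^2)) * st * cos(phi)
        uz <- max(-1, min(1, uz))
        if (abs(uz) < 1e-9) uz <- sign(uz + 1e-12) * 1e-9
      } else {
        z2 <- zb + uz * 1e-9
        tally(z, zb, uz)
        z <- z2
        if (z <= 0 || z >= zmax) break
      }
    }
  }
  track / (dz * n_photons)
}

# layer-mean relative fluence profile of a voxel run
phi_depth_profile <- function(fluence) {
  apply(fluence$phi, 3, mean)
}

# memoized expensive runs shared by the acceptance blocks ---------------------
.acc_env <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (!is.null(.acc_env$runs)) return(.acc_env$runs)
  op <- optical_properties()
  tiles <- list(shallow = build_tile(shallow_params()),
                mesophotic = build_tile(mesophotic_params()))
  ko <- list(shallow = build_tile(knockout(shallow_params(), "corallite")),
             mesophotic = build_tile(knockout(mesophotic_params(), "corallite")))
  runs <- list(tiles = tiles, knockout_tiles = ko,
               default = list(), knockout = list())
  for (m in names(tiles)) {
    runs$default[[m]] <- lapply(1:5, function(s) {
      run_mc(tiles[[m]], op, transport_config(n_photons = 1e6, seed = s))
    })
    runs$knockout[[m]] <- lapply(1:2, function(s) {
      run_mc(ko[[m]], op, transport_config(n_photons = 1e6, seed = s))
    })
  }
  .acc_env$runs <- runs
  runs
}
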