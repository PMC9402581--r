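test_that("Henyey-Greenstein sampling hits its closed-form endpoints", {
  expect_identical(sample_hg(0, 0.5), 0)
  expect_equal(sample_hg(0.9, 1), 1)
  expect_equal(sample_hg(0.9, 0), -1)
  expect_error(sample_hg(1, 0.5))
  # the compiled kernel and the R closed form agree
  u <- seq(0, 1, length.out = 101)
  expect_equal(corallux:::.hg_cos_cpp(0.9, u), sample_hg(0.9, u),
               tolerance = 1e-12)
  expect_equal(corallux:::.hg_cos_cpp(0, u), sample_hg(0, u),
               tolerance = 1e-12)
})

test_that("HG sample mean reproduces the anisotropy", {
  set.seed(1)
  n <- 1e6
  for (g in c(0.9, -0.4)) {
    ct <- sample_hg(g, runif(n))
    se <- sd(ct) / sqrt(n)
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
})

test_that("an absorbing-only slab follows the exponential attenuation law", {
  mua_mm <- 0.5          # mm^-1 -> 5 cm^-1 in config units
  dx <- 0.02
  vol <- make_slab(20, 20, 250, dx = dx)
  op <- uniform_optics(mua = 5, mus = 0)
  fl <- run_mc(vol, op, transport_config(n_photons = 1e5, seed = 2))
  prof <- phi_depth_profile(fl)
  z <- (seq_along(prof) - 0.5) * dx
  keep <- z * mua_mm <= 2          # to two optical depths at this photon count
  # voxel-averaged analytic fluence
  lo <- (seq_along(prof) - 1) * dx; hi <- seq_along(prof) * dx
  analytic <- (exp(-mua_mm * lo) - exp(-mua_mm * hi)) / (mua_mm * dx)
  expect_lt(max(abs(prof[keep] / analytic[keep] - 1)), 0.05)
})

test_that("energy is conserved on every run", {
  vol <- build_tile(mesophotic_params(), resolution = 0.04,
                    tile_corallites = 1, water_mm = 0.1, slab_mm = 0.4)
  # with roulette: the ledger closes once the roulette net term is included
  fl <- run_mc(vol, optical_properties(), transport_config(n_photons = 5e4))
  expect_lt(abs(energy_ledger(fl)$closure - 1), 1e-9)
  # without roulette: absorbed + escaped alone balance the launched weight
  fl2 <- run_mc(vol, optical_properties(),
                transport_config(n_photons = 5e4, roulette_threshold = 0))
  expect_equal(fl2$roulette_net, 0)
  expect_lt(abs(fl2$escaped_top + fl2$escaped_other + sum(fl2$absorbed) - 1),
            1e-6)
  # no absorption: all launched weight escapes
  op0 <- uniform_optics(mua = 0, mus = 20, g = 0.8)
  fl3 <- run_mc(make_slab(20, 20, 40), op0, transport_config(n_photons = 2e4))
  expect_lt(abs(fl3$escaped_top + fl3$escaped_other - 1), 1e-3)
  expect_equal(sum(fl3$absorbed), 0)
})

test_that("a transparent medium transmits the beam with phi = 1", {
  vol <- make_slab(15, 15, 30)
  op <- uniform_optics(mua = 0, mus = 0)
  fl <- run_mc(vol, op, transport_config(n_photons = 2e4, seed = 5))
  expect_equal(fl$escaped_other, 1)   # straight through to the bottom
  expect_equal(fl$escaped_top, 0)
  # every photon crosses every slice once: slice means are exactly 1, and
  # per-voxel values fluctuate only by the multinomial spread of launch sites
  expect_equal(phi_depth_profile(fl), rep(1, 30), tolerance = 1e-9)
  expect_lt(max(abs(fl$phi - 1)), 0.6)
  # surface escape map on a transparent tile is 1 up to counting noise
  tvol <- make_slab(15, 15, 30)
  tvol$labels[, , 1:14] <- 0L  # water above a tissue slab
  fl2 <- run_mc(tvol, op, transport_config(n_photons = 2e4, seed = 5))
  es <- surface_escape_profile(fl2, tvol)
  expect_equal(dim(es), dim(tvol$labels)[1:2])
  expect_equal(mean(es), 1, tolerance = 1e-9)
  expect_lt(max(abs(es - 1)), 0.6)
})

test_that("runs are reproducible under a fixed seed and vary across seeds", {
  vol <- make_slab(20, 20, 30)
  op <- uniform_optics(mua = 1, mus = 50, g = 0.9)
  f1 <- run_mc(vol, op, transport_config(n_photons = 1e4, seed = 7))
  f2 <- run_mc(vol, op, transport_config(n_photons = 1e4, seed = 7))
  expect_identical(f1$phi, f2$phi)
  f3 <- run_mc(vol, op, transport_config(n_photons = 1e4, seed = 8))
  expect_false(identical(f1$phi, f3$phi))
  # and the seed-to-seed differences look like counting noise, not bias
  expect_equal(mean(f1$phi), mean(f3$phi), tolerance = 0.05)
})

test_that("depth profiles match an independent 1-D layered reference", {
  dx <- 0.02
  # water (transparent-ish) over tissue-like over skeleton-like layers
  vol <- make_slab(24, 24, 60, dx = dx, label = 0L)
  vol$labels[, , 11:25] <- 1L
  vol$labels[, , 26:60] <- 2L
  op <- optical_properties(
    water = medium_optics(mua = 0.001, mus = 0.1, g = 0.9),
    tissue = medium_optics(mua = 5, mus = 50, g = 0.9),
    skeleton = medium_optics(mua = 1, mus = 100, g = 0.9))
  fl <- run_mc(vol, op, transport_config(n_photons = 4e4, seed = 3))
  prof <- phi_depth_profile(fl)

  layers <- data.frame(
    z0 = c(0, 10, 25) * dx, z1 = c(10, 25, 60) * dx,
    mua = c(0.001, 5, 1) / 10, mus = c(0.1, 50, 100) / 10,
    g = 0.9)
  ref <- ref_mc_layered(layers, n_photons = 2e4, seed = 4, dz = dx,
                        zmax = 60 * dx)
  keep <- ref > 0.05
  expect_lt(median(abs(prof[keep] / ref[keep] - 1)), 0.05)
  expect_lt(max(abs(prof[keep] - ref[keep])), 0.15)
})

test_that("mean fluence is stable under grid refinement", {
  op <- uniform_optics(mua = 2, mus = 30, g = 0.9)
  f1 <- run_mc(make_slab(20, 20, 40, dx = 0.02), op,
               transport_config(n_photons = 1e5, seed = 1))
  f2 <- run_mc(make_slab(40, 40, 80, dx = 0.01), op,
               transport_config(n_photons = 1e5, seed = 1))
  expect_lt(abs(mean(f1$phi) - mean(f2$phi)) / mean(f2$phi), 0.03)
})

test_that("the two fluence estimators agree where absorption is present", {
  vol <- make_slab(20, 20, 40)
  op <- uniform_optics(mua = 3, mus = 30, g = 0.9)
  f_path <- run_mc(vol, op, transport_config(n_photons = 1e5, seed = 6))
  f_abs <- run_mc(vol, op, transport_config(n_photons = 1e5, seed = 6,
                                            estimator = "absorbed_weight"))
  expect_equal(mean(f_abs$phi), mean(f_path$phi), tolerance = 0.02)
})

test_that("Monte Carlo error shrinks like the square root of photon count", {
  vol <- make_slab(16, 16, 24)
  op <- uniform_optics(mua = 2, mus = 30, g = 0.9)
  mean_phi <- function(n, s) {
    mean(run_mc(vol, op, transport_config(n_photons = n, seed = s))$phi)
  }
  lo <- vapply(1:8, function(s) mean_phi(1e3, s), 1)
  hi <- vapply(101:108, function(s) mean_phi(16e3, s), 1)
  ratio <- sd(lo) / sd(hi)
  expect_gt(ratio, 1.8)   # expected 4, allow wide stochastic slack
  expect_lt(ratio, 9)
})

test_that("backscatter enhances the surface escape map above unity", {
  p <- mesophotic_params()
  vol <- build_tile(p, tile_corallites = 1)
  op <- optical_properties(
    skeleton = medium_optics(mua = 0.01, musp = 100, g = 0.9))
  fl <- run_mc(vol, op, transport_config(n_photons = 1e5, seed = 9))
  es <- surface_escape_profile(fl, vol)
  expect_equal(dim(es), dim(vol$labels)[1:2])
  expect_gt(max(es, na.rm = TRUE), 1)
})

test_that("fluence volumes round-trip through float TIFF + sidecar", {
  vol <- make_slab(10, 10, 12)
  fl <- run_mc(vol, uniform_optics(mua = 2, mus = 10, g = 0.5),
               transport_config(n_photons = 2e3, seed = 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_fluence_volume(fl, path)
  back <- read_fluence_volume(path)
  expect_equal(back$phi, fl$phi, tolerance = 1e-6)
  expect_equal(back$escaped_top, fl$escaped_top)
})

test_that("absorbing lateral boundaries divert weight from the periodic paths", {
  vol <- make_slab(12, 12, 20)
  op <- uniform_optics(mua = 0, mus = 50, g = 0.5)
  per <- run_mc(vol, op, transport_config(n_photons = 2e4, seed = 3,
                                          lateral_boundary = "periodic"))
  abs_ <- run_mc(vol, op, transport_config(n_photons = 2e4, seed = 3,
                                           lateral_boundary = "absorbing"))
  # with mua = 0 everything escapes either way, but the absorbing run loses
  # sideways-travelling weight that the periodic run returns through the top
  expect_lt(abs(per$escaped_top + per$escaped_other - 1), 1e-3)
  expect_lt(abs(abs_$escaped_top + abs_$escaped_other - 1), 1e-3)
  expect_gt(abs_$escaped_other, per$escaped_other)
  expect_lt(abs_$escaped_top, per$escaped_top)
})

test_that("the scattering skeleton turns the calyx into a fluence-enhancing cavity", {
  # mechanism behind the morphotype-ordering result: with near-lossless
  # skeletal scattering, relative fluence rises toward the calyx floor, so the
  # polyp plug is brighter than the coenosarc drape, not darker
  vol <- build_tile(shallow_params(), tile_corallites = 1)
  fl <- run_mc(vol, optical_properties(),
               transport_config(n_photons = 1e5, seed = 2))
  z <- (slice.index(vol$labels, 3) - 0.5) * vol$resolution
  tis <- vol$labels == 1L
  plug <- tis & z > vol$meta$z_coeno    # tissue inside the calyx recess
  drape <- tis & z <= vol$meta$z_coeno  # tissue over the coenosteum
  phi_plug <- mean(fl$phi[plug])
  phi_drape <- mean(fl$phi[drape])
  expect_gt(phi_plug, phi_drape)
  expect_gt(phi_plug, 2)     # well above the incident irradiance
  expect_gt(phi_drape, 1.5)
})
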