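test_that("blueprint validation enforces the trait invariants", {
  expect_error(morphotype_params(CD = 2, TH = .5, SL = .2, SW = .06, CH = .15,
                                 SS = .18, SPL = .12, SPW = .06, CSC = 1.5,
                                 CSM = .4),
               "CD must not exceed CSC", class = "corallux_invalid_params")
  expect_error(morphotype_params(CD = 1, TH = .2, SL = .2, SW = .06, CH = .5,
                                 SS = .18, SPL = .12, SPW = .06, CSC = 1.5,
                                 CSM = .4),
               "CH", class = "corallux_invalid_params")
  expect_error(morphotype_params(CD = -1, TH = .2, SL = .2, SW = .06, CH = .1,
                                 SS = .18, SPL = .12, SPW = .06, CSC = 1.5,
                                 CSM = .4),
               "CD", class = "corallux_invalid_params")
  expect_error(morphotype_params(CD = 1, TH = .5, SL = .2, SW = .06, CH = .15,
                                 SS = .18, SPL = .12, SPW = .06, CSC = 1.5,
                                 CSM = 1.2),
               "CSM", class = "corallux_invalid_params")
})

test_that("the flat limit is a uniform layered slab with rugosity exactly 1", {
  flat <- morphotype_params(CD = 0, TH = 0, SL = 0, SW = 0, CH = 0, SS = 0.2,
                            SPL = 0, SPW = 0, CSC = 1.0, CSM = 0.5,
                            tissue_thickness = 0.1)
  vol <- build_tile(flat, resolution = 0.02, tile_corallites = 1,
                    water_mm = 0.1, slab_mm = 0.2)
  m <- surface_metrics(vol)
  expect_identical(m$rugosity, 1)
  d <- dim(vol$labels)
  expect_equal(m$surface_area, d[1] * d[2] * 0.02^2)
  # the tissue layer is uniform: every column holds the same tissue count
  per_col <- apply(vol$labels == 1L, c(1, 2), sum)
  expect_true(all(per_col == per_col[1, 1]))
})

test_that("default mesophotic tile honours the construction contract", {
  p <- mesophotic_params()
  vol <- build_tile(p)
  dx <- vol$resolution
  d <- dim(vol$labels)
  cx <- round(vol$meta$pitch / 2 / dx)  # first corallite center column
  # voxel at the calyx center between columella top and rim: tissue
  # (first voxel whose center lies at or below the polyp fill surface)
  z_fill <- vol$meta$z_coeno + p$polyp_recess * p$TH
  z_coltop <- vol$meta$z_floor - p$CH
  j <- ceiling(z_fill / dx + 0.5)
  expect_lt((j - 0.5) * dx, z_coltop)   # sits above the columella top
  expect_equal(vol$labels[cx, cx, j], 1L)
  # slab interior: skeleton
  expect_equal(vol$labels[cx, cx, d[3] - 2L], 2L)
  # above the tissue surface: water
  expect_equal(vol$labels[cx, cx, 2L], 0L)
  # label conservation
  expect_equal(sum(tabulate(as.integer(vol$labels) + 1L, 3L)), prod(d))
})

test_that("tiles are laterally periodic with the corallite pitch", {
  vol <- build_tile(mesophotic_params(), tile_corallites = 2)
  d <- dim(vol$labels)
  h <- d[1] / 2
  expect_identical(vol$labels[1:h, , ], vol$labels[h + 1:h, , ])
  expect_identical(vol$labels[, 1:h, ], vol$labels[, h + 1:h, ])
})

test_that("coarse resolutions are rejected", {
  expect_error(build_tile(mesophotic_params(), resolution = 0.1),
               "resolution", class = "corallux_resolution_error")
})

test_that("tissue volume converges under grid refinement", {
  v1 <- build_tile(mesophotic_params(), resolution = 0.02, tile_corallites = 1)
  v2 <- build_tile(mesophotic_params(), resolution = 0.01, tile_corallites = 1)
  tv1 <- surface_metrics(v1)$tissue_volume
  tv2 <- surface_metrics(v2)$tissue_volume
  expect_lt(abs(tv1 - tv2) / tv2, 0.02)
})

test_that("knock-outs remove their feature and conserve what they must", {
  p <- shallow_params()
  base <- build_tile(p)

  ks <- knockout(p, "spines")
  vs <- build_tile(ks)
  # no skeleton protrudes above the coenosteum plane
  j_coeno <- ceiling(vs$meta$z_coeno / vs$resolution)
  expect_false(any(vs$labels[, , 1:(j_coeno - 1)] == 2L))
  # draped tissue thickness was frozen, not zeroed
  expect_gt(sum(vs$labels == 1L), 0.8 * sum(base$labels == 1L))

  kc <- knockout(p, "corallite")
  vc <- build_tile(kc)
  expect_lte(abs(sum(vc$labels == 1L) - sum(base$labels == 1L)) /
               sum(base$labels == 1L), 0.01)
  # calyx gone: no water voxels below the coenosteum plane
  jj <- ceiling(vc$meta$z_coeno / vc$resolution) + 1L
  expect_false(any(vc$labels[, , jj:dim(vc$labels)[3]] == 0L))

  kl <- knockout(p, "columella")
  vl <- build_tile(kl)
  diff_idx <- which(vl$labels != base$labels, arr.ind = TRUE)
  # changes confined to the calyx interior depth range
  dx <- base$resolution
  z_mm <- (diff_idx[, 3] - 0.5) * dx
  expect_true(all(z_mm >= base$meta$z_coeno & z_mm <= base$meta$z_floor))
  # and laterally inside the calyx radius (local lattice coordinates)
  pitch <- base$meta$pitch
  ux <- ((diff_idx[, 1] - 0.5) * dx) %% pitch - pitch / 2
  uy <- ((diff_idx[, 2] - 0.5) * dx) %% pitch - pitch / 2
  expect_true(all(sqrt(ux^2 + uy^2) <= p$CD / 2 + dx))

  expect_error(knockout(kl, "columella"), "not present")
  expect_error(knockout(p, "tentacles"))
})

test_that("trait exchange is an identity with itself and an involution", {
  sp <- shallow_params(); mp <- mesophotic_params()
  same <- exchange_traits(sp, sp, c("spacing", "height"))
  for (f in c("CD", "TH", "CSC", "CSM"))
    expect_equal(same[[f]], sp[[f]])

  once <- exchange_traits(sp, mp, "spacing")
  back <- exchange_traits(once, sp, "spacing")
  for (f in c("CD", "TH", "CSC", "CSM"))
    expect_equal(back[[f]], sp[[f]])
  expect_equal(once$CSM, mp$CSM)
})

test_that("exchanged-spacing rugosity lies between the default morphotypes", {
  sp <- shallow_params(); mp <- mesophotic_params()
  r_sh <- surface_metrics(build_tile(sp))$rugosity
  r_ms <- surface_metrics(build_tile(mp))$rugosity
  for (tr in c("spacing", "height")) {
    r_x <- surface_metrics(build_tile(exchange_traits(sp, mp, tr)))$rugosity
    expect_gt(r_x, min(r_sh, r_ms))
    expect_lt(r_x, max(r_sh, r_ms))
  }
})

test_that("rugosity responds monotonically to theca height and spacing", {
  mk <- function(TH, CSM, CSC) morphotype_params(
    CD = 0.8, TH = TH, SL = 0.15, SW = 0.05, CH = 0.1, SS = 0.15, SPL = 0.1,
    SPW = 0.05, CSC = CSC, CSM = CSM)
  r1 <- surface_metrics(build_tile(mk(0.2, 0.5, 1.4)))$rugosity
  r2 <- surface_metrics(build_tile(mk(0.5, 0.5, 1.4)))$rugosity
  expect_gte(r2, r1)
  # wider margins at fixed CD: lower corallite areal density
  expect_lt(1 / mk(0.3, 0.9, 1.8)$CSC^2, 1 / mk(0.3, 0.5, 1.4)$CSC^2)
})

test_that("surface area matches the analytic hemisphere", {
  dx <- 0.005
  n <- 120L
  R <- 0.25
  nz <- 70L  # deep enough that the bump apex stays inside the grid
  labels <- array(0L, dim = c(n, n, nz))
  labels[, , (nz - 4):nz] <- 1L  # flat tissue base
  ctr <- n / 2 * dx
  zb <- (nz - 5L) * dx  # top face of the flat tissue
  for (j in seq_len(nz - 5)) {
    zc <- (j - 0.5) * dx
    h <- zb - zc  # height above the base
    if (h < R) {
      r2 <- R^2 - h^2
      xc <- (seq_len(n) - 0.5) * dx - ctr
      m <- outer(xc^2, xc^2, "+") <= r2
      sl <- labels[, , j]; sl[m] <- 1L; labels[, , j] <- sl
    }
  }
  vol <- label_volume(labels, dx)
  a <- surface_metrics(vol)$surface_area
  analytic <- (n * dx)^2 + pi * R^2  # plane + (2*pi*R^2 cap - pi*R^2 disc)
  expect_lt(abs(a - analytic) / analytic, 0.03)
})

test_that("surface metrics reject tissue-free volumes", {
  vol <- make_slab(10, 10, 10, label = 2L)
  expect_error(surface_metrics(vol), "no tissue")
})

test_that("the stochastic pore generator hits the target porosity", {
  vol <- build_tile(mesophotic_params(), tile_corallites = 1)
  por <- surface_metrics(add_skeletal_pores(vol, 0.1557, seed = 3))$porosity
  expect_equal(por, 0.1557, tolerance = 0.02)
})

test_that("label volumes round-trip through TIFF + sidecar", {
  vol <- build_tile(mesophotic_params(), resolution = 0.04,
                    tile_corallites = 1, water_mm = 0.1, slab_mm = 0.2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$resolution, vol$resolution)
})

test_that("blueprints round-trip through YAML", {
  p <- shallow_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_morphotype_params(p, path)
  back <- read_morphotype_params(path)
  for (f in c("CD", "TH", "SL", "SW", "CH", "SS", "SPL", "SPW", "CSC", "CSM",
              "n_septa", "polyp_recess", "columella_diameter"))
    expect_equal(back[[f]], p[[f]])
  expect_identical(back$tissue_thickness, p$tissue_thickness)
})
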