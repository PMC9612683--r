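# Synthetic phantom: geometry sampling, rasterization, phase rendering,
# automatic footprints.

test_that("geometry sampling is deterministic and scales radii linearly", {
  spec <- phantom_spec(seed = 3)
  g1 <- sample_pcs_geometry(spec)
  g2 <- sample_pcs_geometry(spec)
  expect_identical(g1, g2)

  s1 <- phantom_spec(seed = 9, dilation_factor = 1)
  s2 <- phantom_spec(seed = 9, dilation_factor = 2)
  ga <- sample_pcs_geometry(s1)
  gb <- sample_pcs_geometry(s2)
  for (i in seq_along(ga$primitives)) {
    pa <- ga$primitives[[i]]
    pb <- gb$primitives[[i]]
    if (pa$role == "stone") next   # stone size is anatomy, not dilation
    if (!is.null(pa$radii)) expect_equal(pb$radii, 2 * pa$radii)
    if (!is.null(pa$radius)) expect_equal(pb$radius, 2 * pa$radius)
  }
})

test_that("major calyx count honours the spec bounds", {
  for (s in 1:50) {
    spec <- phantom_spec(seed = s, n_major_calyces = c(3L, 3L))
    expect_identical(sample_pcs_geometry(spec)$n_major, 3L)
  }
  counts <- vapply(1:50, function(s) {
    sample_pcs_geometry(phantom_spec(seed = s))$n_major
  }, integer(1))
  expect_true(all(counts >= 2 & counts <= 4))
  expect_gt(length(unique(counts)), 1)
})

test_that("rasterized sphere volume matches the analytic value within 2%", {
  spec <- phantom_spec(shape = c(60L, 60L, 60L), spacing = c(0.5, 0.5, 0.5),
                       seed = 1)
  geom <- structure(list(primitives = list(
    list(kind = "sphere", role = "calyx", center = c(0, 0, 0), radius = 10)
  ), n_major = 0L, n_minor_total = 1L, tips = rbind(c(0, 0, 0))),
  class = "pcs_geometry")
  ras <- rasterize_phantom(geom, spec)
  vox_vol <- sum(ras$labels$labels == 2L) * prod(spec$spacing)
  expect_lt(abs(vox_vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  expect_lt(abs(ras$gt$lumen_volume_mm3 - vox_vol) / vox_vol, 0.05)
})

test_that("stone primitives take priority over the lumen", {
  spec <- phantom_spec(shape = c(40L, 40L, 40L), spacing = c(0.5, 0.5, 0.5))
  geom <- structure(list(primitives = list(
    list(kind = "sphere", role = "calyx", center = c(0, 0, 0), radius = 8),
    list(kind = "sphere", role = "stone", center = c(0, 0, 0), radius = 3,
         mean_hu = 700)
  ), n_major = 0L, n_minor_total = 1L, tips = rbind(c(0, 0, 5))),
  class = "pcs_geometry")
  ras <- rasterize_phantom(geom, spec)
  ctr <- ras$labels$labels[20, 20, 20]
  expect_identical(ctr, 3L)
  expect_gt(sum(ras$labels$labels == 2L), 0)
})

test_that("empty geometry rasterizes to all-background without error", {
  spec <- phantom_spec(shape = c(10L, 10L, 10L))
  geom <- structure(list(primitives = list(), n_major = 0L,
                         n_minor_total = 0L, tips = NULL),
                    class = "pcs_geometry")
  ras <- rasterize_phantom(geom, spec)
  expect_true(all(ras$labels$labels == 0L))
  expect_equal(ras$gt$lumen_volume_mm3, 0)
})

test_that("noise-free unblurred tissue densities stay in their ranges", {
  spec <- phantom_spec(seed = 4, dilation_factor = 2, noise_sd_hu = 0,
                       blur_sigma_voxels = 0)
  ras <- rasterize_phantom(sample_pcs_geometry(spec), spec)
  nat <- render_phase(ras$labels, "native", spec)
  lum <- ras$labels$labels == 2L
  par <- ras$labels$labels == 1L
  expect_true(all(nat$voxels[lum] >= 0 & nat$voxels[lum] <= 15))
  expect_true(all(nat$voxels[par] >= 30 & nat$voxels[par] <= 45))
  exc <- render_phase(ras$labels, "excretory", spec)
  expect_true(all(exc$voxels[lum] == spec$contrast_lumen_hu))
  # phases differ only at lumen voxels before blur
  expect_identical(nat$voxels[!lum], exc$voxels[!lum])
})

test_that("rendering is reproducible and shares the noise field", {
  spec <- phantom_spec(seed = 12, dilation_factor = 1.5)
  ras <- rasterize_phantom(sample_pcs_geometry(spec), spec)
  n1 <- render_phase(ras$labels, "native", spec)
  n2 <- render_phase(ras$labels, "native", spec)
  expect_identical(n1$voxels, n2$voxels)
  # same noise in both phases: away from any blurred lumen influence the
  # two renderings must agree exactly
  exc <- render_phase(ras$labels, "excretory", spec)
  lum_influence <- pcs3d:::blur3d(
    array(as.double(ras$labels$labels == 2L), dim(ras$labels$labels)),
    spec$blur_sigma_voxels
  )
  far <- lum_influence < 1e-12
  expect_gt(sum(far), 0)
  expect_lt(max(abs(n1$voxels[far] - exc$voxels[far])), 1e-6)
})

test_that("stone density draws match the 720 +/- 210 HU model", {
  spec <- phantom_spec(seed = 1)
  x <- sample_stone_hu(500, spec)
  expect_lt(abs(mean(x) - 720), 3 * 210 / sqrt(500))
  expect_lt(abs(sd(x) - 210), 30)
  xc <- sample_stone_hu(500, spec, clip = TRUE)
  expect_true(all(xc >= 300 & xc <= 3000))
})

test_that("auto footprints sit inside the lumen, respect k and flag shortfall", {
  spec <- phantom_spec(seed = 6, dilation_factor = 2, noise_sd_hu = 0)
  ph <- generate_phantom(spec)
  fps <- auto_footprints(ph$gt, 3)
  expect_length(fps, 3)
  lum <- ph$labels$labels == 2L
  for (fp in fps) {
    idx <- pcs3d:::footprint_voxel_idx(ph$native, fp)
    expect_true(all(lum[idx]))
  }
  # centres pairwise at least 6 mm apart (non-overlapping circles)
  ctr <- t(vapply(fps, function(f) {
    c((f$slice - 1) * spec$spacing[1] + spec$origin[1], f$center)
  }, numeric(3)))
  dists <- as.matrix(dist(ctr))
  expect_true(all(dists[upper.tri(dists)] >= 6))
  expect_warning(fps_many <- auto_footprints(ph$gt, 50), "available")
  expect_gt(attr(fps_many, "shortfall"), 0)
  # empty lumen errors
  empty <- label_volume(array(0L, c(4, 4, 4)))
  expect_error(auto_footprints(empty, 1), "nothing to annotate")
})

test_that("voxel-counted lumen volume converges to the analytic volume", {
  geom_at <- function(sp) {
    spec <- phantom_spec(shape = as.integer(round(c(30, 30, 30) / sp)),
                        spacing = rep(sp, 3), seed = 2)
    geom <- structure(list(primitives = list(
      list(kind = "capsule", role = "infundibulum",
           p0 = c(0, -8, 0), p1 = c(0, 8, 0), radius = 3)
    ), n_major = 1L, n_minor_total = 0L, tips = NULL),
    class = "pcs_geometry")
    ras <- rasterize_phantom(geom, spec)
    sum(ras$labels$labels == 2L) * prod(spec$spacing)
  }
  analytic <- pi * 9 * 16 + 4 / 3 * pi * 27
  err1 <- abs(geom_at(1.0) - analytic) / analytic
  err05 <- abs(geom_at(0.5) - analytic) / analytic
  expect_lt(err05, err1)
  expect_lt(err05, 0.02)
})
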