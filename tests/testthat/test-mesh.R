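# Surface extraction, Taubin smoothing, area/volume, STL, printability.

test_that("a single interior voxel meshes to a closed Euler-2 surface", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  mesh <- extract_surface(m, gaussian_sigma_voxels = 0)
  rep <- printability_report(mesh)
  expect_true(rep$watertight)
  expect_equal(rep$euler_characteristic, 2)
  expect_equal(rep$n_components, 1)
  expect_gt(mesh_volume(mesh), 0)
  expect_error(extract_surface(array(FALSE, c(3, 3, 3))), "nothing to mesh")
})

test_that("voxelized sphere recovers analytic area and volume", {
  m <- sphere_mask(10, 0.5)
  co <- attr(m, "coords")
  mesh <- extract_surface(m, spacing = rep(0.5, 3), origin = rep(co[1], 3))
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.03)
  sm <- smooth_mesh(mesh)
  a <- surface_area(sm)
  expect_lt(abs(a - 4 * pi * 100) / (4 * pi * 100), 0.03)
  # smoothing removes staircase area: moves towards the analytic value
  expect_lt(abs(a - 4 * pi * 100), abs(surface_area(mesh) - 4 * pi * 100))
})

test_that("area and volume converge with finer spacing", {
  errs <- vapply(c(1.0, 0.5), function(sp) {
    m <- sphere_mask(10, sp)
    co <- attr(m, "coords")
    mesh <- smooth_mesh(extract_surface(m, spacing = rep(sp, 3),
                                        origin = rep(co[1], 3)))
    abs(surface_area(mesh) - 4 * pi * 100) / (4 * pi * 100)
  }, numeric(1))
  expect_lt(errs[2], 0.03)
  expect_lt(errs[1], 0.05)
})

test_that("Taubin smoothing preserves topology, volume and determinism", {
  m <- sphere_mask(6, 1)
  co <- attr(m, "coords")
  mesh <- extract_surface(m, spacing = c(1, 1, 1), origin = rep(co[1], 3))
  expect_identical(smooth_mesh(mesh, iterations = 0), mesh)
  s1 <- smooth_mesh(mesh, 10)
  s2 <- smooth_mesh(mesh, 10)
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(nrow(s1$vertices), nrow(mesh$vertices))
  expect_identical(s1$faces, mesh$faces)
  expect_lt(abs(mesh_volume(s1) - mesh_volume(mesh)) / mesh_volume(mesh),
            0.02)
  r0 <- printability_report(mesh)
  r1 <- printability_report(s1)
  expect_equal(r1$euler_characteristic, r0$euler_characteristic)
})

test_that("surface area is the exact triangle-area sum", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)
  set.seed(10)
  V <- matrix(runif(30), 10, 3)
  F <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(1, 5, 9))
  mesh <- surface_mesh(V, F)
  brute <- sum(apply(F, 1, function(f) {
    e1 <- V[f[2], ] - V[f[1], ]
    e2 <- V[f[3], ] - V[f[1], ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    0.5 * sqrt(sum(cr^2))
  }))
  expect_equal(surface_area(mesh), brute)
})

test_that("STL round-trips in both dialects", {
  m <- sphere_mask(4, 1)
  co <- attr(m, "coords")
  mesh <- extract_surface(m, spacing = c(1, 1, 1), origin = rep(co[1], 3))
  fa <- tempfile(fileext = ".stl")
  export_stl(mesh, fa, binary = FALSE)
  back <- read_stl(fa)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  expect_lt(abs(surface_area(back) - surface_area(mesh)), 1e-6)
  txt <- readLines(fa)
  expect_gt(sum(grepl("facet normal", txt)), 0)

  fb <- tempfile(fileext = ".stl")
  export_stl(mesh, fb, binary = TRUE)
  expect_equal(file.info(fb)$size, 84 + 50 * nrow(mesh$faces))
  bback <- read_stl(fb)
  expect_equal(nrow(bback$faces), nrow(mesh$faces))
  # binary stores float32: area agrees to single precision
  expect_lt(abs(surface_area(bback) - surface_area(mesh)) /
              surface_area(mesh), 1e-5)
})

test_that("printability flags defects and sums disjoint components", {
  m <- array(FALSE, c(7, 7, 16))
  m[3:5, 3:5, 3:5] <- TRUE
  m[3:5, 3:5, 11:13] <- TRUE   # 8-voxel offset keeps the lattice parity
  mesh <- extract_surface(m, gaussian_sigma_voxels = 0)
  rep <- printability_report(mesh)
  expect_equal(rep$n_components, 2)
  expect_true(rep$watertight)
  expect_true(rep$consistently_oriented)
  one <- extract_surface(m[, , 1:8, drop = FALSE], gaussian_sigma_voxels = 0)
  expect_equal(surface_area(mesh), 2 * surface_area(one))

  broken <- surface_mesh(mesh$vertices, mesh$faces[-1, , drop = FALSE])
  repb <- printability_report(broken)
  expect_false(repb$watertight)
})
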