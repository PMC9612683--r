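# Smart brush, seed statistics, region growing, incremental updates,
# stone harvesting and the classical threshold baseline.

test_that("smart brush keeps a uniform circle and drops the minority tissue", {
  arr <- array(10, c(1, 11, 11))
  vol <- make_ct(arr)
  fp <- footprint(1, center = c(5, 5), radius = 3)
  lab <- refine_footprint(vol, fp)
  idx <- pcs3d:::footprint_voxel_idx(vol, fp)
  expect_setequal(lab$labeled, idx)
  expect_length(lab$excluded, 0)

  # circle straddling lumen (5 HU) and parenchyma (40 HU), majority lumen:
  # the median +/- 3 MAD band drops the parenchyma voxels
  arr2 <- array(5, c(1, 11, 11))
  arr2[1, , 9:11] <- 40
  vol2 <- make_ct(arr2)
  fp2 <- footprint(1, center = c(5, 7.2), radius = 2.5)
  idx2 <- pcs3d:::footprint_voxel_idx(vol2, fp2)
  hu2 <- round(vol2$voxels[idx2])
  med <- median(hu2)
  madv <- median(abs(hu2 - med))
  expected <- idx2[hu2 >= med - 3 * madv & hu2 <= med + 3 * madv]
  lab2 <- refine_footprint(vol2, fp2)
  expect_setequal(lab2$labeled, expected)
  expect_true(all(vol2$voxels[lab2$labeled] == 5))
  expect_true(any(vol2$voxels[idx2] == 40))   # circle really straddles
})

test_that("stone voxels inside a circle are excluded, never labelled", {
  arr <- array(8, c(1, 11, 11))
  arr[1, 6, 6] <- 720
  vol <- make_ct(arr)
  lab <- refine_footprint(vol, footprint(1, c(5, 5), 3))
  stone_idx <- which(vol$voxels == 720)
  expect_identical(lab$excluded, stone_idx)
  expect_false(stone_idx %in% lab$labeled)
  # footprint entirely on stone errors
  arr2 <- array(700, c(1, 5, 5))
  expect_error(refine_footprint(make_ct(arr2), footprint(1, c(2, 2), 1.5)),
               "footprint on stone")
  expect_error(refine_footprint(vol, footprint(5, c(2, 2), 1)),
               "out of bounds")
})

test_that("seed statistics average labelled voxels and skip stones exactly", {
  arr <- array(0, c(1, 2, 3))
  arr[1, 1, 1] <- 5; arr[1, 1, 2] <- 10; arr[1, 1, 3] <- 720
  vol <- make_ct(arr)
  fp <- footprint(1, c(0, 1), 2)
  lab <- raw_label(fp, labeled_idx = which(arr %in% c(5, 10)),
                   excluded_idx = which(arr == 720))
  st <- seed_statistics(list(lab), vol)
  expect_equal(st$mu, 7.5)
  expect_equal(st$n_stone_excluded, 1L)

  arr2 <- array(12, c(1, 3, 3))
  st2 <- seed_statistics(raw_label(fp, seq_len(9)), make_ct(arr2))
  expect_equal(st2$mu, 12)
  expect_equal(st2$sd, 0)

  # stone-exclusion exactness: mu with/without one stone voxel differs by
  # exactly removing that HU from the arithmetic mean
  set.seed(31)
  vals <- round(runif(99, 0, 15))
  arr3 <- array(c(vals, 720), c(1, 10, 10))
  vol3 <- make_ct(arr3)
  with_stone <- seed_statistics(raw_label(fp, 1:100), vol3)
  wo_stone <- seed_statistics(raw_label(fp, 1:99, 100L), vol3)
  expect_equal(wo_stone$mu, mean(vals))
  expect_equal(with_stone$mu, mean(c(vals, 720)))

  # union over two labels equals brute-force mean of the concatenation
  set.seed(8)
  arr4 <- array(round(runif(200, 0, 40)), c(2, 10, 10))
  vol4 <- make_ct(arr4)
  l1 <- raw_label(fp, 1:100)
  l2 <- raw_label(fp, 101:200)
  expect_equal(seed_statistics(list(l1, l2), vol4)$mu, mean(arr4))
  expect_error(seed_statistics(list(raw_label(fp, integer(0))), vol4),
               "no seed voxels")
})

test_that("region growing reproduces the worked one-row example", {
  arr <- array(c(40, 12, 8, 5, 14, 38), c(1, 1, 6))
  vol <- make_ct(arr)
  fp <- footprint(1, c(0, 2), 1.1)
  lab <- raw_label(fp, labeled_idx = which(arr == 8))
  st <- structure(list(mu = 6.5, sd = 0, n_voxels = 2,
                       n_stone_excluded = 0), class = "seed_stats")
  m <- grow_region(vol, list(lab), stats = st,
                   cfg = seg_config(min_region_voxels = 1))
  expect_identical(as.vector(m$mask[1, 1, ]),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("uniform volume at the seed mean is segmented entirely", {
  arr <- array(10, c(4, 6, 6))
  vol <- make_ct(arr)
  m <- grow_region(vol, list(raw_label(footprint(2, c(2, 2), 1), 100L)),
                   cfg = seg_config(min_region_voxels = 1))
  expect_true(all(m$mask))
  expect_error(
    grow_region(make_ct(array(500, c(2, 4, 4))),
                list(raw_label(footprint(1, c(1, 1), 1), 5L)),
                stats = structure(list(mu = 8, sd = 0, n_voxels = 1,
                                       n_stone_excluded = 0),
                                  class = "seed_stats"),
                cfg = seg_config(min_region_voxels = 2)),
    "empty segmentation")
})

test_that("segmented set is monotone in delta_up and in the footprint set", {
  set.seed(77)
  spec <- phantom_spec(seed = 77, dilation_factor = 2)
  ph <- generate_phantom(spec)
  fps <- auto_footprints(ph$gt, 3)
  m15 <- grow_region(ph$native, fps, cfg = seg_config(delta_up = 15))
  m25 <- grow_region(ph$native, fps, cfg = seg_config(delta_up = 25))
  expect_true(all(m25$mask[m15$mask]))
  expect_gt(sum(m25$mask), sum(m15$mask))
  # monotone in the footprint set at fixed band (same seed statistics)
  labs <- lapply(fps, function(f) refine_footprint(ph$native, f))
  st <- seed_statistics(labs, ph$native)
  m2 <- grow_region(ph$native, labs[1:2], stats = st)
  m3 <- grow_region(ph$native, labs, stats = st)
  expect_true(all(m3$mask[m2$mask]))
})

test_that("footprint order never changes the mask", {
  spec <- phantom_spec(seed = 21, dilation_factor = 2)
  ph <- generate_phantom(spec)
  fps <- auto_footprints(ph$gt, 3)
  base <- grow_region(ph$native, fps)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(grow_region(ph$native, fps[perm])$mask, base$mask)
  }
})

test_that("adding footprints is incremental-equals-batch and idempotent", {
  # two tissue pools joined by an intermediate band: the second footprint
  # is informative (its pool is beyond the first band) and extends the mask
  arr <- array(8, c(3, 20, 20))
  arr[, , 10] <- 18
  arr[, , 11:20] <- 25
  vol <- make_ct(arr)
  fp1 <- footprint(2, c(10, 4), 2.5)
  fp2 <- footprint(2, c(10, 15), 2.5)
  m1 <- grow_region(vol, list(fp1))
  expect_false(any(m1$mask[, , 12:20]))
  inc <- add_footprint(vol, m1, fp2)
  batch <- grow_region(vol, list(fp1, fp2))
  expect_identical(inc$mask, batch$mask)
  expect_true(all(inc$mask[m1$mask]))
  expect_gt(sum(inc$mask), sum(m1$mask))
  # random footprint sequences: incremental always lands on the batch mask
  set.seed(55)
  for (rep in 1:3) {
    fps <- lapply(1:3, function(i) {
      footprint(sample(1:3, 1), runif(2, 2, 17), runif(1, 1.5, 3))
    })
    cur <- grow_region(vol, fps[1])
    for (i in 2:3) cur <- add_footprint(vol, cur, fps[[i]])
    ref <- grow_region(vol, cur$provenance$footprints)
    expect_identical(cur$mask, ref$mask)
  }
  # redundant footprint wholly inside the mask: exact no-op
  spec <- phantom_spec(seed = 13, dilation_factor = 2)
  ph <- generate_phantom(spec)
  full <- grow_region(ph$native, auto_footprints(ph$gt, 3))
  D <- pcs3d:::distance_transform(full$mask, spec$spacing)
  ctr_idx <- which.max(D)
  ijk <- arrayInd(ctr_idx, dim(full$mask))
  redundant <- footprint(ijk[1, 1],
                         center = voxel_to_world(ph$native, ijk[1, ] - 1)[2:3],
                         radius = 1)
  again <- add_footprint(ph$native, full, redundant)
  expect_identical(again$mask, full$mask)
})

test_that("region growing matches the independent oracle on random fields", {
  set.seed(99)
  for (trial in 1:25) {
    d <- c(sample(2:10, 1), sample(4:16, 1), sample(4:16, 1))
    hu <- array(round(runif(prod(d), -30, 60)), d)
    vol <- make_ct(hu)
    seed_idx <- sample(prod(d), 1)
    mu <- hu[seed_idx]
    st <- structure(list(mu = mu, sd = 0, n_voxels = 1,
                         n_stone_excluded = 0), class = "seed_stats")
    ijk <- arrayInd(seed_idx, d)
    fp <- footprint(ijk[1, 1], voxel_to_world(vol, ijk[1, ] - 1)[2:3], 0.6)
    m <- grow_region(vol, list(raw_label(fp, seed_idx)), stats = st,
                     cfg = seg_config(min_region_voxels = 1))
    oracle <- oracle_grow(hu, seed_idx, mu - 20, mu + 15)
    expect_identical(m$mask, oracle)
  }
})

test_that("stones claimed by a circle are harvested into the model", {
  # 9 mm stone inside a urine-filled cavity
  d <- c(30, 40, 40)
  arr <- array(8, d)
  zi <- slice.index(arr, 1); yi <- slice.index(arr, 2)
  xi <- slice.index(arr, 3)
  stone <- (zi - 15)^2 + (yi - 20)^2 + (xi - 20)^2 <= 4.5^2
  arr[stone] <- 720
  vol <- make_ct(arr)
  fps <- list(footprint(15, c(19, 19), 8))
  m <- grow_region(vol, fps)
  expect_false(any(m$mask[stone]))
  h <- harvest_stones(vol, m, fps)
  expect_true(all(h$mask[stone]))
  expect_true(all(h$stone[stone]))
  # no cavity left at the stone site
  inv <- pcs3d:::label_components(!h$mask, 6L)
  border_labs <- unique(c(inv[1, , ], inv[d[1], , ], inv[, 1, ],
                          inv[, d[2], ], inv[, , 1], inv[, , d[3]]))
  expect_setequal(setdiff(unique(as.vector(inv)), 0),
                  setdiff(border_labs, 0))
  # stone never contaminates the seed statistics
  expect_equal(m$provenance$stats$mu, 8)

  # stone outside the mask and every circle is untouched
  arr2 <- array(8, d)
  arr2[, , 21:40] <- 40          # not grown: outside the band
  arr2[5, 5, 30] <- 720          # stone in the ungrown region
  vol2 <- make_ct(arr2)
  fp2 <- list(footprint(15, c(10, 10), 3))
  m2 <- harvest_stones(vol2, grow_region(vol2, fp2), fp2)
  expect_false(m2$mask[5, 5, 30])
  expect_false(any(m2$stone))
})

test_that("classical threshold reconstruction matches its contract", {
  spec <- phantom_spec(seed = 2, dilation_factor = 2, noise_sd_hu = 0,
                       blur_sigma_voxels = 0, with_stone = TRUE)
  ph <- generate_phantom(spec)
  m <- classical_threshold_segmentation(ph$native, 200)
  expect_identical(unname(which(m$mask)),
                   unname(which(ph$labels$labels == 3L)))
  # excretory phase at the mid threshold recovers the lumen, not parenchyma
  spec2 <- phantom_spec(seed = 2, dilation_factor = 2)
  ph2 <- generate_phantom(spec2)
  e <- classical_threshold_segmentation(ph2$excretory, 172.5, c(0, 0, 0))
  expect_gt(dice(e$mask, ph2$labels$labels == 2L), 0.9)
  expect_error(classical_threshold_segmentation(ph2$native, 4000),
               "empty segmentation")
  expect_error(classical_threshold_segmentation(ph2$excretory, 172.5,
                                                c(-20, -28, -28)),
               "seed not in mask")
})
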