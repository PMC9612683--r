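# phantom: synthetic paired native/excretory CT volumes of a branching,
# optionally dilated pelvicalyceal system (PCS), with per-voxel ground
# truth, so every downstream stage is testable without patient data.

#' Phantom generator parameters
#'
#' Defines the study conditions for the synthetic CT phantom. Defaults
#' follow the densities reported for non-contrast CT of the urinary tract:
#' urine 0-15 HU, renal parenchyma 30-45 HU, perinephric fat around
#' -100 HU, stones 720 +/- 210 HU with a typical 9 mm diameter, and an
#' acquisition grid with a 0.5 mm slice step (0.7 mm in plane).
#'
#' `dilation_factor` scales every lumen radius linearly and models
#' hydronephrosis: at 1 the system is collapsed (infundibula under one
#' voxel wide), at the cohort default of 2 it is moderately distended.
#' Partial volume is modelled as a Gaussian blur of the tissue map
#' (`blur_sigma_voxels`) applied before additive Gaussian noise
#' (`noise_sd_hu`). A fixed `seed` makes geometry, labels and both phase
#' renderings bit-exactly reproducible.
#'
#' @param shape grid size `(nz, ny, nx)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param urine_hu_range,parenchyma_hu_range,fat_hu_range tissue HU ranges.
#' @param stone_hu_mean,stone_hu_sd per-stone mean density model (HU).
#' @param stone_diameter_mm stone diameter when a stone is placed.
#' @param contrast_lumen_hu lumen density in the excretory phase
#'   (opacified urine).
#' @param n_major_calyces,n_minor_per_major integer ranges (length 2).
#' @param dilation_factor lumen radius scale, >= 1.
#' @param noise_sd_hu additive Gaussian noise, HU.
#' @param blur_sigma_voxels partial-volume blur sigma, voxel units.
#' @param with_stone place a stone sphere at the ureteropelvic junction.
#' @param seed RNG seed for all phantom substreams.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(100L, 88L, 88L),
                         spacing = c(0.5, 0.7, 0.7),
                         urine_hu_range = c(0, 15),
                         parenchyma_hu_range = c(30, 45),
                         fat_hu_range = c(-120, -80),
                         stone_hu_mean = 720,
                         stone_hu_sd = 210,
                         stone_diameter_mm = 9,
                         contrast_lumen_hu = 300,
                         n_major_calyces = c(2L, 4L),
                         n_minor_per_major = c(1L, 3L),
                         dilation_factor = 1,
                         noise_sd_hu = 5,
                         blur_sigma_voxels = 0.7,
                         with_stone = FALSE,
                         seed = 1L) {
  stopifnot(
    length(shape) == 3L, all(shape >= 2),
    length(spacing) == 3L, all(spacing > 0),
    diff(urine_hu_range) >= 0, diff(parenchyma_hu_range) >= 0,
    diff(fat_hu_range) >= 0,
    dilation_factor >= 1,
    noise_sd_hu >= 0, blur_sigma_voxels >= 0
  )
  spec <- list(
    shape = as.integer(shape), spacing = as.double(spacing),
    urine_hu_range = urine_hu_range,
    parenchyma_hu_range = parenchyma_hu_range,
    fat_hu_range = fat_hu_range,
    stone_hu_mean = stone_hu_mean, stone_hu_sd = stone_hu_sd,
    stone_diameter_mm = stone_diameter_mm,
    contrast_lumen_hu = contrast_lumen_hu,
    n_major_calyces = as.integer(n_major_calyces),
    n_minor_per_major = as.integer(n_minor_per_major),
    dilation_factor = dilation_factor,
    noise_sd_hu = noise_sd_hu,
    blur_sigma_voxels = blur_sigma_voxels,
    with_stone = isTRUE(with_stone),
    seed = as.integer(seed)
  )
  # origin centres the grid on the world origin
  spec$origin <- -(spec$shape - 1) * spec$spacing / 2
  class(spec) <- "phantom_spec"
  spec
}

# Collapsed-state (dilation 1) base geometry, mm. The normal renal pelvis
# retains a little urine; infundibula are apposed to under one in-plane
# voxel so they vanish into partial volume, which is what defeats
# non-contrast reconstruction of non-distended systems.
PELVIS_RZ <- c(4.0, 4.8)
PELVIS_RY <- c(5.0, 6.0)
PELVIS_RX <- c(3.4, 4.2)
INFUND_R <- c(0.50, 0.65)
INFUND_LEN <- c(6, 9)
STEM_R_FRAC <- 0.9
STEM_LEN <- c(1.5, 3)
CUP_R <- c(0.9, 1.2)

#' Sample a branching PCS geometry
#'
#' Draws a tree of lumen primitives (pelvis ellipsoid, infundibulum
#' capsules, minor-calyx bulbs, optional ureter stub with a UPJ stone) in
#' mm, deterministically under the spec seed. `dilation_factor` scales
#' every lumen radius linearly; axis lengths are unchanged.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `pcs_geometry`: list of primitives plus
#'   counts and per-minor-calyx tip positions.
#' @export
sample_pcs_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dil <- spec$dilation_factor
  with_substream(spec$seed, "geometry", {
    prim <- list()
    centre <- c(0, 0, 0)
    pelvis_r <- c(runif(1, PELVIS_RZ[1], PELVIS_RZ[2]),
                  runif(1, PELVIS_RY[1], PELVIS_RY[2]),
                  runif(1, PELVIS_RX[1], PELVIS_RX[2]))
    prim[[1]] <- list(kind = "ellipsoid", role = "pelvis",
                      center = centre, radii = pelvis_r * dil)
    n_major <- if (spec$n_major_calyces[1] == spec$n_major_calyces[2]) {
      spec$n_major_calyces[1]
    } else {
      sample(spec$n_major_calyces[1]:spec$n_major_calyces[2], 1)
    }
    # fan of infundibula in the z-y plane, away from the hilum (-y)
    base_ang <- seq(-70, 70, length.out = n_major) * pi / 180
    tips <- NULL
    n_minor_total <- 0L
    for (m in seq_len(n_major)) {
      ang <- base_ang[m] + runif(1, -8, 8) * pi / 180
      tilt <- runif(1, -12, 12) * pi / 180
      dir <- c(sin(ang), cos(ang) * cos(tilt), cos(ang) * sin(tilt))
      dir <- dir / sqrt(sum(dir^2))
      r_inf <- runif(1, INFUND_R[1], INFUND_R[2])
      len <- runif(1, INFUND_LEN[1], INFUND_LEN[2])
      # start on the pelvis surface along dir
      ext <- 1 / sqrt(sum((dir / (pelvis_r * dil))^2))
      p0 <- centre + dir * ext * 0.6
      p1 <- centre + dir * (ext + len)
      prim[[length(prim) + 1]] <- list(kind = "capsule", role = "infundibulum",
                                       p0 = p0, p1 = p1, radius = r_inf * dil)
      n_minor <- if (spec$n_minor_per_major[1] == spec$n_minor_per_major[2]) {
        spec$n_minor_per_major[1]
      } else {
        sample(spec$n_minor_per_major[1]:spec$n_minor_per_major[2], 1)
      }
      spread <- if (n_minor == 1) 0 else seq(-25, 25, length.out = n_minor)
      for (s in seq_len(n_minor)) {
        da <- spread[s] * pi / 180 + runif(1, -6, 6) * pi / 180
        rot <- c(
          dir[1] * cos(da) + dir[2] * sin(da),
          -dir[1] * sin(da) + dir[2] * cos(da),
          dir[3]
        )
        rot <- rot / sqrt(sum(rot^2))
        slen <- runif(1, STEM_LEN[1], STEM_LEN[2])
        r_cup <- runif(1, CUP_R[1], CUP_R[2])
        q0 <- p1
        q1 <- p1 + rot * slen
        prim[[length(prim) + 1]] <- list(kind = "capsule", role = "stem",
                                         p0 = q0, p1 = q1,
                                         radius = r_inf * STEM_R_FRAC * dil)
        prim[[length(prim) + 1]] <- list(kind = "sphere", role = "calyx",
                                         center = q1, radius = r_cup * dil)
        tips <- rbind(tips, q1)
        n_minor_total <- n_minor_total + 1L
      }
    }
    if (spec$with_stone) {
      # ureter stub leaving the hilum, obstructing stone at the UPJ
      u_dir <- c(0, -1, 0)
      ext <- 1 / sqrt(sum((u_dir / (pelvis_r * dil))^2))
      u0 <- centre + u_dir * ext * 0.6
      u1 <- centre + u_dir * (ext + 8)
      prim[[length(prim) + 1]] <- list(kind = "capsule", role = "ureter",
                                       p0 = u0, p1 = u1,
                                       radius = 0.5 * dil)
      prim[[length(prim) + 1]] <- list(
        kind = "sphere", role = "stone",
        center = centre + u_dir * (ext + 2),
        radius = spec$stone_diameter_mm / 2,
        mean_hu = sample_stone_hu(1, spec)
      )
    }
    geom <- structure(
      list(primitives = prim, n_major = n_major,
           n_minor_total = n_minor_total, tips = tips),
      class = "pcs_geometry"
    )
    check_geometry_bounds(geom, spec)
    geom
  })
}

check_geometry_bounds <- function(geom, spec) {
  half <- (spec$shape - 1) * spec$spacing / 2
  margin <- 2
  for (p in geom$primitives) {
    pts <- switch(p$kind,
      ellipsoid = rbind(p$center - p$radii, p$center + p$radii),
      capsule = rbind(p$p0 - p$radius, p$p0 + p$radius,
                      p$p1 - p$radius, p$p1 + p$radius),
      sphere = rbind(p$center - p$radius, p$center + p$radius)
    )
    if (any(abs(pts) > rep(half - margin, each = nrow(pts)))) {
      stop("degenerate geometry: primitives exceed grid bounds")
    }
  }
  invisible(geom)
}

#' Draw per-stone mean densities
#'
#' Stone mean density follows a Normal(720, 210) HU model; at render time
#' values are clipped to \[300, 3000\] HU so no stone voxel masquerades as
#' soft tissue.
#'
#' @param n number of stones.
#' @param spec a [phantom_spec()] (supplies mean, sd and seed).
#' @param clip clip draws to the render range.
#' @return numeric vector of stone densities (HU).
#' @export
sample_stone_hu <- function(n, spec, clip = FALSE) {
  x <- with_substream(spec$seed, "stone",
                      rnorm(n, spec$stone_hu_mean, spec$stone_hu_sd))
  if (clip) pmin(pmax(x, 300), 3000) else x
}

# voxel-centre coordinate vectors, mm
grid_coords <- function(spec) {
  list(
    z = spec$origin[1] + (seq_len(spec$shape[1]) - 1) * spec$spacing[1],
    y = spec$origin[2] + (seq_len(spec$shape[2]) - 1) * spec$spacing[2],
    x = spec$origin[3] + (seq_len(spec$shape[3]) - 1) * spec$spacing[3]
  )
}

# logical array of voxel centres inside a primitive, optionally with the
# radius expanded by `grow` mm (used for the parenchyma shell)
rasterize_primitive <- function(p, spec, grow = 0) {
  co <- grid_coords(spec)
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  out <- array(FALSE, spec$shape)
  if (p$kind == "ellipsoid") {
    r <- p$radii + grow
    dz2 <- ((co$z - p$center[1]) / r[1])^2
    dy2 <- ((co$y - p$center[2]) / r[2])^2
    dx2 <- ((co$x - p$center[3]) / r[3])^2
    out <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  } else if (p$kind == "sphere") {
    r <- p$radius + grow
    dz2 <- (co$z - p$center[1])^2
    dy2 <- (co$y - p$center[2])^2
    dx2 <- (co$x - p$center[3])^2
    out <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
  } else if (p$kind == "capsule") {
    r <- p$radius + grow
    ax <- p$p1 - p$p0
    len2 <- sum(ax^2)
    # squared distance from every voxel centre to the segment p0-p1
    Z <- array(co$z, spec$shape)
    Y <- array(rep(co$y, each = nz), spec$shape)
    X <- array(rep(co$x, each = nz * ny), spec$shape)
    if (len2 < 1e-12) {
      d2 <- (Z - p$p0[1])^2 + (Y - p$p0[2])^2 + (X - p$p0[3])^2
    } else {
      t <- ((Z - p$p0[1]) * ax[1] + (Y - p$p0[2]) * ax[2] +
              (X - p$p0[3]) * ax[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (Z - (p$p0[1] + t * ax[1]))^2 +
        (Y - (p$p0[2] + t * ax[2]))^2 +
        (X - (p$p0[3] + t * ax[3]))^2
    }
    out <- d2 <= r^2
  } else {
    stop("unknown primitive kind: ", p$kind)
  }
  dim(out) <- spec$shape
  out
}

#' Rasterize a PCS geometry into labels and ground truth
#'
#' Labels every voxel centre by the highest-priority primitive covering it
#' (stone > lumen > parenchyma > fat). The parenchyma is a 6 mm shell
#' around the analytic lumen (so a collapsed, sub-voxel lumen is still
#' embedded in kidney tissue). The ground truth records the label volume,
#' a grid-independent lumen volume (quasi-random point estimate over the
#' primitive union) and the per-calyx tip coordinates.
#'
#' @param geom a [sample_pcs_geometry()] result.
#' @param spec the matching [phantom_spec()].
#' @return list with elements `labels` (a [label_volume()]) and `gt`
#'   (class `pcs_ground_truth`: `labels`, `lumen_volume_mm3`, `tips`).
#' @export
rasterize_phantom <- function(geom, spec) {
  lumen <- array(FALSE, spec$shape)
  stone <- array(FALSE, spec$shape)
  shell <- array(FALSE, spec$shape)
  lumen_prims <- list()
  for (p in geom$primitives) {
    if (p$role == "stone") {
      stone <- stone | rasterize_primitive(p, spec)
    } else {
      lumen <- lumen | rasterize_primitive(p, spec)
      shell <- shell | rasterize_primitive(p, spec, grow = 6)
      lumen_prims[[length(lumen_prims) + 1]] <- p
    }
  }
  labels <- array(0L, spec$shape)
  labels[shell] <- 1L
  labels[lumen] <- 2L
  labels[stone] <- 3L
  lv <- label_volume(labels, spacing = spec$spacing, origin = spec$origin)
  gt <- structure(
    list(labels = lv,
         lumen_volume_mm3 = union_volume_mc(lumen_prims, spec),
         tips = geom$tips),
    class = "pcs_ground_truth"
  )
  list(labels = lv, gt = gt)
}

# Grid-independent volume of the union of lumen primitives: fixed-seed
# Monte-Carlo point sampling over the union bounding box.
union_volume_mc <- function(prims, spec, n = 2e5) {
  if (length(prims) == 0) return(0)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (p in prims) {
    b <- switch(p$kind,
      ellipsoid = rbind(p$center - p$radii, p$center + p$radii),
      sphere = rbind(p$center - p$radius, p$center + p$radius),
      capsule = rbind(p$p0 - p$radius, p$p1 - p$radius,
                      p$p0 + p$radius, p$p1 + p$radius)
    )
    lo <- pmin(lo, apply(b, 2, min))
    hi <- pmax(hi, apply(b, 2, max))
  }
  pts <- with_substream(spec$seed, "analytic-volume",
                        matrix(runif(3 * n), ncol = 3))
  pts <- sweep(sweep(pts, 2, hi - lo, `*`), 2, lo, `+`)
  inside <- rep(FALSE, n)
  for (p in prims) {
    idx <- which(!inside)
    if (length(idx) == 0) break
    q <- pts[idx, , drop = FALSE]
    inp <- switch(p$kind,
      ellipsoid = {
        rowSums(sweep(sweep(q, 2, p$center), 2, p$radii, `/`)^2) <= 1
      },
      sphere = rowSums(sweep(q, 2, p$center)^2) <= p$radius^2,
      capsule = {
        ax <- p$p1 - p$p0
        len2 <- max(sum(ax^2), 1e-12)
        t <- pmin(pmax((sweep(q, 2, p$p0) %*% ax) / len2, 0), 1)
        proj <- sweep(t %*% t(ax), 2, -p$p0)
        rowSums((q - proj)^2) <= p$radius^2
      }
    )
    inside[idx[inp]] <- TRUE
  }
  prod(hi - lo) * mean(inside)
}

#' Render a CT phase from a label volume
#'
#' Native phase: lumen HU ~ Uniform(urine range), parenchyma ~
#' Uniform(parenchyma range), fat ~ Uniform(fat range), stone voxels take
#' the per-stone mean density (Normal(720, 210), clipped to
#' \[300, 3000\]). Excretory phase: identical tissue draws except the lumen
#' is set to the opacified-urine density `contrast_lumen_hu`. Both phases
#' are then blurred (partial volume) and share the same additive noise
#' field, so under a fixed seed the two phases differ only at lumen voxels
#' before blur.
#'
#' @param labels a [label_volume()] from [rasterize_phantom()].
#' @param phase `"native"` or `"excretory"`.
#' @param spec the matching [phantom_spec()].
#' @return a [ct_volume()].
#' @export
render_phase <- function(labels, phase = c("native", "excretory"), spec) {
  phase <- match.arg(phase)
  lab <- labels$labels
  n <- length(lab)
  u <- with_substream(spec$seed, "tissue", runif(n))
  hu <- spec$fat_hu_range[1] + u * diff(spec$fat_hu_range)
  par_i <- lab == 1L
  hu[par_i] <- spec$parenchyma_hu_range[1] +
    u[par_i] * diff(spec$parenchyma_hu_range)
  lum_i <- lab == 2L
  if (phase == "native") {
    hu[lum_i] <- spec$urine_hu_range[1] + u[lum_i] * diff(spec$urine_hu_range)
  } else {
    hu[lum_i] <- spec$contrast_lumen_hu
  }
  st_i <- lab == 3L
  if (any(st_i)) hu[st_i] <- sample_stone_hu(1, spec, clip = TRUE)
  dim(hu) <- dim(lab)
  hu <- blur3d(hu, spec$blur_sigma_voxels)
  if (spec$noise_sd_hu > 0) {
    noise <- with_substream(spec$seed, "noise", rnorm(n, 0, spec$noise_sd_hu))
    hu <- hu + noise
  }
  hu <- pmin(pmax(hu, -1024), 3071)
  dim(hu) <- dim(lab)
  ct_volume(hu, spacing = labels$spacing, origin = labels$origin)
}

#' Automatic circle footprints from ground truth
#'
#' Stand-in for the user's clicks: places `k` footprints at interior
#' maxima of the lumen distance transform (greedy, minimum 6 mm apart),
#' each with a radius below the local distance to the lumen boundary.
#' Deterministic for a given ground truth. If fewer than `k` sufficiently
#' separated maxima exist, the available ones are returned with a
#' `shortfall` attribute.
#'
#' @param gt a `pcs_ground_truth` (or a [label_volume()]).
#' @param k number of footprints requested.
#' @param min_separation_mm minimum distance between footprint centres.
#' @return list of [footprint()] objects.
#' @export
auto_footprints <- function(gt, k = 3, min_separation_mm = 6) {
  lv <- if (inherits(gt, "pcs_ground_truth")) gt$labels else gt
  lumen <- lv$labels == 2L
  if (!any(lumen)) stop("nothing to annotate: lumen label is empty")
  D <- distance_transform(lumen, lv$spacing)
  idx <- which(lumen)
  ord <- idx[order(-D[idx], idx)]
  d <- dim(lv$labels)
  picked <- integer(0)
  picked_world <- NULL
  for (v in ord) {
    if (length(picked) >= k) break
    ijk <- arrayInd(v, d) - 1L
    w <- voxel_to_world(lv, ijk[1, ])
    if (!is.null(picked_world)) {
      if (min(sqrt(rowSums(sweep(picked_world, 2, w)^2))) < min_separation_mm)
        next
    }
    picked <- c(picked, v)
    picked_world <- rbind(picked_world, w)
  }
  fps <- lapply(seq_along(picked), function(m) {
    v <- picked[m]
    w <- picked_world[m, ]
    footprint(slice = arrayInd(v, d)[1, 1],
              center = w[2:3],
              radius = max(min(0.9 * D[v], 4), 0.25 * min(lv$spacing[2:3])))
  })
  if (length(fps) < k) {
    warning(sprintf("only %d of %d requested footprints available",
                    length(fps), k))
    attr(fps, "shortfall") <- k - length(fps)
  }
  fps
}

#' Generate a complete phantom study
#'
#' Convenience wrapper: geometry, labels, ground truth and both phase
#' renderings for one spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `geometry`, `labels`, `gt`, `native`, `excretory`.
#' @export
generate_phantom <- function(spec) {
  geom <- sample_pcs_geometry(spec)
  ras <- rasterize_phantom(geom, spec)
  list(
    geometry = geom,
    labels = ras$labels,
    gt = ras$gt,
    native = render_phase(ras$labels, "native", spec),
    excretory = render_phase(ras$labels, "excretory", spec)
  )
}
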