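# segmentation: circle-footprint labelling with an edge-preserving smart
# brush, stone-excluded seed statistics, HU-band region growing with the
# ">15 HU density increase" stopping rule, slice fusion, stone harvesting
# and the classical global-threshold baseline.

#' Circle footprint on an axial slice
#'
#' A user-placed circle annotation: axial slice (1-based array index),
#' centre in mm (`(y, x)` world coordinates) and radius in mm.
#'
#' @param slice 1-based axial slice index.
#' @param center numeric `(y, x)` centre, mm.
#' @param radius radius in mm, > 0.
#' @return an object of class `footprint`.
#' @export
footprint <- function(slice, center, radius) {
  stopifnot(length(center) == 2L, radius > 0)
  structure(list(slice = as.integer(slice), center = as.double(center),
                 radius = as.double(radius)),
            class = "footprint")
}

#' Segmentation configuration
#'
#' Tunable parameters of the footprint-seeded reconstruction.
#' `delta_up` is the density increase above the seed mean that stops
#' expansion (the ">15 HU" rule); `delta_low` bounds the decrease below
#' the mean so perinephric fat cannot leak in. `stone_threshold_hu`
#' separates urine/parenchyma from stone; the smart brush keeps circle
#' voxels within `median +/- brush_mad_k * MAD` of the circle's non-stone
#' densities.
#'
#' @param delta_up HU increase above the seed mean that stops expansion.
#' @param delta_low allowed HU decrease below the seed mean.
#' @param stone_threshold_hu voxels at or above this HU count as stone.
#' @param brush_mad_k MAD multiplier of the smart brush.
#' @param in_slice_connectivity in-slice pixel connectivity (8).
#' @param min_region_voxels components smaller than this are discarded.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(delta_up = 15, delta_low = 20,
                       stone_threshold_hu = 100, brush_mad_k = 3,
                       in_slice_connectivity = 8L,
                       min_region_voxels = 10L) {
  stopifnot(delta_up > 0, delta_low > 0, stone_threshold_hu > 0,
            brush_mad_k > 0, in_slice_connectivity == 8L)
  structure(list(delta_up = delta_up, delta_low = delta_low,
                 stone_threshold_hu = stone_threshold_hu,
                 brush_mad_k = brush_mad_k,
                 in_slice_connectivity = 8L,
                 min_region_voxels = as.integer(min_region_voxels)),
            class = "seg_config")
}

# linear (1-based) indices of the voxel centres inside a footprint circle;
# always includes the voxel containing the centre point
footprint_voxel_idx <- function(vol, fp) {
  d <- vol_dim(vol)
  if (fp$slice < 1 || fp$slice > d[1]) stop("footprint out of bounds")
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  xs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  d2 <- outer((ys - fp$center[1])^2, (xs - fp$center[2])^2, `+`)
  jk <- which(d2 <= fp$radius^2, arr.ind = TRUE)
  cj <- which.min(abs(ys - fp$center[1]))
  ck <- which.min(abs(xs - fp$center[2]))
  if (d2[cj, ck] <= max(vol$spacing[2:3])^2) {
    jk <- rbind(jk, c(cj, ck))
    jk <- jk[!duplicated(jk), , drop = FALSE]
  }
  if (nrow(jk) == 0) stop("footprint out of bounds")
  fp$slice + (jk[, 1] - 1L) * d[1] + (jk[, 2] - 1L) * d[1] * d[2]
}

#' Refine a footprint with the smart brush
#'
#' Keeps the circle voxels whose HU lies within
#' `median +/- brush_mad_k * MAD` of the circle's non-stone densities
#' (edge preservation: a circle straddling lumen and parenchyma drops the
#' minority tissue). Voxels at or above the stone threshold are moved to
#' the excluded set so that a harvested stone never biases the density
#' statistics.
#'
#' @param vol a [ct_volume()].
#' @param fp a [footprint()].
#' @param cfg a [seg_config()].
#' @return an object of class `footprint_label`: `footprint`, `labeled`
#'   and `excluded` linear voxel indices.
#' @export
refine_footprint <- function(vol, fp, cfg = seg_config()) {
  idx <- footprint_voxel_idx(vol, fp)
  hu <- round(vol$voxels[idx])
  is_stone <- hu >= cfg$stone_threshold_hu
  if (all(is_stone)) stop("footprint on stone")
  ns <- hu[!is_stone]
  med <- median(ns)
  mad_ <- median(abs(ns - med))
  keep <- !is_stone & hu >= med - cfg$brush_mad_k * mad_ &
    hu <= med + cfg$brush_mad_k * mad_
  structure(list(footprint = fp,
                 labeled = idx[keep],
                 excluded = idx[is_stone]),
            class = "footprint_label")
}

#' Seed density statistics
#'
#' Arithmetic mean and sd of the HU values over the union of labelled
#' voxels across footprints. Stone-excluded voxels never contribute.
#'
#' @param labels list of [refine_footprint()] results.
#' @param vol the [ct_volume()] the labels refer to.
#' @return an object of class `seed_stats`: `mu`, `sd`, `n_voxels`,
#'   `n_stone_excluded`.
#' @export
seed_statistics <- function(labels, vol) {
  if (inherits(labels, "footprint_label")) labels <- list(labels)
  lab_idx <- unique(unlist(lapply(labels, `[[`, "labeled")))
  if (length(lab_idx) == 0) stop("no seed voxels")
  exc_idx <- unique(unlist(lapply(labels, `[[`, "excluded")))
  vals <- vol$voxels[lab_idx]
  structure(list(mu = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else 0,
                 n_voxels = length(vals),
                 n_stone_excluded = length(exc_idx)),
            class = "seed_stats")
}

new_segmentation_mask <- function(mask, stone, vol, provenance) {
  structure(list(mask = mask, stone = stone,
                 spacing = vol$spacing, origin = vol$origin,
                 provenance = provenance),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d voxels (%.1f mm3), %d stone voxels\n",
              sum(x$mask), sum(x$mask) * prod(x$spacing), sum(x$stone)))
  invisible(x)
}

#' Grow the PCS region from footprint seeds
#'
#' Per axial slice, an 8-connected flood fill from that slice's seed
#' voxels accepts a voxel iff its (integer-rounded) HU lies in
#' `[mu - delta_low, mu + delta_up]`; the segmented area on a slice seeds
#' its neighbours by direct overlap projection until no slice gains
#' voxels. Footprint-labelled voxels are always part of the mask. The
#' result is the single 3-D connected component containing the
#' footprints; components below `min_region_voxels` are discarded first.
#' The outcome does not depend on footprint order.
#'
#' @param vol a [ct_volume()].
#' @param labels list of [refine_footprint()] results (or [footprint()]s,
#'   refined on the fly).
#' @param stats optional [seed_statistics()]; recomputed when `NULL`.
#' @param cfg a [seg_config()].
#' @return a `segmentation_mask`.
#' @export
grow_region <- function(vol, labels, stats = NULL, cfg = seg_config()) {
  if (inherits(labels, "footprint_label")) labels <- list(labels)
  labels <- lapply(labels, function(l) {
    if (inherits(l, "footprint")) refine_footprint(vol, l, cfg) else l
  })
  if (is.null(stats)) stats <- seed_statistics(labels, vol)
  lo <- stats$mu - cfg$delta_low
  hi <- stats$mu + cfg$delta_up
  d <- vol_dim(vol)
  seeds <- sort(unique(unlist(lapply(labels, `[[`, "labeled"))))
  raw <- cpp_region_grow(as.double(vol$voxels), as.integer(d),
                         as.integer(seeds - 1L), lo, hi)
  dim(raw) <- d
  lab3 <- label_components(raw, 26L)
  sizes <- tabulate(lab3[raw])
  keep_big <- which(sizes >= cfg$min_region_voxels)
  seed_comps <- unique(lab3[seeds])
  seed_comps <- seed_comps[seed_comps %in% keep_big]
  if (length(seed_comps) == 0) stop("empty segmentation")
  if (length(seed_comps) > 1) {
    stop("disconnected footprints: seed regions form ",
         length(seed_comps), " separate components")
  }
  mask <- lab3 == seed_comps
  fps <- lapply(labels, `[[`, "footprint")
  new_segmentation_mask(
    mask, array(FALSE, d), vol,
    provenance = list(footprints = fps, stats = stats, config = cfg,
                      algorithm = "pcs3d-region-grow-1")
  )
}

#' Add a footprint to an existing segmentation
#'
#' A footprint whose refined label lies wholly inside the current mask
#' carries no new information: it is a no-op (the seed statistics are not
#' perturbed), which makes redundant clicks exactly idempotent. Any
#' informative footprint triggers a full refine/statistics/grow rerun on
#' the extended footprint set, so the incremental result is bit-identical
#' to segmenting the same footprints in one batch.
#'
#' @param vol a [ct_volume()].
#' @param current the existing `segmentation_mask`.
#' @param new_fp the additional [footprint()].
#' @param cfg a [seg_config()].
#' @return a `segmentation_mask` for the full footprint set.
#' @export
add_footprint <- function(vol, current, new_fp, cfg = seg_config()) {
  lab <- refine_footprint(vol, new_fp, cfg)
  if (all(current$mask[lab$labeled])) {
    return(current)
  }
  fps <- c(current$provenance$footprints, list(new_fp))
  grow_region(vol, fps, stats = NULL, cfg = cfg)
}

#' Harvest stones into the model
#'
#' Every connected component of voxels at or above the stone threshold
#' that is claimed by a footprint circle (the clinical gesture: the stone
#' is situated within a circle footprint) or lies entirely inside the
#' hole-filled mask is added to the mask and recorded in the stone
#' sub-mask. Stone voxels never alter the seed statistics.
#'
#' @param vol a [ct_volume()].
#' @param mask a `segmentation_mask`.
#' @param footprints list of [footprint()]s (defaults to the mask's
#'   provenance footprints).
#' @param cfg a [seg_config()].
#' @return the updated `segmentation_mask`.
#' @export
harvest_stones <- function(vol, mask, footprints = NULL,
                           cfg = seg_config()) {
  if (is.null(footprints)) footprints <- mask$provenance$footprints
  d <- vol_dim(vol)
  cand <- array(round(vol$voxels) >= cfg$stone_threshold_hu, d)
  if (!any(cand)) return(mask)
  circ <- array(FALSE, d)
  for (fp in footprints) {
    circ[footprint_voxel_idx(vol, fp)] <- TRUE
  }
  filled <- fill_holes(mask$mask | circ)
  lab <- label_components(cand, 26L)
  out_mask <- mask$mask
  out_stone <- mask$stone
  for (comp in seq_len(max(lab))) {
    vox <- lab == comp
    claimed <- any(vox & circ) || all(filled[vox])
    if (claimed) {
      out_mask <- out_mask | vox
      out_stone <- out_stone | vox
    }
  }
  # close any residual cavity at the stone site
  if (any(out_stone)) out_mask <- fill_holes(out_mask)
  prov <- mask$provenance
  prov$stones_harvested <- sum(out_stone)
  new_segmentation_mask(out_mask, out_stone,
                        list(spacing = mask$spacing, origin = mask$origin,
                             voxels = NULL),
                        provenance = prov)
}

#' Classical global-threshold segmentation
#'
#' The conventional reconstruction baseline: every voxel with an
#' attenuation at or above the chosen threshold belongs to the model
#' (default +200 HU, suited to bone and urinary stones; lower thresholds
#' reconstruct opacified urine in the excretory phase). With a seed
#' point, only the 3-D connected component containing it is kept.
#'
#' @param vol a [ct_volume()].
#' @param threshold_hu global HU threshold.
#' @param seed_point optional world point `(z, y, x)` in mm.
#' @return a `segmentation_mask`.
#' @export
classical_threshold_segmentation <- function(vol, threshold_hu = 200,
                                             seed_point = NULL) {
  stopifnot(is.finite(threshold_hu))
  d <- vol_dim(vol)
  mask <- array(round(vol$voxels) >= threshold_hu, d)
  if (!any(mask)) stop("empty segmentation")
  if (!is.null(seed_point)) {
    idx <- round(world_to_voxel(vol, seed_point)) + 1
    if (any(idx < 1) || any(idx > d)) stop("seed not in mask")
    if (!mask[idx[1], idx[2], idx[3]]) stop("seed not in mask")
    lab <- label_components(mask, 26L)
    mask <- lab == lab[idx[1], idx[2], idx[3]]
  }
  new_segmentation_mask(
    mask, array(FALSE, d), vol,
    provenance = list(threshold_hu = threshold_hu, seed_point = seed_point,
                      algorithm = "classical-threshold")
  )
}
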