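# Shared fixtures and independent oracles, built in code at test time.

make_ct <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  ct_volume(arr, spacing = spacing, origin = origin)
}

# logical sphere mask of radius r_mm on an isotropic-in-plane grid
sphere_mask <- function(r_mm, spacing_mm, pad_vox = 4) {
  n <- ceiling(2 * r_mm / spacing_mm) + 2 * pad_vox
  co <- (seq_len(n) - (n + 1) / 2) * spacing_mm
  m <- array(outer(outer(co^2, co^2, `+`), co^2, `+`) <= r_mm^2, c(n, n, n))
  attr(m, "coords") <- co
  m
}

shift_arr <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  zs <- seq_len(d[1]) - dz; ys <- seq_len(d[2]) - dy; xs <- seq_len(d[3]) - dx
  okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okx <- xs >= 1 & xs <= d[3]
  out[okz, oky, okx] <- a[zs[okz], ys[oky], xs[okx]]
  out
}

# Independent brute-force oracle for the hybrid region growth: iterate
# one-step expansions (in-slice 8-neighbourhood, face overlap across
# slices) to a fixed point. Seeds are always included; every other voxel
# must have integer-rounded HU inside [lo, hi].
oracle_grow <- function(hu, seeds_idx, lo, hi) {
  d <- dim(hu)
  band <- array(round(hu) >= lo & round(hu) <= hi, d)
  mask <- array(FALSE, d)
  mask[seeds_idx] <- TRUE
  repeat {
    grown <- mask
    for (s in list(c(0, -1, -1), c(0, -1, 0), c(0, -1, 1), c(0, 0, -1),
                   c(0, 0, 1), c(0, 1, -1), c(0, 1, 0), c(0, 1, 1),
                   c(-1, 0, 0), c(1, 0, 0))) {
      grown <- grown | (shift_arr(mask, s[1], s[2], s[3]) & band)
    }
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

# manual footprint label (bypasses the smart brush) for targeted tests
raw_label <- function(fp, labeled_idx, excluded_idx = integer(0)) {
  structure(list(footprint = fp, labeled = labeled_idx,
                 excluded = excluded_idx),
            class = "footprint_label")
}

# bare segmentation_mask around a logical array
as_mask <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  pcs3d:::new_segmentation_mask(arr, array(FALSE, dim(arr)),
                                list(spacing = spacing, origin = origin),
                                provenance = list())
}

path_length <- function(wp) {
  sum(sqrt(rowSums(diff(as.matrix(wp[, c("z", "y", "x")]))^2)))
}
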