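# evaluation: overlap metrics, the normality-gated paired area test and
# the synthetic cohort experiment (contrast vs non-contrast surface area).

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks are defined as
#' identical (Dice 1).
#'
#' @param a,b logical arrays (or `segmentation_mask`s) of equal shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (inherits(a, "segmentation_mask")) a <- a$mask
  if (inherits(b, "segmentation_mask")) b <- b$mask
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Paired comparison of surface areas
#'
#' Shapiro-Wilk on the paired differences decides the branch: normal
#' differences go to a paired t-test, otherwise to the Wilcoxon
#' signed-rank test. Significance at `alpha`.
#'
#' @param areas_a,areas_b paired area vectors (mm^2), equal length >= 3.
#' @param alpha significance level.
#' @return list: `test_used`, `statistic`, `p_value`, `significant`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `shapiro_p`.
#' @export
compare_areas <- function(areas_a, areas_b, alpha = 0.05) {
  stopifnot(length(areas_a) == length(areas_b), length(areas_a) >= 3)
  d <- areas_a - areas_b
  base <- list(mean_a = mean(areas_a), sd_a = sd(areas_a),
               mean_b = mean(areas_b), sd_b = sd(areas_b))
  if (all(d == 0)) {
    return(c(list(test_used = "none", statistic = NA_real_, p_value = NA_real_,
                  significant = FALSE, shapiro_p = NA_real_,
                  note = "no variation"), base))
  }
  if (sd(d) == 0) {
    # constant non-zero shift: normality is undefined, the signed-rank
    # test still applies
    wt <- suppressWarnings(wilcox.test(areas_a, areas_b, paired = TRUE))
    return(c(list(test_used = "wilcoxon", statistic = unname(wt$statistic),
                  p_value = wt$p.value,
                  significant = wt$p.value < alpha, shapiro_p = NA_real_),
             base))
  }
  sw <- shapiro.test(d)
  if (sw$p.value > 0.05) {
    tt <- t.test(areas_a, areas_b, paired = TRUE)
    res <- list(test_used = "t_test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(areas_a, areas_b, paired = TRUE))
    res <- list(test_used = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  c(res, list(significant = res$p_value < alpha, shapiro_p = sw$p.value), base)
}

#' Segment the native phase of one phantom
#'
#' The full non-contrast pipeline on one phantom: automatic footprints,
#' smart-brush refinement, seed statistics, region growing and stone
#' harvesting. Errors (empty lumen, empty segmentation, disconnected
#' footprints) are returned as a failed reconstruction, not raised.
#'
#' @param phantom a [generate_phantom()] result.
#' @param k_footprints number of automatic footprints.
#' @param cfg a [seg_config()].
#' @return list: `mask` (or `NULL`), `footprints`, `error`.
#' @keywords internal
#' @export
segment_native_phantom <- function(phantom, k_footprints = 3,
                                   cfg = seg_config()) {
  res <- tryCatch({
    fps <- suppressWarnings(auto_footprints(phantom$gt, k = k_footprints))
    mask <- grow_region(phantom$native, fps, cfg = cfg)
    mask <- harvest_stones(phantom$native, mask, cfg = cfg)
    list(mask = mask, footprints = fps, error = NA_character_)
  }, error = function(e) {
    list(mask = NULL, footprints = NULL, error = conditionMessage(e))
  })
  res
}

# default excretory threshold: midway between parenchyma and opacified urine
excretory_threshold <- function(spec) {
  (spec$parenchyma_hu_range[2] + spec$contrast_lumen_hu) / 2
}

#' Run the synthetic cohort experiment
#'
#' For each phantom: sample a geometry, render both CTU phases, segment
#' the excretory phase with the classical global threshold (midway
#' between parenchyma and opacified urine) and the native phase with the
#' footprint algorithm, mesh and smooth both models, and record surface
#' areas, Dice against ground truth and reconstruction success. Success
#' means a non-empty native mask with Dice >= 0.5 whose reconstruction
#' reaches every ground-truth calyx tip (the whole-tree criterion).
#' Areas of successful pairs go to [compare_areas()].
#'
#' @param spec_template a [phantom_spec()]; per-phantom seeds are derived
#'   from `seed`.
#' @param n number of phantoms, >= 3.
#' @param seed cohort seed.
#' @param dilation_factor lumen dilation applied to every phantom.
#' @param k_footprints automatic footprints per phantom.
#' @param tip_tolerance_mm a calyx tip counts as reached when mask voxels
#'   exist within this distance.
#' @return an object of class `cohort_result`: `records` (data.frame),
#'   `test` (from [compare_areas()], or `NULL` if < 3 successes), `spec`.
#' @export
run_cohort <- function(spec_template = phantom_spec(), n = 20, seed = 1,
                       dilation_factor = 2.0, k_footprints = 3,
                       tip_tolerance_mm = 3) {
  stopifnot(n >= 3)
  seeds <- with_substream(seed, "cohort",
                          sample.int(2147483646L, n))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- spec_template
    spec$seed <- seeds[i]
    spec$dilation_factor <- dilation_factor
    ph <- generate_phantom(spec)
    gt_lumen <- ph$gt$labels$labels == 2L
    # excretory: classical threshold seeded at the pelvis centre
    exc <- tryCatch(
      classical_threshold_segmentation(ph$excretory,
                                       threshold_hu = excretory_threshold(spec),
                                       seed_point = c(0, 0, 0)),
      error = function(e) NULL
    )
    area_c <- NA_real_
    if (!is.null(exc)) {
      mc <- smooth_mesh(extract_surface(exc))
      area_c <- surface_area(mc)
    }
    seg <- segment_native_phantom(ph, k_footprints = k_footprints)
    area_n <- NA_real_
    dc <- NA_real_
    tips_reached <- NA_integer_
    success <- FALSE
    if (!is.null(seg$mask)) {
      dc <- dice(seg$mask$mask, gt_lumen | (ph$gt$labels$labels == 3L))
      mn <- smooth_mesh(extract_surface(seg$mask))
      area_n <- surface_area(mn)
      tips_reached <- tips_covered(seg$mask, ph$gt$tips, tip_tolerance_mm)
      success <- sum(seg$mask$mask) > 0 && dc >= 0.5 &&
        tips_reached == nrow(ph$gt$tips)
    }
    rec[[i]] <- data.frame(
      phantom = i, seed = seeds[i], dilation_factor = dilation_factor,
      area_contrast = area_c, area_native = area_n,
      dice_native_vs_gt = dc,
      tips_total = if (is.null(ph$gt$tips)) 0L else nrow(ph$gt$tips),
      tips_reached = tips_reached,
      reconstruction_success = success,
      error = seg$error %||% NA_character_
    )
  }
  records <- do.call(rbind, rec)
  ok <- records$reconstruction_success & is.finite(records$area_contrast)
  test <- NULL
  if (sum(ok) >= 3) {
    test <- compare_areas(records$area_contrast[ok], records$area_native[ok])
  }
  structure(list(records = records, test = test, spec = spec_template,
                 seed = seed, dilation_factor = dilation_factor),
            class = "cohort_result")
}

# number of ground-truth calyx tips with mask voxels within tol mm
tips_covered <- function(mask, tips, tol_mm = 3) {
  if (is.null(tips) || nrow(tips) == 0) return(0L)
  d <- dim(mask$mask)
  idx <- which(mask$mask)
  ai <- arrayInd(idx, d)
  W <- cbind(mask$origin[1] + (ai[, 1] - 1) * mask$spacing[1],
             mask$origin[2] + (ai[, 2] - 1) * mask$spacing[2],
             mask$origin[3] + (ai[, 3] - 1) * mask$spacing[3])
  covered <- 0L
  for (t in seq_len(nrow(tips))) {
    d2 <- (W[, 1] - tips[t, 1])^2 + (W[, 2] - tips[t, 2])^2 +
      (W[, 3] - tips[t, 3])^2
    if (min(d2) <= tol_mm^2) covered <- covered + 1L
  }
  covered
}

#' @export
print.cohort_result <- function(x, ...) {
  r <- x$records
  cat(sprintf("<cohort_result> n=%d, dilation=%.2g, success %d/%d\n",
              nrow(r), x$dilation_factor,
              sum(r$reconstruction_success), nrow(r)))
  if (!is.null(x$test)) {
    cat(sprintf(
      "  contrast %.0f +/- %.0f mm2 vs native %.0f +/- %.0f mm2 (%s, P = %.4f)\n",
      x$test$mean_a, x$test$sd_a, x$test$mean_b, x$test$sd_b,
      x$test$test_used, x$test$p_value
    ))
  }
  invisible(x)
}
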