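# Internal helpers shared across modules.

#' Derive a reproducible RNG substream seed
#'
#' Hashes a base seed together with a stream name into a 31-bit integer so
#' that independent parts of the pipeline (geometry, tissue texture, noise,
#' per-phantom cohort streams) draw from distinct but reproducible streams.
#'
#' @param seed base integer seed.
#' @param stream character stream name.
#' @return an integer seed suitable for [set.seed()].
#' @keywords internal
#' @noRd
substream_seed <- function(seed, stream) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# 3-D Gaussian blur of a numeric array, sigma in voxel units.
blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  out <- cpp_gaussian_blur(as.double(arr), as.integer(d), sigma)
  array(out, dim = d)
}

# Euclidean distance (mm) to the nearest background voxel centre.
distance_transform <- function(mask, spacing) {
  d <- dim(mask)
  array(cpp_edt(as.logical(mask), as.integer(d), as.double(spacing)), dim = d)
}

# Connected components (integer labels, 0 = background).
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(cpp_label3d(as.logical(mask), as.integer(d), as.integer(connectivity)),
        dim = d)
}

# Fill internal cavities: background components not touching the array
# border (6-connectivity on the complement) become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  lab <- label_components(!mask, connectivity = 6L)
  border <- unique(c(
    lab[1, , ], lab[d[1], , ],
    lab[, 1, ], lab[, d[2], ],
    lab[, , 1], lab[, , d[3]]
  ))
  border <- border[border > 0]
  cavity <- lab > 0 & !(lab %in% border)
  mask | cavity
}

`%||%` <- function(a, b) if (is.null(a)) b else a
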