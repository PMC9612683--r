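# Minimal DICOM series reader: uncompressed single-frame CT slices,
# explicit or implicit VR little endian. Covers exactly the tags needed to
# assemble an HU volume (geometry, rescale, pixel data). A matching writer
# (internal) exists so the test-suite can build synthetic series on the fly.

DICM_TAGS <- list(
  rows              = c(0x0028, 0x0010),
  cols              = c(0x0028, 0x0011),
  pixel_spacing     = c(0x0028, 0x0030),
  bits_allocated    = c(0x0028, 0x0100),
  pixel_rep         = c(0x0028, 0x0103),
  rescale_intercept = c(0x0028, 0x1052),
  rescale_slope     = c(0x0028, 0x1053),
  ipp               = c(0x0020, 0x0032),
  slice_location    = c(0x0020, 0x1041),
  frame_of_ref      = c(0x0020, 0x0052),
  pixel_data        = c(0x7fe0, 0x0010)
)

read_uint <- function(raw, size) {
  sum(as.double(as.integer(raw[seq_len(size)])) * 256^(seq_len(size) - 1))
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file: ", path)
  }
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw)) {
    group <- read_uint(raw[pos:(pos + 1)], 2)
    elem <- read_uint(raw[(pos + 2):(pos + 3)], 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit) {
      if (vr %in% long_vrs) {
        len <- read_uint(raw[(pos + 8):(pos + 11)], 4)
        hdr <- 12L
      } else {
        len <- read_uint(raw[(pos + 6):(pos + 7)], 2)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- read_uint(raw[(pos + 4):(pos + 7)], 4)
      hdr <- 8L
    }
    value_start <- pos + hdr
    value <- if (len > 0) raw[value_start:(value_start + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr, value = value)
    pos <- value_start + len
  }
  out
}

dicom_value <- function(elems, tag, kind = c("str", "num", "uint16")) {
  kind <- match.arg(kind)
  key <- sprintf("%04x,%04x", tag[1], tag[2])
  el <- elems[[key]]
  if (is.null(el)) return(NULL)
  if (kind == "uint16") return(read_uint(el$value, 2))
  s <- rawToChar(el$value)
  if (kind == "str") return(trimws(s))
  as.double(strsplit(trimws(s), "\\\\")[[1]])
}

read_dicom_slice <- function(path) {
  elems <- parse_dicom_file(path)
  rows <- dicom_value(elems, DICM_TAGS$rows, "uint16")
  cols <- dicom_value(elems, DICM_TAGS$cols, "uint16")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns: ", path)
  bits <- dicom_value(elems, DICM_TAGS$bits_allocated, "uint16") %||% 16
  if (bits != 16) stop("only 16-bit pixel data supported")
  rep_ <- dicom_value(elems, DICM_TAGS$pixel_rep, "uint16") %||% 0
  slope <- dicom_value(elems, DICM_TAGS$rescale_slope, "num") %||% 1
  intercept <- dicom_value(elems, DICM_TAGS$rescale_intercept, "num") %||% 0
  ps <- dicom_value(elems, DICM_TAGS$pixel_spacing, "num") %||% c(1, 1)
  ipp <- dicom_value(elems, DICM_TAGS$ipp, "num")
  zloc <- if (!is.null(ipp) && length(ipp) == 3) {
    ipp[3]
  } else {
    dicom_value(elems, DICM_TAGS$slice_location, "num") %||% 0
  }
  for_uid <- dicom_value(elems, DICM_TAGS$frame_of_ref, "str") %||% ""
  px <- elems[[sprintf("%04x,%04x", DICM_TAGS$pixel_data[1],
                       DICM_TAGS$pixel_data[2])]]
  if (is.null(px)) stop("missing PixelData: ", path)
  stored <- readBin(px$value, "integer", n = rows * cols, size = 2,
                    signed = rep_ == 1, endian = "little")
  hu <- slope * stored + intercept
  list(
    hu = matrix(hu, nrow = rows, ncol = cols, byrow = TRUE),
    spacing_yx = ps, z = zloc, origin_yx = if (!is.null(ipp)) {
      c(ipp[2], ipp[1])
    } else {
      c(0, 0)
    },
    frame_of_ref = for_uid
  )
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("inconsistent series: no files in ", dir)
  slices <- lapply(files, read_dicom_slice)
  fors <- vapply(slices, `[[`, "", "frame_of_ref")
  dims <- vapply(slices, function(s) dim(s$hu), integer(2))
  sp <- vapply(slices, function(s) s$spacing_yx, double(2))
  if (length(unique(fors)) > 1 || nrow(unique(t(dims))) > 1 ||
      max(abs(sweep(sp, 1, sp[, 1]))) > 1e-6) {
    stop("inconsistent series")
  }
  z <- vapply(slices, `[[`, 0, "z")
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  nz <- length(slices)
  dz <- if (nz > 1) {
    steps <- diff(z)
    if (max(steps) - min(steps) > 1e-3) stop("inconsistent series: uneven z")
    mean(steps)
  } else {
    1
  }
  arr <- array(0, c(nz, nrow(slices[[1]]$hu), ncol(slices[[1]]$hu)))
  for (i in seq_len(nz)) arr[i, , ] <- slices[[i]]$hu
  ct_volume(arr,
            spacing = c(dz, slices[[1]]$spacing_yx),
            origin = c(z[1], slices[[1]]$origin_yx))
}

# --- internal writer (test fixtures only) ----------------------------------

uint_bytes <- function(x, size) {
  as.raw((floor(x / 256^(seq_len(size) - 1))) %% 256)
}

dicom_element <- function(group, elem, vr, value_raw) {
  head <- c(uint_bytes(group, 2), uint_bytes(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), uint_bytes(length(value_raw), 4), value_raw)
  } else {
    c(head, uint_bytes(length(value_raw), 2), value_raw)
  }
}

ds_raw <- function(x) {
  s <- paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\")
  if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
  charToRaw(s)
}

write_dicom_slice <- function(path, hu, spacing_yx, ipp_xyz,
                              slope = 1, intercept = -1024,
                              frame_of_ref = "1.2.3.4") {
  stored <- round((hu - intercept) / slope)
  stopifnot(all(stored >= 0 & stored <= 65535))
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  for_uid <- frame_of_ref
  if (nchar(for_uid) %% 2 == 1) for_uid <- paste0(for_uid, " ")
  body <- c(
    dicom_element(0x0020, 0x0032, "DS", ds_raw(ipp_xyz)),
    dicom_element(0x0020, 0x0052, "UI", charToRaw(for_uid)),
    dicom_element(0x0028, 0x0010, "US", uint_bytes(nrow(hu), 2)),
    dicom_element(0x0028, 0x0011, "US", uint_bytes(ncol(hu), 2)),
    dicom_element(0x0028, 0x0030, "DS", ds_raw(spacing_yx)),
    dicom_element(0x0028, 0x0100, "US", uint_bytes(16, 2)),
    dicom_element(0x0028, 0x0103, "US", uint_bytes(0, 2)),
    dicom_element(0x0028, 0x1052, "DS", ds_raw(intercept)),
    dicom_element(0x0028, 0x1053, "DS", ds_raw(slope)),
    dicom_element(0x7fe0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}
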