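# Minimal single-frame DICOM support: explicit VR little endian only, the
# profile this package itself writes. Covers exactly the attributes the
# volumetry pipeline needs (geometry, series identity, 16-bit pixel data);
# multi-frame/enhanced DICOM and other transfer syntaxes are out of scope.

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16_bytes <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(uint16_bytes(group), uint16_bytes(element), charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    if (length(value_raw) > 65534) stop("value too long for short VR")
    c(hdr, uint16_bytes(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, element, vr, text) {
  dcm_element(group, element, vr, charToRaw(paste(text, collapse = "\\")))
}
dcm_us <- function(group, element, value) {
  dcm_element(group, element, "US", uint16_bytes(value))
}
dcm_ds <- function(group, element, values) {
  dcm_str(group, element, "DS", format(values, digits = 10, trim = TRUE))
}

#' Write an image volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian file per coronal slice, with pixel spacing,
#' slice thickness, series UID and per-slice patient position, so the series
#' can be read back with [read_dicom_series()]. Pixel data are stored as
#' unsigned 16-bit integers; voxel values must already be integers in
#' \[0, 65535\].
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if needed).
#' @param series_uid series instance UID; defaults to a fixed-root UID derived
#'   from the volume's `source_id` so identical volumes give identical files.
#' @return invisibly, the file paths written.
#' @export
write_dicom_series <- function(vol, dir, series_uid = NULL) {
  stopifnot(is_image_volume(vol))
  v <- vol$voxels
  if (any(v != round(v)) || min(v) < 0 || max(v) > 65535)
    stop("DICOM writer stores unsigned 16-bit integers; rescale/round first")
  if (is.null(series_uid))
    series_uid <- paste0("1.2.826.0.1.999999.",
                         sum(utf8ToInt(vol$source_id)) %% 99999L, ".1")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nk <- n_coronal(vol)
  paths <- character(nk)
  for (k in seq_len(nk)) {
    sl <- coronal_slice(vol, k)
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = dim(vol$voxels)[axis_dim(vol, "sagittal")])
    rows <- nrow(sl); cols <- ncol(sl)
    pix <- uint16_bytes(as.integer(round(as.vector(t(sl)))))
    meta <- c(
      dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      dcm_str(0x0002, 0x0003, "UI", paste0(series_uid, ".", k)),
      dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4, endian = "little")),
              meta)
    body <- c(
      dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      dcm_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      dcm_ds(0x0018, 0x0050, vol$slice_thickness),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      dcm_ds(0x0020, 0x0032, c(0, -(k - 1) * vol$slice_thickness, 0)),
      dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 0, 1)),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, rows),
      dcm_us(0x0028, 0x0011, cols),
      dcm_ds(0x0028, 0x0030, vol$spacing_inplane),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 0L),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(paths)
}

# parse one explicit-VR little-endian single-frame file into a tag list
read_dicom_file <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 132 || rawToChar(buf[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path))
  pos <- 133L
  tags <- list()
  n <- length(buf)
  u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("'%s': unsupported transfer syntax (implicit VR?)", path))
    if (vr %in% DCM_LONG_VRS) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (vstart + len - 1L > n) stop(sprintf("'%s': truncated DICOM element", path))
    key <- sprintf("%04X,%04X", group, element)
    val <- buf[seq.int(vstart, length.out = len)]
    tags[[key]] <- list(vr = vr, raw = val)
    pos <- vstart + len
  }
  tags
}

dcm_get_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  s <- rawToChar(t$raw[t$raw != as.raw(0)])
  trimws(s)
}
dcm_get_num <- function(tags, key) {
  s <- dcm_get_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_get_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$raw, "integer", n = length(t$raw) / 2, size = 2,
          signed = FALSE, endian = "little")
}

#' Read a single-frame DICOM series into an image volume
#'
#' All files in `dir` must belong to one series (one coronal slice each).
#' Slices are sorted by the projection of the image position onto the slice
#' normal (falling back to instance number when positions are absent).
#' Missing or zero pixel-spacing / slice-thickness tags are an error, never a
#' silent default. A rescale slope/intercept pair, when present, is applied
#' exactly once.
#'
#' @param dir directory containing the series.
#' @return an [image_volume()] in canonical (sagittal, coronal, axial) order.
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: '%s'", dir))
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop(sprintf("empty DICOM directory: '%s'", dir))
  parsed <- lapply(files, read_dicom_file)

  series <- vapply(parsed, function(t) {
    s <- dcm_get_str(t, "0020,000E"); if (is.null(s)) "" else s
  }, character(1))
  if (length(unique(series)) > 1)
    stop("directory mixes multiple DICOM series: ",
         paste(unique(series), collapse = ", "))

  spacing <- dcm_get_num(parsed[[1]], "0028,0030")
  if (is.null(spacing) || length(spacing) != 2 || any(spacing <= 0))
    stop("PixelSpacing (0028,0030) missing or non-positive; refusing to guess")
  thickness <- dcm_get_num(parsed[[1]], "0018,0050")
  if (is.null(thickness) || thickness <= 0)
    stop("SliceThickness (0018,0050) missing or non-positive; refusing to guess")
  between <- dcm_get_num(parsed[[1]], "0018,0088")
  if (!is.null(between) && abs(between - thickness) > 1e-6) {
    warning(sprintf(paste0("nonzero slice gap: spacing between slices %.4g mm != ",
                           "thickness %.4g mm; using spacing between slices for volumetry"),
                    between, thickness))
    thickness <- between
  }

  orient <- dcm_get_num(parsed[[1]], "0020,0037")
  if (is.null(orient)) orient <- c(1, 0, 0, 0, 0, 1)
  normal <- c(orient[2] * orient[6] - orient[3] * orient[5],
              orient[3] * orient[4] - orient[1] * orient[6],
              orient[1] * orient[5] - orient[2] * orient[4])
  key <- vapply(seq_along(parsed), function(i) {
    pos <- dcm_get_num(parsed[[i]], "0020,0032")
    if (!is.null(pos) && length(pos) == 3) sum(pos * normal)
    else {
      inst <- dcm_get_num(parsed[[i]], "0020,0013")
      if (is.null(inst)) i else inst
    }
  }, numeric(1))
  parsed <- parsed[order(key)]

  slices <- lapply(parsed, function(t) {
    rows <- dcm_get_us(t, "0028,0010"); cols <- dcm_get_us(t, "0028,0011")
    if (is.null(rows) || is.null(cols)) stop("Rows/Columns tags missing")
    bits <- dcm_get_us(t, "0028,0100")
    if (!is.null(bits) && bits != 16) stop("only 16-bit pixel data supported")
    pd <- t[["7FE0,0010"]]
    if (is.null(pd)) stop("PixelData (7FE0,0010) missing")
    v <- readBin(pd$raw, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
    m <- t(matrix(v, nrow = cols, ncol = rows))
    slope <- dcm_get_num(t, "0028,1053"); icpt <- dcm_get_num(t, "0028,1052")
    if (!is.null(slope) || !is.null(icpt)) {
      if (is.null(slope)) slope <- 1
      if (is.null(icpt)) icpt <- 0
      m <- m * slope + icpt
    }
    m
  })
  d1 <- nrow(slices[[1]]); d3 <- ncol(slices[[1]])
  if (!all(vapply(slices, function(m) nrow(m) == d1 && ncol(m) == d3, logical(1))))
    stop("slices in the series have inconsistent matrix sizes")
  vox <- array(0, dim = c(d1, length(slices), d3))
  for (k in seq_along(slices)) vox[, k, ] <- slices[[k]]
  image_volume(vox, spacing_inplane = spacing, slice_thickness = thickness,
               source_id = if (nzchar(series[1])) series[1] else "dicom")
}
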