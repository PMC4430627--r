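#' Read a volume from disk
#'
#' Supported containers:
#' * MetaImage (`.mhd` + raw): the canonical interchange format — explicit
#'   spacing and origin, bit-exact round trips;
#' * multi-page TIFF (`.tif`/`.tiff`): grey stack; carries no physical
#'   spacing, so `spacing` must be supplied;
#' * DICOM series (a directory of `.dcm` slices): slices are ordered by
#'   their z position regardless of file naming; spacing is converted from
#'   millimetres to micrometres and must be consistent across the series.
#'
#' @param path File (`.mhd`, `.tif`) or DICOM directory.
#' @param spacing Voxel size in µm; required for TIFF, ignored otherwise.
#' @return A [grey_volume()] or (for 8-bit MetaImage label data) a
#'   [label_volume()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (dir.exists(path)) return(read_dicom_series(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") return(read_metaimage(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff_stack(path, spacing))
  stop("unsupported volume format: ", path)
}

#' Write a volume to disk
#'
#' MetaImage (`.mhd`/`.raw`) or multi-page TIFF by extension, or a DICOM
#' series when `path` has no extension (treated as a directory). MetaImage
#' stores grey data as 64-bit floats (bit-exact round trip) and labels as
#' unsigned bytes.
#'
#' @param vol A [grey_volume()] or [label_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") return(write_metaimage(vol, path))
  if (ext %in% c("tif", "tiff")) return(write_tiff_stack(vol, path))
  if (ext == "") return(write_dicom_series(vol, path))
  stop("unsupported volume format: ", path)
}

# ---- MetaImage ------------------------------------------------------------

write_metaimage <- function(vol, path) {
  is_label <- inherits(vol, "label_volume")
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(vol$data)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(rep(vol$spacing, 3), collapse = " ")),
           paste("Offset =", paste(vol$origin, collapse = " ")),
           paste("ElementType =", if (is_label) "MET_UCHAR" else "MET_DOUBLE"),
           paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (is_label)
    writeBin(as.raw(as.integer(vol$data)), con)
  else
    writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  if (max(sp) - min(sp) > 1e-9 * max(sp))
    stop("anisotropic spacing not supported")
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  etype <- get("ElementType")
  msb <- identical(get("BinaryDataByteOrderMSB", "False"), "True")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  endian <- if (msb) "big" else "little"
  data <- switch(etype,
    MET_UCHAR = as.integer(readBin(con, "raw", n)),
    MET_SHORT = readBin(con, "integer", n, size = 2, signed = TRUE,
                        endian = endian),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = endian),
    MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = endian),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported ElementType: ", etype))
  arr <- array(data, dim = d)
  if (etype == "MET_UCHAR" && all(arr <= 3))
    label_volume(arr, spacing = sp[1], origin = origin)
  else grey_volume(arr, spacing = sp[1], origin = origin)
}

# ---- TIFF -----------------------------------------------------------------

# TIFF stores 32-bit floats clamped to [0, 1]; grey values are rescaled to
# that range on write and the range + spacing recorded in a JSON sidecar
# (<path>.json), used to undo the scaling on read when present.
write_tiff_stack <- function(vol, path) {
  d <- dim(vol$data)
  rng <- range(vol$data)
  scl <- if (diff(rng) > 0) diff(rng) else 1
  slices <- lapply(seq_len(d[3]), function(k) (vol$data[, , k] - rng[1]) / scl)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(grey_min = rng[1], grey_max = rng[2],
                            spacing_um = vol$spacing, origin_um = vol$origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tiff_stack <- function(path, spacing = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(slices)) slices <- list(slices)
  d <- dim(slices[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  side <- paste0(path, ".json")
  origin <- c(0, 0, 0)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    arr <- arr * (meta$grey_max - meta$grey_min) + meta$grey_min
    if (is.null(spacing)) spacing <- meta$spacing_um
    origin <- meta$origin_um
  }
  if (is.null(spacing))
    stop("TIFF stacks carry no spacing metadata; supply `spacing` (µm)")
  grey_volume(arr, spacing = spacing, origin = origin)
}

# ---- DICOM (minimal explicit-VR little-endian reader/writer) --------------
# No DICOM package exists in this R installation, so a narrowly scoped
# reader/writer is provided: uncompressed monochrome 16-bit slices, explicit
# VR little endian, one file per slice. Enough for series exported by
# reconstruction software and for round-tripping this package's own output.

dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2 == 1) {
    value_raw <- c(value_raw, as.raw(if (vr == "UI") 0 else 32))
    len <- len + 1
  }
  head <- writeBin(c(group, elem), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4, endian = "little"), value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(len), raw(), size = 2, endian = "little"), value_raw)
  }
}

dcm_str <- function(x) charToRaw(as.character(x))
dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

write_dicom_series <- function(vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$data)
  sp_mm <- vol$spacing / 1000
  for (k in seq_len(d[3])) {
    # 16-bit unsigned storage: values are rounded and clipped to [0, 65535]
    px <- round(vol$data[, , k])
    px[px < 0] <- 0; px[px > 65535] <- 65535
    z_mm <- (vol$origin[3] + (k - 1) * vol$spacing) / 1000
    body <- c(
      dcm_element(0x0018L, 0x0050L, "DS", dcm_str(format(sp_mm))),
      dcm_element(0x0020L, 0x0013L, "IS", dcm_str(k)),
      dcm_element(0x0020L, 0x0032L, "DS",
                  dcm_str(sprintf("%s\\%s\\%s", format(vol$origin[1] / 1000),
                                  format(vol$origin[2] / 1000), format(z_mm)))),
      dcm_element(0x0020L, 0x1041L, "DS", dcm_str(format(z_mm))),
      dcm_element(0x0028L, 0x0002L, "US", dcm_us(1)),
      dcm_element(0x0028L, 0x0010L, "US", dcm_us(d[1])),
      dcm_element(0x0028L, 0x0011L, "US", dcm_us(d[2])),
      dcm_element(0x0028L, 0x0030L, "DS",
                  dcm_str(sprintf("%s\\%s", format(sp_mm), format(sp_mm)))),
      dcm_element(0x0028L, 0x0100L, "US", dcm_us(16)),
      dcm_element(0x0028L, 0x0101L, "US", dcm_us(16)),
      dcm_element(0x0028L, 0x0102L, "US", dcm_us(15)),
      dcm_element(0x0028L, 0x0103L, "US", dcm_us(0)),
      dcm_element(0x7FE0L, 0x0010L, "OW",
                  writeBin(as.integer(px), raw(), size = 2, endian = "little")))
    ts <- charToRaw("1.2.840.10008.1.2.1")
    meta <- dcm_element(0x0002L, 0x0010L, "UI", ts)
    meta <- c(dcm_element(0x0002L, 0x0000L, "UL",
                          writeBin(length(meta), raw(), size = 4,
                                   endian = "little")), meta)
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

read_dicom_slice <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128)
  if (rawToChar(readBin(con, "raw", 4)) != "DICM")
    stop("not a DICOM file: ", path)
  tags <- list()
  repeat {
    hdr <- readBin(con, "raw", 4)
    if (length(hdr) < 4) break
    group <- readBin(hdr[1:2], "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    elem <- readBin(hdr[3:4], "integer", 1, size = 2, signed = FALSE,
                    endian = "little")
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    val <- readBin(con, "raw", len)
    tags[[sprintf("%04x,%04x", group, elem)]] <- list(vr = vr, raw = val)
    if (seek(con, where = NA) >= sz) break
  }
  num <- function(tag) as.numeric(strsplit(trimws(rawToChar(tags[[tag]]$raw)),
                                           "\\\\")[[1]])
  us <- function(tag) readBin(tags[[tag]]$raw, "integer", 1, size = 2,
                              signed = FALSE, endian = "little")
  rows <- us("0028,0010"); cols <- us("0028,0011")
  px_sp <- num("0028,0030")
  pos <- if (!is.null(tags[["0020,0032"]])) num("0020,0032")
  else c(0, 0, num("0020,1041"))
  pix <- readBin(tags[["7fe0,0010"]]$raw, "integer", rows * cols, size = 2,
                 signed = FALSE, endian = "little")
  list(data = matrix(pix, nrow = rows, ncol = cols), pixel_spacing = px_sp,
       position = pos)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", dir)
  slices <- lapply(files, read_dicom_slice)
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  sp_mm <- unique(round(unlist(lapply(slices, `[[`, "pixel_spacing")), 9))
  if (length(sp_mm) != 1) stop("inconsistent in-plane spacing across series")
  if (length(z) > 1) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-6 || abs(mean(dz) - sp_mm) > 1e-6)
      stop("inconsistent or anisotropic slice spacing across series")
  }
  d <- dim(slices[[1]]$data)
  arr <- array(0, dim = c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$data
  origin <- slices[[1]]$position * 1000
  grey_volume(arr, spacing = sp_mm * 1000, origin = origin)
}
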