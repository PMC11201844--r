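#' Read a CT volume from NIfTI, NRRD, or a DICOM series directory
#'
#' Intensities are returned in Hounsfield units (the DICOM rescale
#' slope/intercept is applied on read). Geometry is normalized so that axes
#' are axis-aligned with positive spacing; the internal axis order is
#' (z, y, x). Volumes with any spacing component above 1.5 mm trigger a
#' thick-slice warning, since the downstream pipeline assumes thin-slice
#' acquisitions resampled to 1 mm.
#'
#' @param path File path (`.nii`, `.nii.gz`, `.nrrd`) or a directory holding
#'   one DICOM file per slice.
#' @param format One of `"nifti"`, `"nrrd"`, `"dicom_dir"`; guessed from the
#'   path when omitted.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else "nifti"
  }
  if (format == "dicom_dir") {
    if (!dir.exists(path)) stop(sprintf("read_volume: directory not found: %s", path))
  } else if (!file.exists(path)) {
    stop(sprintf("read_volume: file not found: %s", path))
  }
  vol <- switch(format,
                nifti = read_nifti_volume(path),
                nrrd = read_nrrd_volume(path),
                dicom_dir = read_dicom_series(path))
  if (any(vol$spacing > 1.5))
    warning(sprintf("read_volume: spacing %s mm exceeds 1.5 mm; thin-slice input is assumed",
                    paste(format(vol$spacing, digits = 3), collapse = "x")))
  vol
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' HU volumes are stored as 64-bit floats so a read/write round trip is
#' bit-exact; masks are stored as unsigned 8-bit with values 0/1.
#'
#' @param x An [image_volume()] or [binary_mask()].
#' @param path Output path; `.nrrd` selects NRRD, anything else NIfTI.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) write_nrrd_volume(x, path)
  else write_nifti_volume(x, path)
  invisible(path)
}

## ---- NIfTI (via RNifti) ----

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("read_volume: cannot parse '%s' as NIfTI: %s",
                                                   path, conditionMessage(e))))
  if (length(dim(img)) != 3L)
    stop("read_volume: only 3D NIfTI volumes are supported")
  xf <- RNifti::xform(img)
  lin <- xf[1:3, 1:3]
  # normalize orientation: detect the axis permutation/flip; oblique terms
  # beyond 1% of the voxel size are dropped with a warning
  perm <- apply(abs(lin), 2, which.max)
  if (length(unique(perm)) != 3L) {
    warning("read_volume: degenerate orientation matrix; assuming identity")
    perm <- 1:3
    lin <- diag(as.numeric(RNifti::pixdim(img)))
  }
  off <- abs(lin)
  for (j in 1:3) off[perm[j], j] <- 0
  if (any(off > 0.01 * max(abs(lin))))
    warning("read_volume: oblique orientation approximated by the nearest axis-aligned grid")
  dat <- as.array(img)                      # (x, y, z) storage order
  spac <- sqrt(colSums(lin^2))              # voxel sizes from the xform columns
  if (any(spac <= 0)) spac <- abs(as.numeric(RNifti::pixdim(img))[1:3])
  orig <- xf[1:3, 4]
  # flip axes with negative direction so all spacings are positive
  for (j in 1:3) {
    if (lin[perm[j], j] < 0) {
      dat <- flip_axis(dat, j)
      orig[perm[j]] <- orig[perm[j]] + lin[perm[j], j] * (dim(dat)[j] - 1)
    }
  }
  # reorder storage axes so storage axis j measures world axis perm[j];
  # we want world axes in (x, y, z) order then transpose to (z, y, x)
  ord <- order(perm)
  dat <- aperm(dat, ord)
  spac <- spac[ord]
  image_volume(aperm(dat, c(3, 2, 1)), rev(spac), rev(orig[c(1, 2, 3)]))
}

flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- dim(a)[axis]:1
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

write_nifti_volume <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  dat <- aperm(if (is_mask) x$data * 1 else x$data, c(3, 2, 1)) # back to (x, y, z)
  sp <- rev(x$spacing)
  or <- rev(x$origin)
  img <- RNifti::asNifti(dat, datatype = if (is_mask) "uint8" else "double",
                         pixdim = sp)
  aff <- diag(4)
  diag(aff)[1:3] <- sp
  aff[1:3, 4] <- or
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

## ---- NRRD (minimal reader/writer: raw and gzip encodings) ----

nrrd_type_map <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "numeric", size = 4, signed = TRUE),
  "double" = list(what = "numeric", size = 8, signed = TRUE))

read_nrrd_volume <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw_all == as.raw(10L))
  # header ends at the first blank line
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L || (p == prev + 2L && raw_all[p - 1L] == as.raw(13L))) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("read_volume: malformed NRRD header (no blank line)")
  hdr <- strsplit(rawToChar(raw_all[1:hdr_end]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("read_volume: not an NRRD file")
  fields <- list()
  for (line in hdr[-1]) {
    if (!nzchar(line) || startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (!identical(dim_n, 3L)) stop("read_volume: only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- tolower(fields[["type"]])
  tinfo <- nrrd_type_map[[type]]
  if (is.null(tinfo)) stop(sprintf("read_volume: unsupported NRRD type '%s'", type))
  enc <- tolower(fields[["encoding"]])
  if (!is.null(fields[["endian"]]) && tolower(fields[["endian"]]) != "little" && tinfo$size > 1)
    stop("read_volume: only little-endian NRRD data is supported")
  spac <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spac <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]], gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]),
                  numeric(3)))
    spac <- sqrt(rowSums(m^2))
  }
  orig <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    orig <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (identical(enc, "gzip") || identical(enc, "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (!identical(enc, "raw")) stop(sprintf("read_volume: unsupported NRRD encoding '%s'", enc))
  n <- prod(sizes)
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = "little")
  # NRRD stores the first size fastest; interpret axes as (x, y, z)
  dat <- array(as.numeric(vals), sizes)
  image_volume(aperm(dat, c(3, 2, 1)), rev(spac), rev(orig))
}

write_nrrd_volume <- function(x, path, encoding = "gzip") {
  is_mask <- inherits(x, "binary_mask")
  dat <- aperm(if (is_mask) x$data * 1L else x$data, c(3, 2, 1))
  type <- if (is_mask) "uint8" else "double"
  size <- if (is_mask) 1L else 8L
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(dat), collapse = " ")),
           sprintf("spacings: %s", paste(format(rev(x$spacing), digits = 17), collapse = " ")),
           sprintf("space origin: (%s)", paste(format(rev(x$origin), digits = 17), collapse = ",")),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  payload <- writeBin(if (is_mask) as.integer(dat) else as.numeric(dat),
                      raw(), size = size, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}

## ---- DICOM series (minimal little-endian reader + test writer) ----

dcm_read_u16 <- function(r, off) as.integer(r[off]) + 256L * as.integer(r[off + 1L])
dcm_read_u32 <- function(r, off) {
  as.numeric(r[off]) + 256 * as.numeric(r[off + 1L]) +
    65536 * as.numeric(r[off + 2L]) + 16777216 * as.numeric(r[off + 3L])
}

# Parse one DICOM file, returning the tags the pipeline needs.
parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("read_volume: '%s' is not a DICOM file", path))
  pos <- 133L
  explicit <- TRUE
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(r)) {
    grp <- dcm_read_u16(r, pos)
    ele <- dcm_read_u16(r, pos + 2L)
    pos <- pos + 4L
    vr <- rawToChar(r[pos:(pos + 1L)])
    is_vr <- grepl("^[A-Z]{2}$", vr)
    if (explicit && is_vr) {
      if (vr %in% long_vrs) {
        len <- dcm_read_u32(r, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- dcm_read_u16(r, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      len <- dcm_read_u32(r, pos)
      pos <- pos + 4L
      vr <- ""
    }
    if (len > length(r)) stop("read_volume: truncated DICOM element")
    val <- r[pos:(pos + len - 1L)]
    pos <- pos + len
    key <- sprintf("%04x,%04x", grp, ele)
    out[[key]] <- list(vr = vr, bytes = val)
    if (grp == 0x7fe0 && ele == 0x0010) break
  }
  out
}

dcm_str <- function(el) if (is.null(el)) NULL else trimws(rawToChar(el$bytes))
dcm_nums <- function(el) if (is.null(el)) NULL else as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
dcm_u16val <- function(el) if (is.null(el)) NULL else dcm_read_u16(el$bytes, 1L)

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("read_volume: empty DICOM directory")
  slices <- lapply(sort(files), function(f) {
    el <- parse_dicom_file(f)
    rows <- dcm_u16val(el[["0028,0010"]])
    cols <- dcm_u16val(el[["0028,0011"]])
    if (is.null(rows) || is.null(cols))
      stop(sprintf("read_volume: '%s' lacks Rows/Columns", f))
    ps <- dcm_nums(el[["0028,0030"]])
    ipp <- dcm_nums(el[["0020,0032"]])
    slope <- dcm_nums(el[["0028,1053"]])
    icept <- dcm_nums(el[["0028,1052"]])
    bits <- dcm_u16val(el[["0028,0100"]])
    pixrep <- dcm_u16val(el[["0028,0103"]])
    px <- el[["7fe0,0010"]]
    if (is.null(px)) stop(sprintf("read_volume: '%s' lacks PixelData", f))
    if (is.null(bits) || !(bits %in% c(8L, 16L)))
      stop("read_volume: only 8/16-bit DICOM pixel data is supported")
    vals <- readBin(px$bytes, "integer", n = rows * cols, size = bits / 8L,
                    signed = !is.null(pixrep) && pixrep == 1L, endian = "little")
    if (bits == 8L) vals <- as.integer(vals) # readBin signed=FALSE handled above
    hu <- vals * (if (is.null(slope)) 1 else slope[1]) +
      (if (is.null(icept)) 0 else icept[1])
    list(img = matrix(hu, nrow = cols, ncol = rows),   # column index fastest = x
         ps = if (is.null(ps)) c(1, 1) else ps,
         z = if (is.null(ipp)) NA_real_ else ipp[3],
         origin_xy = if (is.null(ipp)) c(0, 0) else ipp[1:2])
  })
  zs <- vapply(slices, `[[`, numeric(1), "z")
  if (anyNA(zs)) zs <- seq_along(slices)
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (any(abs(dz - dz[1]) > 0.01 * abs(dz[1]) + 1e-6))
      stop("read_volume: inconsistent DICOM slice spacing")
    slice_sp <- abs(dz[1])
  } else slice_sp <- 1
  ps <- slices[[1]]$ps              # (row spacing = y, col spacing = x)
  nx <- nrow(slices[[1]]$img)
  ny <- ncol(slices[[1]]$img)
  dat <- array(NA_real_, c(length(slices), ny, nx))  # (z, y, x)
  for (i in seq_along(slices)) dat[i, , ] <- t(slices[[i]]$img)
  image_volume(dat,
               spacing = c(slice_sp, ps[1], ps[2]),
               origin = c(zs[1], slices[[1]]$origin_xy[2], slices[[1]]$origin_xy[1]))
}

# Minimal single-slice CT DICOM writer (explicit VR little endian); used to
# build test fixtures and small synthetic series.
write_dicom_slice <- function(img_yx, path, z_position, pixel_spacing = c(1, 1),
                              slope = 1, intercept = -1024) {
  stored <- round((img_yx - intercept) / slope)
  if (any(stored < 0 | stored > 65535)) stop("write_dicom_slice: stored values out of uint16 range")
  el <- function(grp, ele, vr, bytes) {
    if (length(bytes) %% 2L == 1L)
      bytes <- c(bytes, if (vr %in% c("UI")) as.raw(0L) else charToRaw(" "))
    head <- writeBin(c(as.integer(grp), as.integer(ele)), raw(), size = 2, endian = "little")
    if (vr %in% c("OB", "OW")) {
      c(head, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(bytes), raw(), size = 4, endian = "little"), bytes)
    } else {
      c(head, charToRaw(vr),
        writeBin(length(bytes), raw(), size = 2, endian = "little"), bytes)
    }
  }
  s <- function(x) charToRaw(as.character(x))
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  rows <- nrow(img_yx); cols <- ncol(img_yx)
  # pixel data: x fastest within each row (DICOM row-major: row = y)
  stored_vec <- as.integer(t(stored))  # row-major
  px <- writeBin(stored_vec, raw(), size = 2, endian = "little")
  body <- c(
    el(0x0008, 0x0060, "CS", s("CT")),
    el(0x0020, 0x0032, "DS", s(sprintf("0\\0\\%g", z_position))),
    el(0x0020, 0x0037, "DS", s("1\\0\\0\\0\\1\\0")),
    el(0x0028, 0x0002, "US", u16(1)),
    el(0x0028, 0x0010, "US", u16(rows)),
    el(0x0028, 0x0011, "US", u16(cols)),
    el(0x0028, 0x0030, "DS", s(sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))),
    el(0x0028, 0x0100, "US", u16(16)),
    el(0x0028, 0x0101, "US", u16(16)),
    el(0x0028, 0x0102, "US", u16(15)),
    el(0x0028, 0x0103, "US", u16(0)),
    el(0x0028, 0x1052, "DS", s(sprintf("%g", intercept))),
    el(0x0028, 0x1053, "DS", s(sprintf("%g", slope))),
    el(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
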