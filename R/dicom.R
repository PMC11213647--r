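# Minimal DICOM image-slice I/O: Explicit VR Little Endian, one single-frame
# secondary-capture-style file per axial slice, carrying the tags the
# ImageGrid contract needs (geometry, rescale, pixel data). Not a general
# DICOM implementation: well-formed Explicit-VR-LE axial series only.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SC_CLASS <- "1.2.840.10008.5.1.4.1.1.7"

dcmUID <- function(suffix) {
  # deterministic private-root UID from a numeric suffix
  paste0("1.2.826.0.1.3680043.9.7435.", suffix)
}

dcmPad <- function(raw) if (length(raw) %% 2 == 1) c(raw, as.raw(0)) else raw

dcmElement <- function(group, element, vr, value) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                   endian = "little")
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH", "DA", "TM")) {
    val <- charToRaw(value)
    if (length(val) %% 2 == 1)
      val <- c(val, if (vr == "UI") as.raw(0) else charToRaw(" "))
    len <- writeBin(as.integer(length(val)), raw(), size = 2,
                    endian = "little")
    c(head, charToRaw(vr), len, val)
  } else if (vr == "US") {
    val <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
    len <- writeBin(as.integer(length(val)), raw(), size = 2,
                    endian = "little")
    c(head, charToRaw(vr), len, val)
  } else if (vr == "UL") {
    val <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
    len <- writeBin(as.integer(length(val)), raw(), size = 2,
                    endian = "little")
    c(head, charToRaw(vr), len, val)
  } else if (vr %in% c("OB", "OW")) {
    val <- value  # already raw
    len <- writeBin(as.integer(length(val)), raw(), size = 4,
                    endian = "little")
    c(head, charToRaw(vr), as.raw(c(0, 0)), len, val)
  } else stop("unsupported VR ", vr)
}

dcmDS <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

# Encode one slice matrix (rows x cols, numeric) as raw pixel data.
# Integer-valued data: 16- or 32-bit with slope 1; floats: 32-bit scaled.
dcmEncodePixels <- function(m) {
  v <- as.numeric(t(m))   # DICOM row-major order
  lo <- min(v)
  if (max(abs(v - round(v))) == 0) {
    stored <- round(v) - round(lo)
    slope <- 1; intercept <- round(lo)
  } else {
    rng <- max(v) - lo
    slope <- if (rng > 0) rng / (2^32 - 1) else 1
    intercept <- lo
    stored <- round((v - lo) / slope)
  }
  if (max(stored) < 2^16) {
    bits <- 16L
    dat <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  } else {
    bits <- 32L
    s <- stored
    s[s >= 2^31] <- s[s >= 2^31] - 2^32
    dat <- writeBin(as.integer(s), raw(), size = 4, endian = "little")
  }
  list(data = dat, bits = bits, slope = slope, intercept = intercept)
}

writeDicomSeries <- function(grid, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", dir, "'")
  }
  d <- dim(grid@voxels)
  modality <- switch(grid@modality, CT = "CT", MR = "MR", "OT")
  studyUID <- dcmUID("1.1")
  seriesUID <- dcmUID("1.2")
  for (i in seq_len(d[1])) {
    enc <- dcmEncodePixels(grid@voxels[i, , ] * 1.0)
    sopUID <- dcmUID(paste0("2.", i))
    pos <- c(grid@origin[3], grid@origin[2],
             grid@origin[1] + (i - 1) * grid@spacing[1])
    ds <- c(
      dcmElement(0x0008, 0x0016, "UI", DICOM_SC_CLASS),
      dcmElement(0x0008, 0x0018, "UI", sopUID),
      dcmElement(0x0008, 0x0060, "CS", modality),
      dcmElement(0x0018, 0x0050, "DS", dcmDS(grid@spacing[1])),
      dcmElement(0x0020, 0x000D, "UI", studyUID),
      dcmElement(0x0020, 0x000E, "UI", seriesUID),
      dcmElement(0x0020, 0x0013, "IS", as.character(i)),
      dcmElement(0x0020, 0x0032, "DS", dcmDS(pos)),
      dcmElement(0x0020, 0x0037, "DS", dcmDS(c(1, 0, 0, 0, 1, 0))),
      dcmElement(0x0028, 0x0002, "US", 1L),
      dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcmElement(0x0028, 0x0010, "US", d[2]),
      dcmElement(0x0028, 0x0011, "US", d[3]),
      dcmElement(0x0028, 0x0030, "DS", dcmDS(grid@spacing[2:3])),
      dcmElement(0x0028, 0x0100, "US", enc$bits),
      dcmElement(0x0028, 0x0101, "US", enc$bits),
      dcmElement(0x0028, 0x0102, "US", enc$bits - 1L),
      dcmElement(0x0028, 0x0103, "US", 0L),
      dcmElement(0x0028, 0x1052, "DS", dcmDS(enc$intercept)),
      dcmElement(0x0028, 0x1053, "DS", dcmDS(enc$slope)),
      dcmElement(0x7FE0, 0x0010, "OW", enc$data)
    )
    meta <- c(
      dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcmElement(0x0002, 0x0002, "UI", DICOM_SC_CLASS),
      dcmElement(0x0002, 0x0003, "UI", sopUID),
      dcmElement(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
      dcmElement(0x0002, 0x0012, "UI", dcmUID("0.1"))
    )
    groupLen <- dcmElement(0x0002, 0x0000, "UL", length(meta))
    out <- c(raw(128), charToRaw("DICM"), groupLen, meta, ds)
    path <- file.path(dir, sprintf("slice%04d.dcm", i))
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot write '", path, "'"))
    writeBin(out, con)
    close(con)
  }
  invisible(dir)
}

# Parse a single Explicit-VR-LE DICOM file into the tags we use.
parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  tags <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 8 <= n + 1) {
    grp <- readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little",
                   signed = FALSE)
    el <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                  endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% longVRs) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      body <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      body <- pos + 8L
    }
    if (len < 0 || body + len - 1 > n)
      stop("malformed DICOM element at tag (",
           sprintf("%04X,%04X", grp, el), ") in ", path)
    key <- sprintf("%04X%04X", grp, el)
    val <- raw[body:(body + len - 1)]
    tags[[key]] <- list(vr = vr, bytes = val)
    pos <- body + len
  }
  tags
}

dcmString <- function(tags, key) {
  if (is.null(tags[[key]])) return(NULL)
  b <- tags[[key]]$bytes
  b <- b[b != as.raw(0)]              # strip UI null padding
  sub(" +$", "", rawToChar(b))
}

dcmNumerics <- function(tags, key) {
  s <- dcmString(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcmUShort <- function(tags, key) {
  if (is.null(tags[[key]])) return(NULL)
  readBin(tags[[key]]$bytes, "integer", size = 2, endian = "little",
          signed = FALSE)
}

readDicomSeries <- function(dir, units = "HU") {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files in ", dir)
  slices <- lapply(files, function(f) {
    tags <- parseDicomFile(f)
    ts <- dcmString(tags, "00020010")
    if (!is.null(ts) && ts != DICOM_TS_EXPLICIT_LE)
      stop("unsupported transfer syntax '", ts, "' in ", f)
    rows <- dcmUShort(tags, "00280010")
    cols <- dcmUShort(tags, "00280011")
    bits <- dcmUShort(tags, "00280100")
    if (is.null(rows) || is.null(cols) || is.null(bits))
      stop("DICOM file ", f, " lacks image pixel description (0028,0010/0011/0100)")
    px <- tags[["7FE00010"]]
    if (is.null(px)) stop("DICOM file ", f, " lacks PixelData (7FE0,0010)")
    stored <- readBin(px$bytes, "integer", size = bits / 8, endian = "little",
                      signed = (bits == 32), n = rows * cols)
    if (bits == 32) stored[stored < 0] <- stored[stored < 0] + 2^32
    slope <- dcmNumerics(tags, "00281053"); if (is.null(slope)) slope <- 1
    icpt <- dcmNumerics(tags, "00281052"); if (is.null(icpt)) icpt <- 0
    v <- stored * slope + icpt
    pos <- dcmNumerics(tags, "00200032")
    if (is.null(pos)) stop("DICOM file ", f, " lacks ImagePositionPatient")
    orient <- dcmString(tags, "00200037")
    psp <- dcmNumerics(tags, "00280030")
    list(m = t(matrix(v, nrow = cols, ncol = rows)), z = pos[3],
         y0 = pos[2], x0 = pos[1], orient = orient, psp = psp,
         modality = dcmString(tags, "00080060"))
  })
  orients <- unique(vapply(slices, function(s) s$orient %||% "", character(1)))
  if (length(orients) > 1)
    stop("mixed-orientation DICOM series rejected (orientations: ",
         paste(orients, collapse = " | "), ")")
  ord <- order(vapply(slices, function(s) s$z, numeric(1)))
  slices <- slices[ord]
  zs <- vapply(slices, function(s) s$z, numeric(1))
  dz <- if (length(zs) > 1) diff(zs)[1] else 2.5
  if (length(zs) > 2 && any(abs(diff(zs) - dz) > 1e-3))
    stop("non-uniform slice spacing in DICOM series")
  s1 <- slices[[1]]
  vox <- array(0, c(length(slices), nrow(s1$m), ncol(s1$m)))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$m
  modality <- switch(s1$modality %||% "CT", CT = "CT", MR = "MR", "DOSE")
  if (modality == "MR" && units == "HU") units <- "arbitrary"
  if (modality == "DOSE" && units == "HU") units <- "Gy"
  ImageGrid(vox, spacing = c(dz, s1$psp[1], s1$psp[2]),
            origin = c(zs[1], s1$y0, s1$x0), modality = modality,
            units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
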