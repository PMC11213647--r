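#' Read a 3D volume
#'
#' Reads a NIfTI file or a DICOM image series into an \linkS4class{ImageGrid}.
#' Arrays are reordered to the package's (slice, row, col) axis convention.
#' For DICOM, the HU rescale (slope/intercept) is applied on read and slices
#' are sorted by their axial position; a series with mixed in-plane
#' orientations is rejected.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param dialect "nifti" or "dicom_series".
#' @param modality,units stored on the returned grid; for DICOM the modality
#'   tag in the file wins.
#' @return An \linkS4class{ImageGrid}.
#' @export
readVolume <- function(path, dialect = c("nifti", "dicom_series"),
                       modality = "CT", units = "HU") {
  dialect <- match.arg(dialect)
  if (dialect == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file '", path,
                                             "': ", conditionMessage(e)))
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
    pd <- attr(img, "pixdim")            # (x, y, z)
    vox <- aperm(arr, c(3, 2, 1))        # -> (z, y, x)
    orig <- attr(img, "sctdose_origin")
    hdr <- RNifti::niftiHeader(img)
    origin_xyz <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    ImageGrid(vox, spacing = rev(pd[1:3]), origin = rev(origin_xyz),
              modality = modality, units = units)
  } else {
    readDicomSeries(path, units = units)
  }
}

#' Write a 3D volume
#'
#' Writes an \linkS4class{ImageGrid} as a single NIfTI file or as a DICOM
#' series with one file per slice. Round trips through
#' \code{\link{readVolume}} are voxel-exact for integer-valued data and
#' agree within 1e-6 for floating-point dose grids.
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param path output file (NIfTI) or directory (DICOM series).
#' @param dialect "nifti" or "dicom_series".
#' @export
writeVolume <- function(grid, path, dialect = c("nifti", "dicom_series")) {
  dialect <- match.arg(dialect)
  if (dialect == "nifti") {
    arr <- aperm(grid@voxels * 1.0, c(3, 2, 1))   # (x, y, z)
    o <- rev(grid@origin)
    sp <- rev(grid@spacing)
    xf <- structure(rbind(cbind(diag(sp), o), c(0, 0, 0, 1)), code = 2L)
    img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, sp, rep(0, 4))))
    RNifti::qform(img) <- xf
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e)))
    invisible(ok)
  } else {
    writeDicomSeries(grid, path)
  }
}

#' Read and write JSON contour files
#'
#' The canonical plain-text contour dialect: a JSON array of objects
#' \code{{structure, slice, points_mm}} where \code{points_mm} is an n x 2
#' array of (row_mm, col_mm) vertices of a closed polygon.
#'
#' @param path JSON file path.
#' @return list of \linkS4class{Contour}.
#' @export
readContours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(js, function(el) {
    pts <- el$points_mm
    if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
    Contour(el$structure, el$slice, pts)
  })
}

#' @rdname readContours
#' @param contours list of \linkS4class{Contour} (or a
#'   \linkS4class{StructureSet}, whose contours are written).
#' @export
writeContours <- function(contours, path) {
  if (is(contours, "StructureSet")) contours <- contours@contours
  js <- lapply(contours, function(cn) {
    list(structure = cn@structure, slice = cn@slice,
         points_mm = unname(apply(cn@points, 1, function(p) c(p[1], p[2]),
                                  simplify = FALSE)))
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize closed contours onto a reference grid
#'
#' A voxel is true iff its center lies inside the polygon of its slice under
#' the even-odd rule. Multiple polygons of the same structure on one slice
#' are combined by union. There is no interpolation between slices.
#'
#' @param contours list of \linkS4class{Contour} (typically one structure).
#' @param reference \linkS4class{ImageGrid} defining the output geometry.
#' @return boolean \linkS4class{ImageGrid}.
#' @export
rasterizeContours <- function(contours, reference) {
  d <- dim(reference@voxels)
  out <- array(FALSE, d)
  rowC <- axisCoords(reference, 2)
  colC <- axisCoords(reference, 3)
  for (cn in contours) {
    if (cn@slice < 1L || cn@slice > d[1])
      stop("contour slice ", cn@slice, " outside reference extent [1, ",
           d[1], "]")
    m <- cpp_rasterize_slice(cn@points, rowC, colC)
    out[cn@slice, , ] <- out[cn@slice, , ] | m
  }
  withVoxels(reference, out, modality = "MASK", units = "bool")
}

fillValueFor <- function(grid) {
  switch(grid@units, HU = -1000, arbitrary = 0, Gy = 0, bool = FALSE,
         label = 0)
}

#' Resample a grid onto a target geometry
#'
#' Trilinear interpolation for intensity volumes, nearest neighbour for
#' masks and label maps. Voxels outside the source extent take a
#' units-dependent fill value (HU: -1000; arbitrary/Gy/label: 0;
#' bool: FALSE).
#'
#' @param grid source \linkS4class{ImageGrid}.
#' @param target \linkS4class{ImageGrid} whose geometry defines the output.
#' @param method "trilinear" or "nearest".
#' @return \linkS4class{ImageGrid} on the target geometry.
#' @export
resampleGrid <- function(grid, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  for (ax in 1:3) {
    sLo <- grid@origin[ax]
    sHi <- grid@origin[ax] + (dim(grid@voxels)[ax] - 1) * grid@spacing[ax]
    tLo <- target@origin[ax]
    tHi <- target@origin[ax] + (dim(target@voxels)[ax] - 1) * target@spacing[ax]
    if (sHi < tLo || tHi < sLo)
      stop("disjoint physical extents on axis ", ax)
  }
  isBool <- is.logical(grid@voxels)
  fill <- as.numeric(fillValueFor(grid))
  src <- if (isBool) grid@voxels * 1.0 else grid@voxels
  out <- cpp_resample(as.numeric(src), dim(grid@voxels), grid@spacing,
                      grid@origin, dim(target@voxels), target@spacing,
                      target@origin, method == "nearest", fill)
  dim(out) <- dim(target@voxels)
  if (isBool) out <- out > 0.5
  withVoxels(target, out, modality = grid@modality, units = grid@units)
}
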