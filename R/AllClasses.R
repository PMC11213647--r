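#' @import methods
#' @importFrom stats sd quantile approx rnorm runif rbinom pnorm pt qnorm
#' @importFrom utils write.csv read.csv
#' @useDynLib sctDose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_MODALITIES <- c("CT", "MR", "DOSE", "MASK", "LABEL")
VALID_UNITS <- c("HU", "arbitrary", "Gy", "bool", "label")

#' ImageGrid: a 3D scalar volume on a regular axial grid
#'
#' The universal voxel container shared by all pipeline stages. Voxels are
#' stored as a 3D array in (slice, row, col) order, i.e. inferior-to-superior,
#' posterior-to-anterior, right-to-left (LPS-consistent axial stacks).
#' Coordinates are voxel-center based: the center of voxel (i, j, k)
#' (1-based) lies at \code{origin + (c(i,j,k) - 1) * spacing} millimetres.
#'
#' @slot voxels 3D numeric or logical array (slices x rows x cols).
#' @slot spacing numeric length-3, mm per axis (slice, row, col); all > 0.
#' @slot origin numeric length-3, mm position of the first voxel center.
#' @slot modality one of "CT", "MR", "DOSE", "MASK", "LABEL".
#' @slot units one of "HU", "arbitrary", "Gy", "bool", "label".
#' @export
setClass("ImageGrid",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 modality = "character", units = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values (mm)")
    if (!is.logical(object@voxels) &&
        any(is.infinite(object@voxels) | is.nan(object@voxels)))
      msg <- c(msg, "voxels must be finite (NA allowed for excluded voxels)")
    if (!object@modality %in% VALID_MODALITIES)
      msg <- c(msg, sprintf("modality must be one of %s",
                            paste(VALID_MODALITIES, collapse = ", ")))
    if (!object@units %in% VALID_UNITS)
      msg <- c(msg, sprintf("units must be one of %s",
                            paste(VALID_UNITS, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Construct an ImageGrid
#'
#' @param voxels 3D array (slices x rows x cols).
#' @param spacing mm per axis, length 3; default matches the 2.5 mm slice /
#'   0.98 mm in-plane CT protocol the pipeline assumes.
#' @param origin mm of first voxel center; default centers the grid on 0.
#' @param modality,units see \linkS4class{ImageGrid}.
#' @return An \linkS4class{ImageGrid}.
#' @export
ImageGrid <- function(voxels, spacing = c(2.5, 0.98, 0.98), origin = NULL,
                      modality = "CT", units = "HU") {
  if (is.null(dim(voxels))) stop("voxels must be an array")
  voxels <- as.array(voxels)
  if (is.null(origin)) origin <- -(dim(voxels) - 1) / 2 * spacing
  new("ImageGrid", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality, units = units)
}

#' @rdname ImageGrid-accessors
#' @param x an ImageGrid
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ImageGrid-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname ImageGrid-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname ImageGrid-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname ImageGrid-accessors
#' @export
setGeneric("gridUnits", function(x) standardGeneric("gridUnits"))

#' Accessors for ImageGrid slots
#' @name ImageGrid-accessors
#' @aliases voxels spacing origin modality gridUnits
NULL

setMethod("voxels", "ImageGrid", function(x) x@voxels)
setMethod("spacing", "ImageGrid", function(x) x@spacing)
setMethod("origin", "ImageGrid", function(x) x@origin)
setMethod("modality", "ImageGrid", function(x) x@modality)
setMethod("gridUnits", "ImageGrid", function(x) x@units)

setMethod("dim", "ImageGrid", function(x) dim(x@voxels))

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageGrid [%s, %s]: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              object@modality, object@units, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  v <- object@voxels
  cat(sprintf("  range: [%.4g, %.4g]\n", min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
})

# Same geometry (shape, spacing, origin) up to tolerance
sameGeometry <- function(a, b, tol = 1e-6) {
  identical(dim(a@voxels), dim(b@voxels)) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

# Replace voxels, keep geometry; convenience used throughout
withVoxels <- function(grid, voxels, modality = grid@modality,
                       units = grid@units) {
  dim(voxels) <- dim(grid@voxels)
  new("ImageGrid", voxels = voxels, spacing = grid@spacing,
      origin = grid@origin, modality = modality, units = units)
}

# Voxel-center physical coordinates (mm) along one axis
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(dim(grid@voxels)[axis]) - 1) * grid@spacing[axis]
}

#' Contour: one closed planar polygon of a delineated structure
#'
#' @slot structure structure name, e.g. "RECTUM".
#' @slot slice 1-based axial slice index.
#' @slot points n x 2 matrix of (row_mm, col_mm) vertices; closed implicitly
#'   (last vertex connects to first); at least 3 vertices.
#' @export
setClass("Contour",
  representation(structure = "character", slice = "integer", points = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@points) < 3L) msg <- c(msg, "contour needs >= 3 vertices")
    if (ncol(object@points) != 2L) msg <- c(msg, "points must be n x 2 (row_mm, col_mm)")
    if (any(!is.finite(object@points))) msg <- c(msg, "points must be finite")
    if (length(object@slice) != 1L || object@slice < 1L)
      msg <- c(msg, "slice must be a single index >= 1")
    if (is.null(msg) && polygonArea(object@points) <= 0)
      msg <- c(msg, "polygon area must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname Contour
#' @param structure,slice,points see slots.
#' @export
Contour <- function(structure, slice, points) {
  new("Contour", structure = as.character(structure),
      slice = as.integer(slice), points = as.matrix(points))
}

# Unsigned shoelace area (mm^2)
polygonArea <- function(pts) {
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  abs(sum(pts[j, 1] * pts[, 2] - pts[, 1] * pts[j, 2])) / 2
}

# Signed shoelace area in (col, row) plane; positive = counter-clockwise
# when col is plotted rightwards and row upwards.
polygonSignedArea <- function(pts) {
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  sum(pts[j, 2] * pts[, 1] - pts[, 2] * pts[j, 1]) / 2
}

#' StructureSet: named contours plus rasterized masks on a reference grid
#'
#' @slot contours list of \linkS4class{Contour}.
#' @slot masks named list of boolean \linkS4class{ImageGrid}s, one per
#'   structure, all on the same reference grid.
#' @export
setClass("StructureSet",
  representation(contours = "list", masks = "list"),
  validity = function(object) {
    msg <- NULL
    nm <- unique(vapply(object@contours, function(cn) cn@structure, character(1)))
    if (length(nm) && !all(nm %in% names(object@masks)))
      msg <- c(msg, "every contoured structure needs a mask")
    if (length(object@masks) > 1) {
      d0 <- dim(object@masks[[1]]@voxels)
      ok <- all(vapply(object@masks, function(m)
        identical(dim(m@voxels), d0), logical(1)))
      if (!ok) msg <- c(msg, "masks must share the reference grid shape")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname StructureSet
#' @param contours,masks see slots.
#' @export
StructureSet <- function(contours = list(), masks = list()) {
  new("StructureSet", contours = contours, masks = masks)
}

#' @rdname StructureSet
#' @param x a StructureSet
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @rdname StructureSet
#' @param name structure name
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))
setMethod("structureMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks)) stop("no mask for structure '", name, "'")
  x@masks[[name]]
})

#' @rdname StructureSet
#' @export
setGeneric("structureContours", function(x, name) standardGeneric("structureContours"))
setMethod("structureContours", "StructureSet", function(x, name) {
  keep <- vapply(x@contours, function(cn) cn@structure == name, logical(1))
  x@contours[keep]
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet: %d structures, %d contours\n",
              length(object@masks), length(object@contours)))
  for (nm in names(object@masks))
    cat(sprintf("  %-12s %d voxels\n", nm, sum(object@masks[[nm]]@voxels)))
})

#' PlanConfig: prescription, beam geometry and fluence scaling
#'
#' Describes a 60 Gy / 20 fraction prostate plan delivered by equispaced
#' coplanar parallel beams with a conformal aperture (beam's-eye-view
#' projection of the target plus margin) and Gaussian penumbra. The fluence
#' scale \code{muScale} is fixed at planning time (PTV60 median = prescription)
#' and reused unchanged for fixed-MU recalculation on synthetic CTs.
#'
#' @slot prescriptionGy prescription dose, Gy (default 60).
#' @slot fractions number of fractions (default 20).
#' @slot gantryAngles beam angles, degrees (0 = anterior, clockwise).
#' @slot beamWeights positive per-beam weights.
#' @slot apertureMarginMm target-to-field margin, mm.
#' @slot penumbraSigmaMm Gaussian penumbra sigma, mm.
#' @slot muEff effective linear attenuation coefficient, 1/mm.
#' @slot isocenter mm, (slice, row, col) position of the isocenter.
#' @slot muScale global fluence scale; NA until set by planning.
#' @export
setClass("PlanConfig",
  representation(prescriptionGy = "numeric", fractions = "numeric",
                 gantryAngles = "numeric", beamWeights = "numeric",
                 apertureMarginMm = "numeric", penumbraSigmaMm = "numeric",
                 muEff = "numeric", isocenter = "numeric", muScale = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@prescriptionGy <= 0 || object@fractions < 1)
      msg <- c(msg, "prescription and fractions must be positive")
    if (length(object@gantryAngles) < 2L)
      msg <- c(msg, "need >= 2 beams")
    if (length(object@beamWeights) != length(object@gantryAngles) ||
        any(object@beamWeights <= 0))
      msg <- c(msg, "beamWeights must be positive, one per beam")
    if (object@penumbraSigmaMm < 0 || object@muEff <= 0 ||
        object@apertureMarginMm < 0)
      msg <- c(msg, "penumbra/margin must be >= 0 and muEff > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Default treatment plan configuration
#'
#' @param prescriptionGy,fractions prescription (60 Gy in 20 fractions).
#' @param nBeams number of equispaced coplanar beams.
#' @param apertureMarginMm BEV margin around PTV60.
#' @param penumbraSigmaMm Gaussian penumbra sigma.
#' @param muEff effective attenuation, 1/mm (about 6 MV in water).
#' @param isocenter mm (slice, row, col); default the grid center (0,0,0).
#' @return A \linkS4class{PlanConfig} with unset (NA) muScale.
#' @export
PlanConfig <- function(prescriptionGy = 60, fractions = 20, nBeams = 7,
                       apertureMarginMm = 6, penumbraSigmaMm = 4,
                       muEff = 0.005, isocenter = c(0, 0, 0)) {
  ang <- seq(0, 360, length.out = nBeams + 1)[seq_len(nBeams)]
  new("PlanConfig", prescriptionGy = prescriptionGy, fractions = fractions,
      gantryAngles = ang, beamWeights = rep(1, nBeams),
      apertureMarginMm = apertureMarginMm, penumbraSigmaMm = penumbraSigmaMm,
      muEff = muEff, isocenter = as.numeric(isocenter), muScale = NA_real_)
}

setMethod("show", "PlanConfig", function(object) {
  cat(sprintf("PlanConfig: %g Gy / %g fx, %d beams, muScale %s\n",
              object@prescriptionGy, object@fractions,
              length(object@gantryAngles),
              if (is.na(object@muScale)) "unset" else
                sprintf("%.4g", object@muScale)))
})

#' LKBParams: Lyman-Kutcher-Burman model parameters for one endpoint
#'
#' @slot td50 dose of 50\% complication probability (Gy, EQD2 domain).
#' @slot m slope parameter (unitless).
#' @slot n volume-effect exponent in (0, 1].
#' @slot alphaBeta alpha/beta ratio (Gy) used for EQD2 conversion.
#' @slot endpoint endpoint label.
#' @export
setClass("LKBParams",
  representation(td50 = "numeric", m = "numeric", n = "numeric",
                 alphaBeta = "numeric", endpoint = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@td50 <= 0) msg <- c(msg, "td50 must be > 0")
    if (object@m <= 0) msg <- c(msg, "m must be > 0")
    if (object@n <= 0 || object@n > 1) msg <- c(msg, "n must be in (0, 1]")
    if (object@alphaBeta <= 0) msg <- c(msg, "alphaBeta must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname LKBParams
#' @param td50,m,n,alphaBeta,endpoint see slots.
#' @export
LKBParams <- function(td50, m, n, alphaBeta = 3, endpoint = "custom") {
  new("LKBParams", td50 = td50, m = m, n = n, alphaBeta = alphaBeta,
      endpoint = endpoint)
}

#' Published LKB parameter sets for the two rectal endpoints
#'
#' Grade-2 rectal bleeding: TD50 = 97.7 Gy, m = 0.27, n = 0.085, a/b = 3 Gy.
#' Late faecal incontinence: TD50 = 105.0 Gy, m = 0.43, n = 1.0, a/b = 3 Gy.
#' @return An \linkS4class{LKBParams}.
#' @export
g2rbParams <- function() LKBParams(97.7, 0.27, 0.085, 3, "G2_rectal_bleeding")

#' @rdname g2rbParams
#' @export
lfiParams <- function() LKBParams(105.0, 0.43, 1.0, 3, "late_faecal_incontinence")

setMethod("show", "LKBParams", function(object) {
  cat(sprintf("LKBParams [%s]: TD50 %.1f Gy, m %.3g, n %.3g, a/b %.3g Gy\n",
              object@endpoint, object@td50, object@m, object@n,
              object@alphaBeta))
})

#' DoseSurfaceMap: unwrapped rectal surface dose
#'
#' Rows run inferior to superior (cranio-caudal), columns circumferentially
#' starting at the posterior-most contour point and moving clockwise as seen
#' from inferior.
#'
#' @slot raw n_slices x n_samples dose array (Gy).
#' @slot interpolated 42 x 42 bilinearly interpolated map (may be empty
#'   before interpolation).
#' @slot isEQD2 whether doses have been EQD2-converted.
#' @export
setClass("DoseSurfaceMap",
  representation(raw = "matrix", interpolated = "matrix", isEQD2 = "logical"),
  validity = function(object) {
    msg <- NULL
    if (any(object@raw < 0)) msg <- c(msg, "doses must be >= 0")
    if (length(object@interpolated) &&
        !identical(dim(object@interpolated), c(42L, 42L)))
      msg <- c(msg, "interpolated map must be exactly 42 x 42")
    if (is.null(msg)) TRUE else msg
  })

DoseSurfaceMap <- function(raw, interpolated = matrix(numeric(0), 0, 0),
                           isEQD2 = FALSE) {
  new("DoseSurfaceMap", raw = raw, interpolated = interpolated,
      isEQD2 = isEQD2)
}

setMethod("show", "DoseSurfaceMap", function(object) {
  cat(sprintf("DoseSurfaceMap: raw %d x %d%s%s\n",
              nrow(object@raw), ncol(object@raw),
              if (length(object@interpolated)) ", interpolated 42 x 42" else "",
              if (object@isEQD2) " (EQD2)" else ""))
})

#' DVHCurve: differential + cumulative dose-volume histogram
#'
#' @slot binEdges dose bin edges, Gy (length nbins + 1).
#' @slot vDiff differential volume fractions per bin (sums to 1).
#' @slot cumulative fraction of volume receiving >= each bin edge.
#' @export
setClass("DVHCurve",
  representation(binEdges = "numeric", vDiff = "numeric",
                 cumulative = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@vDiff) != length(object@binEdges) - 1L)
      msg <- c(msg, "vDiff must have length(binEdges) - 1 entries")
    if (any(object@vDiff < 0)) msg <- c(msg, "vDiff must be >= 0")
    if (abs(sum(object@vDiff) - 1) > 1e-8) msg <- c(msg, "vDiff must sum to 1")
    if (any(diff(object@cumulative) > 1e-12))
      msg <- c(msg, "cumulative must be non-increasing")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve: %d bins, dose range [%.3g, %.3g] Gy\n",
              length(object@vDiff), min(object@binEdges),
              max(object@binEdges)))
})

#' StratificationRules: thresholds and nominal HUs for tissue stratification
#'
#' Five classes partition the within-body HU axis: inside air, fat, muscle,
#' spongy bone, cortical bone. Nominal replacement HUs default to the values
#' of the commercial tissue-stratified sCT product the pipeline emulates
#' (inside air -500, fat -75, muscle 0, spongy bone 204, cortical bone 1067).
#'
#' @slot breakpoints strictly increasing HU thresholds (length 4) separating
#'   the five classes.
#' @slot nominalHU named replacement HU per class.
#' @slot ctvOverride reassign fat/spongy/cortical voxels inside the CTV
#'   (calcifications, fiducial markers) to muscle.
#' @slot spongyOverride reassign fat/muscle voxels inside the bone interior
#'   to spongy bone.
#' @export
setClass("StratificationRules",
  representation(breakpoints = "numeric", nominalHU = "numeric",
                 ctvOverride = "logical", spongyOverride = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@breakpoints) != 4L ||
        any(diff(object@breakpoints) <= 0))
      msg <- c(msg, "breakpoints must be 4 strictly increasing HUs")
    need <- c("inside_air", "fat", "muscle", "spongy_bone", "cortical_bone")
    if (!all(need %in% names(object@nominalHU)))
      msg <- c(msg, "nominalHU must name all five classes")
    if (is.null(msg)) TRUE else msg
  })

#' Default stratification rules
#'
#' Threshold breakpoints bracket the nominal class HUs with conventional CT
#' tissue ranges: inside_air < -200 <= fat < -30 <= muscle < 100 <=
#' spongy < 400 <= cortical.
#' @param breakpoints,nominalHU,ctvOverride,spongyOverride see
#'   \linkS4class{StratificationRules}.
#' @return A \linkS4class{StratificationRules}.
#' @export
StratificationRules <- function(breakpoints = c(-200, -30, 100, 400),
                                nominalHU = c(inside_air = -500, fat = -75,
                                              muscle = 0, spongy_bone = 204,
                                              cortical_bone = 1067),
                                ctvOverride = TRUE, spongyOverride = TRUE) {
  new("StratificationRules", breakpoints = breakpoints, nominalHU = nominalHU,
      ctvOverride = ctvOverride, spongyOverride = spongyOverride)
}

#' GammaCriteria: acceptance criteria for gamma analysis
#'
#' @slot doseTol fractional local dose tolerance (default 0.02).
#' @slot dtaMm distance-to-agreement, mm (default 2).
#' @slot threshold low-dose exclusion threshold as fraction of the reference
#'   maximum (default 0.20).
#' @export
setClass("GammaCriteria",
  representation(doseTol = "numeric", dtaMm = "numeric", threshold = "numeric"),
  validity = function(object) {
    if (object@doseTol <= 0 || object@dtaMm <= 0 || object@threshold <= 0)
      "doseTol, dtaMm and threshold must all be positive" else TRUE
  })

#' @rdname GammaCriteria-class
#' @param doseTol,dtaMm,threshold see slots.
#' @export
GammaCriteria <- function(doseTol = 0.02, dtaMm = 2, threshold = 0.20) {
  new("GammaCriteria", doseTol = doseTol, dtaMm = dtaMm, threshold = threshold)
}

#' CalibrationCurve: HU to relative electron density
#'
#' Monotone piecewise-linear mapping used by the simplified dose engine;
#' extrapolation is clamped to the end densities.
#' @slot hu control-point HUs (strictly increasing).
#' @slot red relative electron densities at the control points.
#' @export
setClass("CalibrationCurve",
  representation(hu = "numeric", red = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@hu) != length(object@red) || length(object@hu) < 2)
      msg <- c(msg, "need >= 2 aligned control points")
    if (any(diff(object@hu) <= 0)) msg <- c(msg, "hu must be strictly increasing")
    if (any(diff(object@red) <= 0)) msg <- c(msg, "red must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Default HU-to-relative-electron-density calibration
#'
#' Anchored at air (-1000 HU, RED 0) and water (0 HU, RED 1) with
#' representative densities at the nominal stratification HUs.
#' @param hu,red control points.
#' @return A \linkS4class{CalibrationCurve}.
#' @export
CalibrationCurve <- function(hu = c(-1000, -75, 0, 204, 1067),
                             red = c(0, 0.97, 1.0, 1.10, 1.60)) {
  new("CalibrationCurve", hu = hu, red = red)
}
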