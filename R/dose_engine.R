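#' Convert HU to relative electron density
#'
#' Per-voxel monotone piecewise-linear interpolation of the calibration
#' curve; extrapolation is clamped to the end densities.
#'
#' @param ct CT \linkS4class{ImageGrid}.
#' @param curve \linkS4class{CalibrationCurve}.
#' @return RED \linkS4class{ImageGrid} (unitless, stored as "arbitrary").
#' @export
huToRED <- function(ct, curve = CalibrationCurve()) {
  validObject(curve)
  red <- stats::approx(curve@hu, curve@red, xout = as.numeric(ct@voxels),
                       rule = 2)$y
  withVoxels(ct, red, modality = "CT", units = "arbitrary")
}

# Beam's-eye-view fluence maps: one (nu x nslices) matrix per beam.
# Binary conformal aperture = projection of the target plus margin (in the
# lateral BEV coordinate u and cranio-caudally), then Gaussian penumbra.
beamFluence <- function(targetMask, plan) {
  d <- dim(targetMask@voxels)
  spz <- targetMask@spacing[1]
  du <- 1
  u <- seq(-100, 100, by = du)
  idx <- which(targetMask@voxels, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty target mask")
  zmm <- axisCoords(targetMask, 1)[idx[, 1]]
  ymm <- axisCoords(targetMask, 2)[idx[, 2]] - plan@isocenter[2]
  xmm <- axisCoords(targetMask, 3)[idx[, 3]] - plan@isocenter[3]
  sliceZ <- axisCoords(targetMask, 1)
  gauss <- function(coords, sigma) {
    if (sigma <= 0) return(NULL)
    k <- stats::dnorm(outer(coords, coords, "-"), sd = sigma)
    sweep(k, 1, rowSums(k), "/")
  }
  Ku <- gauss(u, plan@penumbraSigmaMm)
  Kz <- gauss(sliceZ, plan@penumbraSigmaMm)
  lapply(plan@gantryAngles, function(angDeg) {
    a <- angDeg * pi / 180
    uv <- xmm * cos(a) - ymm * sin(a)
    ap <- matrix(0, length(u), d[1])
    for (s in seq_len(d[1])) {
      near <- abs(zmm - sliceZ[s]) <= plan@apertureMarginMm + spz / 2
      if (!any(near)) next
      lo <- min(uv[near]) - plan@apertureMarginMm
      hi <- max(uv[near]) + plan@apertureMarginMm
      ap[u >= lo & u <= hi, s] <- 1
    }
    if (!is.null(Ku)) ap <- Ku %*% ap
    if (!is.null(Kz)) ap <- ap %*% t(Kz)
    ap
  })
}

#' Compute dose on a relative-electron-density grid
#'
#' The simplified engine: per beam, parallel rays through a conformal
#' aperture (beam's-eye-view projection of the target plus margin) with a
#' Gaussian penumbra, attenuated as exp(-muEff * radiological path length)
#' where the radiological path is the line integral of RED from the entry
#' point; beams are summed with their weights. If the plan carries a fixed
#' \code{muScale}, the summed dose is multiplied by it and no renormalization
#' occurs; with \code{muScale} unset an unscaled beam sum is returned (use
#' \code{\link{planDose}} to set the scale).
#'
#' @param red RED \linkS4class{ImageGrid} from \code{\link{huToRED}}.
#' @param plan \linkS4class{PlanConfig}.
#' @param targetMask boolean \linkS4class{ImageGrid} the aperture conforms
#'   to (PTV60).
#' @param stepMm ray-marching step (default 1 mm).
#' @return dose \linkS4class{ImageGrid} (Gy).
#' @export
computeDose <- function(red, plan, targetMask, stepMm = 1) {
  validObject(plan)
  if (!sameGeometry(red, targetMask))
    stop("red and targetMask must share geometry")
  fl <- beamFluence(targetMask, plan)
  dose <- cpp_dose(as.numeric(red@voxels), dim(red@voxels), red@spacing,
                   red@origin, plan@isocenter, plan@gantryAngles * pi / 180,
                   plan@beamWeights, fl, -100, 1, plan@muEff, stepMm)
  if (all(dose == 0)) stop("zero total fluence: no ray reached the grid")
  if (!is.na(plan@muScale)) dose <- dose * plan@muScale
  dim(dose) <- dim(red@voxels)
  withVoxels(red, dose, modality = "DOSE", units = "Gy")
}

#' Create a plan on the planning CT
#'
#' Runs the engine with unit fluence, then fixes the global fluence scale
#' so that the median target (PTV60) dose equals the prescription. The
#' returned plan carries that \code{muScale} for later fixed-MU
#' recalculation on synthetic CTs.
#'
#' @param ct planning CT \linkS4class{ImageGrid}.
#' @param plan \linkS4class{PlanConfig} (muScale unset).
#' @param targetMask PTV60 boolean mask.
#' @param curve \linkS4class{CalibrationCurve}.
#' @param stepMm ray-marching step, mm.
#' @return list(dose = \linkS4class{ImageGrid}, plan = updated
#'   \linkS4class{PlanConfig}).
#' @export
planDose <- function(ct, plan, targetMask, curve = CalibrationCurve(),
                     stepMm = 1) {
  plan@muScale <- NA_real_
  red <- huToRED(ct, curve)
  raw <- computeDose(red, plan, targetMask, stepMm)
  med <- stats::median(raw@voxels[targetMask@voxels])
  if (med <= 0) stop("zero median target dose; cannot normalize plan")
  scale <- plan@prescriptionGy / med
  plan@muScale <- scale
  list(dose = withVoxels(raw, raw@voxels * scale), plan = plan)
}

#' Recalculate dose on a synthetic CT with fixed monitor units
#'
#' Identical engine and fluence scale as the planning run: the plan must
#' carry the \code{muScale} fixed on the planning CT; no renormalization is
#' performed, so a bit-identical sCT reproduces the planning dose exactly.
#'
#' @param sct synthetic CT \linkS4class{ImageGrid}.
#' @param plan \linkS4class{PlanConfig} with fixed muScale.
#' @param targetMask PTV60 boolean mask (defines the aperture, as at
#'   planning).
#' @param curve \linkS4class{CalibrationCurve}.
#' @param stepMm ray-marching step, mm.
#' @return dose \linkS4class{ImageGrid} (Gy).
#' @export
recalcFixedMU <- function(sct, plan, targetMask, curve = CalibrationCurve(),
                          stepMm = 1) {
  if (is.na(plan@muScale))
    stop("plan lacks a fixed muScale; run planDose on the planning CT first")
  computeDose(huToRED(sct, curve), plan, targetMask, stepMm)
}

#' GammaResult: gamma map and pass rate
#'
#' @slot gammaMap \linkS4class{ImageGrid}; NA where the reference dose is
#'   below the evaluation threshold.
#' @slot passRate percent of evaluated voxels with gamma <= 1.
#' @slot nEvaluated number of evaluated voxels.
#' @export
setClass("GammaResult",
  representation(gammaMap = "ImageGrid", passRate = "numeric",
                 nEvaluated = "integer"))

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult: %.2f%% of %d voxels pass (gamma <= 1)\n",
              object@passRate, object@nEvaluated))
})

#' 3D local gamma analysis
#'
#' gamma(r) = min over the search sphere of sqrt(
#' (dose difference / (doseTol * reference dose at r))^2 +
#' (distance / dta)^2 ), with local normalization; voxels with reference
#' dose below threshold * max(reference) are excluded. The search uses
#' trilinear interpolation of the evaluated dose at 0.5 mm steps within a
#' radius of 3 * dta.
#'
#' @param reference,evaluated dose \linkS4class{ImageGrid}s on one geometry
#'   (resample first otherwise).
#' @param criteria \linkS4class{GammaCriteria} (default 2\% / 2 mm, 20\%
#'   threshold).
#' @param searchStepMm search discretization (default 0.5 mm).
#' @return A \linkS4class{GammaResult}.
#' @export
gammaAnalysis <- function(reference, evaluated, criteria = GammaCriteria(),
                          searchStepMm = 0.5) {
  validObject(criteria)
  if (!sameGeometry(reference, evaluated))
    stop("geometries differ; resample the evaluated dose first")
  thr <- criteria@threshold * max(reference@voxels)
  if (all(reference@voxels < thr))
    stop("all voxels below the evaluation threshold")
  g <- cpp_gamma(as.numeric(reference@voxels), as.numeric(evaluated@voxels),
                 dim(reference@voxels), reference@spacing, criteria@doseTol,
                 criteria@dtaMm, thr, 3 * criteria@dtaMm, searchStepMm)
  dim(g) <- dim(reference@voxels)
  ok <- !is.na(g)
  new("GammaResult",
      gammaMap = withVoxels(reference, ifelse(ok, g, NA_real_),
                            modality = "DOSE", units = "arbitrary"),
      passRate = 100 * sum(g[ok] <= 1) / sum(ok),
      nEvaluated = sum(ok))
}
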