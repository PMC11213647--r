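#' Bulk-density synthetic CT
#'
#' Assigns one uniform HU to every voxel inside the body surface and -1000
#' (air) outside. \code{fillHU = 0} gives the water-equivalent bulk-density
#' sCT (sCT_BDw); \code{fillHU} set to a population-average body HU gives
#' the population bulk-density variant (sCT_BDp).
#'
#' @param bodyMask boolean \linkS4class{ImageGrid} of the body surface.
#' @param fillHU HU assigned inside the body (default 0).
#' @return CT-valued \linkS4class{ImageGrid}.
#' @export
makeBulkDensitySCT <- function(bodyMask, fillHU = 0) {
  m <- bodyMask@voxels
  if (!any(m)) stop("body mask is empty")
  out <- array(-1000, dim(m))
  out[m] <- fillHU
  withVoxels(bodyMask, out, modality = "CT", units = "HU")
}

#' Population mean body HU over a training cohort
#'
#' Mean HU over the pooled body voxels of all training CTs, as used to set
#' the fill value of the population bulk-density sCT.
#'
#' @param trainingCTs list of CT \linkS4class{ImageGrid}s.
#' @param bodyMasks aligned list of boolean body masks.
#' @return scalar HU.
#' @export
populationMeanHU <- function(trainingCTs, bodyMasks) {
  if (!length(trainingCTs) || length(trainingCTs) != length(bodyMasks))
    stop("trainingCTs and bodyMasks must be non-empty aligned lists")
  tot <- 0; n <- 0
  for (i in seq_along(trainingCTs)) {
    m <- bodyMasks[[i]]@voxels
    if (!any(m)) stop("empty body mask at position ", i)
    tot <- tot + sum(trainingCTs[[i]]@voxels[m])
    n <- n + sum(m)
  }
  tot / n
}

#' Threshold-based tissue stratification of a CT
#'
#' Classifies every within-body voxel into inside air, fat, muscle, spongy
#' bone or cortical bone by HU thresholds, then applies two reassignment
#' rules: calcifications and fiducial markers inside the CTV (voxels
#' thresholded as fat, spongy or cortical bone) become muscle, and voxels
#' thresholded as fat or muscle inside the spongy-bone compartment become
#' spongy bone.
#'
#' @param ct CT \linkS4class{ImageGrid}.
#' @param rules \linkS4class{StratificationRules}.
#' @param structures \linkS4class{StructureSet}; must provide BODY, and CTV /
#'   BONES_INTERIOR when the respective overrides are enabled.
#' @return label \linkS4class{ImageGrid} (0 outside, 1 inside air, 2 fat,
#'   3 muscle, 4 spongy bone, 5 cortical bone).
#' @export
stratifyTissues <- function(ct, rules = StratificationRules(), structures) {
  body <- structureMask(structures, "BODY")@voxels
  if (!identical(dim(body), dim(ct@voxels)))
    stop("CT and masks must be aligned")
  hu <- ct@voxels
  bp <- rules@breakpoints
  cls <- array(0L, dim(hu))
  cls[body] <- 1L + findInterval(hu[body], bp)   # 1..5 within body
  if (rules@ctvOverride) {
    if (!"CTV" %in% structureNames(structures))
      stop("ctvOverride enabled but no CTV structure present")
    ctv <- structureMask(structures, "CTV")@voxels
    sel <- ctv & (cls == 2L | cls == 4L | cls == 5L)
    cls[sel] <- 3L
  }
  if (rules@spongyOverride) {
    if (!"BONES_INTERIOR" %in% structureNames(structures))
      stop("spongyOverride enabled but no BONES_INTERIOR structure present")
    interior <- structureMask(structures, "BONES_INTERIOR")@voxels
    sel <- interior & (cls == 2L | cls == 3L)
    cls[sel] <- 4L
  }
  withVoxels(ct, cls, modality = "LABEL", units = "label")
}

#' Tissue-stratified synthetic CT from a label map
#'
#' Replaces each tissue class by its nominal HU (outside the body stays
#' -1000). Composing \code{\link{stratifyTissues}} with this function on a
#' planning CT yields the ground-truth-stratification control sCT.
#'
#' @param labels label \linkS4class{ImageGrid} from
#'   \code{\link{stratifyTissues}} (or a phantom's label map).
#' @param rules \linkS4class{StratificationRules} carrying the nominal HUs.
#' @return CT-valued \linkS4class{ImageGrid}.
#' @export
makeTissueSCT <- function(labels, rules = StratificationRules()) {
  lab <- labels@voxels
  if (any(!lab %in% 0:5))
    stop("unknown label value(s): ", paste(setdiff(unique(lab), 0:5),
                                           collapse = ", "))
  nh <- rules@nominalHU
  lut <- c(-1000, nh[["inside_air"]], nh[["fat"]], nh[["muscle"]],
           nh[["spongy_bone"]], nh[["cortical_bone"]])
  out <- array(lut[lab + 1L], dim(lab))
  withVoxels(labels, out, modality = "CT", units = "HU")
}

#' HU error metrics between an sCT and the ground-truth CT
#'
#' Mean error, mean absolute error and sample SD (n - 1) of the voxel-wise
#' HU difference (sct - ct) over a region.
#'
#' @param sct,ct aligned \linkS4class{ImageGrid}s.
#' @param region boolean \linkS4class{ImageGrid} (e.g. the body mask).
#' @return list with me, mae, sd, nVoxels, region.
#' @export
huErrorMetrics <- function(sct, ct, region) {
  if (!identical(dim(sct@voxels), dim(ct@voxels)) ||
      !identical(dim(sct@voxels), dim(region@voxels)))
    stop("grids must be aligned")
  m <- region@voxels
  if (!any(m)) stop("empty region")
  d <- sct@voxels[m] - ct@voxels[m]
  list(me = mean(d), mae = mean(abs(d)),
       sd = if (length(d) > 1) stats::sd(d) else 0,
       nVoxels = length(d), region = region@modality)
}
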