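#' Compute a dose-volume histogram
#'
#' Voxel-count histogram of dose within a mask (equal voxel volumes), with
#' the cumulative curve V(d) = fraction of volume receiving at least d
#' evaluated at every bin edge.
#'
#' @param dose dose \linkS4class{ImageGrid}.
#' @param mask boolean \linkS4class{ImageGrid}, non-empty, aligned.
#' @param binWidth histogram bin width, Gy (default 0.1).
#' @return A \linkS4class{DVHCurve}.
#' @export
computeDVH <- function(dose, mask, binWidth = 0.1) {
  if (!identical(dim(dose@voxels), dim(mask@voxels)))
    stop("dose and mask must be aligned")
  if (!any(mask@voxels)) stop("empty mask")
  v <- dose@voxels[mask@voxels]
  edges <- seq(0, max(v) + binWidth, by = binWidth)
  counts <- graphics::hist(v, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  vdiff <- counts / length(v)
  cum <- rev(cumsum(rev(vdiff)))          # V at left edges
  new("DVHCurve", binEdges = edges, vDiff = vdiff,
      cumulative = c(cum, 0))             # V at all edges incl. top
}

#' Evaluate a DVH point metric
#'
#' D-metrics (dose to at least p of the volume) take the largest dose at
#' which the interpolated cumulative curve still covers the fraction:
#' Dp = max d with V(d) >= p, linearly interpolated between bin edges and
#' right-continuous at jumps. V(d) is the interpolated covered fraction at
#' dose d.
#'
#' @param dvh a \linkS4class{DVHCurve}.
#' @param metric "D95", "Dmedian" or "V".
#' @param doseGy threshold dose for metric = "V".
#' @return Gy for D-metrics; volume fraction for V.
#' @export
dvhMetric <- function(dvh, metric = c("D95", "Dmedian", "V"), doseGy = NULL) {
  if (!metric[1] %in% c("D95", "Dmedian", "V"))
    stop("unknown metric '", metric[1], "'")
  metric <- match.arg(metric)
  e <- dvh@binEdges
  V <- dvh@cumulative
  if (metric == "V") {
    if (is.null(doseGy)) stop("metric 'V' needs doseGy")
    if (doseGy >= max(e)) return(0)
    if (doseGy <= 0) return(1)
    stats::approx(e, V, xout = doseGy)$y
  } else {
    p <- if (metric == "D95") 0.95 else 0.5
    dvhDoseAt(e, V, p)
  }
}

# largest d with interpolated V(d) >= p
dvhDoseAt <- function(e, V, p) {
  i <- max(which(V >= p))
  if (i == length(V)) return(e[i])
  # V decreases from V[i] >= p to V[i+1] < p; linear crossing
  e[i] + (V[i] - p) / (V[i] - V[i + 1]) * (e[i + 1] - e[i])
}

#' Equivalent dose in 2 Gy fractions
#'
#' Linear-quadratic fractionation correction: with per-fraction dose
#' d = dose/fractions, EQD2 = dose * (d + alpha/beta) / (2 + alpha/beta).
#' Vectorized over dose (applied per voxel or per DVH bin).
#'
#' @param dose total dose, Gy (scalar or array).
#' @param fractions number of fractions delivering it.
#' @param alphaBeta alpha/beta ratio, Gy (default 3).
#' @return EQD2 dose(s), Gy.
#' @export
eqd2 <- function(dose, fractions, alphaBeta = 3) {
  stopifnot(all(dose >= 0), fractions >= 1)
  d <- dose / fractions
  dose * (d + alphaBeta) / (2 + alphaBeta)
}

#' Generalized equivalent uniform dose
#'
#' Power-mean of the DVH with exponent 1/n over bin centers:
#' gEUD = (sum_i v_i D_i^(1/n))^n. n = 1 gives the mean dose; small n
#' approaches the maximum dose (serial organ behaviour).
#'
#' @param dvh \linkS4class{DVHCurve} in the EQD2 domain.
#' @param n volume-effect exponent, > 0.
#' @return gEUD, Gy.
#' @export
gEUD <- function(dvh, n) {
  if (n <= 0) stop("n must be > 0")
  centers <- (dvh@binEdges[-1] + dvh@binEdges[-length(dvh@binEdges)]) / 2
  sum(dvh@vDiff * centers^(1 / n))^n
}

#' RiskResult: gEUD and NTCP for one endpoint
#'
#' @slot geud generalized equivalent uniform dose, Gy (EQD2 domain).
#' @slot ntcp complication probability in [0, 1].
#' @slot endpoint endpoint name.
#' @export
setClass("RiskResult",
  representation(geud = "numeric", ntcp = "numeric", endpoint = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@ntcp < 0 || object@ntcp > 1) msg <- c(msg, "ntcp must be in [0,1]")
    if (object@geud < 0) msg <- c(msg, "geud must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "RiskResult", function(object) {
  cat(sprintf("RiskResult [%s]: gEUD %.2f Gy, NTCP %.3f%%\n",
              object@endpoint, object@geud, 100 * object@ntcp))
})

#' Lyman-Kutcher-Burman NTCP
#'
#' Probit dose-response on the gEUD: t = (gEUD - TD50) / (m * TD50),
#' NTCP = Phi(t).
#'
#' @param geud gEUD, Gy (EQD2 domain).
#' @param params \linkS4class{LKBParams}.
#' @return A \linkS4class{RiskResult}.
#' @export
lkbNTCP <- function(geud, params) {
  validObject(params)
  t <- (geud - params@td50) / (params@m * params@td50)
  new("RiskResult", geud = geud, ntcp = stats::pnorm(t),
      endpoint = params@endpoint)
}

#' DVH-based rectal toxicity risk from a dose distribution
#'
#' Convenience chain: per-voxel EQD2 conversion (fractionation from the
#' plan), DVH within the mask, gEUD with the endpoint's volume exponent,
#' LKB NTCP.
#'
#' @param dose physical dose \linkS4class{ImageGrid}.
#' @param mask organ mask.
#' @param params \linkS4class{LKBParams}.
#' @param fractions fractions delivering the dose.
#' @param binWidth DVH bin width, Gy.
#' @return A \linkS4class{RiskResult}.
#' @export
rectalRisk <- function(dose, mask, params, fractions = 20, binWidth = 0.1) {
  eq <- withVoxels(dose, eqd2(dose@voxels, fractions, params@alphaBeta))
  dvh <- computeDVH(eq, mask, binWidth)
  lkbNTCP(gEUD(dvh, params@n), params)
}
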