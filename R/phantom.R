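#' PhantomConfig: parameters of the synthetic pelvic phantom
#'
#' The generator emulates the imaging study the pipeline targets: axial CT
#' stacks at 2.5 mm slice thickness and 0.98 mm in-plane pixels, a
#' co-registered T2-like MR, closed-polygon contours and a 60 Gy / 20
#' fraction prostate plan. Tissue mean HUs default to realistic values that
#' deliberately differ from the nominal stratification HUs (real fat is not
#' exactly -75 HU), so that tissue-stratified sCTs carry a realistic
#' systematic bias. \code{\link{nominalPhantomConfig}} instead paints exactly
#' the nominal HUs with zero noise, for exact-recovery controls.
#'
#' @slot gridShape (slices, rows, cols).
#' @slot spacing mm per axis.
#' @slot huMeans named tissue mean HUs; names cover air, gas, fat, muscle,
#'   spongy_bone, cortical_bone.
#' @slot huNoiseSD Gaussian CT noise SD, HU.
#' @slot mrIntensity named T2-like tissue intensities in arbitrary units.
#' @slot mrBiasAmplitude multiplicative bias-field amplitude (fraction).
#' @slot mrNoiseSD Rician noise sigma (arbitrary units).
#' @slot gasProb probability that the rectum carries gas pockets.
#' @slot nCalc number of calcification/fiducial speckles inside the CTV.
#' @slot geometry named list of organ geometry parameters, mm.
#' @slot seed integer master seed.
#' @export
setClass("PhantomConfig",
  representation(gridShape = "integer", spacing = "numeric",
                 huMeans = "numeric", huNoiseSD = "numeric",
                 mrIntensity = "numeric", mrBiasAmplitude = "numeric",
                 mrNoiseSD = "numeric", gasProb = "numeric",
                 nCalc = "integer", geometry = "list", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("air", "gas", "fat", "muscle", "spongy_bone", "cortical_bone")
    if (!all(need %in% names(object@huMeans)))
      msg <- c(msg, paste("huMeans must name:", paste(need, collapse = ", ")))
    g <- object@geometry
    rads <- c(g$rectumRadius, g$prostateRadius, g$bladderRadius, g$boneRadius)
    if (any(rads <= 0)) msg <- c(msg, "all radii must be positive")
    if (g$rectumOffset + g$rectumRadius > g$bodyRowAxis)
      msg <- c(msg, "rectum exceeds body extent")
    if (g$bladderRowOffset + g$bladderRadius > g$bodyRowAxis)
      msg <- c(msg, "bladder exceeds body extent")
    if (g$boneColOffset + g$boneRadius > g$bodyColAxis)
      msg <- c(msg, "bones exceed body extent")
    if (object@gasProb < 0 || object@gasProb > 1)
      msg <- c(msg, "gasProb must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Default phantom configuration
#'
#' @param seed integer master seed; all randomness (anatomy jitter, gas
#'   pockets, CT/MR noise, bias field) flows from it through named
#'   sub-generators.
#' @param gridShape,spacing grid geometry; default 40 x 128 x 128 voxels at
#'   (2.5, 0.98, 0.98) mm.
#' @param huNoiseSD CT noise SD (default 10 HU).
#' @param gasProb probability of rectal gas (default 0.8).
#' @param nCalc CTV calcification speckles (default 3).
#' @return A \linkS4class{PhantomConfig}.
#' @export
PhantomConfig <- function(seed = 1L, gridShape = c(40L, 128L, 128L),
                          spacing = c(2.5, 0.98, 0.98), huNoiseSD = 10,
                          gasProb = 0.8, nCalc = 3L,
                          huMeans = c(air = -1000, gas = -650, fat = -98,
                                      muscle = 45, spongy_bone = 250,
                                      cortical_bone = 1100),
                          mrBiasAmplitude = 0.15, mrNoiseSD = 0.02) {
  geometry <- list(
    bodyRowAxis = 52, bodyColAxis = 58,        # body ellipse semi-axes
    fatShellMm = 9,                            # subcutaneous fat thickness
    prostateRadius = 14, prostateZAxis = 15, prostateColAxis = 16,
    ptv60MarginMm = 5, ptv48MarginMm = 9,
    rectumOffset = 36,                         # posterior of prostate center
    rectumRadius = 9, rectumZHalfLength = 36,
    rectumCurveAmpMm = 3, rectumLateralAmpMm = 3,
    bladderRowOffset = 26, bladderZOffset = 16,
    bladderRadius = 13, bladderZAxis = 15,
    boneColOffset = 40, boneRadius = 11, boneZHalfLength = 30,
    corticalShellMm = 3.5,
    gasRadiusMm = 4, calcRadiusMm = 1.4)
  mrIntensity <- c(air = 0.02, gas = 0.03, fat = 0.92, muscle = 0.40,
                   spongy_bone = 0.45, cortical_bone = 0.08,
                   bladder = 0.95, prostate = 0.55)
  new("PhantomConfig", gridShape = as.integer(gridShape),
      spacing = spacing, huMeans = huMeans, huNoiseSD = huNoiseSD,
      mrIntensity = mrIntensity, mrBiasAmplitude = mrBiasAmplitude,
      mrNoiseSD = mrNoiseSD, gasProb = gasProb, nCalc = as.integer(nCalc),
      geometry = geometry, seed = as.integer(seed))
}

#' Noiseless nominal-HU phantom configuration
#'
#' Paints tissues at exactly the nominal stratification HUs with zero noise,
#' no calcification speckles and deterministic gas, so that stratifying the
#' CT and replacing classes by their nominal HUs reproduces the CT exactly
#' (the tissue-stratification-of-CT control).
#' @param seed integer master seed.
#' @param gasProb probability of rectal gas.
#' @return A \linkS4class{PhantomConfig}.
#' @export
nominalPhantomConfig <- function(seed = 1L, gasProb = 0.8) {
  PhantomConfig(seed = seed, huNoiseSD = 0, nCalc = 0L, gasProb = gasProb,
                huMeans = c(air = -1000, gas = -500, fat = -75, muscle = 0,
                            spongy_bone = 204, cortical_bone = 1067))
}

PHANTOM_LABELS <- c(outside = 0L, inside_air = 1L, fat = 2L, muscle = 3L,
                    spongy_bone = 4L, cortical_bone = 5L)

#' Phantom: co-registered CT, pseudo-MR, structures and plan
#'
#' @slot ct,mr \linkS4class{ImageGrid}s sharing one geometry.
#' @slot labels integer tissue label map (0 outside, 1 inside air/gas,
#'   2 fat, 3 muscle, 4 spongy bone, 5 cortical bone).
#' @slot structures \linkS4class{StructureSet} with BODY, FAT, MUSCLE,
#'   BONES, BONES_INTERIOR, RECTUM, RECTAL_GAS, BLADDER, CTV, PTV60, PTV48.
#' @slot plan \linkS4class{PlanConfig}.
#' @slot config the generating \linkS4class{PhantomConfig}.
#' @export
setClass("Phantom",
  representation(ct = "ImageGrid", mr = "ImageGrid", labels = "ImageGrid",
                 structures = "StructureSet", plan = "PlanConfig",
                 config = "PhantomConfig"),
  validity = function(object) {
    msg <- NULL
    if (!sameGeometry(object@ct, object@mr) ||
        !sameGeometry(object@ct, object@labels))
      msg <- c(msg, "ct, mr and labels must share geometry")
    ss <- object@structures
    if (!all(c("BODY", "RECTUM", "CTV", "PTV60") %in% names(ss@masks)))
      msg <- c(msg, "structures must include BODY, RECTUM, CTV, PTV60")
    else {
      rect <- apply(ss@masks[["RECTUM"]]@voxels, 1, any)
      runs <- rle(rect)
      if (max(c(0, runs$lengths[runs$values])) < 5)
        msg <- c(msg, "RECTUM must be non-empty on >= 5 contiguous slices")
      ctv <- ss@masks[["CTV"]]@voxels
      ptv <- ss@masks[["PTV60"]]@voxels
      body <- ss@masks[["BODY"]]@voxels
      if (any(ctv & !ptv) || any(ptv & !body))
        msg <- c(msg, "need CTV within PTV60 within BODY")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "Phantom", function(object) {
  d <- dim(object@ct@voxels)
  cat(sprintf("Phantom (seed %d): %d x %d x %d voxels\n",
              object@config@seed, d[1], d[2], d[3]))
  show(object@structures)
})

# Deterministic sub-seeds: one named stream per stochastic sub-process.
phantomSeeds <- function(seed) {
  base <- (abs(as.integer(seed)) %% 100000L) * 10000L
  c(anatomy = base + 11L, gas = base + 23L, ctNoise = base + 37L,
    mrBias = base + 53L, mrNoise = base + 71L, calc = base + 89L)
}

ellipsoidMask <- function(Z, Y, X, center, semi) {
  ((Z - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((X - center[3]) / semi[3])^2 <= 1
}

#' Generate a synthetic pelvic phantom
#'
#' Builds the anatomy label map (body with subcutaneous fat shell, femoral
#' heads with cortical shell and spongy core, bladder, prostate CTV, curved
#' rectum with optional gas pockets), paints the CT as tissue mean plus
#' Gaussian noise, synthesizes a T2-like MR, rasterizes the structure set
#' from analytic contours, and attaches the default treatment plan. Output
#' is deterministic for a fixed seed.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{Phantom}.
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  g <- config@geometry
  d <- config@gridShape
  sp <- config@spacing
  origin <- -(d - 1) / 2 * sp
  z <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  x <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  Z <- array(rep(z, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  X <- array(rep(x, each = d[1] * d[2]), d)

  seeds <- phantomSeeds(config@seed)
  set.seed(seeds[["anatomy"]])
  # small per-phantom anatomical variation
  jit <- stats::rnorm(6, 0, 1)
  bodyRow <- g$bodyRowAxis + jit[1]
  bodyCol <- g$bodyColAxis + 1.5 * jit[2]
  prostR <- g$prostateRadius * (1 + 0.04 * jit[3])
  rectR <- g$rectumRadius * (1 + 0.05 * jit[4])
  rectPhase <- stats::runif(1, 0, 2 * pi)
  bladderR <- g$bladderRadius * (1 + 0.05 * jit[5])

  body <- (Y / bodyRow)^2 + (X / bodyCol)^2 <= 1
  inner <- (Y / (bodyRow - g$fatShellMm))^2 +
           (X / (bodyCol - g$fatShellMm))^2 <= 1
  labels <- array(PHANTOM_LABELS[["outside"]], d)
  labels[body] <- PHANTOM_LABELS[["fat"]]
  labels[inner] <- PHANTOM_LABELS[["muscle"]]

  # femoral heads: cylinders along z with cortical shell and spongy core
  bones <- array(FALSE, d); spongyCore <- array(FALSE, d)
  for (sgn in c(-1, 1)) {
    cx <- sgn * g$boneColOffset
    inZ <- abs(Z) <= g$boneZHalfLength
    r2 <- (Y - 0)^2 + (X - cx)^2
    cyl <- inZ & r2 <= g$boneRadius^2
    core <- inZ & r2 <= (g$boneRadius - g$corticalShellMm)^2
    bones <- bones | cyl
    spongyCore <- spongyCore | core
  }
  labels[bones] <- PHANTOM_LABELS[["cortical_bone"]]
  labels[spongyCore] <- PHANTOM_LABELS[["spongy_bone"]]

  # bladder (urine-filled, muscle-equivalent HU, T2-bright)
  bladder <- ellipsoidMask(Z, Y, X,
                           c(g$bladderZOffset, g$bladderRowOffset, 0),
                           c(g$bladderZAxis, bladderR, bladderR + 2))
  bladder <- bladder & inner & !bones
  labels[bladder] <- PHANTOM_LABELS[["muscle"]]

  # prostate (CTV) centered at isocenter
  ctv <- ellipsoidMask(Z, Y, X, c(0, 0, 0),
                       c(g$prostateZAxis, prostR, g$prostateColAxis))
  ptv60 <- ellipsoidMask(Z, Y, X, c(0, 0, 0),
                         c(g$prostateZAxis + g$ptv60MarginMm,
                           prostR + g$ptv60MarginMm,
                           g$prostateColAxis + g$ptv60MarginMm)) & body
  ptv48 <- ellipsoidMask(Z, Y, X, c(0, 0, 0),
                         c(g$prostateZAxis + g$ptv48MarginMm,
                           prostR + g$ptv48MarginMm,
                           g$prostateColAxis + g$ptv48MarginMm)) & body

  # rectum: curved soft-tissue tube posterior to the prostate
  rectSlices <- which(abs(z) <= g$rectumZHalfLength)
  rectCenterRow <- -g$rectumOffset +
    g$rectumCurveAmpMm * sin(2 * pi * z / 180 + rectPhase)
  rectCenterCol <- g$rectumLateralAmpMm * cos(2 * pi * z / 160 + rectPhase)
  rectum <- array(FALSE, d)
  contours <- list()
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  for (i in rectSlices) {
    pts <- cbind(rectCenterRow[i] + rectR * cos(th),
                 rectCenterCol[i] + rectR * sin(th))
    contours[[length(contours) + 1]] <- Contour("RECTUM", i, pts)
  }
  refGrid <- ImageGrid(array(0, d), spacing = sp, origin = origin,
                       modality = "MASK", units = "bool")
  rectum <- rasterizeContours(contours, refGrid)@voxels
  labels[rectum] <- PHANTOM_LABELS[["muscle"]]

  # rectal gas pockets (inside the tube, away from the wall)
  set.seed(seeds[["gas"]])
  gas <- array(FALSE, d)
  if (stats::runif(1) < config@gasProb) {
    nPockets <- sample(1:2, 1)
    for (p in seq_len(nPockets)) {
      zc <- stats::runif(1, -g$rectumZHalfLength + 12,
                         g$rectumZHalfLength - 12)
      i0 <- which.min(abs(z - zc))
      pocket <- ellipsoidMask(Z, Y, X,
                              c(z[i0], rectCenterRow[i0], rectCenterCol[i0]),
                              c(g$gasRadiusMm * 2.2, g$gasRadiusMm,
                                g$gasRadiusMm))
      gas <- gas | (pocket & rectum)
    }
  }
  labels[gas] <- PHANTOM_LABELS[["inside_air"]]

  # paint CT: tissue mean + Gaussian noise within the body, -1000 outside
  hu <- config@huMeans
  lut <- c(hu[["air"]], hu[["gas"]], hu[["fat"]], hu[["muscle"]],
           hu[["spongy_bone"]], hu[["cortical_bone"]])
  ct <- array(lut[labels + 1L], d)
  set.seed(seeds[["calc"]])
  calc <- array(FALSE, d)
  if (config@nCalc > 0) {
    idx <- which(ctv & labels == PHANTOM_LABELS[["muscle"]])
    centers <- sample(idx, config@nCalc)
    for (ci in centers) {
      pos <- arrayInd(ci, d)
      speck <- ellipsoidMask(Z, Y, X,
                             c(z[pos[1]], y[pos[2]], x[pos[3]]),
                             rep(g$calcRadiusMm, 3))
      calc <- calc | speck
    }
    ct[calc] <- 300
  }
  if (config@huNoiseSD > 0) {
    set.seed(seeds[["ctNoise"]])
    noise <- array(stats::rnorm(prod(d), 0, config@huNoiseSD), d)
    ct[body] <- ct[body] + noise[body]
  }

  ctGrid <- ImageGrid(ct, spacing = sp, origin = origin, modality = "CT",
                      units = "HU")
  labGrid <- ImageGrid(labels, spacing = sp, origin = origin,
                       modality = "LABEL", units = "label")

  masks <- list(
    BODY = body, FAT = labels == PHANTOM_LABELS[["fat"]],
    MUSCLE = labels == PHANTOM_LABELS[["muscle"]],
    BONES = bones, BONES_INTERIOR = spongyCore,
    RECTUM = rectum, RECTAL_GAS = gas, BLADDER = bladder,
    CTV = ctv, PTV60 = ptv60, PTV48 = ptv48)
  masks <- lapply(masks, function(m)
    ImageGrid(m, spacing = sp, origin = origin, modality = "MASK",
              units = "bool"))
  structures <- StructureSet(contours = contours, masks = masks)

  phantom <- new("Phantom", ct = ctGrid, mr = ctGrid, labels = labGrid,
                 structures = structures,
                 plan = PlanConfig(isocenter = c(0, 0, 0)),
                 config = config)
  phantom@mr <- synthesizeMR(phantom, config)
  phantom
}

#' Synthesize a T2-like MR from a phantom's tissue labels
#'
#' Maps tissues to T2-like intensities (fat and urine bright, muscle mid,
#' cortical bone dark), deliberately breaking any affine relation to HU
#' (bright fat has low HU, dark bone has high HU), then applies a smooth
#' multiplicative bias field and Rician noise.
#'
#' @param phantom a \linkS4class{Phantom} (its labels and structures are
#'   used).
#' @param config a \linkS4class{PhantomConfig}.
#' @return MR \linkS4class{ImageGrid} on the phantom geometry.
#' @export
synthesizeMR <- function(phantom, config = phantom@config) {
  labels <- phantom@labels@voxels
  d <- dim(labels)
  mi <- config@mrIntensity
  lut <- c(mi[["air"]], mi[["gas"]], mi[["fat"]], mi[["muscle"]],
           mi[["spongy_bone"]], mi[["cortical_bone"]])
  mr <- array(lut[labels + 1L], d)
  mr[phantom@structures@masks[["BLADDER"]]@voxels] <- mi[["bladder"]]
  mr[phantom@structures@masks[["CTV"]]@voxels &
       labels == PHANTOM_LABELS[["muscle"]]] <- mi[["prostate"]]
  seeds <- phantomSeeds(config@seed)
  if (config@mrBiasAmplitude > 0) {
    set.seed(seeds[["mrBias"]])
    bias <- smoothRandomField(d, config@spacing, nModes = 4L)
    mr <- mr * (1 + config@mrBiasAmplitude * bias)
  }
  if (config@mrNoiseSD > 0) {
    set.seed(seeds[["mrNoise"]])
    e1 <- array(stats::rnorm(prod(d), 0, config@mrNoiseSD), d)
    e2 <- array(stats::rnorm(prod(d), 0, config@mrNoiseSD), d)
    mr <- sqrt((mr + e1)^2 + e2^2)   # Rician magnitude noise
  }
  ImageGrid(mr, spacing = phantom@mr@spacing, origin = phantom@mr@origin,
            modality = "MR", units = "arbitrary")
}

# Band-limited random field in [-1, 1]: sum of low-frequency cosine modes.
smoothRandomField <- function(d, sp, nModes = 4L) {
  origin <- -(d - 1) / 2 * sp
  z <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  x <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  Z <- array(rep(z, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  X <- array(rep(x, each = d[1] * d[2]), d)
  field <- array(0, d)
  for (m in seq_len(nModes)) {
    k <- stats::rnorm(3, 0, 1 / 120)   # wavelengths of order 100+ mm
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    field <- field + amp * cos(2 * pi * (k[1] * Z + k[2] * Y + k[3] * X) +
                               phase)
  }
  field / max(abs(field))
}

#' DeformationField: smooth per-voxel 3D displacement
#'
#' @slot dz,dy,dx displacement components, mm, on the phantom grid.
#' @slot maxMagnitude maximum displacement magnitude, mm.
#' @export
setClass("DeformationField",
  representation(dz = "array", dy = "array", dx = "array",
                 maxMagnitude = "numeric"),
  validity = function(object) {
    mag <- sqrt(object@dz^2 + object@dy^2 + object@dx^2)
    if (max(mag) > object@maxMagnitude + 1e-9)
      "displacement magnitude exceeds maxMagnitude" else TRUE
  })

#' Generate a smooth random deformation field
#'
#' @param d grid shape (slices, rows, cols).
#' @param spacing mm per axis.
#' @param maxMagnitudeMm maximum displacement magnitude, mm.
#' @param seed integer seed.
#' @return A \linkS4class{DeformationField}.
#' @export
randomDeformationField <- function(d, spacing, maxMagnitudeMm = 3,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  comps <- lapply(1:3, function(i) smoothRandomField(d, spacing, nModes = 3L))
  mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
  scale <- maxMagnitudeMm / max(mag)
  new("DeformationField", dz = comps[[1]] * scale, dy = comps[[2]] * scale,
      dx = comps[[3]] * scale, maxMagnitude = maxMagnitudeMm)
}

#' Uniform translation as a DeformationField
#'
#' @param d grid shape; @param shiftMm length-3 (slice, row, col) shift, mm.
#' @export
uniformShiftField <- function(d, shiftMm) {
  new("DeformationField", dz = array(shiftMm[1], d), dy = array(shiftMm[2], d),
      dx = array(shiftMm[3], d),
      maxMagnitude = sqrt(sum(shiftMm^2)) + 1e-12)
}

#' Apply a residual-misregistration perturbation to a phantom
#'
#' Warps the MR (pull-back sampling at position + displacement) while the CT
#' and CT-side structures stay fixed, emulating residual CT-MR mismatch
#' after deformable registration. Fields beyond 10 mm are rejected as
#' unphysical.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param field a \linkS4class{DeformationField} on the phantom grid.
#' @return A perturbed copy of the phantom.
#' @export
perturbRegistration <- function(phantom, field) {
  if (field@maxMagnitude > 10)
    stop("deformation magnitude > 10 mm rejected as unphysical")
  d <- dim(phantom@mr@voxels)
  if (!identical(dim(field@dz), d))
    stop("field must be on the phantom grid")
  warped <- cpp_warp(as.numeric(phantom@mr@voxels), d, phantom@mr@spacing,
                     as.numeric(field@dz), as.numeric(field@dy),
                     as.numeric(field@dx), 0)
  dim(warped) <- d
  out <- phantom
  out@mr <- withVoxels(phantom@mr, warped)
  out
}
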