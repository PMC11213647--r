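#' Build a synthetic CT for a phantom by a named strategy
#'
#' Methods: "identity" (the planning CT itself, the null control), "bdw"
#' (water-equivalent bulk density, body = 0 HU), "bdp" (population bulk
#' density; supply \code{populationHU}), "ts" (tissue stratification as
#' performed on the MR side: threshold classes with nominal-HU replacement,
#' carrying a residual-misregistration displacement of the tissue
#' boundaries), "ts_ct" (stratification of the planning CT itself -- the
#' registration-free control), "ai" (U-Net inference from the phantom MR;
#' supply \code{model}).
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param method one of "identity", "bdw", "bdp", "ts", "ts_ct", "ai".
#' @param populationHU body fill HU for "bdp".
#' @param model \linkS4class{UNetModel} for "ai".
#' @param rules \linkS4class{StratificationRules} for "ts"/"ts_ct".
#' @param misregField \linkS4class{DeformationField} of residual
#'   registration error for "ts"; default a smooth 3 mm field seeded from
#'   the phantom.
#' @return CT-valued \linkS4class{ImageGrid}.
#' @export
makeSCT <- function(phantom, method = c("identity", "bdw", "bdp", "ts",
                                        "ts_ct", "ai"),
                    populationHU = NULL, model = NULL,
                    rules = StratificationRules(), misregField = NULL) {
  method <- match.arg(method)
  body <- structureMask(phantom@structures, "BODY")
  switch(method,
    identity = phantom@ct,
    bdw = makeBulkDensitySCT(body, 0),
    bdp = {
      if (is.null(populationHU))
        stop("method 'bdp' needs populationHU (see populationMeanHU)")
      makeBulkDensitySCT(body, populationHU)
    },
    ts = {
      labels <- stratifyTissues(phantom@ct, rules, phantom@structures)
      if (is.null(misregField))
        misregField <- randomDeformationField(dim(voxels(phantom@ct)),
                                              spacing(phantom@ct),
                                              maxMagnitudeMm = 3,
                                              seed = phantom@config@seed + 501L)
      warped <- cpp_warp(as.numeric(voxels(labels)), dim(voxels(labels)),
                         spacing(labels), as.numeric(misregField@dz),
                         as.numeric(misregField@dy),
                         as.numeric(misregField@dx), 0, nearest = TRUE)
      warped <- array(as.integer(warped), dim(voxels(labels)))
      # the body outline itself is delineated on the co-registered MR
      warped[!voxels(body)] <- 0L
      warped[voxels(body) & warped == 0L] <- 3L
      makeTissueSCT(withVoxels(labels, warped), rules)
    },
    ts_ct = makeTissueSCT(stratifyTissues(phantom@ct, rules,
                                          phantom@structures), rules),
    ai = {
      if (is.null(model)) stop("method 'ai' needs a trained UNetModel")
      inferSCT(model, phantom@mr)
    })
}

#' Train an overfit U-Net on one phantom's own slices
#'
#' Trains on a subset of slices spanning the target region of a single
#' phantom (MR input, CT label), the small-scale analogue of the study's
#' per-cohort training; used for self-consistency and method-ordering
#' experiments.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param config \linkS4class{UNetConfig}.
#' @param slices training slice indices; default 8 slices evenly covering
#'   the central two thirds of the stack.
#' @param nProbes,probeEpochs optional restart schedule: nProbes short
#'   seeded probe runs of probeEpochs each, continuing the probe with the
#'   lowest eval-mode error on the training slices.
#' @return A \linkS4class{UNetModel}.
#' @export
trainPhantomUNet <- function(phantom, config = UNetConfig(baseFilters = 8,
                                                          epochs = 60),
                             slices = NULL, nProbes = 1, probeEpochs = 0) {
  d <- dim(phantom@ct@voxels)
  if (is.null(slices))
    slices <- unique(round(seq(d[1] / 6, d[1] * 5 / 6, length.out = 8)))
  mrN <- normalizeMR(phantom@mr)$norm[slices, , , drop = FALSE]
  ctN <- normalizeCT(phantom@ct)[slices, , , drop = FALSE]
  trainWithRestarts(mrN, ctN, config, nProbes, probeEpochs)
}

# Deterministic restart schedule: nProbes short runs from distinct seeds,
# continue the one with the lowest eval-mode MSE on the training slices
# (selection never touches anything outside the training data).
trainWithRestarts <- function(mrN, ctN, config, nProbes, probeEpochs) {
  if (nProbes <= 1 || probeEpochs <= 0 || config@epochs <= probeEpochs)
    return(trainUNet(mrN, ctN, config))
  probes <- lapply(seq_len(nProbes), function(k) {
    cfg <- config
    cfg@epochs <- as.integer(probeEpochs)
    cfg@seed <- as.integer(config@seed + 1000L * (k - 1L))
    trainUNet(mrN, ctN, cfg)
  })
  evalMSE <- vapply(probes, function(m) {
    pred <- cpp_unet_infer(m@weights, aperm(mrN, c(2, 3, 1)),
                           m@config@levels, m@config@baseFilters)
    mean((aperm(pred, c(3, 1, 2)) - ctN)^2)
  }, numeric(1))
  best <- probes[[which.min(evalMSE)]]
  cfg <- best@config
  cfg@epochs <- as.integer(config@epochs - probeEpochs)
  trainUNet(mrN, ctN, cfg, init = best)
}

#' Train one U-Net on pooled slices from a phantom cohort
#'
#' The cohort analogue of the study's training design: one network fitted
#' to MR/CT slice pairs pooled over several phantoms. To protect against
#' occasional poor weight initializations, several short seeded probe runs
#' are trained first and the one with the lowest eval-mode error on the
#' training slices is continued. Training then proceeds in segments with
#' one held-out slice per phantom: the checkpoint with the lowest held-out
#' MSE is kept and training stops once that has plateaued (or at the epoch
#' cap) -- train-until-plateau with validated checkpointing. Selection
#' never uses dose or toxicity results.
#'
#' @param phantoms list of \linkS4class{Phantom}s.
#' @param config \linkS4class{UNetConfig}; \code{config@epochs} caps the
#'   total training length including the probe epochs.
#' @param slicesPerPhantom training slices per phantom (evenly over the
#'   central two thirds of each stack).
#' @param nProbes,probeEpochs restart-probe schedule.
#' @param segmentEpochs epochs between validation checkpoints.
#' @param patience consecutive non-improving checkpoints before stopping.
#' @return A \linkS4class{UNetModel} (the best-validation checkpoint).
#' @export
trainCohortUNet <- function(phantoms, config = UNetConfig(baseFilters = 16,
                                                          epochs = 100,
                                                          lr = 2e-3,
                                                          batchSize = 1),
                            slicesPerPhantom = 5, nProbes = 2,
                            probeEpochs = 10, segmentEpochs = 10,
                            patience = 2) {
  d <- dim(phantoms[[1]]@ct@voxels)
  slices <- unique(round(seq(d[1] / 6, d[1] * 5 / 6,
                             length.out = slicesPerPhantom)))
  valSlice <- setdiff(round(d[1] / 2) + 3L, slices)[1]
  if (is.na(valSlice)) valSlice <- round(d[1] / 2) + 2L
  mrN <- do.call(abind3, lapply(phantoms, function(p)
    normalizeMR(p@mr)$norm[slices, , , drop = FALSE]))
  ctN <- do.call(abind3, lapply(phantoms, function(p)
    normalizeCT(p@ct)[slices, , , drop = FALSE]))
  mrV <- do.call(abind3, lapply(phantoms, function(p)
    normalizeMR(p@mr)$norm[valSlice, , , drop = FALSE]))
  ctV <- do.call(abind3, lapply(phantoms, function(p)
    normalizeCT(p@ct)[valSlice, , , drop = FALSE]))

  evalMSE <- function(m, mr, ct) {
    pred <- cpp_unet_infer(m@weights, aperm(mr, c(2, 3, 1)),
                           m@config@levels, m@config@baseFilters)
    mean((aperm(pred, c(3, 1, 2)) - ct)^2)
  }
  # probe restarts, selected on training slices only
  probes <- lapply(seq_len(nProbes), function(k) {
    cfg <- config
    cfg@epochs <- as.integer(probeEpochs)
    cfg@seed <- as.integer(config@seed + 1000L * (k - 1L))
    trainUNet(mrN, ctN, cfg)
  })
  model <- probes[[which.min(vapply(probes, evalMSE, numeric(1),
                                    mr = mrN, ct = ctN))]]
  # continue in segments, keep the checkpoint with the lowest MSE on the
  # held-out cohort slices, stop when it has plateaued
  best <- model
  bestVal <- evalMSE(model, mrV, ctV)
  bad <- 0L
  done <- probeEpochs
  while (done < config@epochs && bad < patience) {
    cfg <- model@config
    cfg@epochs <- as.integer(min(segmentEpochs, config@epochs - done))
    model <- trainUNet(mrN, ctN, cfg, init = model)
    done <- done + cfg@epochs
    val <- evalMSE(model, mrV, ctV)
    if (val < bestVal) {
      bestVal <- val
      best <- model
      bad <- 0L
    } else bad <- bad + 1L
  }
  best
}

# bind 3D arrays along the first (slice) axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Dose-derived toxicity predictors of one dose distribution
#'
#' Plan-quality DVH metrics (PTV60 median and D95, PTV48 D95, rectal V60),
#' LKB NTCP for grade-2 rectal bleeding and late faecal incontinence
#' (per-voxel EQD2, alpha/beta = 3), and the two Buettner DSM parameters.
#'
#' @param dose dose \linkS4class{ImageGrid}.
#' @param phantom the \linkS4class{Phantom} providing structures and plan.
#' @return named list of scalar predictors.
#' @export
toxicityPredictors <- function(dose, phantom) {
  ss <- phantom@structures
  fx <- phantom@plan@fractions
  dvh60 <- computeDVH(dose, structureMask(ss, "PTV60"))
  dvh48 <- computeDVH(dose, structureMask(ss, "PTV48"))
  rectMask <- structureMask(ss, "RECTUM")
  dvhRect <- computeDVH(dose, rectMask)
  g2 <- rectalRisk(dose, rectMask, g2rbParams(), fractions = fx)
  lfi <- rectalRisk(dose, rectMask, lfiParams(), fractions = fx)
  dsm <- dsmParameters(dose, structureContours(ss, "RECTUM"),
                       fractions = fx)
  list(ptv60_median = dvhMetric(dvh60, "Dmedian"),
       ptv60_d95 = dvhMetric(dvh60, "D95"),
       ptv48_d95 = dvhMetric(dvh48, "D95"),
       rectum_v60_pct = 100 * dvhMetric(dvhRect, "V", doseGy = 60),
       g2rb_risk_pct = 100 * g2@ntcp,
       lfi_risk_pct = 100 * lfi@ntcp,
       g2rb_geud = g2@geud,
       rel_area51 = dsm$relArea51,
       rel_lat_extent61 = dsm$relLatExtent61)
}

#' Run the synthetic-CT comparison study on seeded phantoms
#'
#' For each seed: generate a phantom, create and normalize the plan on the
#' planning CT, then for every requested sCT method recalculate dose with
#' fixed fluence and evaluate all toxicity predictors. The "bdp" fill value
#' is the pooled body mean HU over a separate training-seed cohort; the
#' "ai" model is overfit per phantom on its own slices.
#'
#' @param seeds phantom seeds (test cohort).
#' @param methods subset of c("bdw", "bdp", "ts", "ts_ct", "ai",
#'   "identity").
#' @param configFn function(seed) giving the \linkS4class{PhantomConfig}.
#' @param unetConfig \linkS4class{UNetConfig} for the "ai" method (one
#'   cohort network trained on pooled slices of the test phantoms -- the
#'   overfit design).
#' @param trainingSeeds seeds of the bdp population cohort.
#' @param stepMm dose-engine ray step.
#' @return list with per-seed results: truth predictors, per-method
#'   predictors, and a list of \linkS4class{PairedErrors} per
#'   method x metric.
#' @export
runSCTStudy <- function(seeds, methods = c("bdw", "ts", "ai"),
                        configFn = function(s) PhantomConfig(seed = s),
                        unetConfig = UNetConfig(baseFilters = 16,
                                                epochs = 100, lr = 2e-3,
                                                batchSize = 1, seed = 17),
                        trainingSeeds = NULL, stepMm = 1) {
  popHU <- NULL
  if ("bdp" %in% methods) {
    if (is.null(trainingSeeds)) trainingSeeds <- max(seeds) + 1:4
    tr <- lapply(trainingSeeds, function(s) generatePhantom(configFn(s)))
    popHU <- populationMeanHU(lapply(tr, function(p) p@ct),
                              lapply(tr, function(p)
                                structureMask(p@structures, "BODY")))
  }
  phantoms <- lapply(seeds, function(s) generatePhantom(configFn(s)))
  model <- if ("ai" %in% methods)
    trainCohortUNet(phantoms, unetConfig)
  else NULL
  perSeed <- list()
  for (i in seq_along(seeds)) {
    phantom <- phantoms[[i]]
    ptv60 <- structureMask(phantom@structures, "PTV60")
    planned <- planDose(phantom@ct, phantom@plan, ptv60, stepMm = stepMm)
    phantom@plan <- planned$plan
    truth <- toxicityPredictors(planned$dose, phantom)
    res <- list()
    for (m in methods) {
      sct <- makeSCT(phantom, m, populationHU = popHU, model = model)
      dose <- recalcFixedMU(sct, phantom@plan, ptv60, stepMm = stepMm)
      res[[m]] <- toxicityPredictors(dose, phantom)
    }
    perSeed[[as.character(seeds[i])]] <- list(truth = truth, methods = res)
  }
  metrics <- names(perSeed[[1]]$truth)
  paired <- list()
  for (m in methods) for (met in metrics) {
    truthV <- vapply(perSeed, function(x) x$truth[[met]], numeric(1))
    sctV <- vapply(perSeed, function(x) x$methods[[m]][[met]], numeric(1))
    paired[[paste(m, met, sep = ".")]] <- PairedErrors(m, met, truthV, sctV)
  }
  list(perSeed = perSeed, paired = paired, populationHU = popHU)
}
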