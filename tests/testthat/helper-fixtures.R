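# Shared fixtures. Heavy objects (phantoms, planned doses, trained networks)
# are memoized in this environment so multiple test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# small uniform grid helper
makeGrid <- function(value = 0, d = c(4L, 8L, 8L), spacing = c(2.5, 1, 1),
                     modality = "CT", units = "HU") {
  ImageGrid(array(value, d), spacing = spacing, modality = modality,
            units = units)
}

# closed circle contour (row/col mm), counter-clockwise vertex order
circleContour <- function(structure, slice, center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  Contour(structure, slice,
          cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)))
}

defaultPhantom <- function(seed = 1)
  memoFixture(paste0("phantom", seed),
              generatePhantom(PhantomConfig(seed = seed)))

nominalPhantom <- function(seed = 1)
  memoFixture(paste0("nominal", seed),
              generatePhantom(nominalPhantomConfig(seed = seed)))

# phantom with its plan normalized on the planning CT
plannedPhantom <- function(seed = 1, nominal = FALSE) {
  key <- paste0("planned", seed, if (nominal) "n" else "")
  memoFixture(key, {
    ph <- if (nominal) generatePhantom(nominalPhantomConfig(seed = seed))
          else generatePhantom(PhantomConfig(seed = seed))
    pl <- planDose(ph@ct, ph@plan,
                   structureMask(ph@structures, "PTV60"))
    ph@plan <- pl$plan
    list(phantom = ph, dose = pl$dose)
  })
}

# the single-phantom overfit protocol (pilot-calibrated: per-slice Adam
# steps, raised learning rate), trained on 4 central slices of the
# noiseless nominal phantom; shared by the U-Net tests
overfitSlices <- c(14L, 18L, 22L, 26L)

overfitModel <- function(seed = 1) {
  memoFixture(paste0("unet", seed), {
    ph <- nominalPhantom(seed)
    trainPhantomUNet(ph,
                     UNetConfig(baseFilters = 8, epochs = 200, lr = 2e-3,
                                batchSize = 1, seed = seed * 13 + 7),
                     slices = overfitSlices, nProbes = 2, probeEpochs = 5)
  })
}
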