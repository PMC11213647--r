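test_that("phantom generation is deterministic for a fixed seed", {
  a <- generatePhantom(PhantomConfig(seed = 3))
  b <- generatePhantom(PhantomConfig(seed = 3))
  expect_identical(voxels(a@ct), voxels(b@ct))
  expect_identical(voxels(a@mr), voxels(b@mr))
  expect_identical(voxels(a@labels), voxels(b@labels))
})

test_that("noiseless phantom paints tissues at their exact means", {
  ph <- nominalPhantom(1)
  fat <- voxels(structureMask(ph@structures, "FAT"))
  expect_true(all(voxels(ph@ct)[fat] == -75))
  gas <- voxels(structureMask(ph@structures, "RECTAL_GAS"))
  expect_true(all(voxels(ph@ct)[gas] == -500))
  outside <- !voxels(structureMask(ph@structures, "BODY"))
  expect_true(all(voxels(ph@ct)[outside] == -1000))
})

test_that("mean body HU matches the label-map mixture mean", {
  ph <- defaultPhantom(1)
  cfg <- ph@config
  body <- voxels(structureMask(ph@structures, "BODY"))
  lab <- voxels(ph@labels)[body]
  lut <- c(cfg@huMeans[["gas"]], cfg@huMeans[["fat"]], cfg@huMeans[["muscle"]],
           cfg@huMeans[["spongy_bone"]], cfg@huMeans[["cortical_bone"]])
  mixture <- mean(lut[lab])   # volume-weighted analytic mean (no noise term)
  # calcification speckles shift the mean by < 0.1 HU; noise SE dominates
  se <- cfg@huNoiseSD / sqrt(sum(body))
  calcShift <- sum(voxels(ph@ct)[body] - lut[lab]) / sum(body)
  expect_lt(abs(mean(voxels(ph@ct)[body]) - mixture - calcShift), 3 * se)
  expect_lt(abs(mean(voxels(ph@ct)[body]) - mixture), 0.5)
})

test_that("structure labels partition the body", {
  ph <- defaultPhantom(1)
  ss <- ph@structures
  fat <- voxels(structureMask(ss, "FAT"))
  mus <- voxels(structureMask(ss, "MUSCLE"))
  bon <- voxels(structureMask(ss, "BONES"))
  gas <- voxels(structureMask(ss, "RECTAL_GAS"))
  expect_false(any(fat & mus) || any(fat & bon) || any(mus & bon) ||
                 any(gas & (fat | mus)))
  body <- voxels(structureMask(ss, "BODY"))
  expect_true(all(body == (fat | mus | bon | gas)))
  # containment chain
  ctv <- voxels(structureMask(ss, "CTV"))
  p60 <- voxels(structureMask(ss, "PTV60"))
  p48 <- voxels(structureMask(ss, "PTV48"))
  expect_true(all(p60[ctv]) && all(p48[p60]) && all(body[p48]))
})

test_that("seed changes voxels but preserves structure topology", {
  a <- defaultPhantom(1)
  b <- memoFixture("phantom2", generatePhantom(PhantomConfig(seed = 2)))
  expect_false(identical(voxels(a@ct), voxels(b@ct)))
  for (nm in c("BODY", "RECTUM", "CTV", "PTV60", "BLADDER")) {
    sa <- apply(voxels(structureMask(a@structures, nm)), 1, any)
    sb <- apply(voxels(structureMask(b@structures, nm)), 1, any)
    expect_identical(sa, sb)   # same axial footprint
  }
})

test_that("synthetic MR has T2-like contrast and is not affine in HU", {
  ph <- defaultPhantom(1)
  mr <- voxels(ph@mr)
  bone <- voxels(structureMask(ph@structures, "BONES")) &
    voxels(ph@labels) == 5
  mus <- voxels(structureMask(ph@structures, "MUSCLE"))
  expect_lt(median(mr[bone]), median(mr[mus]))   # cortical dark on T2
  body <- voxels(structureMask(ph@structures, "BODY"))
  expect_lt(abs(cor(mr[body], voxels(ph@ct)[body])), 0.9)
})

test_that("bias-free noiseless MR is piecewise constant per tissue", {
  cfg <- PhantomConfig(seed = 4, huNoiseSD = 0, mrBiasAmplitude = 0,
                       mrNoiseSD = 0, nCalc = 0L)
  ph <- generatePhantom(cfg)
  fat <- voxels(structureMask(ph@structures, "FAT"))
  expect_equal(unique(voxels(ph@mr)[fat]), cfg@mrIntensity[["fat"]])
})

test_that("registration perturbation warps MR only and respects limits", {
  ph <- defaultPhantom(1)
  d <- dim(voxels(ph@ct))
  zero <- uniformShiftField(d, c(0, 0, 0))
  same <- perturbRegistration(ph, zero)
  expect_equal(voxels(same@mr), voxels(ph@mr), tolerance = 1e-12)
  expect_identical(voxels(same@ct), voxels(ph@ct))

  shift <- uniformShiftField(d, c(0, 2, 0))   # 2 mm anterior
  warped <- perturbRegistration(ph, shift)
  com <- function(v) {
    rows <- sctDose:::axisCoords(ph@mr, 2)
    w <- apply(v, 2, sum)
    sum(rows * w) / sum(w)
  }
  # pull-back warp by +2 mm displacement shifts content by -2 mm
  expect_equal(com(voxels(warped@mr)) - com(voxels(ph@mr)), -2,
               tolerance = 0.1)

  big <- uniformShiftField(d, c(0, 11, 0))
  expect_error(perturbRegistration(ph, big), "unphysical")
})

test_that("a warped gas pocket no longer aligns with the CT gas mask", {
  ph <- defaultPhantom(1)
  gasCT <- voxels(structureMask(ph@structures, "RECTAL_GAS"))
  expect_gt(sum(gasCT), 0)
  d <- dim(gasCT)
  field <- uniformShiftField(d, c(0, 3, 0))
  warpedGas <- sctDose:::cpp_warp(as.numeric(gasCT), d, spacing(ph@ct),
                                  as.numeric(field@dz), as.numeric(field@dy),
                                  as.numeric(field@dx), 0) > 0.5
  dice <- 2 * sum(gasCT & warpedGas) / (sum(gasCT) + sum(warpedGas))
  expect_lt(dice, 1)
})
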