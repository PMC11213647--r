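test_that("bulk-density sCTs fill the body uniformly and leave air outside", {
  ph <- defaultPhantom(1)
  body <- structureMask(ph@structures, "BODY")
  bdw <- makeBulkDensitySCT(body, 0)
  expect_true(all(voxels(bdw)[voxels(body)] == 0))
  expect_true(all(voxels(bdw)[!voxels(body)] == -1000))
  bdp <- makeBulkDensitySCT(body, 11)
  expect_true(all(voxels(bdp)[voxels(body)] == 11))
  empty <- ImageGrid(array(FALSE, dim(voxels(body))), modality = "MASK",
                     units = "bool")
  expect_error(makeBulkDensitySCT(empty, 0), "empty")
})

test_that("population mean HU pools voxels across the cohort", {
  m <- ImageGrid(array(TRUE, c(2, 3, 3)), modality = "MASK", units = "bool")
  ct11 <- ImageGrid(array(11, c(2, 3, 3)))
  expect_equal(populationMeanHU(list(ct11), list(m)), 11)
  ct0 <- ImageGrid(array(0, c(2, 3, 3)))
  ct22 <- ImageGrid(array(22, c(2, 3, 3)))
  expect_equal(populationMeanHU(list(ct0, ct22), list(m, m)), 11)

  # phantom cohort vs flat-concatenation oracle
  phs <- lapply(1:3, function(s) defaultPhantom(s))
  cts <- lapply(phs, function(p) p@ct)
  masks <- lapply(phs, function(p) structureMask(p@structures, "BODY"))
  pooled <- unlist(lapply(seq_along(phs), function(i)
    voxels(cts[[i]])[voxels(masks[[i]])]))
  expect_equal(populationMeanHU(cts, masks), mean(pooled), tolerance = 1e-9)
  expect_error(populationMeanHU(list(), list()), "non-empty")
})

test_that("tissue stratification recovers a noiseless phantom's label map", {
  ph <- nominalPhantom(1)
  lab <- stratifyTissues(ph@ct, StratificationRules(), ph@structures)
  expect_identical(voxels(lab), voxels(ph@labels))
})

test_that("CTV calcifications and bone-interior soft voxels are reassigned", {
  ph <- defaultPhantom(1)
  rules <- StratificationRules()
  lab <- stratifyTissues(ph@ct, rules, ph@structures)
  # calcification speckles (300 HU, spongy range) inside CTV -> muscle
  calcVox <- voxels(structureMask(ph@structures, "CTV")) &
    voxels(ph@ct) > 250
  expect_gt(sum(calcVox), 0)
  expect_true(all(voxels(lab)[calcVox] == 3))

  # a -20 HU voxel (fat range) inside the spongy interior -> spongy bone
  ct2 <- ph@ct
  interior <- which(voxels(structureMask(ph@structures, "BONES_INTERIOR")))
  v <- voxels(ct2); v[interior[1]] <- -20
  ct2 <- sctDose:::withVoxels(ph@ct, v)
  lab2 <- stratifyTissues(ct2, rules, ph@structures)
  expect_equal(voxels(lab2)[interior[1]], 4)

  # overrides require the structures they reference
  ss <- ph@structures
  ss@masks <- ss@masks[setdiff(names(ss@masks), "BONES_INTERIOR")]
  ss@contours <- list()
  expect_error(stratifyTissues(ph@ct, rules, ss), "BONES_INTERIOR")
})

test_that("nominal-HU replacement produces only the five printed values", {
  ph <- defaultPhantom(1)
  rules <- StratificationRules()
  sct <- makeTissueSCT(stratifyTissues(ph@ct, rules, ph@structures), rules)
  expect_true(all(voxels(sct) %in% c(-1000, -500, -75, 0, 204, 1067)))
  # class anchors
  lab <- ImageGrid(array(c(0L, 1L, 2L, 3L, 4L, 5L), c(1, 2, 3)),
                   modality = "LABEL", units = "label")
  out <- voxels(makeTissueSCT(lab, rules))
  expect_equal(as.vector(out), c(-1000, -500, -75, 0, 204, 1067))
  bad <- ImageGrid(array(7L, c(1, 1, 1)), modality = "LABEL", units = "label")
  expect_error(makeTissueSCT(bad, rules), "unknown label")
})

test_that("stratify-then-replace on a noiseless nominal phantom is exact", {
  ph <- nominalPhantom(1)
  rules <- StratificationRules()
  sct <- makeTissueSCT(stratifyTissues(ph@ct, rules, ph@structures), rules)
  expect_identical(voxels(sct), voxels(ph@ct))
})

test_that("HU error metrics match hand computations and satisfy mae >= |me|", {
  g <- makeGrid(0, d = c(1L, 1L, 2L))
  region <- ImageGrid(array(TRUE, c(1, 1, 2)), modality = "MASK",
                      units = "bool")
  same <- huErrorMetrics(g, g, region)
  expect_equal(c(same$me, same$mae, same$sd), c(0, 0, 0))
  plus5 <- sctDose:::withVoxels(g, voxels(g) + 5)
  m5 <- huErrorMetrics(plus5, g, region)
  expect_equal(c(m5$me, m5$mae, m5$sd), c(5, 5, 0))
  pm2 <- sctDose:::withVoxels(g, array(c(-2, 2), c(1, 1, 2)))
  m2 <- huErrorMetrics(pm2, g, region)
  expect_equal(c(m2$me, m2$mae), c(0, 2))
  expect_equal(m2$sd, 2 * sqrt(2), tolerance = 1e-12)   # n - 1 = 1
  set.seed(9)
  for (i in 1:20) {
    a <- sctDose:::withVoxels(g, array(rnorm(2, 0, 50), c(1, 1, 2)))
    mm <- huErrorMetrics(a, g, region)
    expect_gte(mm$mae, abs(mm$me))
  }
  emptyR <- ImageGrid(array(FALSE, c(1, 1, 2)), modality = "MASK",
                      units = "bool")
  expect_error(huErrorMetrics(g, g, emptyR), "empty")
})
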