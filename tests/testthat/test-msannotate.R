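# Calibration, noise filtering, ppm matching and RT-CV verification.

test_that("ppm error is signed relative deviation in parts per million", {
  expect_identical(ppmError(500, 500), 0)
  expect_equal(ppmError(500.025, 500), 50, tolerance = 1e-9)
  expect_equal(ppmError(499.975, 500), -50, tolerance = 1e-9)
  expect_error(ppmError(500, 0), "positive")
})

test_that("calibration fits recover planted linear distortions", {
  # error-free standards: identity model
  theo <- c(300.2, 538.5, 760.6)
  cal <- fitMassCalibration(theo, theo)
  expect_equal(calibrationSlope(cal), 1, tolerance = 1e-12)
  expect_equal(calibrationIntercept(cal), 0, tolerance = 1e-10)

  # constant +30 ppm bias: corrected standards near-exact
  obs <- theo * (1 + 30e-6)
  cal <- fitMassCalibration(obs, theo)
  expect_lt(max(abs(residualPpm(cal))), 0.1)

  # single standard: offset-only model, slope pinned at 1
  cal1 <- fitMassCalibration(500.010, 500.000)
  expect_identical(calibrationSlope(cal1), 1)
  expect_equal(calibrationIntercept(cal1), -0.010, tolerance = 1e-12)

  expect_error(fitMassCalibration(numeric(), numeric()), "at least one")
  expect_error(fitMassCalibration(c(500, -1), c(500, 400)), "positive")
})

test_that("applying a calibration shifts m/z and nothing else", {
  feat <- data.frame(mz = c(500, 700), intensity = c(10, 20), rt = c(1, 2))
  ident <- fitMassCalibration(c(400, 600), c(400, 600))
  expect_equal(applyCalibration(feat, ident), feat, tolerance = 1e-9)

  offs <- fitMassCalibration(c(400.01, 600.01), c(400, 600))
  shifted <- applyCalibration(feat, offs)
  expect_equal(shifted$mz, feat$mz - 0.01, tolerance = 1e-9)
  expect_identical(shifted$intensity, feat$intensity)
  expect_identical(shifted$rt, feat$rt)
})

test_that("calibration then matching undoes a planted +30 ppm bias", {
  cfg <- simConfig(seed = 11, massBiasPpm = 30, nDbLipids = 40)
  db <- makeToyDb(40, seed = 11, minSeparationPpm = 120)
  run <- simulateShotgunRun(db, cfg)
  cal <- fitMassCalibration(run$standards$observed_mz,
                            run$standards$theoretical_mz)
  corrected <- applyCalibration(run$features, cal)
  truth <- run$groundTruth[run$groundTruth$kind != "noise", ]
  residual <- ppmError(corrected$mz[truth$feature], truth$true_mz)
  expect_lt(median(abs(residual)), 2)
})

test_that("noise baseline is the median of the lowest intensity decile", {
  expect_equal(estimateNoiseBaseline(rep(3.5, 25)), 3.5)
  expect_equal(estimateNoiseBaseline(c(rep(1, 90), rep(1000, 10))), 1)
  expect_error(estimateNoiseBaseline(numeric()), "empty")
})

test_that("noise filter keeps exactly the features at or above k x baseline", {
  feat <- data.frame(mz = 1:5, intensity = c(1, 2, 3.9, 4, 7))
  kept <- filterNoise(feat, baseline = 2, noiseFactor = 2)
  expect_equal(kept$intensity, c(4, 7))
  # boundary is inclusive: "at least twice the level"
  expect_true(4 %in% filterNoise(feat, 2, 2)$intensity)
  # zero baseline keeps everything
  expect_equal(nrow(filterNoise(feat, 0, 2)), 5L)
  expect_error(filterNoise(feat, -1, 2), "negative")
  # monotone: raising the factor never adds a feature
  set.seed(3)
  f2 <- data.frame(mz = 1:50, intensity = rlnorm(50, 1, 1))
  prev <- f2
  for (k in c(1, 2, 4, 8)) {
    cur <- filterNoise(f2, 0.8, k)
    expect_true(all(cur$mz %in% prev$mz))
    prev <- cur
  }
})

test_that("matchFeatures equals a brute-force all-pairs scan", {
  adducts <- defaultAdducts("positive")
  for (seed in 1:8) {
    inst <- randomMatchInstance(nFeat = 40, nDb = 30, seed = seed)
    ann <- matchFeatures(inst$features, inst$db, adducts)
    for (i in seq_len(nrow(inst$features))) {
      ref <- oracleBestMatch(inst$features$mz[i], inst$db, adducts, 50)
      if (is.null(ref)) {
        expect_true(is.na(ann$lipid_id[i]))
      } else {
        expect_identical(ann$lipid_id[i], ref$lipid_id)
        expect_equal(ann$ppm_error[i], ref$ppm, tolerance = 1e-12)
      }
    }
  }
})

test_that("matchFeatures applies the tolerance and tie-break contracts", {
  db <- lipidDb(id = c("AAA", "BBB"), name = c("a", "b"),
                category = "sterols", monoisotopic_mass = c(400, 500))
  prot <- adductSpec("protonated", 1.007276, 1L, "positive")

  # exact theoretical m/z: ppm 0
  f0 <- data.frame(mz = 501.007276, polarity = "positive")
  ann <- matchFeatures(f0, db, prot)
  expect_identical(ann$lipid_id, "BBB")
  expect_equal(ann$ppm_error, 0, tolerance = 1e-9)

  # 51 ppm away from the only candidate: unannotated at tol 50
  f51 <- data.frame(mz = 501.007276 * (1 + 51e-6), polarity = "positive")
  expect_true(is.na(matchFeatures(f51, db[2, ], prot)$lipid_id))

  # exact |ppm| tie (two records at the same mass): lexicographically
  # lower id wins and both remain recorded as candidates
  db2 <- lipidDb(id = c("LIPB", "LIPA"), name = c("b", "a"),
                 category = "sterols", monoisotopic_mass = c(500, 500))
  ftie <- data.frame(mz = 500 * (1 + 10e-6) + 1.007276, polarity = "positive")
  anntie <- matchFeatures(ftie, db2, prot)
  expect_identical(anntie$lipid_id, "LIPA")
  expect_equal(anntie$n_candidates, 2L)
  expect_true(grepl("LIPB", anntie$candidates))

  # near-equidistant +-10 ppm: both are candidates, smaller |ppm| reported
  db3 <- lipidDb(id = c("N1", "N2"), name = c("a", "b"),
                 category = "sterols",
                 monoisotopic_mass = c(500 * (1 - 10e-6), 500 * (1 + 11e-6)))
  fnear <- data.frame(mz = 500 + 1.007276, polarity = "positive")
  annnear <- matchFeatures(fnear, db3, prot)
  expect_equal(annnear$n_candidates, 2L)
  expect_identical(annnear$lipid_id, "N1")

  expect_error(matchFeatures(f0, db[0, ], prot), "empty database")
})

test_that("matchFeatures 'all' mode returns every candidate pair", {
  db <- lipidDb(id = c("A1", "A2"), name = c("a", "b"),
                category = "sterols",
                monoisotopic_mass = c(500, 500 * (1 + 20e-6)))
  prot <- adductSpec("protonated", 1.007276, 1L, "positive")
  f <- data.frame(mz = theoreticalMz(500.004, prot), polarity = "positive")
  allAnn <- matchFeatures(f, db, prot, mode = "all")
  expect_equal(nrow(allAnn), 2L)
  expect_setequal(allAnn$lipid_id, c("A1", "A2"))
})

test_that("RT-CV filter applies the 25% rule and min-observation contract", {
  cfg <- annotationConfig()
  # identical RTs: CV 0, kept
  annA <- data.frame(lipid_id = "L1", sample_id = paste0("s", 1:5), rt = 8.2)
  resA <- rtCvFilter(annA, cfg, nSamples = 5)
  expect_identical(resA$kept, "L1")
  expect_equal(resA$cvTable$cv, 0)

  # mean 10 min, population sd 3 min: CV 0.30 > 0.25, removed
  annB <- data.frame(lipid_id = "L2", sample_id = c("s1", "s2"), rt = c(7, 13))
  resB <- rtCvFilter(annB, cfg, nSamples = 2)
  expect_equal(resB$cvTable$cv, 0.3, tolerance = 1e-12)
  expect_length(resB$kept, 0)

  # observed in too few samples: reported separately, not imputed
  annC <- rbind(annA, data.frame(lipid_id = "L3", sample_id = "s1", rt = 5))
  resC <- rtCvFilter(annC, cfg, nSamples = 5)
  expect_identical(resC$insufficient, "L3")

  expect_error(rtCvFilter(data.frame(lipid_id = "x", sample_id = "s",
                                     rt = NA_real_), cfg), "missing")
})

test_that("RT-CV kept set is order- and scale-invariant", {
  set.seed(21)
  ann <- do.call(rbind, lapply(1:15, function(l) {
    data.frame(lipid_id = sprintf("L%02d", l),
               sample_id = paste0("s", 1:10),
               rt = 10 * exp(rnorm(10, 0, ifelse(l <= 8, 0.02, 0.4))))
  }))
  ref <- rtCvFilter(ann)$kept
  shuf <- ann[sample(nrow(ann)), ]
  expect_setequal(rtCvFilter(shuf)$kept, ref)
  scaled <- transform(ann, rt = rt * 3.7)
  expect_setequal(rtCvFilter(scaled)$kept, ref)
})
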