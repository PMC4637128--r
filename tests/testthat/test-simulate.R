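test_that("simulation is deterministic and respects trivial configurations", {
  cfg <- smallSimConfig(rngSeed = 7L)
  a <- simulateImage(cfg)
  b <- simulateImage(cfg)
  expect_identical(a$green, b$green)
  expect_identical(a$red, b$red)
  expect_identical(a$truth$cells, b$truth$cells)

  blank <- simulateImage(smallSimConfig(nCells = 0L, rngSeed = 1L))
  expect_equal(nrow(blank$truth$cells), 0L)
  expect_lt(max(blank$red), 0.1)   # background + noise only
  expect_lt(max(blank$green), 0.1)

  allPos <- simulateImage(simConfig(nCells = 30L, positiveFraction = 1,
                                    rngSeed = 7L))
  expect_equal(nrow(allPos$truth$cells), 30L)
  expect_true(all(allPos$truth$cells$is_positive))
  expect_true(all(allPos$truth$cells$kinetoplast_intensity > 0))
})

test_that("positive fraction follows the binomial sampling model", {
  nSeeds <- 40L; nCells <- 20L; p <- 0.5
  frac <- vapply(seq_len(nSeeds), function(s) {
    gt <- simulateImage(smallSimConfig(nCells = nCells, positiveFraction = p,
                                       rngSeed = s))$truth$cells
    mean(gt$is_positive)
  }, numeric(1))
  # mean over seeds within 3 binomial SDs of p
  se <- sqrt(p * (1 - p) / (nSeeds * nCells))
  expect_lt(abs(mean(frac) - p), 3 * se)
})

test_that("organelles sit in fixed order and green signal stays inside cells", {
  sim <- simulateImage(simConfig(nCells = 30L, positiveFraction = 1,
                                 nucleusFraction = 1, basalBodyFraction = 1,
                                 rngSeed = 3L))
  gt <- sim$truth$cells
  expect_true(all(gt$pos_basal_body < gt$pos_kinetoplast))
  expect_true(all(gt$pos_kinetoplast < gt$pos_nucleus))
  # bright green pixels lie within a small reach of a counterstained body
  body <- sim$red > 0.2
  grown <- EBImage::dilate(body, EBImage::makeBrush(21, "disc")) > 0
  hot <- sim$green > 0.2
  expect_gt(mean(grown[hot]), 0.995)
})

test_that("artefact injection matches its contracts", {
  img <- matrix(0.02, 256, 256)
  set.seed(5)
  blob <- simulateArtefact(img, "bright_blob", areaPx = 3000)
  expect_lt(abs(sum(blob$mask) - 3000) / 3000, 0.1)
  expect_true(all(blob$image[blob$mask] > 0.5))

  set.seed(5)
  sat <- simulateArtefact(img, "saturation_patch", areaPx = 2500)
  expect_equal(max(sat$image[sat$mask]), 1)
  expect_equal(min(sat$image[sat$mask]), 1)

  set.seed(5)
  fib <- simulateArtefact(img, "fiber")
  expect_gt(sum(fib$mask), 100)
  expect_error(simulateArtefact(img, "scratch"), "unknown artefact kind")

  clean <- simulateImage(smallSimConfig(artefactCount = 0L, rngSeed = 2L))
  expect_false(any(clean$truth$artefactMask))
  withArt <- simulateImage(smallSimConfig(artefactCount = 2L, rngSeed = 2L))
  expect_gt(sum(withArt$truth$artefactMask), 0)
})

test_that("dilution series scales intensity inversely and defines titer truth", {
  expect_error(simulateDilutionSeries(smallSimConfig(), numeric(0)),
               "non-empty")
  expect_error(simulateDilutionSeries(smallSimConfig(), c(10, 1)),
               "increasing")

  # one dilution at factor 1 reproduces simulateImage exactly
  cfg <- smallSimConfig(rngSeed = 9L)
  ser <- simulateDilutionSeries(cfg, 1)
  ref <- simulateImage(cfg)
  expect_identical(ser$images[[1]]$green, ref$green)
  expect_identical(ser$images[[1]]$red, ref$red)

  # noiseless amplitudes scale as 1/f
  cfg0 <- smallSimConfig(positiveFraction = 1, noiseSd = 0, rngSeed = 4L,
                         organelleIntensity = list(
                           kinetoplast = c(mean = 0.5, sd = 0),
                           nucleus = c(mean = 0.45, sd = 0),
                           basal_body = c(mean = 0.4, sd = 0)))
  ser <- simulateDilutionSeries(cfg0, c(1, 10, 100))
  amps <- vapply(ser$images, function(im)
    mean(im$truth$cells$kinetoplast_intensity), numeric(1))
  expect_equal(amps / amps[1], c(1, 0.1, 0.01), tolerance = 1e-12)

  # titer ground truth equals independent thresholding of the noiseless series
  for (s in 1:50) {
    kin <- runif(1, 0.05, 3)
    cfgS <- smallSimConfig(nCells = 5L, positiveFraction = 1, rngSeed = s,
                           organelleIntensity = list(
                             kinetoplast = c(mean = kin, sd = 0),
                             nucleus = c(mean = 0.45, sd = 0),
                             basal_body = c(mean = 0.4, sd = 0)))
    f <- c(1, 3.2, 10, 32, 100)
    ser <- simulateDilutionSeries(cfgS, f)
    # oracle: recount reactive dilutions from the per-image drawn amplitudes
    perImage <- vapply(ser$images, function(im)
      mean(im$truth$cells$kinetoplast_intensity), numeric(1))
    oracle <- sum(perImage >= cfgS@titerIntensityThreshold - 1e-12)
    expect_equal(ser$trueTiterLevel, oracle)
  }
})

test_that("cells that cannot be placed are reported as skipped", {
  # frame far too small for 40 px cells at this density
  cfg <- simConfig(imageWidth = 120L, imageHeight = 120L, nCells = 30L,
                   rngSeed = 1L)
  sim <- simulateImage(cfg)
  expect_equal(nrow(sim$truth$cells) + sim$truth$skipped, 30L)
  expect_gt(sim$truth$skipped, 0L)
})

test_that("simulator config invariants are enforced", {
  expect_error(simConfig(positiveFraction = 1.5), "positiveFraction")
  expect_error(simConfig(nCells = -1), "nCells")
  expect_error(simConfig(organellePositions = c(basal_body = 0.6,
                                                kinetoplast = 0.25,
                                                nucleus = 0.9)),
               "order")
})
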