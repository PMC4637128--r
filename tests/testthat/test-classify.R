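test_that("discriminant training validates input and reports accuracy", {
  tab <- testTrainingTable()
  model <- testModel()
  expect_s4_class(model, "TrainedClassifier")
  expect_gt(model@trainingAccuracy, 0.95)
  expect_length(model@weights, 2L * runConfig()@profileBins)

  onlyPos <- tab[tab$label, ]
  expect_error(trainClassifier(onlyPos, runConfig()), "both classes")
  expect_error(trainClassifier(tab[1:80, ], runConfig()), ">= 50 cells")
})

test_that("the discriminant agrees with an independent reference fit", {
  skip_if_not_installed("MASS")
  tab <- testTrainingTable()
  model <- testModel()
  X <- as.matrix(tab[, model@featureNames])
  ours <- as.numeric(X %*% model@weights) - model@bias >= 0
  ref <- MASS::lda(x = X, grouping = tab$label)
  theirs <- predict(ref, X)$class == "TRUE"
  expect_gt(mean(ours == theirs), 0.99)
})

test_that("serialization round-trips predictions bit-stably", {
  model <- testModel()
  tab <- utils::head(testTrainingTable(), 100)
  p <- withr::local_tempfile(fileext = ".json")
  saveClassifier(model, p)
  m2 <- readClassifier(p)
  X <- as.matrix(tab[, model@featureNames])
  s1 <- as.numeric(X %*% model@weights) - model@bias
  s2 <- as.numeric(X %*% m2@weights) - m2@bias
  expect_identical(s1 >= 0, s2 >= 0)
  expect_lt(max(abs(s1 - s2)), 1e-12)
})

test_that("with no class signal the classifier is at chance", {
  rc <- runConfig()
  # kinetoplast intensity zero: positives and negatives are indistinguishable
  cfg <- simConfig(organelleIntensity = list(
    kinetoplast = c(mean = 0, sd = 0), nucleus = c(mean = 0.45, sd = 0.05),
    basal_body = c(mean = 0.4, sd = 0.05)))
  tab <- suppressWarnings(
    buildTrainingTable(nPerClass = 150L, cfg, rc, seed = 31L,
                       maxImages = 40L))
  set.seed(31)
  idx <- sample(nrow(tab))
  nTrain <- floor(0.75 * nrow(tab))
  fit <- trainClassifier(tab[idx[seq_len(nTrain)], ], rc)
  test <- tab[idx[-seq_len(nTrain)], ]
  X <- as.matrix(test[, fit@featureNames])
  pred <- as.numeric(X %*% fit@weights) - fit@bias >= 0
  # held-out accuracy at chance level
  expect_lt(abs(mean(pred == test$label) - 0.5), 0.2)
})

test_that("dark cells bypass the model and excluded cells stay excluded", {
  model <- testModel()
  rc <- runConfig()
  res <- simulatedCells(simConfig(nCells = 20L, positiveFraction = 0,
                                  nucleusFraction = 0, basalBodyFraction = 0,
                                  rngSeed = 41L), rc)
  i <- which(res$cells$table$qc_pass)[1]
  rec <- res$cells$records[[i]]
  expect_true(isDark(rec))
  resetClassifierInvocations()
  call <- classifyCell(res$cells$profiles[[i]], rec, model,
                       res$cells$background[["mean"]], rc)
  expect_equal(cellLabel(call), "negative")
  expect_equal(classifierInvocations(), 0L)
  expect_true(is.na(call@posterior))

  recBad <- rec
  recBad@qcPass <- FALSE; recBad@qcReasons <- "area"; recBad@isDark <- FALSE
  expect_equal(cellLabel(classifyCell(NULL, recBad, model)), "excluded")

  # feature-dimension mismatch is an error
  recOk <- rec; recOk@isDark <- FALSE
  smallProf <- new("AxisProfile", values = rep(0, 8), spread = rep(0, 8),
                   rawValues = rep(0, 8), lengthPx = 10,
                   orientationCanonical = TRUE)
  expect_error(classifyCell(smallProf, recOk, model,
                            cfg = runConfig(profile_bins = 8)),
               "dimension mismatch")
})

test_that("positive cells and all negative archetypes are called correctly", {
  model <- testModel()
  rc <- runConfig()
  archetypes <- list(
    positive = c(pf = 1, nf = 0, bf = 0),
    nucleus_only = c(pf = 0, nf = 1, bf = 0),
    basal_only = c(pf = 0, nf = 0, bf = 1),
    nucleus_and_basal = c(pf = 0, nf = 1, bf = 1))
  for (nm in names(archetypes)) {
    a <- archetypes[[nm]]
    res <- simulatedCells(simConfig(nCells = 20L, positiveFraction = a["pf"],
                                    nucleusFraction = a["nf"],
                                    basalBodyFraction = a["bf"],
                                    rngSeed = 50L), rc)
    calls <- lapply(seq_along(res$cells$records), function(i)
      classifyCell(res$cells$profiles[[i]], res$cells$records[[i]], model,
                   res$cells$background[["mean"]], rc))
    labs <- vapply(calls, cellLabel, character(1))
    labs <- labs[labs != "excluded"]
    if (nm == "positive") expect_gt(mean(labs == "positive"), 0.9)
    else expect_true(all(labs == "negative"))
  }
})

test_that("kinetoplast brightness scales with amplitude, not with the nucleus", {
  rc <- runConfig()
  med <- function(kin, nuc) {
    cfg <- simConfig(nCells = 15L, positiveFraction = 1,
                     nucleusFraction = if (nuc > 0) 1 else 0,
                     basalBodyFraction = 0, rngSeed = 21L, noiseSd = 0.002,
                     organelleIntensity = list(
                       kinetoplast = c(mean = kin, sd = 1e-4),
                       nucleus = c(mean = max(nuc, 1e-4), sd = 1e-4),
                       basal_body = c(mean = 0.4, sd = 0.05)))
    res <- simulatedCells(cfg, rc)
    br <- vapply(seq_along(res$cells$profiles), function(i)
      if (!is.null(res$cells$profiles[[i]]))
        extractKinetoplastBrightness(res$cells$profiles[[i]],
                                     res$cells$background[["mean"]], rc)
      else NA_real_, numeric(1))
    median(br, na.rm = TRUE)
  }
  b3 <- med(0.3, 0); b6 <- med(0.6, 0)
  expect_lt(abs(b6 / b3 - 2), 0.15 * 2)
  base <- med(0.4, 0)
  for (nuc in c(0.4, 0.8))
    expect_lt(abs(med(0.4, nuc) - base) / base, 0.10)

  # negative cell: brightness within noise of zero
  resN <- simulatedCells(simConfig(nCells = 10L, positiveFraction = 0,
                                   nucleusFraction = 0, basalBodyFraction = 0,
                                   rngSeed = 9L), rc)
  i <- which(resN$cells$table$qc_pass)[1]
  bN <- extractKinetoplastBrightness(resN$cells$profiles[[i]],
                                     resN$cells$background[["mean"]], rc)
  expect_lt(bN, 3 * 0.01)
})

test_that("image aggregation follows the cutoff with the >= boundary rule", {
  rc <- runConfig()
  mk <- function(nPos, nNeg, nExc = 0) {
    c(lapply(seq_len(nPos), mkCall, label = "positive", brightness = 0.3),
      lapply(nPos + seq_len(nNeg), mkCall, label = "negative"),
      lapply(nPos + nNeg + seq_len(nExc), mkCall, label = "excluded",
             brightness = NA_real_))
  }
  expect_equal(verdict(classifyImage(mk(0, 30), rc)), "negative")
  boundary <- classifyImage(mk(15, 15), rc)
  expect_equal(verdict(boundary), "positive")   # exactly at the cutoff
  expect_equal(fractionPositive(boundary), 0.5)
  none <- classifyImage(mk(0, 0, 5), rc)
  expect_equal(verdict(none), "rejected_qc")
  expect_equal(none@rejectReason, "no_evaluable_cells")

  # permutation invariance
  calls <- mk(7, 13, 3)
  set.seed(1)
  shuffled <- calls[sample(length(calls))]
  a <- classifyImage(calls, rc); b <- classifyImage(shuffled, rc)
  expect_equal(verdict(a), verdict(b))
  expect_equal(fractionPositive(a), fractionPositive(b))
  expect_equal(titerEstimate(a), titerEstimate(b))
  expect_equal(confidence(a), confidence(b))
})

test_that("image verdicts match an exhaustive decision table at 8 bins", {
  rc <- runConfig(profile_bins = 8)
  for (nPos in 0:10) for (nNeg in 0:(10 - nPos)) {
    calls <- c(lapply(seq_len(nPos), mkCall, label = "positive"),
               lapply(nPos + seq_len(nNeg), mkCall, label = "negative"))
    if (length(calls) == 0L) next
    got <- verdict(classifyImage(calls, rc))
    # independent hand rule: count positives, compare to half the classified
    want <- if (nPos + nNeg == 0L) "rejected_qc" else
      if (nPos >= 0.5 * (nPos + nNeg)) "positive" else "negative"
    expect_identical(got, want)
  }
})

test_that("titer estimation maps brightness monotonically with >= boundaries", {
  rc <- runConfig()
  mkB <- function(b) lapply(seq_along(b), function(i)
    mkCall(i, "positive", brightness = b[i]))
  expect_equal(estimateTiter(mkB(c(0.3, 0.4)), rc, verdict = "negative"),
               "negative")
  bp <- rc@brightnessToTiterBreakpoints
  # exactly at a breakpoint: the higher step
  expect_equal(estimateTiter(mkB(rep(bp[1], 3)), rc), rc@titerSteps[2])
  expect_equal(estimateTiter(mkB(rep(bp[1] - 1e-6, 3)), rc), rc@titerSteps[1])
  # raising every brightness never lowers the estimate
  steps <- rc@titerSteps
  for (s in 1:20) {
    set.seed(s)
    b <- runif(8, 0, 1.1)
    l1 <- match(estimateTiter(mkB(b), rc), steps)
    l2 <- match(estimateTiter(mkB(b * 1.5), rc), steps)
    expect_gte(l2, l1)
  }
  bad <- runConfig()
  expect_error(runConfig(brightness_to_titer_breakpoints = c(0.1, 0.2)),
               "one entry fewer")
})

test_that("dilution merging takes any-positive verdicts and the highest titer", {
  rc <- runConfig()
  ic <- function(verdict, dil, titer = "negative", conf = 0.9,
                 sample = "S1") {
    new("ImageCall", biochipId = "B", sampleId = sample,
        dilutionFactor = dil, verdict = verdict,
        rejectReason = character(0), nCellsTotal = 30L,
        nCellsClassified = 30L,
        fractionPositive = if (verdict == "positive") 0.9 else 0.05,
        titerEstimate = titer, confidence = conf, classifierEvals = 30L)
  }
  single <- mergeDilutions(list(ic("negative", 10)), rc)
  expect_equal(verdict(single), "negative")
  expect_equal(finalTiter(single), "negative")

  mixed <- mergeDilutions(list(ic("positive", 10, "1:10", conf = 0.8),
                               ic("negative", 100)), rc)
  expect_equal(verdict(mixed), "positive")
  expect_gte(match(finalTiter(mixed), rc@titerSteps), 1L)

  # positivity at 1:100 implies a titer of at least 1:100
  deep <- mergeDilutions(list(ic("positive", 10, "1:10"),
                              ic("positive", 100, "1:10")), rc)
  expect_gte(match(finalTiter(deep), rc@titerSteps),
             match("1:100", rc@titerSteps))
  # confidence is the minimum over contributing images
  expect_equal(confidence(mixed), 0.8)

  expect_error(mergeDilutions(list(ic("positive", 10),
                                   ic("negative", 100, sample = "S2")), rc),
               "conflicting sample ids")
})

test_that("end-to-end verdicts recover the ground truth in separable regimes", {
  model <- testModel()
  rc <- runConfig()
  for (pf in c(0, 1)) for (s in 1:6) {
    cfg <- smallSimConfig(positiveFraction = pf, rngSeed = 100L + s)
    sim <- simulateImage(cfg)
    pair <- channelPair(sim$green, sim$red, dilutionFactor = 10)
    out <- processPair(pair, model, rc)
    expect_equal(verdict(out$call), if (pf == 1) "positive" else "negative")
  }
})
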