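test_that("moment-based shape features match analytic ellipse properties", {
  g <- matrix(0.1, 141, 141); r <- matrix(0.5, 141, 141)
  rec <- measureCell(ellipseLabel(60, 15), 1L, g, r)
  expect_lt(abs(rec@aspectRatio - 4) / 4, 0.05)
  expect_lt(abs(rec@ellipseAxes[1] - 60) / 60, 0.05)
  expect_gt(rec@solidity, 0.95)

  circ <- measureCell(ellipseLabel(30, 30), 1L, g, r)
  expect_lt(abs(circ@aspectRatio - 1), 0.05)
  qc <- applyCellQC(circ)
  expect_false(qcPass(qc))
  expect_true("ellipse_form" %in% qcReasons(qc))
})

test_that("fused cells fail solidity QC and tiny masks fail immediately", {
  H <- 141L; W <- 141L
  dr <- matrix(seq_len(H) - 71, H, W); dc <- matrix(seq_len(W) - 71, H, W,
                                                    byrow = TRUE)
  u <- dc * cos(pi / 4) + dr * sin(pi / 4)
  v <- -dc * sin(pi / 4) + dr * cos(pi / 4)
  lab <- matrix(0L, H, W)
  lab[((dc / 20)^2 + (dr / 5)^2 <= 1) | ((u / 20)^2 + (v / 5)^2 <= 1)] <- 1L
  g <- matrix(0.1, H, W); r <- matrix(0.5, H, W)
  rec <- applyCellQC(measureCell(lab, 1L, g, r))
  expect_lt(rec@solidity, 0.85)
  expect_true("convex_defect" %in% qcReasons(rec))

  tiny <- matrix(0L, 20, 20); tiny[10, 10:12] <- 1L
  recT <- measureCell(tiny, 1L, matrix(0, 20, 20), matrix(0, 20, 20))
  expect_false(qcPass(applyCellQC(recT)))
  expect_equal(qcReasons(recT), "too_small")
})

test_that("QC names every violated feature and passes clean cells", {
  g <- matrix(0.1, 141, 141); r <- matrix(0.5, 141, 141)
  rec <- measureCell(ellipseLabel(60, 15), 1L, g, r)
  ok <- applyCellQC(rec, list(area = c(70, 1200), aspect_ratio = c(2, 12),
                              solidity = c(0.85, 1)))
  expect_true(qcPass(ok))
  expect_length(qcReasons(ok), 0L)
  bad <- applyCellQC(rec, list(area = c(1, 10), aspect_ratio = c(2, 12),
                               solidity = c(0.85, 1)))
  expect_false(qcPass(bad))
  expect_equal(qcReasons(bad), "area")
})

test_that("simulated clean cells overwhelmingly pass default QC limits", {
  passed <- 0L; total <- 0L
  for (s in 1:4) {
    res <- simulatedCells(simConfig(nCells = 30L, rngSeed = s))
    passed <- passed + sum(res$cells$table$qc_pass)
    total <- total + nrow(res$cells$table)
  }
  expect_gte(total, 100L)
  expect_gte(passed / total, 0.95)
})

test_that("the dark-cell rule matches its formula exactly and sorts archetypes", {
  rc <- runConfig()
  res <- simulatedCells(simConfig(nCells = 30L, rngSeed = 5L), rc)
  bg <- res$cells$background
  for (i in seq_along(res$cells$records)) {
    recI <- res$cells$records[[i]]
    expect_identical(isDark(recI),
                     recI@meanGreen < bg[["mean"]] + rc@darkCellK * bg[["sd"]])
  }
  # fully negative cells are dark; kinetoplast-positive cells are not
  gt <- res$gt[res$match, ]
  fullNeg <- !gt$is_positive & !gt$nucleus_fluorescent &
    !gt$basal_body_fluorescent
  dark <- res$cells$table$is_dark
  expect_true(all(dark[fullNeg]))
  expect_false(any(dark[gt$is_positive]))
})

test_that("orientation is recovered to within 2 degrees including direction", {
  res <- simulatedCells(simConfig(nCells = 30L, rngSeed = 5L))
  tab <- res$cells$table
  gt <- res$gt[res$match, ]
  ok <- tab$qc_pass & tab$orientation_reliable
  d <- (tab$orientation_deg[ok] - gt$orientation_deg[ok]) %% 360
  d <- pmin(d, 360 - d)
  # canonicalization resolves the 180-degree ambiguity, so the error is
  # small in absolute direction, not just modulo 180
  expect_lt(max(d), 2)
})

test_that("circles have no reliable orientation", {
  g <- matrix(0.1, 141, 141); r <- matrix(0.5, 141, 141)
  rec <- measureCell(ellipseLabel(30, 30), 1L, g, r)
  rec@qcPass <- TRUE
  rec <- estimateOrientation(rec, r, g)
  expect_false(rec@orientationReliable)
})

test_that("a cell and its 180-degree flip give identical canonical profiles", {
  rc <- runConfig()
  sim <- simulateImage(simConfig(nCells = 12L, positiveFraction = 1,
                                 rngSeed = 13L))
  rot <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  segA <- segmentCells(sim$red, NULL, rc)
  cellsA <- measureCells(segA, sim$green, sim$red, rc)
  segB <- segmentCells(rot(sim$red), NULL, rc)
  cellsB <- measureCells(segB, rot(sim$green), rot(sim$red), rc)
  tA <- cellsA$table; tB <- cellsB$table
  H <- nrow(sim$red); W <- ncol(sim$red)
  d2 <- outer(tA$centroid_row, (H - 1) - tB$centroid_row, "-")^2 +
    outer(tA$centroid_col, (W - 1) - tB$centroid_col, "-")^2
  match <- apply(d2, 1, which.min)
  mcols <- paste0("m", seq_len(rc@profileBins))
  ok <- tA$qc_pass & tB$qc_pass[match]
  dif <- abs(as.matrix(tA[ok, mcols]) - as.matrix(tB[match[ok], mcols]))
  expect_lt(mean(dif), 0.02)
})

test_that("profiles are rotation-equivariant under 90-degree image rotation", {
  rc <- runConfig()
  sim <- simulateImage(simConfig(nCells = 12L, positiveFraction = 1,
                                 rngSeed = 14L))
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m)))]  # counter-clockwise
  segA <- segmentCells(sim$red, NULL, rc)
  cellsA <- measureCells(segA, sim$green, sim$red, rc)
  segB <- segmentCells(rot90(sim$red), NULL, rc)
  cellsB <- measureCells(segB, rot90(sim$green), rot90(sim$red), rc)
  tA <- cellsA$table; tB <- cellsB$table
  H <- nrow(sim$red)
  # (r, c) maps to (H-1-c', ...) under rot90: match centroids through the map
  d2 <- outer(tA$centroid_col, tB$centroid_row, "-")^2 +
    outer(tA$centroid_row, (ncol(rot90(sim$red)) - 1) - tB$centroid_col,
          "-")^2
  match <- apply(d2, 1, which.min)
  mcols <- paste0("m", seq_len(rc@profileBins))
  ok <- tA$qc_pass & tB$qc_pass[match]
  dif <- abs(as.matrix(tA[ok, mcols]) - as.matrix(tB[match[ok], mcols]))
  expect_lt(mean(dif), 0.05)
})

test_that("profile peaks localize organelles and flag uniform cells", {
  rc <- runConfig()
  # uniform green cell: flat, all-zero normalized profile
  lab <- ellipseLabel(60, 15)
  g <- matrix(0.4, 141, 141); r <- matrix(0.5, 141, 141)
  rec <- measureCell(lab, 1L, g, r)
  rec@qcPass <- TRUE
  rec <- estimateOrientation(rec, r, g)
  prof <- extractProfile(rec, g, rc)
  expect_equal(profileValues(prof), rep(0, rc@profileBins))

  # kinetoplast-only positives peak in the kinetoplast band
  res <- simulatedCells(simConfig(nCells = 20L, positiveFraction = 1,
                                  nucleusFraction = 0, basalBodyFraction = 0,
                                  rngSeed = 21L), rc)
  tab <- res$cells$table
  mcols <- paste0("m", seq_len(rc@profileBins))
  ok <- tab$qc_pass & tab$orientation_reliable
  peaks <- apply(as.matrix(tab[ok, mcols]), 1, which.max) / rc@profileBins
  expect_true(all(peaks >= 0.15 & peaks <= 0.35))

  # nucleus-only negatives: peak in the nucleus band, kinetoplast band dark
  resN <- simulatedCells(simConfig(nCells = 20L, positiveFraction = 0,
                                   nucleusFraction = 1, basalBodyFraction = 0,
                                   rngSeed = 22L), rc)
  tabN <- resN$cells$table
  okN <- tabN$qc_pass & tabN$orientation_reliable
  peaksN <- apply(as.matrix(tabN[okN, mcols]), 1, which.max) / rc@profileBins
  expect_true(all(peaksN >= 0.45 & peaksN <= 0.8))
  kinBand <- as.matrix(tabN[okN, mcols[ceiling(0.18 * 32):floor(0.32 * 32)]])
  expect_lt(mean(kinBand), 0.25)
})
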