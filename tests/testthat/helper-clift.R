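# shared fixtures, built in code and cached for the session

.testCache <- new.env(parent = emptyenv())

# small frames keep unit tests fast; geometry matches the full-scale defaults
smallSimConfig <- function(nCells = 10L, ...) {
  simConfig(imageWidth = 306L, imageHeight = 256L, nCells = nCells, ...)
}

# a classifier trained once per session on 300 cells per class
testModel <- function() {
  if (is.null(.testCache$model)) {
    rc <- runConfig()
    tab <- buildTrainingTable(nPerClass = 300L, simConfig(), rc, seed = 11L)
    .testCache$model <- trainClassifier(tab, rc)
    .testCache$trainingTable <- tab
  }
  .testCache$model
}

testTrainingTable <- function() {
  testModel()
  .testCache$trainingTable
}

# filled ellipse mask as an integer label image (axes = full lengths, px)
ellipseLabel <- function(majorAxis, minorAxis, H = 141L, W = 141L,
                         thetaDeg = 0) {
  dr <- matrix(seq_len(H) - (H + 1) / 2, H, W)
  dc <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
  th <- thetaDeg * pi / 180
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  mask <- (u / (majorAxis / 2))^2 + (v / (minorAxis / 2))^2 <= 1
  lab <- matrix(0L, H, W)
  lab[mask] <- 1L
  lab
}

# run the chain on one simulated frame and return matched cells + ground truth
simulatedCells <- function(cfg, rc = runConfig()) {
  sim <- simulateImage(cfg)
  seg <- segmentCells(sim$red, NULL, rc)
  cells <- measureCells(seg, sim$green, sim$red, rc)
  gt <- sim$truth$cells
  near <- rep(NA_integer_, nrow(cells$table %||% data.frame()))
  if (!is.null(cells$table) && nrow(gt) > 0) {
    d2 <- outer(cells$table$centroid_row, gt$row, "-")^2 +
      outer(cells$table$centroid_col, gt$col, "-")^2
    near <- apply(d2, 1, which.min)
  }
  list(sim = sim, seg = seg, cells = cells, gt = gt, match = near)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick constructor for synthetic cell calls
mkCall <- function(id, label, brightness = 0.2, posterior = NA_real_) {
  new("CellCall", cellId = as.integer(id), label = label,
      kinetoplastBrightness = brightness, posterior = posterior)
}
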