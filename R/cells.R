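#' Measure shape and brightness features of one segmented cell
#'
#' Computes area, the moment-equivalent ellipse (axes from the eigenvalues
#' of the second central moments), aspect ratio, convex-hull solidity,
#' orientation, centroid, and mean channel intensities. Masks of fewer than
#' 5 px fail QC immediately with reason `"too_small"`.
#'
#' @param seg a [SegmentationResult-class] (or a raw integer label matrix).
#' @param cellId component label to measure.
#' @param green,red registered channel matrices.
#' @return A [CellRecord-class] (QC and dark flags not yet set; see
#'   [applyCellQC()] and [flagDarkCell()]).
#' @export
measureCell <- function(seg, cellId, green, red) {
  lab <- if (is(seg, "SegmentationResult")) seg@labelImage else seg
  idx <- which(lab == cellId)
  if (length(idx) == 0L) stop("cell ", cellId, " not present in label image")
  H <- nrow(lab)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  area <- length(idx)
  if (area < 5L)
    return(new("CellRecord", cellId = as.integer(cellId),
               pixelIdx = as.integer(idx), areaPx = area,
               ellipseAxes = c(NA_real_, NA_real_), aspectRatio = NA_real_,
               solidity = NA_real_, orientationDeg = NA_real_,
               orientationReliable = FALSE,
               centroid = c(mean(rr) - 1, mean(cc) - 1),
               meanGreen = mean(green[idx]), meanRed = mean(red[idx]),
               qcPass = FALSE, qcReasons = "too_small", isDark = NA))
  # second central moments in (x = col, y = row) coordinates
  x <- cc - mean(cc); y <- rr - mean(rr)
  mu20 <- mean(x * x) + 1 / 12      # pixel-footprint correction
  mu02 <- mean(y * y) + 1 / 12
  mu11 <- mean(x * y)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 1e-9))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  hullArea <- convexHullArea(rr, cc)
  new("CellRecord", cellId = as.integer(cellId), pixelIdx = as.integer(idx),
      areaPx = area, ellipseAxes = c(major, minor),
      aspectRatio = major / minor, solidity = min(1, area / hullArea),
      orientationDeg = theta %% 360, orientationReliable = TRUE,
      centroid = c(mean(rr) - 1, mean(cc) - 1),
      meanGreen = mean(green[idx]), meanRed = mean(red[idx]),
      qcPass = NA, qcReasons = character(0), isDark = NA)
}

#' Apply shape quality-control limits to a cell
#'
#' A cell passes iff every configured feature lies inside its `(min, max)`
#' interval; each violated feature is named in `qcReasons` (`"area"`,
#' `"aspect_ratio"` reported as `"ellipse_form"` for near-circular masks,
#' `"solidity"` as `"convex_defect"`). Defective cells are excluded from all
#' subsequent evaluation.
#'
#' @param record a [CellRecord-class].
#' @param limits named list of `c(min, max)`; default from [runConfig()].
#' @return The record with `qcPass` and `qcReasons` set.
#' @export
applyCellQC <- function(record, limits = runConfig()@cellQcLimits) {
  if (identical(record@qcReasons, "too_small")) return(record)
  feats <- c(area = record@areaPx, aspect_ratio = record@aspectRatio,
             solidity = record@solidity)
  reasons <- character(0)
  for (nm in names(limits)) {
    v <- feats[[nm]]
    if (is.null(v) || is.na(v)) next
    lim <- limits[[nm]]
    if (v < lim[1] || v > lim[2]) {
      tag <- switch(nm,
                    solidity = "convex_defect",
                    aspect_ratio = if (v < lim[1]) "ellipse_form" else
                      "aspect_ratio",
                    nm)
      reasons <- c(reasons, tag)
    }
  }
  record@qcPass <- length(reasons) == 0L
  record@qcReasons <- reasons
  record
}

#' Background statistics of the green channel
#'
#' Mean and standard deviation of green pixels outside every segmented cell
#' and outside the artefact mask; the reference for the dark-cell rule and
#' for kinetoplast brightness subtraction.
#'
#' @param green green-channel matrix.
#' @param labelImage integer label matrix (0 = background).
#' @param artefactMask optional logical matrix to exclude.
#' @return `c(mean, sd)`.
#' @export
backgroundStats <- function(green, labelImage, artefactMask = NULL) {
  bg <- labelImage == 0L
  if (!is.null(artefactMask)) bg <- bg & !artefactMask
  px <- green[bg]
  if (length(px) < 2L) return(c(mean = 0, sd = 0))
  c(mean = mean(px), sd = stats::sd(px))
}

#' Flag a dark (whole-cell negative) cell
#'
#' A cell is dark iff its mean green brightness over the complete mask stays
#' below `background mean + k * background sd`. Dark cells are negative by
#' construction and bypass the discriminant classifier; when every cell of
#' an image is dark the whole image short-circuits to negative.
#'
#' @param record a [CellRecord-class].
#' @param backgroundStats `c(mean, sd)` from [backgroundStats()].
#' @param k sigma multiplier (default 3, the run-config default).
#' @return The record with `isDark` set.
#' @export
flagDarkCell <- function(record, backgroundStats, k = 3) {
  record@isDark <- record@meanGreen <
    backgroundStats[["mean"]] + k * backgroundStats[["sd"]]
  record
}

#' Canonicalize the orientation of a cell
#'
#' The mask moments define the main axis only up to 180 degrees. The
#' ambiguity is resolved with the red-channel intensity centroid: the
#' counterstained cell body is widest at the nucleus-bearing posterior, so
#' the red-weighted centroid lies towards that end, which is mapped to the
#' upper half of the axis profile (the basal-body end becomes position 0).
#' Near-circular cells (`aspect < minAspect`) have no defined axis; they are
#' flagged unreliable and excluded from classification.
#'
#' @param record a [CellRecord-class] with `qcPass = TRUE`.
#' @param red,green registered channel matrices.
#' @param minAspect below this aspect ratio the orientation is unreliable.
#' @return The record with `orientationDeg` canonical (pointing basal body
#'   to nucleus) and `orientationReliable` set.
#' @export
estimateOrientation <- function(record, red, green, minAspect = 1.3) {
  if (is.na(record@aspectRatio) || record@aspectRatio < minAspect) {
    record@orientationReliable <- FALSE
    return(record)
  }
  H <- nrow(red)
  idx <- record@pixelIdx
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  th <- record@orientationDeg * pi / 180
  dirR <- sin(th); dirC <- cos(th)
  t <- (cc - mean(cc)) * dirC + (rr - mean(rr)) * dirR
  w <- red[idx]
  tMid <- (min(t) + max(t)) / 2
  tBar <- sum(w * t) / sum(w)
  if (tBar < tMid) record@orientationDeg <- (record@orientationDeg + 180) %% 360
  record@orientationReliable <- TRUE
  record
}

#' Extract the discrete normalized axis profile of a cell
#'
#' Projects the cell pixels onto the canonical main axis, partitions the
#' projection range into `profileBins` equal-length segments and computes
#' the per-bin mean and standard deviation of the green intensity. Bin means
#' are min-max normalized per cell (an absent organelle stays near 0; a
#' constant cell yields the all-zero profile by convention) and the spread
#' vector is scaled by the same factor. The un-normalized bin means are kept
#' for brightness extraction.
#'
#' @param record a [CellRecord-class] with canonical orientation.
#' @param green green-channel matrix.
#' @param cfg a [RunConfig-class] (`profile_bins`).
#' @return An [AxisProfile-class].
#' @export
extractProfile <- function(record, green, cfg = runConfig()) {
  nb <- cfg@profileBins
  H <- nrow(green)
  idx <- record@pixelIdx
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  th <- record@orientationDeg * pi / 180
  t <- (cc - mean(cc)) * cos(th) + (rr - mean(rr)) * sin(th)
  rng <- range(t)
  span <- diff(rng)
  if (span < 1e-9) {
    z <- rep(0, nb)
    return(new("AxisProfile", values = z, spread = z, rawValues = z,
               lengthPx = 0, orientationCanonical = record@orientationReliable))
  }
  bin <- pmin(pmax(ceiling((t - rng[1]) / span * nb), 1L), nb)
  g <- green[idx]
  m <- vapply(seq_len(nb), function(b) {
    v <- g[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  s <- vapply(seq_len(nb), function(b) {
    v <- g[bin == b]
    if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1))
  # empty bins (possible for very thin diagonal masks) take neighbours
  if (anyNA(m)) {
    filled <- which(!is.na(m))
    m[is.na(m)] <- m[filled[vapply(which(is.na(m)), function(i)
      which.min(abs(filled - i)), integer(1))]]
  }
  lo <- min(m); hi <- max(m)
  scale <- hi - lo
  if (scale < 1e-9) {
    vals <- rep(0, nb); spr <- rep(0, nb)
  } else {
    vals <- (m - lo) / scale
    spr <- s / scale
  }
  new("AxisProfile", values = vals, spread = spr, rawValues = m,
      lengthPx = span, orientationCanonical = record@orientationReliable)
}

#' Measure, QC and profile every cell of a segmented image
#'
#' Runs [measureCell()], [applyCellQC()], [flagDarkCell()],
#' [estimateOrientation()] and [extractProfile()] over all components and
#' assembles the per-cell feature table used both for classification and as
#' the classifier training format.
#'
#' @param seg a [SegmentationResult-class].
#' @param green,red registered channel matrices.
#' @param cfg a [RunConfig-class].
#' @param artefactMask optional logical matrix for background statistics.
#' @return list with `records` (list of [CellRecord-class]), `profiles`
#'   (list of [AxisProfile-class] or NULL for excluded cells), `background`
#'   (`c(mean, sd)`) and `table` (data.frame: one row per cell with scalar
#'   features and the flattened profile: columns `m1..mB`, `s1..sB`).
#' @export
measureCells <- function(seg, green, red, cfg = runConfig(),
                         artefactMask = NULL) {
  bg <- backgroundStats(green, seg@labelImage, artefactMask)
  nb <- cfg@profileBins
  records <- vector("list", seg@nComponents)
  profiles <- vector("list", seg@nComponents)
  rows <- vector("list", seg@nComponents)
  for (i in seq_len(seg@nComponents)) {
    rec <- measureCell(seg, i, green, red)
    rec <- applyCellQC(rec, cfg@cellQcLimits)
    rec <- flagDarkCell(rec, bg, cfg@darkCellK)
    prof <- NULL
    if (isTRUE(rec@qcPass)) {
      rec <- estimateOrientation(rec, red, green, cfg@minOrientationAspect)
      if (rec@orientationReliable)
        prof <- extractProfile(rec, green, cfg)
    }
    records[[i]] <- rec
    profiles[[i]] <- prof
    pm <- if (is.null(prof)) rep(NA_real_, nb) else prof@values
    ps <- if (is.null(prof)) rep(NA_real_, nb) else prof@spread
    rows[[i]] <- data.frame(
      cell_id = rec@cellId, area_px = rec@areaPx,
      aspect_ratio = rec@aspectRatio, solidity = rec@solidity,
      orientation_deg = rec@orientationDeg,
      orientation_reliable = rec@orientationReliable,
      centroid_row = rec@centroid[1], centroid_col = rec@centroid[2],
      mean_green = rec@meanGreen, mean_red = rec@meanRed,
      qc_pass = isTRUE(rec@qcPass),
      qc_reasons = paste(rec@qcReasons, collapse = ";"),
      is_dark = rec@isDark,
      as.data.frame(c(setNames(as.list(pm), paste0("m", seq_len(nb))),
                      setNames(as.list(ps), paste0("s", seq_len(nb))))))
  }
  tab <- if (seg@nComponents > 0L) do.call(rbind, rows) else NULL
  list(records = records, profiles = profiles, background = bg, table = tab)
}
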