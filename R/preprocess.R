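#' Register the green channel onto the red channel
#'
#' The two cameras are rigidly co-mounted, so the overlay is a pure
#' integer-pixel translation. The shift maximizing the FFT cross-correlation
#' between the channels (searched within `maxShiftFrac` of the image width)
#' is applied to the green channel; vacated pixels take the green median.
#' When the green channel carries structure but the best normalized
#' correlation is too low, or the required shift sits at the search
#' boundary, the pair is flagged as a registration failure (the images are
#' likely unpaired). A structureless green channel -- the normal appearance
#' of an anti-dsDNA negative biochip -- registers trivially with zero shift
#' and is never flagged: all segmentation happens on the red channel and a
#' dark green channel simply contributes no brightness.
#'
#' @param pair a [ChannelPair-class].
#' @param maxShiftFrac maximum credible shift as a fraction of image width.
#' @param minCorrelation normalized cross-correlation below which
#'   registration is declared failed.
#' @param minGreenStructure green-channel standard deviation below which the
#'   channel is treated as structureless (zero shift, no failure).
#' @return list with `pair` (green shifted), `shift` (integer
#'   `c(d_row, d_col)`) and `failed` (logical).
#' @export
registerPair <- function(pair, maxShiftFrac = 0.05, minCorrelation = 0.1,
                         minGreenStructure = 0.03) {
  g <- pair@green; r <- pair@red
  stopifnot(identical(dim(g), dim(r)))
  H <- nrow(g); W <- ncol(g)
  maxShift <- max(1L, floor(W * maxShiftFrac))
  if (stats::sd(as.numeric(g)) < minGreenStructure)
    return(list(pair = pair, shift = c(0L, 0L), failed = FALSE))
  g0 <- g - mean(g); r0 <- r - mean(r)
  cc <- Re(stats::fft(stats::fft(r0) * Conj(stats::fft(g0)), inverse = TRUE)) / (H * W)
  # admissible circular shifts: |d| <= maxShift in both axes
  dRows <- c(0:maxShift, (H - maxShift):(H - 1)) %% H
  dCols <- c(0:maxShift, (W - maxShift):(W - 1)) %% W
  sub <- cc[dRows + 1L, dCols + 1L, drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  toSigned <- function(d, n) if (d > n / 2) d - n else d
  dr <- toSigned(dRows[best[1L]], H)
  dc <- toSigned(dCols[best[2L]], W)
  ncc <- max(sub) /
    (H * W * stats::sd(as.numeric(g0)) * stats::sd(as.numeric(r0)) + 1e-12)
  failed <- !is.finite(ncc) || ncc < minCorrelation ||
    abs(dr) >= maxShift || abs(dc) >= maxShift
  gShift <- shiftMatrix(g, dr, dc, fill = stats::median(g))
  out <- pair
  out@green <- gShift
  list(pair = out, shift = c(as.integer(dr), as.integer(dc)), failed = failed)
}

#' Score image sharpness on the red channel
#'
#' Sharpness is the variance of a 3x3 Laplacian response, normalized by the
#' squared mean intensity so that the score is invariant to illumination
#' scale. It is computed on the counterstain channel, in which every cell is
#' visible regardless of antibody status -- an anti-dsDNA negative (green
#' dark) image therefore never resembles a defocused one. The score is
#' strictly decreasing in applied Gaussian blur; a constant image scores 0.
#'
#' @param red red-channel intensity matrix.
#' @return Non-negative focus score.
#' @export
scoreFocus <- function(red) {
  stopifnot(length(red) > 0L)
  mu <- mean(red)
  if (stats::var(as.numeric(red)) < .Machine$double.eps) return(0)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  # light pre-smoothing suppresses single-pixel read noise, whose Laplacian
  # response would otherwise put a blur-independent floor under the score
  resp <- EBImage::filter2(EBImage::gblur(red, sigma = 1), lap)
  stats::var(as.numeric(resp)) / (mu^2 + 1e-12)
}

#' Detect incubation artefacts
#'
#' Flags (i) saturated patches: connected components of near-maximum pixels
#' in either channel whose area exceeds `satMinArea` (small saturated spots
#' are genuine organelle signal and are left alone), and (ii) red-channel
#' components whose area exceeds the plausible cell range
#' (`artefactMinArea`). The returned mask feeds segmentation, which never
#' lets a cell component intersect it.
#'
#' @param red,green registered channel matrices.
#' @param cfg a [RunConfig-class].
#' @param artefactMinArea red components larger than this are artefacts
#'   (default 4x the QC area maximum).
#' @param satMinArea minimum area of a saturated patch to be flagged.
#' @return list with `mask` (logical matrix) and `areaFraction`.
#' @export
detectArtefacts <- function(red, green, cfg = runConfig(),
                            artefactMinArea = NULL, satMinArea = 400L) {
  if (is.null(artefactMinArea))
    artefactMinArea <- 4 * cfg@cellQcLimits$area[2]
  sat <- red >= 0.995 | green >= 0.995
  mask <- matrix(FALSE, nrow(red), ncol(red))
  if (any(sat)) {
    lab <- EBImage::bwlabel(sat)
    areas <- tabulate(lab[lab > 0L])
    big <- which(areas >= satMinArea)
    if (length(big)) mask <- mask | matrix(lab %in% big, nrow(red))
  }
  bw <- .adaptiveThreshold(red)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0L])
  big <- which(areas >= artefactMinArea)
  if (length(big)) mask <- mask | matrix(lab %in% big, nrow(red))
  if (any(mask))
    mask <- EBImage::dilate(mask, EBImage::makeBrush(5, "disc")) > 0
  list(mask = mask, areaFraction = mean(mask))
}

# adaptive foreground mask: local mean over a window about twice the
# expected cell length, plus k local standard deviations and an absolute
# floor (Evans blue background varies across biochips, so a global
# threshold is not reliable)
.adaptiveThreshold <- function(img, window = 81L, k = 0.5, floorOffset = 0.04) {
  box <- matrix(1 / (window * window), window, window)
  mu <- EBImage::filter2(img, box)
  mu2 <- EBImage::filter2(img * img, box)
  sdl <- sqrt(pmax(mu2 - mu * mu, 0))
  img > (mu + pmax(k * sdl, floorOffset))
}

#' Segment candidate cells in the red channel
#'
#' Adaptive local-mean thresholding followed by a morphological opening
#' (disk, radius 1) to break thin bridges, connected-component labelling, an
#' area floor, and removal of any component touching the artefact mask.
#' Touching-cell clumps are deliberately not split: a clump fails downstream
#' shape QC and is excluded, mirroring the strategy of discarding defective
#' masks rather than repairing them. Labels are contiguous `1..n`.
#'
#' @param red red-channel matrix (in-focus image).
#' @param artefactMask logical matrix from [detectArtefacts()]; `NULL` for
#'   none.
#' @param cfg a [RunConfig-class] (`min_cell_area` is applied here).
#' @return A [SegmentationResult-class].
#' @export
segmentCells <- function(red, artefactMask = NULL, cfg = runConfig()) {
  bw <- .adaptiveThreshold(red)
  if (!is.null(artefactMask)) bw[artefactMask] <- FALSE
  bw <- EBImage::opening(bw, EBImage::makeBrush(3, "disc")) > 0
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n == 0L)
    return(new("SegmentationResult",
               labelImage = matrix(0L, nrow(red), ncol(red)),
               nComponents = 0L,
               components = data.frame(label = integer(), area_px = integer(),
                                       rmin = integer(), rmax = integer(),
                                       cmin = integer(), cmax = integer(),
                                       crow = numeric(), ccol = numeric())))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- areas >= cfg@minCellArea
  if (!is.null(artefactMask) && any(artefactMask)) {
    grown <- EBImage::dilate(artefactMask, EBImage::makeBrush(3, "disc")) > 0
    touching <- unique(lab[grown & lab > 0L])
    keep[touching] <- FALSE
  }
  # relabel contiguously
  remap <- integer(n)
  remap[keep] <- seq_len(sum(keep))
  labNew <- matrix(0L, nrow(red), ncol(red))
  pos <- lab > 0L
  labNew[pos] <- remap[lab[pos]]
  nNew <- sum(keep)
  comps <- if (nNew > 0L) {
    idx <- which(labNew > 0L)
    lv <- labNew[idx]
    rr <- ((idx - 1L) %% nrow(red)) + 1L
    cc <- ((idx - 1L) %/% nrow(red)) + 1L
    data.frame(label = seq_len(nNew),
               area_px = as.integer(tabulate(lv, nbins = nNew)),
               rmin = as.integer(tapply(rr, lv, min)),
               rmax = as.integer(tapply(rr, lv, max)),
               cmin = as.integer(tapply(cc, lv, min)),
               cmax = as.integer(tapply(cc, lv, max)),
               crow = as.numeric(tapply(rr, lv, mean)) - 1,
               ccol = as.numeric(tapply(cc, lv, mean)) - 1)
  } else data.frame(label = integer(), area_px = integer(), rmin = integer(),
                    rmax = integer(), cmin = integer(), cmax = integer(),
                    crow = numeric(), ccol = numeric())
  rownames(comps) <- NULL
  new("SegmentationResult", labelImage = labNew, nComponents = as.integer(nNew),
      components = comps)
}

#' Full image-level quality control
#'
#' Convenience wrapper running registration, focus scoring and artefact
#' detection, returning an [ImageQC-class].
#'
#' @param pair a [ChannelPair-class].
#' @param cfg a [RunConfig-class].
#' @return list with `qc` ([ImageQC-class]) and `pair` (registered pair).
#' @export
imageQC <- function(pair, cfg = runConfig()) {
  reg <- registerPair(pair)
  fs <- scoreFocus(reg$pair@red)
  art <- detectArtefacts(reg$pair@red, reg$pair@green, cfg)
  qc <- new("ImageQC", focusScore = fs, inFocus = fs >= cfg@focusThreshold,
            artefactMask = art$mask, artefactAreaFraction = art$areaFraction,
            registrationShift = reg$shift, registrationFailed = reg$failed)
  list(qc = qc, pair = reg$pair)
}
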