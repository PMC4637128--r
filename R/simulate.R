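#' Construct a simulator configuration
#'
#' Builds a validated [SimConfig-class]. The defaults emulate one quarter of
#' a full 2448 x 2048 field of view (612 x 512 px) holding on average 30
#' elongated \emph{Crithidia luciliae} cells, the density seen at 400-fold
#' magnification. Each cell carries its basal body, kinetoplast and nucleus
#' in that fixed order along the main axis (default fractional positions
#' 0.10, 0.25, 0.60 from the tapered anterior end); the whole cell body is
#' drawn in the red counterstain channel while only fluorescent organelles
#' appear in the green channel. Gaussian read noise is added after the
#' optional defocus blur; shot noise is deliberately omitted so that a fixed
#' seed yields bit-identical frames.
#'
#' @param imageWidth,imageHeight frame size in pixels (full scale: 2448 x 2048).
#' @param nCells number of cells to place (default 30).
#' @param positiveFraction probability that a cell's kinetoplast fluoresces.
#' @param nucleusFraction,basalBodyFraction independent probabilities of
#'   nucleus / basal-body fluorescence (both occur in positive and negative
#'   samples and are diagnostic noise).
#' @param organelleIntensity named list of `c(mean, sd)` green amplitudes.
#' @param organellePositions fractional axis positions, strictly increasing
#'   in the order basal_body < kinetoplast < nucleus.
#' @param organelleSigmaPx Gaussian spot radii in pixels.
#' @param cellLengthPx,cellAspect `c(mean, sd)` of cell length (px) and
#'   aspect ratio.
#' @param cellRedIntensity counterstain level of the cell body.
#' @param backgroundLevel,noiseSd background offset and read-noise sd on the
#'   normalized [0,1] intensity scale.
#' @param blurSigma defocus blur sd in pixels (0 = in focus).
#' @param artefactCount number of incubation artefacts to inject.
#' @param titerIntensityThreshold kinetoplast amplitude at the limit of
#'   reactivity, used to derive titer ground truth in dilution series. The
#'   default (0.25) is the amplitude at which a kinetoplast-only cell of
#'   default geometry crosses the whole-cell 3-sigma brightness rule, i.e.
#'   the detectability limit of the read-out -- a ground truth defined below
#'   what the assay can see would be meaningless.
#' @param maxPlacementAttempts rejection-sampling budget per cell; cells that
#'   cannot be placed without overlap are skipped and reported.
#' @param rngSeed integer seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCells = 10, rngSeed = 1)
#' sim <- simulateImage(cfg)
#' dim(sim$red)
#' @export
simConfig <- function(imageWidth = 612L, imageHeight = 512L, nCells = 30L,
                      positiveFraction = 0.5, nucleusFraction = 0.5,
                      basalBodyFraction = 0.5,
                      organelleIntensity = list(
                        kinetoplast = c(mean = 0.5, sd = 0.05),
                        nucleus = c(mean = 0.45, sd = 0.05),
                        basal_body = c(mean = 0.40, sd = 0.05)),
                      organellePositions = c(basal_body = 0.10,
                                             kinetoplast = 0.25,
                                             nucleus = 0.60),
                      organelleSigmaPx = c(basal_body = 1.8,
                                           kinetoplast = 2.5,
                                           nucleus = 4.0),
                      cellLengthPx = c(mean = 40, sd = 3),
                      cellAspect = c(mean = 4, sd = 0.4),
                      cellRedIntensity = 0.5, backgroundLevel = 0.02,
                      noiseSd = 0.01, blurSigma = 0, artefactCount = 0L,
                      titerIntensityThreshold = 0.25,
                      maxPlacementAttempts = 100L, rngSeed = 1L) {
  new("SimConfig", imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight), nCells = as.integer(nCells),
      positiveFraction = positiveFraction, nucleusFraction = nucleusFraction,
      basalBodyFraction = basalBodyFraction,
      organelleIntensity = organelleIntensity,
      organellePositions = organellePositions,
      organelleSigmaPx = organelleSigmaPx, cellLengthPx = cellLengthPx,
      cellAspect = cellAspect, cellRedIntensity = cellRedIntensity,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      blurSigma = blurSigma, artefactCount = as.integer(artefactCount),
      titerIntensityThreshold = titerIntensityThreshold,
      maxPlacementAttempts = as.integer(maxPlacementAttempts),
      rngSeed = as.integer(rngSeed))
}

# pixel set of a tapered ellipse cell; returns NULL when it cannot be placed
# inside the frame. `margin` grows the footprint used for overlap checks.
.cellPixels <- function(r0, c0, thetaDeg, lengthPx, aspect, H, W, margin = 0) {
  a <- lengthPx / 2
  b <- a / aspect
  half <- ceiling(a + margin + 2)
  if (r0 - half < 1 || r0 + half > H || c0 - half < 1 || c0 + half > W)
    return(NULL)
  rs <- (r0 - half):(r0 + half)
  cs <- (c0 - half):(c0 + half)
  th <- thetaDeg * pi / 180
  dirR <- sin(th); dirC <- cos(th)
  dr <- matrix(rs - r0, length(rs), length(cs))
  dc <- matrix(cs - c0, length(rs), length(cs), byrow = TRUE)
  u <- dc * dirC + dr * dirR
  v <- -dc * dirR + dr * dirC
  f <- pmin(pmax((u + a) / (2 * a), 0), 1)
  bEff <- b * (0.55 + 0.45 * f)            # anterior (basal) end tapered
  inside <- (u / (a + margin))^2 + (v / (bEff + margin))^2 <= 1
  idxR <- dr[inside] + r0
  idxC <- dc[inside] + c0
  list(idx = (idxC - 1L) * H + idxR, frac = f[inside])
}

# additive Gaussian spot at (r0, c0)
.addSpot <- function(img, r0, c0, amplitude, sigma) {
  H <- nrow(img); W <- ncol(img)
  half <- ceiling(4 * sigma)
  rs <- max(1, round(r0) - half):min(H, round(r0) + half)
  cs <- max(1, round(c0) - half):min(W, round(c0) + half)
  dr <- matrix(rs - r0, length(rs), length(cs))
  dc <- matrix(cs - c0, length(rs), length(cs), byrow = TRUE)
  img[rs, cs] <- img[rs, cs] + amplitude * exp(-(dr^2 + dc^2) / (2 * sigma^2))
  img
}

#' Simulate one dual-channel CLIFT image with ground truth
#'
#' Places `nCells` non-overlapping cells by rejection sampling, draws the
#' whole body of every cell in the red (counterstain) channel and only the
#' fluorescent organelles in the green channel, then optionally injects
#' incubation artefacts, applies defocus blur and adds Gaussian read noise.
#' All six call archetypes occur: a cell is anti-dsDNA positive iff its
#' kinetoplast fluoresces, irrespective of nucleus or basal-body
#' fluorescence.
#'
#' @param cfg a [SimConfig-class].
#' @return A list with elements `green` and `red` (intensity matrices in
#'   [0,1]), and `truth`, itself a list of:
#'   \describe{
#'     \item{cells}{data.frame, one row per placed cell: centroid (`row`,
#'       `col`, 0-based), `orientation_deg` (direction basal body to
#'       nucleus), `length_px`, `aspect`, fractional organelle positions,
#'       fluorescence flags (`is_positive`, `nucleus_fluorescent`,
#'       `basal_body_fluorescent`) and drawn amplitudes.}
#'     \item{artefactMask}{logical matrix of injected artefact pixels.}
#'     \item{skipped}{number of cells that could not be placed within the
#'       overlap budget (reported, never silently dropped).}
#'   }
#' @examples
#' sim <- simulateImage(simConfig(nCells = 5, rngSeed = 42))
#' sim$truth$cells$is_positive
#' @export
simulateImage <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@rngSeed)
  .simulateImageNoSeed(cfg)
}

# body of simulateImage, reusing the caller's RNG stream (dilution series
# draw several frames from one seeded stream)
.simulateImageNoSeed <- function(cfg) {
  H <- cfg@imageHeight; W <- cfg@imageWidth
  green <- matrix(cfg@backgroundLevel, H, W)
  red <- matrix(cfg@backgroundLevel, H, W)
  occupied <- matrix(FALSE, H, W)
  pos <- cfg@organellePositions
  sig <- cfg@organelleSigmaPx
  rows <- vector("list", cfg@nCells)
  skipped <- 0L
  placed <- 0L
  for (i in seq_len(cfg@nCells)) {
    ok <- FALSE
    for (attempt in seq_len(cfg@maxPlacementAttempts)) {
      L <- max(10, rnorm(1, cfg@cellLengthPx[["mean"]], cfg@cellLengthPx[["sd"]]))
      A <- max(1.5, rnorm(1, cfg@cellAspect[["mean"]], cfg@cellAspect[["sd"]]))
      theta <- runif(1, 0, 360)
      half <- ceiling(L / 2 + 5)
      if (2 * half + 1 >= min(H, W)) next
      r0 <- sample.int(H - 2L * half, 1L) + half
      c0 <- sample.int(W - 2L * half, 1L) + half
      body <- .cellPixels(r0, c0, theta, L, A, H, W, margin = 0)
      grown <- .cellPixels(r0, c0, theta, L, A, H, W, margin = 2.5)
      if (is.null(body) || is.null(grown)) next
      if (any(occupied[grown$idx])) next
      occupied[body$idx] <- TRUE
      red[body$idx] <- red[body$idx] +
        cfg@cellRedIntensity * max(0.2, rnorm(1, 1, 0.05))
      isPos <- rbinom(1, 1, cfg@positiveFraction) == 1
      hasNuc <- rbinom(1, 1, cfg@nucleusFraction) == 1
      hasBb <- rbinom(1, 1, cfg@basalBodyFraction) == 1
      th <- theta * pi / 180
      dirR <- sin(th); dirC <- cos(th)
      amp <- c(basal_body = NA_real_, kinetoplast = NA_real_, nucleus = NA_real_)
      for (org in c("basal_body", "kinetoplast", "nucleus")) {
        lit <- switch(org, basal_body = hasBb, kinetoplast = isPos,
                      nucleus = hasNuc)
        if (!lit) { amp[org] <- 0; next }
        oi <- cfg@organelleIntensity[[org]]
        I <- max(0, rnorm(1, oi[["mean"]], oi[["sd"]]))
        amp[org] <- I
        d <- (pos[[org]] - 0.5) * L
        green <- .addSpot(green, r0 + d * dirR, c0 + d * dirC, I, sig[[org]])
      }
      placed <- placed + 1L
      rows[[placed]] <- data.frame(
        cell = placed, row = mean(((body$idx - 1L) %% H) + 1L) - 1,
        col = mean(((body$idx - 1L) %/% H) + 1L) - 1,
        orientation_deg = theta, length_px = L, aspect = A,
        area_px = length(body$idx),
        pos_basal_body = pos[["basal_body"]],
        pos_kinetoplast = pos[["kinetoplast"]],
        pos_nucleus = pos[["nucleus"]],
        is_positive = isPos, nucleus_fluorescent = hasNuc,
        basal_body_fluorescent = hasBb,
        kinetoplast_intensity = amp[["kinetoplast"]],
        nucleus_intensity = amp[["nucleus"]],
        basal_body_intensity = amp[["basal_body"]])
      ok <- TRUE
      break
    }
    if (!ok) skipped <- skipped + 1L
  }
  cells <- if (placed > 0L) do.call(rbind, rows[seq_len(placed)]) else
    data.frame(cell = integer(), row = numeric(), col = numeric(),
               orientation_deg = numeric(), length_px = numeric(),
               aspect = numeric(), area_px = integer(),
               pos_basal_body = numeric(), pos_kinetoplast = numeric(),
               pos_nucleus = numeric(), is_positive = logical(),
               nucleus_fluorescent = logical(),
               basal_body_fluorescent = logical(),
               kinetoplast_intensity = numeric(),
               nucleus_intensity = numeric(),
               basal_body_intensity = numeric())
  artefactMask <- matrix(FALSE, H, W)
  if (cfg@artefactCount > 0L) {
    kinds <- sample(c("bright_blob", "fiber", "saturation_patch"),
                    cfg@artefactCount, replace = TRUE)
    for (k in kinds) {
      art <- simulateArtefact(red, k, green = green)
      red <- art$image
      green <- art$green
      artefactMask <- artefactMask | art$mask
    }
  }
  if (cfg@blurSigma > 0) {
    green <- EBImage::gblur(green, sigma = cfg@blurSigma)
    red <- EBImage::gblur(red, sigma = cfg@blurSigma)
  }
  if (cfg@noiseSd > 0) {
    green <- green + matrix(rnorm(H * W, 0, cfg@noiseSd), H, W)
    red <- red + matrix(rnorm(H * W, 0, cfg@noiseSd), H, W)
  }
  list(green = clamp01(green), red = clamp01(red),
       truth = list(cells = cells, artefactMask = artefactMask,
                    skipped = skipped))
}

#' Inject a single incubation artefact into an image
#'
#' Supported kinds: `bright_blob` (a stained debris disk), `fiber` (a thick
#' bright line crossing part of the frame) and `saturation_patch` (a
#' rectangle forced to the dtype maximum, i.e. normalized 1.0). The artefact
#' pixels are returned as a mask so downstream QC stages can be scored
#' against them. Consumes the caller's RNG stream.
#'
#' @param image red-channel intensity matrix the artefact is painted into.
#' @param kind one of `"bright_blob"`, `"fiber"`, `"saturation_patch"`.
#' @param green optional green channel to receive the same artefact.
#' @param areaPx approximate artefact area in pixels (blob / patch).
#' @return list with `image` (modified red), `green` (modified green, or
#'   NULL if none supplied) and `mask` (logical artefact pixels).
#' @export
simulateArtefact <- function(image, kind, green = NULL, areaPx = 5000) {
  H <- nrow(image); W <- ncol(image)
  mask <- matrix(FALSE, H, W)
  if (kind == "bright_blob") {
    rad <- sqrt(areaPx / pi)
    r0 <- runif(1, rad + 1, H - rad - 1)
    c0 <- runif(1, rad + 1, W - rad - 1)
    dr <- matrix(seq_len(H) - r0, H, W)
    dc <- matrix(seq_len(W) - c0, H, W, byrow = TRUE)
    mask <- dr^2 + dc^2 <= rad^2
    image[mask] <- image[mask] + 0.7
    if (!is.null(green)) green[mask] <- green[mask] + 0.35
  } else if (kind == "fiber") {
    theta <- runif(1, 0, pi)
    r0 <- runif(1, H * 0.2, H * 0.8)
    c0 <- runif(1, W * 0.2, W * 0.8)
    len <- max(H, W)
    t <- seq(-len, len, by = 0.5)
    rr <- round(r0 + t * sin(theta)); cc <- round(c0 + t * cos(theta))
    keep <- rr >= 2 & rr <= H - 1 & cc >= 2 & cc <= W - 1
    for (d in -1:1) {
      mask[cbind(rr[keep] + d, cc[keep])] <- TRUE
      mask[cbind(rr[keep], cc[keep] + d)] <- TRUE
    }
    image[mask] <- image[mask] + 0.6
    if (!is.null(green)) green[mask] <- green[mask] + 0.3
  } else if (kind == "saturation_patch") {
    side <- max(2L, round(sqrt(areaPx)))
    r0 <- sample.int(max(1L, H - side), 1L)
    c0 <- sample.int(max(1L, W - side), 1L)
    mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- TRUE
    image[mask] <- 1
    if (!is.null(green)) green[mask] <- 1
  } else {
    stop("unknown artefact kind: ", kind)
  }
  list(image = clamp01(image), green = if (is.null(green)) NULL else
    clamp01(green), mask = mask)
}

#' Simulate a dilution series of one sample
#'
#' Draws one image per dilution factor, scaling every green organelle
#' amplitude by `1/factor` (fluorescence falls inversely with serum
#' dilution) while the red counterstain is unchanged. The titer ground truth
#' is the last dilution whose noiseless mean kinetoplast amplitude still
#' reaches `titerIntensityThreshold`, provided the sample is positive at
#' all.
#'
#' @param cfg a [SimConfig-class]; its organelle intensities describe the
#'   first (least dilute) image.
#' @param dilutionFactors positive, strictly increasing factors relative to
#'   the first image (e.g. `c(1, 3.2, 10)`).
#' @return list with `images` (list of simulateImage results, one per
#'   factor), `dilutionFactors`, and `trueTiterLevel` (index into
#'   `dilutionFactors` of the last reactive dilution; 0 if none).
#' @export
simulateDilutionSeries <- function(cfg, dilutionFactors) {
  validObject(cfg)
  if (length(dilutionFactors) == 0L)
    stop("dilutionFactors must be non-empty")
  if (any(dilutionFactors <= 0) ||
      (length(dilutionFactors) > 1L && any(diff(dilutionFactors) <= 0)))
    stop("dilutionFactors must be positive and strictly increasing")
  set.seed(cfg@rngSeed)
  kinMean <- cfg@organelleIntensity$kinetoplast[["mean"]]
  images <- lapply(dilutionFactors, function(f) {
    c2 <- cfg
    c2@organelleIntensity <- lapply(cfg@organelleIntensity, function(x) {
      x[["mean"]] <- x[["mean"]] / f
      x[["sd"]] <- x[["sd"]] / f
      x
    })
    .simulateImageNoSeed(c2)
  })
  lvl <- if (cfg@positiveFraction > 0)
    sum(kinMean / dilutionFactors >= cfg@titerIntensityThreshold) else 0L
  list(images = images, dilutionFactors = dilutionFactors,
       trueTiterLevel = as.integer(lvl))
}

#' Simulate a titer-step dilution series for a sample of known titer
#'
#' Convenience wrapper around [simulateDilutionSeries()] for end-to-end
#' titer recovery experiments: given a true titer level (an index into
#' `titerSteps`), the kinetoplast amplitude at the screening dilution is set
#' 30% above the level's reactivity limit, so the series is reactive exactly
#' through step `trueLevel`. One image is produced per titer step, with
#' `dilutionFactor` metadata matching the step.
#'
#' @param trueLevel integer in `1..length(titerSteps)`.
#' @param cfg a [SimConfig-class] template (intensities are overwritten).
#' @param titerSteps ordered dilution labels, first = screening dilution.
#' @return As [simulateDilutionSeries()], plus `stepFactors`.
#' @export
simulateTiterSeries <- function(trueLevel, cfg,
                                titerSteps = c("1:10", "1:32", "1:100",
                                               "1:320", "1:1000")) {
  stepFactors <- titerStepFactor(titerSteps)
  stopifnot(trueLevel >= 1L, trueLevel <= length(stepFactors))
  rel <- stepFactors / stepFactors[1]
  cfg@positiveFraction <- 1
  iRef <- 1.3 * cfg@titerIntensityThreshold * rel[trueLevel]
  cfg@organelleIntensity$kinetoplast[["mean"]] <- iRef
  cfg@organelleIntensity$kinetoplast[["sd"]] <- 0.1 * iRef
  out <- simulateDilutionSeries(cfg, rel)
  out$stepFactors <- stepFactors
  out
}
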