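# Central S4 containers. Constructors live with their modules; validity here.

#' SimConfig: parameters of the synthetic CLIFT image simulator
#'
#' Holds every knob of the dual-channel simulator. Intensities are on the
#' normalized [0,1] scale used throughout the package (pixel value / dtype
#' max). Lengths are in pixels. The defaults describe a quarter-scale frame
#' (612 x 512) carrying on average 30 cells, the cell density of a 40x
#' CLIFT field of view; see [simConfig()].
#'
#' @slot imageWidth,imageHeight frame size in pixels.
#' @slot nCells number of cells to place.
#' @slot positiveFraction probability that a cell's kinetoplast is
#'   fluorescent (anti-dsDNA positive cell).
#' @slot nucleusFraction,basalBodyFraction independent probabilities that the
#'   nucleus / basal body fluoresce (diagnostic noise in the green channel).
#' @slot organelleIntensity named list `kinetoplast`, `nucleus`, `basal_body`,
#'   each `c(mean, sd)` of the green spot amplitude.
#' @slot organellePositions fractional positions of the three organelles
#'   along the cell axis (basal-body end = 0).
#' @slot organelleSigmaPx Gaussian spot radii (sd, pixels) per organelle.
#' @slot cellLengthPx,cellAspect `c(mean, sd)` of cell length and of the
#'   major/minor aspect ratio.
#' @slot cellRedIntensity Evans blue counterstain level of the cell body.
#' @slot backgroundLevel,noiseSd background offset and Gaussian read-noise sd.
#' @slot blurSigma optional defocus blur (Gaussian sd, pixels; 0 = sharp).
#' @slot artefactCount number of incubation artefacts to inject.
#' @slot titerIntensityThreshold kinetoplast amplitude below which a cell is
#'   treated as non-reactive; defines simulated titer ground truth.
#' @slot maxPlacementAttempts rejection-sampling budget per cell.
#' @slot rngSeed integer seed; identical configs give bit-identical images.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  imageWidth = "integer", imageHeight = "integer", nCells = "integer",
  positiveFraction = "numeric", nucleusFraction = "numeric",
  basalBodyFraction = "numeric", organelleIntensity = "list",
  organellePositions = "numeric", organelleSigmaPx = "numeric",
  cellLengthPx = "numeric", cellAspect = "numeric",
  cellRedIntensity = "numeric", backgroundLevel = "numeric",
  noiseSd = "numeric", blurSigma = "numeric", artefactCount = "integer",
  titerIntensityThreshold = "numeric", maxPlacementAttempts = "integer",
  rngSeed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@imageWidth < 1L || object@imageHeight < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (object@positiveFraction < 0 || object@positiveFraction > 1)
    msg <- c(msg, "positiveFraction must lie in [0, 1]")
  org <- c("kinetoplast", "nucleus", "basal_body")
  if (!all(org %in% names(object@organelleIntensity)))
    msg <- c(msg, "organelleIntensity must name kinetoplast, nucleus, basal_body")
  else if (any(vapply(object@organelleIntensity[org], function(x) x[[1]] < 0, logical(1))))
    msg <- c(msg, "organelle intensity means must be >= 0")
  pos <- object@organellePositions
  if (!all(org %in% names(pos)))
    msg <- c(msg, "organellePositions must name all three organelles")
  else if (!(pos[["basal_body"]] < pos[["kinetoplast"]] &&
             pos[["kinetoplast"]] < pos[["nucleus"]]))
    msg <- c(msg, "organelle order along the axis must be basal_body < kinetoplast < nucleus")
  if (object@noiseSd < 0 || object@blurSigma < 0)
    msg <- c(msg, "noiseSd and blurSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ChannelPair: a registered green/red fluorescence image pair
#'
#' One biochip is photographed twice: the green channel carries the specific
#' FITC signal, the red channel the Evans blue counterstain that renders
#' every cell visible regardless of antibody status. Both arrays are stored
#' as `[row, col]` matrices of intensities normalized to [0,1] by dtype max,
#' so absolute brightness remains comparable across dilutions.
#'
#' @slot green,red intensity matrices, identical dimensions.
#' @slot bitDepth bits per sample of the source files (8 or 16).
#' @slot biochipId,sampleId identifiers parsed from file names or metadata.
#' @slot dilutionFactor serum dilution of this incubation (e.g. 10 for 1:10).
#' @slot sourcePaths character(2), green then red source file.
#' @exportClass ChannelPair
setClass("ChannelPair", representation(
  green = "matrix", red = "matrix", bitDepth = "integer",
  biochipId = "character", sampleId = "character",
  dilutionFactor = "numeric", sourcePaths = "character"))

setValidity("ChannelPair", function(object) {
  msg <- character()
  if (!identical(dim(object@green), dim(object@red)))
    msg <- c(msg, "green and red channels must have identical dimensions")
  if (length(object@dilutionFactor) != 1L || object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be a single value >= 1")
  if (length(msg)) msg else TRUE
})

#' ImageQC: focus, artefact and registration quality of one image pair
#'
#' @slot focusScore sharpness metric (background-normalized variance of a
#'   3x3 Laplacian response) computed on the red channel.
#' @slot inFocus `focusScore >= focusThreshold` of the run configuration.
#' @slot artefactMask logical matrix flagging saturated patches and
#'   implausibly large connected components.
#' @slot artefactAreaFraction fraction of frame pixels flagged, in [0,1].
#' @slot registrationShift integer `c(d_row, d_col)` applied to the green
#'   channel to overlay it onto the red channel.
#' @slot registrationFailed TRUE when no credible overlay was found.
#' @exportClass ImageQC
setClass("ImageQC", representation(
  focusScore = "numeric", inFocus = "logical", artefactMask = "matrix",
  artefactAreaFraction = "numeric", registrationShift = "integer",
  registrationFailed = "logical"))

setValidity("ImageQC", function(object) {
  if (object@artefactAreaFraction < 0 || object@artefactAreaFraction > 1)
    "artefactAreaFraction must lie in [0, 1]" else TRUE
})

#' SegmentationResult: labelled candidate-cell masks of one red image
#'
#' @slot labelImage integer matrix; 0 is background, cells are labelled
#'   contiguously `1..nComponents`.
#' @slot nComponents number of retained components.
#' @slot components data.frame with one row per component: `label`,
#'   `area_px`, bounding box (`rmin`, `rmax`, `cmin`, `cmax`), centroid
#'   (`crow`, `ccol`; 0-based pixel coordinates).
#' @exportClass SegmentationResult
setClass("SegmentationResult", representation(
  labelImage = "matrix", nComponents = "integer", components = "data.frame"))

setValidity("SegmentationResult", function(object) {
  lab <- sort(unique(as.integer(object@labelImage)))
  lab <- lab[lab > 0L]
  if (!identical(lab, seq_len(object@nComponents)[seq_along(lab)]) ||
      length(lab) != object@nComponents)
    "labels must be contiguous 1..nComponents" else TRUE
})

#' CellRecord: shape, quality and brightness of one segmented cell
#'
#' @slot cellId component label in the segmentation.
#' @slot pixelIdx linear indices of the mask pixels in the frame.
#' @slot areaPx mask area in pixels.
#' @slot ellipseAxes `c(major, minor)` full axis lengths (px) of the
#'   moment-equivalent ellipse.
#' @slot aspectRatio major/minor, always >= 1.
#' @slot solidity mask area / convex hull area, in (0, 1].
#' @slot orientationDeg direction of the main axis in degrees; after
#'   canonicalization it points from the basal-body end towards the nucleus.
#' @slot orientationReliable FALSE for near-circular masks whose moments do
#'   not define an axis.
#' @slot centroid `c(row, col)`, 0-based.
#' @slot meanGreen,meanRed mean channel intensity over the mask.
#' @slot qcPass,qcReasons shape QC verdict and the violated feature names.
#' @slot isDark TRUE when the whole-cell green brightness does not exceed
#'   background by `darkCellK` standard deviations.
#' @exportClass CellRecord
setClass("CellRecord", representation(
  cellId = "integer", pixelIdx = "integer", areaPx = "integer",
  ellipseAxes = "numeric", aspectRatio = "numeric", solidity = "numeric",
  orientationDeg = "numeric", orientationReliable = "logical",
  centroid = "numeric", meanGreen = "numeric", meanRed = "numeric",
  qcPass = "logical", qcReasons = "character", isDark = "logical"))

setValidity("CellRecord", function(object) {
  msg <- character()
  if (length(object@aspectRatio) == 1L && is.finite(object@aspectRatio) &&
      object@aspectRatio < 1)
    msg <- c(msg, "aspectRatio must be >= 1")
  if (length(object@solidity) == 1L && is.finite(object@solidity) &&
      (object@solidity <= 0 || object@solidity > 1 + 1e-9))
    msg <- c(msg, "solidity must lie in (0, 1]")
  if (isTRUE(object@qcPass) && length(object@qcReasons) > 0L)
    msg <- c(msg, "qcPass implies empty qcReasons")
  if (length(msg)) msg else TRUE
})

#' AxisProfile: discrete normalized green signal along a cell's main axis
#'
#' Cell pixels are projected onto the canonical main axis and partitioned
#' into `profileBins` equal-length segments; bin 1 sits at the basal-body
#' end. `values` are per-bin mean green intensities min-max normalized per
#' cell (a constant cell gives all zeros); `spread` are per-bin standard
#' deviations scaled by the same factor; `rawValues` keep the
#' un-normalized bin means needed for kinetoplast brightness extraction.
#'
#' @slot values,spread,rawValues numeric vectors of length `profileBins`.
#' @slot lengthPx extent of the cell along its axis.
#' @slot orientationCanonical TRUE once the 180-degree ambiguity has been
#'   resolved so that the nucleus-bearing end maps to high bin indices.
#' @exportClass AxisProfile
setClass("AxisProfile", representation(
  values = "numeric", spread = "numeric", rawValues = "numeric",
  lengthPx = "numeric", orientationCanonical = "logical"))

setValidity("AxisProfile", function(object) {
  msg <- character()
  if (length(object@values) != length(object@spread) ||
      length(object@values) != length(object@rawValues))
    msg <- c(msg, "values, spread and rawValues must have equal length")
  v <- object@values
  if (length(v) && any(is.finite(v)) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, "normalized values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TrainedClassifier: two-class linear discriminant over axis-profile features
#'
#' Fitted on a labelled cell-profile table (feature vector = per-bin profile
#' means followed by per-bin spreads, dimension `2 * profileBins`). Stores
#' the pooled-covariance discriminant direction and bias explicitly so that
#' a serialized model reloads bit-stably.
#'
#' @slot classMeans 2 x d matrix, rows `negative`, `positive`.
#' @slot pooledCov d x d pooled within-class covariance (ridge added).
#' @slot weights,bias discriminant direction `w` and offset `c`; a cell is
#'   positive when `x . w - c >= 0`; the posterior is `plogis(x . w - c)`.
#' @slot featureNames column names of the training features, in order.
#' @slot ridge ridge term added to the covariance diagonal.
#' @slot trainingAccuracy resubstitution accuracy on the training table.
#' @slot nPerClass named integer `c(negative, positive)`.
#' @slot seed seed recorded from training metadata.
#' @slot version serialization format version.
#' @exportClass TrainedClassifier
setClass("TrainedClassifier", representation(
  classMeans = "matrix", pooledCov = "matrix", weights = "numeric",
  bias = "numeric", featureNames = "character", ridge = "numeric",
  trainingAccuracy = "numeric", nPerClass = "integer", seed = "integer",
  version = "character"))

setValidity("TrainedClassifier", function(object) {
  msg <- character()
  d <- length(object@weights)
  if (ncol(object@classMeans) != d || length(object@featureNames) != d)
    msg <- c(msg, "feature dimension mismatch between weights, means and names")
  if (nrow(object@classMeans) != 2L)
    msg <- c(msg, "classMeans must have exactly two rows")
  if (length(msg)) msg else TRUE
})

#' CellCall: per-cell classification outcome
#'
#' @slot cellId component label.
#' @slot label one of `positive`, `negative`, `excluded`. Cells failing
#'   shape QC or with unreliable orientation are `excluded`.
#' @slot kinetoplastBrightness background-subtracted mean green intensity
#'   over the kinetoplast band of the canonical axis, >= 0.
#' @slot posterior probability of the positive class; `NA` for excluded
#'   cells and for dark cells decided without the model.
#' @exportClass CellCall
setClass("CellCall", representation(
  cellId = "integer", label = "character",
  kinetoplastBrightness = "numeric", posterior = "numeric"))

setValidity("CellCall", function(object) {
  msg <- character()
  if (!object@label %in% c("positive", "negative", "excluded"))
    msg <- c(msg, "label must be positive, negative or excluded")
  p <- object@posterior
  if (length(p) == 1L && is.finite(p) && (p < 0 || p > 1))
    msg <- c(msg, "posterior must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ImageCall: the verdict for one biochip image
#'
#' @slot biochipId,sampleId identifiers.
#' @slot dilutionFactor serum dilution of the image.
#' @slot verdict `positive`, `negative` or `rejected_qc`.
#' @slot rejectReason non-empty when `verdict == "rejected_qc"`.
#' @slot nCellsTotal segmented cells; `nCellsClassified` those surviving QC.
#' @slot fractionPositive positives / classified, in [0,1].
#' @slot titerEstimate a label from the configured titer steps, or
#'   `"negative"`.
#' @slot confidence calibrated distance of `fractionPositive` from the
#'   cutoff, in [0,1].
#' @slot classifierEvals number of discriminant evaluations spent on this
#'   image (0 for the all-dark short-circuit).
#' @exportClass ImageCall
setClass("ImageCall", representation(
  biochipId = "character", sampleId = "character", dilutionFactor = "numeric",
  verdict = "character", rejectReason = "character",
  nCellsTotal = "integer", nCellsClassified = "integer",
  fractionPositive = "numeric", titerEstimate = "character",
  confidence = "numeric", classifierEvals = "integer"))

setValidity("ImageCall", function(object) {
  msg <- character()
  if (!object@verdict %in% c("positive", "negative", "rejected_qc"))
    msg <- c(msg, "verdict must be positive, negative or rejected_qc")
  f <- object@fractionPositive
  if (length(f) == 1L && is.finite(f) && (f < 0 || f > 1))
    msg <- c(msg, "fractionPositive must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SampleResult: dilution-merged verdict for one sample
#'
#' @slot sampleId identifier shared by all merged images.
#' @slot verdict `positive` iff any constituent dilution is positive.
#' @slot finalTiter consistent with the highest positive dilution.
#' @slot imageCalls list of the per-dilution [ImageCall-class] objects.
#' @slot confidence minimum confidence over the contributing images.
#' @exportClass SampleResult
setClass("SampleResult", representation(
  sampleId = "character", verdict = "character", finalTiter = "character",
  imageCalls = "list", confidence = "numeric"))

#' ConfusionSummary: agreement of software calls with visual reference calls
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and accuracy =
#' (TP+TN)/N, each `NA` when its denominator is empty (never reported as 0
#' or 1 in that case). Percentages are rounded half-up to one decimal.
#'
#' @slot tp,fp,fn,tn confusion counts (software vs reference).
#' @slot sensitivity,specificity,accuracy fractions in [0,1] or `NA`.
#' @exportClass ConfusionSummary
setClass("ConfusionSummary", representation(
  tp = "integer", fp = "integer", fn = "integer", tn = "integer",
  sensitivity = "numeric", specificity = "numeric", accuracy = "numeric"))

setValidity("ConfusionSummary", function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@tn) < 0L))
    "confusion counts must be >= 0" else TRUE
})

#' RunConfig: thresholds and conventions of a classification run
#'
#' All tunable decision parameters of the pipeline live here; none are
#' hard-coded in the command-line layer. See [runConfig()] for defaults and
#' units.
#'
#' @slot positiveCellCutoff required fraction of positive cells for a
#'   positive image (>= comparison at the boundary).
#' @slot titerSteps ordered dilution labels, first entry the screening
#'   dilution `"1:10"`.
#' @slot brightnessToTiterBreakpoints strictly increasing brightness
#'   thresholds, one fewer than `titerSteps`; a brightness at or above
#'   breakpoint i maps to step i+1.
#' @slot cellQcLimits named list of `c(min, max)` per shape feature.
#' @slot darkCellK sigma multiplier of the dark-cell brightness rule.
#' @slot focusThreshold minimum focus score of an evaluable image.
#' @slot artefactAreaFractionMax images whose artefact mask covers more are
#'   rejected.
#' @slot profileBins number of axis-profile bins (>= 8).
#' @slot kinetoplastBand fractional axis interval read out as kinetoplast
#'   brightness.
#' @slot minCellArea components smaller than this never become candidates.
#' @slot minOrientationAspect below this aspect ratio the axis direction is
#'   considered undefined and the cell is excluded.
#' @slot brightnessAggregate `"median"` (default) or `"mean"` over the
#'   positive cells of an image.
#' @slot classifierPath optional path of a serialized model.
#' @slot rngSeed seed for the stochastic steps of training workflows.
#' @exportClass RunConfig
setClass("RunConfig", representation(
  positiveCellCutoff = "numeric", titerSteps = "character",
  brightnessToTiterBreakpoints = "numeric", cellQcLimits = "list",
  darkCellK = "numeric", focusThreshold = "numeric",
  artefactAreaFractionMax = "numeric", profileBins = "integer",
  kinetoplastBand = "numeric", minCellArea = "integer",
  minOrientationAspect = "numeric", brightnessAggregate = "character",
  classifierPath = "character", rngSeed = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@positiveCellCutoff < 0 || object@positiveCellCutoff > 1)
    msg <- c(msg, "positive_cell_cutoff must lie in [0, 1]")
  if (length(object@titerSteps) == 0L)
    msg <- c(msg, "titer_steps must be non-empty")
  bp <- object@brightnessToTiterBreakpoints
  if (length(bp) > 1L && any(diff(bp) <= 0))
    msg <- c(msg, "brightness_to_titer_breakpoints must be strictly increasing")
  if (length(bp) != length(object@titerSteps) - 1L)
    msg <- c(msg, "brightness_to_titer_breakpoints must have one entry fewer than titer_steps")
  if (object@profileBins < 8L)
    msg <- c(msg, "profile_bins must be >= 8")
  if (length(object@kinetoplastBand) != 2L ||
      object@kinetoplastBand[1] >= object@kinetoplastBand[2])
    msg <- c(msg, "kinetoplast_band must be an increasing interval")
  if (!object@brightnessAggregate %in% c("median", "mean"))
    msg <- c(msg, "brightness_aggregate must be 'median' or 'mean'")
  if (length(msg)) msg else TRUE
})
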