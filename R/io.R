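#' Read a green/red channel pair from disk
#'
#' Reads two single-channel grayscale images (TIFF or PNG, 8- or 16-bit) and
#' returns a [ChannelPair-class]. Intensities are normalized to [0,1] by the
#' dtype maximum -- not by per-image min/max -- so absolute brightness stays
#' comparable across dilutions, which titer aggregation relies on.
#'
#' @param greenPath,redPath image file paths.
#' @param sampleId,biochipId identifiers; default from file names.
#' @param dilutionFactor serum dilution factor (>= 1).
#' @return A [ChannelPair-class].
#' @export
loadChannelPair <- function(greenPath, redPath,
                            sampleId = "sample", biochipId = "biochip",
                            dilutionFactor = 10) {
  g <- .readGray(greenPath)
  r <- .readGray(redPath)
  if (!identical(dim(g$img), dim(r$img)))
    stop("channel dimension mismatch: green ",
         paste(dim(g$img), collapse = "x"), " vs red ",
         paste(dim(r$img), collapse = "x"))
  new("ChannelPair", green = g$img, red = r$img,
      bitDepth = as.integer(max(g$bits, r$bits)),
      biochipId = biochipId, sampleId = sampleId,
      dilutionFactor = dilutionFactor,
      sourcePaths = c(greenPath, redPath))
}

.readGray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    bits <- if (!is.null(bps)) as.integer(bps[1]) else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L)
      stop("multi-channel (RGB) input: ", path,
           "; extract the fluorescence channel to a single-channel ",
           "grayscale file before loading")
    img <- img[, , 1]
  }
  attributes(img) <- list(dim = dim(img))
  list(img = img, bits = bits)
}

#' Construct a ChannelPair from in-memory matrices
#'
#' @param green,red intensity matrices in [0,1], identical dimensions.
#' @param sampleId,biochipId,dilutionFactor metadata.
#' @param bitDepth nominal bit depth (default 16).
#' @return A [ChannelPair-class].
#' @export
channelPair <- function(green, red, sampleId = "sample",
                        biochipId = "biochip", dilutionFactor = 10,
                        bitDepth = 16L) {
  new("ChannelPair", green = green, red = red,
      bitDepth = as.integer(bitDepth), biochipId = biochipId,
      sampleId = sampleId, dilutionFactor = dilutionFactor,
      sourcePaths = character(0))
}

#' Discover channel pairs of a slide directory
#'
#' Scans `dirPath` for images following the naming convention
#' `{sample}_{biochip}_{dilution}_{channel}.{tif|tiff|png}` (overridable
#' regex with exactly four capture groups in that order; dilution is the
#' numeric factor, e.g. 10 for 1:10). Files whose partner channel is
#' missing are listed in the skip report, never silently ignored. The
#' returned descriptors are ordered by sample then ascending dilution, which
#' is stable across file-system enumeration orders.
#'
#' @param dirPath directory to scan.
#' @param pattern regex with capture groups sample, biochip, dilution,
#'   channel.
#' @return list with `pairs` (data.frame: sample_id, biochip_id,
#'   dilution_factor, green_path, red_path) and `skipped` (data.frame:
#'   file, reason).
#' @export
discoverSlide <- function(dirPath,
                          pattern = "^(.+)_([^_]+)_([^_]+)_(green|red)\\.(?:tif|tiff|png)$") {
  files <- sort(list.files(dirPath))
  m <- regmatches(files, regexec(pattern, files))
  ok <- lengths(m) >= 5L
  unrec <- files[!ok & grepl("\\.(tif|tiff|png)$", files)]
  skipped <- data.frame(file = unrec,
                        reason = rep("unrecognized_name", length(unrec)),
                        stringsAsFactors = FALSE)
  if (!any(ok))
    return(list(pairs = data.frame(sample_id = character(),
                                   biochip_id = character(),
                                   dilution_factor = numeric(),
                                   green_path = character(),
                                   red_path = character(),
                                   stringsAsFactors = FALSE),
                skipped = skipped))
  tab <- do.call(rbind, lapply(which(ok), function(i) {
    p <- m[[i]]
    data.frame(file = files[i], sample_id = p[2], biochip_id = p[3],
               dilution = p[4], channel = p[5], stringsAsFactors = FALSE)
  }))
  key <- paste(tab$sample_id, tab$biochip_id, tab$dilution, sep = "\r")
  pairs <- list(); skipRows <- list()
  for (k in unique(key)) {
    sub <- tab[key == k, ]
    g <- sub$file[sub$channel == "green"]
    r <- sub$file[sub$channel == "red"]
    if (length(g) == 1L && length(r) == 1L) {
      pairs[[k]] <- data.frame(
        sample_id = sub$sample_id[1], biochip_id = sub$biochip_id[1],
        dilution_factor = suppressWarnings(as.numeric(sub$dilution[1])),
        green_path = file.path(dirPath, g), red_path = file.path(dirPath, r),
        stringsAsFactors = FALSE)
    } else {
      skipRows[[k]] <- data.frame(file = sub$file,
                                  reason = "unpaired_channel",
                                  stringsAsFactors = FALSE)
    }
  }
  pairsDf <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(sample_id = character(), biochip_id = character(),
               dilution_factor = numeric(), green_path = character(),
               red_path = character(), stringsAsFactors = FALSE)
  if (length(skipRows)) skipped <- rbind(skipped, do.call(rbind, skipRows))
  ord <- order(pairsDf$sample_id, pairsDf$dilution_factor, pairsDf$biochip_id)
  pairsDf <- pairsDf[ord, , drop = FALSE]
  rownames(pairsDf) <- NULL
  rownames(skipped) <- NULL
  list(pairs = pairsDf, skipped = skipped)
}

#' Write a simulated image pair (plus ground truth) to disk
#'
#' Writes 16-bit grayscale TIFFs with `_green.tif` / `_red.tif` suffixes
#' following the discoverable naming convention, the ground-truth cell table
#' as CSV, and the full ground truth (including the artefact mask as run
#' lengths) as JSON.
#'
#' @param sim result of [simulateImage()].
#' @param dir output directory (created if needed).
#' @param sampleId,biochipId,dilutionFactor naming metadata.
#' @return Invisibly, the named character vector of files written.
#' @export
writeSimulatedImage <- function(sim, dir, sampleId = "S1", biochipId = "B1",
                                dilutionFactor = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste(sampleId, biochipId, dilutionFactor, sep = "_"))
  files <- c(green = paste0(stem, "_green.tif"),
             red = paste0(stem, "_red.tif"),
             cells = paste0(stem, "_truth.csv"),
             truth = paste0(stem, "_truth.json"))
  tiff::writeTIFF(sim$green, files[["green"]], bits.per.sample = 16L)
  tiff::writeTIFF(sim$red, files[["red"]], bits.per.sample = 16L)
  write.csv(sim$truth$cells, files[["cells"]], row.names = FALSE)
  art <- rle(as.logical(sim$truth$artefactMask))
  jsonlite::write_json(
    list(cells = sim$truth$cells, skipped = sim$truth$skipped,
         artefact_rle = list(lengths = art$lengths, values = art$values),
         dim = dim(sim$red)),
    files[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
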