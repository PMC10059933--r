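## Stage 2: blob detection in the global mask, per-blob confined range
## re-derivation, and compositing of the refined patches.
##
## Blob coordinates are 1-based inclusive matrix indices (row = y, col = x).

#' Detect foreground blobs in a binary mask
#'
#' Connected components of the foreground (255) pixels under 8-connectivity.
#' Labeling is delegated to `EBImage::bwlabel` (4-connected) and labels that
#' touch diagonally are merged afterwards, yielding 8-connected components.
#'
#' @param mask integer matrix over \{0, 255\}.
#' @return A `data.frame` with one row per blob: `label`, tight bounding box
#'   `minRow`, `minCol`, `maxRow`, `maxCol` (1-based inclusive), `pixelCount`
#'   and `bboxArea` (bounding-box height x width). Zero rows when the mask has
#'   no foreground.
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 3:5] <- 255L
#' detectBlobs(m)
#' @export
detectBlobs <- function(mask) {
    .assertMask(mask)
    fg <- mask == 255L
    empty <- data.frame(label = integer(0), minRow = integer(0),
                        minCol = integer(0), maxRow = integer(0),
                        maxCol = integer(0), pixelCount = integer(0),
                        bboxArea = integer(0))
    if (!any(fg))
        return(empty)
    ## EBImage images are (x, y): transpose in and out
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg) * 1))))
    storage.mode(lab) <- "integer"
    nlab <- max(lab)
    if (nlab > 1L) {
        m <- nrow(lab); n <- ncol(lab)
        pairs <- rbind(
            cbind(as.vector(lab[-m, -n]), as.vector(lab[-1, -1])),   # \ diag
            cbind(as.vector(lab[-m, -1]), as.vector(lab[-1, -n])))   # / diag
        pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                       pairs[, 1] != pairs[, 2], , drop = FALSE]
        if (nrow(pairs) > 0L) {
            pairs <- unique(pairs)
            parent <- seq_len(nlab)
            findRoot <- function(i) {
                while (parent[i] != i) i <- parent[i]
                i
            }
            for (k in seq_len(nrow(pairs))) {
                a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
                if (a != b) parent[max(a, b)] <- min(a, b)
            }
            roots <- vapply(seq_len(nlab), findRoot, integer(1))
            newId <- match(roots, sort(unique(roots)))
            pos <- lab > 0L
            lab[pos] <- newId[lab[pos]]
        }
    }
    idx <- which(lab > 0L, arr.ind = TRUE)
    lbl <- lab[idx]
    blobs <- data.frame(
        label = sort(unique(lbl)),
        minRow = as.integer(tapply(idx[, 1], lbl, min)),
        minCol = as.integer(tapply(idx[, 2], lbl, min)),
        maxRow = as.integer(tapply(idx[, 1], lbl, max)),
        maxCol = as.integer(tapply(idx[, 2], lbl, max)),
        pixelCount = as.integer(table(lbl)))
    blobs$bboxArea <- (blobs$maxRow - blobs$minRow + 1L) *
                      (blobs$maxCol - blobs$minCol + 1L)
    rownames(blobs) <- NULL
    blobs
}

#' Keep blobs whose bounding box reaches the size floor
#'
#' Relevance is judged on bounding-box area (height x width), inclusive of the
#' floor itself.
#'
#' @param blobs a blob `data.frame` from [detectBlobs()].
#' @param minBlobArea bounding-box area floor in pixels (default 500).
#' @return The qualifying rows of `blobs`.
#' @export
selectRelevantBlobs <- function(blobs, minBlobArea = 500L) {
    out <- blobs[blobs$bboxArea >= minBlobArea, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Derive confined local hue/saturation ranges for a blob region
#'
#' The crop's hue histogram is built only from pixels whose hue lies within
#' the global hue range widened by `c1` (clipped to 0--179); it is smoothed,
#' nominated and reduced with [maxContinuousRange()] under `limit2`. The
#' saturation histogram is then built from the saturation values of pixels in
#' the local hue range, confined to the global saturation range widened by
#' `c2`, and reduced the same way. If either confined pipeline has no pixels
#' or nominates nothing, the blob falls back to the global ranges with a
#' warning.
#'
#' @param hsvCrop an [HSVImage-class]: the crop under the blob's bounding box.
#' @param globalHue,globalSat [BinRange-class] global ranges.
#' @param params a [ThresholdParams-class].
#' @return `list(hueRange = BinRange, satRange = BinRange,
#'   fallback = logical)`.
#' @export
localRangesForRegion <- function(hsvCrop, globalHue, globalSat,
                                 params = thresholdParams()) {
    stopifnot(is(hsvCrop, "HSVImage"))
    fallback <- function(why) {
        warning("local range derivation failed (", why,
                "); reusing the global ranges for this blob")
        list(hueRange = globalHue, satRange = globalSat, fallback = TRUE)
    }
    H <- hueChannel(hsvCrop)
    S <- satChannel(hsvCrop)
    hLo <- max(0L, globalHue@low - params@c1)
    hHi <- min(179L, globalHue@high + params@c1)
    hConf <- H[H >= hLo & H <= hHi]
    if (length(hConf) == 0L)
        return(fallback("no pixel inside the confined hue window"))
    smH <- smoothenPmf(channelPmf(hConf, 180L), params@windowSize)
    nomH <- nominatedRange(smH, params@cutoffGradient, params@cutoffArea,
                           params@windowSize)
    if (length(nomH) == 0L)
        return(fallback("no hue bins nominated"))
    runH <- maxContinuousRange(nomH, params@limit2)
    localHue <- binRange(min(runH), max(runH))

    sLo <- max(0L, globalSat@low - params@c2)
    sHi <- min(255L, globalSat@high + params@c2)
    sVals <- findSatValues(localHue@low, localHue@high, H, S)
    sConf <- sVals[sVals >= sLo & sVals <= sHi]
    if (length(sConf) == 0L)
        return(fallback("no pixel inside the confined saturation window"))
    smS <- smoothenPmf(channelPmf(sConf, 256L), params@windowSize)
    nomS <- nominatedRange(smS, params@cutoffGradient, params@cutoffAreaSat,
                           params@windowSize)
    if (length(nomS) == 0L)
        return(fallback("no saturation bins nominated"))
    runS <- maxContinuousRange(nomS, params@limit2)
    list(hueRange = localHue,
         satRange = binRange(min(runS), max(runS)),
         fallback = FALSE)
}

.localThresholdHsv <- function(hsv, global, params) {
    stopifnot(is(global, "GlobalResult"))
    gmask <- globalMask(global)
    if (!identical(dim(gmask), dim(hsv)))
        stop("'global' was computed from an image of different dimensions")
    out <- matrix(0L, nrow(gmask), ncol(gmask))
    blobs <- selectRelevantBlobs(detectBlobs(gmask), params@minBlobArea)
    H <- hueChannel(hsv); S <- satChannel(hsv); V <- valChannel(hsv)
    for (k in seq_len(nrow(blobs))) {
        rows <- blobs$minRow[k]:blobs$maxRow[k]
        cols <- blobs$minCol[k]:blobs$maxCol[k]
        crop <- hsvImage(H[rows, cols, drop = FALSE],
                         S[rows, cols, drop = FALSE],
                         V[rows, cols, drop = FALSE])
        lr <- localRangesForRegion(crop, hueRange(global), satRange(global),
                                   params)
        out[rows, cols] <- applyThreshold(crop, lr$hueRange, lr$satRange)
    }
    out
}

#' @rdname localThreshold
setMethod("localThreshold", signature("HSVImage", "GlobalResult"),
    function(x, global, params) .localThresholdHsv(x, global, params))

#' @rdname localThreshold
setMethod("localThreshold", signature("array", "GlobalResult"),
    function(x, global, params) .localThresholdHsv(rgbToHsv(x), global, params))
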