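## Stage 1: image-wide background hue/saturation range derivation and the
## global threshold.

#' Derive the global background hue range
#'
#' PMF of the hue plane -> moving-average smoothing -> gradient/area
#' nomination -> peak-inclusive maximum-continuous-range selection with
#' `limit1`. The returned range is `[min, max]` of the selected run and always
#' contains the peak bin of the smoothed hue PMF (argmax, smallest bin on
#' ties).
#'
#' @param hsv an [HSVImage-class].
#' @param params a [ThresholdParams-class].
#' @return `list(range = BinRange, peak = integer)`.
#' @export
globalHueRange <- function(hsv, params = thresholdParams()) {
    stopifnot(is(hsv, "HSVImage"), is(params, "ThresholdParams"))
    pmf <- channelPmf(hueChannel(hsv), 180L)
    sm <- smoothenPmf(pmf, params@windowSize)
    peak <- which.max(sm) - 1L
    nom <- nominatedRange(sm, params@cutoffGradient, params@cutoffArea,
                          params@windowSize)
    if (length(nom) == 0L)
        stop("no hue bins were nominated; cannot derive a global hue range")
    run <- maxContinuousRangeWithPeak(nom, peak, params@limit1)
    list(range = binRange(min(run), max(run)), peak = peak)
}

#' Derive the global background saturation range
#'
#' Saturation values of pixels whose hue lies in the global hue range are
#' shortlisted; their 256-bin PMF is smoothed, nominated and reduced with
#' [maxContinuousRange()] under `limit2`. Unlike the hue range, the selection
#' carries no peak constraint.
#'
#' @param hsv an [HSVImage-class].
#' @param hueRange a [BinRange-class]: the global hue range.
#' @param params a [ThresholdParams-class].
#' @return A [BinRange-class].
#' @export
globalSatRange <- function(hsv, hueRange, params = thresholdParams()) {
    stopifnot(is(hsv, "HSVImage"), is(hueRange, "BinRange"))
    satVals <- findSatValues(hueRange@low, hueRange@high,
                             hueChannel(hsv), satChannel(hsv))
    if (length(satVals) == 0L)
        stop("empty shortlist: no pixel has hue inside the global hue range")
    pmf <- channelPmf(satVals, 256L)
    sm <- smoothenPmf(pmf, params@windowSize)
    nom <- nominatedRange(sm, params@cutoffGradient, params@cutoffAreaSat,
                          params@windowSize)
    if (length(nom) == 0L)
        stop("no saturation bins were nominated")
    run <- maxContinuousRange(nom, params@limit2)
    binRange(min(run), max(run))
}

#' Threshold an image with fixed hue/saturation ranges
#'
#' A pixel is background (0) iff its hue AND saturation both lie inside their
#' inclusive ranges; otherwise it is foreground (255). The value plane is
#' ignored, which makes the mask invariant to uniform illumination rescaling.
#'
#' @param hsv an [HSVImage-class].
#' @param hueRange,satRange [BinRange-class] background ranges.
#' @return Integer matrix over \{0, 255\} with the image's dimensions.
#' @export
applyThreshold <- function(hsv, hueRange, satRange) {
    stopifnot(is(hsv, "HSVImage"),
              is(hueRange, "BinRange"), is(satRange, "BinRange"))
    H <- hueChannel(hsv)
    S <- satChannel(hsv)
    mask <- matrix(255L, nrow(H), ncol(H))
    bg <- H >= hueRange@low & H <= hueRange@high &
          S >= satRange@low & S <= satRange@high
    mask[bg] <- 0L
    mask
}

#' @rdname globalThreshold
setMethod("globalThreshold", "HSVImage", function(x, params) {
    hr <- globalHueRange(x, params)
    sr <- globalSatRange(x, hr$range, params)
    new("GlobalResult",
        mask = applyThreshold(x, hr$range, sr),
        hueRange = hr$range, satRange = sr, peakHue = hr$peak)
})

#' @rdname globalThreshold
setMethod("globalThreshold", "array", function(x, params) {
    globalThreshold(rgbToHsv(x), params)
})

#' Run both thresholding stages
#'
#' Convenience wrapper returning the stage-1 result and the stage-2 mask.
#'
#' @inheritParams globalThreshold
#' @return `list(global = GlobalResult, localMask = matrix)`.
#' @export
twoStageThreshold <- function(x, params = thresholdParams()) {
    gr <- globalThreshold(x, params)
    list(global = gr, localMask = localThreshold(x, gr, params))
}
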