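#' @import methods
NULL

#' Inclusive histogram bin range
#'
#' An inclusive `[low, high]` range of integer histogram bins. Bins are the
#' pixel values themselves: hue bins run 0--179 (half-degree convention),
#' saturation bins 0--255.
#'
#' @slot low integer, lower bin (inclusive).
#' @slot high integer, upper bin (inclusive), `low <= high`.
#'
#' @aliases BinRange-class
#' @exportClass BinRange
setClass("BinRange",
    representation(low = "integer", high = "integer"),
    validity = function(object) {
        if (length(object@low) != 1L || length(object@high) != 1L)
            return("'low' and 'high' must be single integers")
        if (is.na(object@low) || is.na(object@high))
            return("'low' and 'high' must not be NA")
        if (object@low < 0L)
            return("'low' must be >= 0")
        if (object@low > object@high)
            return("'low' must be <= 'high'")
        TRUE
    })

#' Construct a BinRange
#'
#' @param low,high inclusive integer bin bounds, `0 <= low <= high`.
#' @return A [BinRange-class] object.
#' @examples
#' binRange(72, 93)
#' @export
binRange <- function(low, high)
    new("BinRange", low = as.integer(low), high = as.integer(high))

#' HSV image planes
#'
#' Integer hue/saturation/value planes of an 8-bit color image. Hue uses the
#' half-degree convention (values 0--179, 180 histogram bins); saturation and
#' value run 0--255. The value plane is carried along but never consulted by
#' the thresholding stages, which operate on chromaticity only.
#'
#' @slot H integer matrix, hue plane, values in 0--179.
#' @slot S integer matrix, saturation plane, values in 0--255.
#' @slot V integer matrix, value plane, values in 0--255.
#'
#' @aliases HSVImage-class
#' @exportClass HSVImage
setClass("HSVImage",
    representation(H = "matrix", S = "matrix", V = "matrix"),
    validity = function(object) {
        d <- dim(object@H)
        if (!identical(d, dim(object@S)) || !identical(d, dim(object@V)))
            return("H, S and V planes must share identical dimensions")
        if (any(d < 1L))
            return("planes must have at least one row and one column")
        if (anyNA(object@H) || anyNA(object@S) || anyNA(object@V))
            return("planes must not contain NA")
        if (min(object@H) < 0L || max(object@H) > 179L)
            return("hue plane values must lie in [0, 179]")
        if (min(object@S) < 0L || max(object@S) > 255L)
            return("saturation plane values must lie in [0, 255]")
        if (min(object@V) < 0L || max(object@V) > 255L)
            return("value plane values must lie in [0, 255]")
        TRUE
    })

#' Construct an HSVImage from integer planes
#'
#' @param H,S,V integer matrices of identical dimensions; hue in 0--179,
#'   saturation and value in 0--255.
#' @return An [HSVImage-class] object.
#' @examples
#' hsv <- hsvImage(matrix(83L, 4, 4), matrix(200L, 4, 4), matrix(128L, 4, 4))
#' dim(hsv)
#' @export
hsvImage <- function(H, S, V) {
    toInt <- function(x) {
        x <- as.matrix(x)
        storage.mode(x) <- "integer"
        x
    }
    new("HSVImage", H = toInt(H), S = toInt(S), V = toInt(V))
}

#' Tunable parameters of the two-stage thresholding algorithm
#'
#' Bundles the nomination cutoffs, the smoothing/nomination window size, the
#' hue and saturation run-continuity limits, the local confinement slacks and
#' the blob size floor. Two presets ship with the package: `"pca"`
#' (`limit1 = 2`, `limit2 = 4`, `c1 = 6`, `c2 = 12`, suited to board-like
#' images with a uniform background) and `"skin"` (`limit1 = 4`, `limit2 = 4`,
#' `c1 = 12`, `c2 = 12`, suited to lesion-like images).
#'
#' @slot cutoffGradient numeric, threshold on the windowed mean arctan
#'   gradient of the smoothed PMF (default 0.001).
#' @slot cutoffArea numeric, threshold on the windowed mean of the smoothed
#'   hue PMF (default `1/180`, one over the hue histogram length).
#' @slot cutoffAreaSat numeric, area cutoff used for the 256-bin saturation
#'   PMF (default `1/180`, matching the hue cutoff).
#' @slot windowSize integer, odd window width for smoothing and nomination
#'   (default 5).
#' @slot limit1 integer, maximum gap between consecutive nominated hue bins
#'   within one continuous run.
#' @slot limit2 integer, maximum gap for saturation runs (also used for both
#'   channels in the local stage).
#' @slot c1 integer, hue slack: local hue histograms are confined to the
#'   global hue range widened by `c1` on each side.
#' @slot c2 integer, saturation slack for the local stage.
#' @slot minBlobArea integer, bounding-box area (height x width) below which a
#'   blob is ignored by the local stage (default 500 pixels).
#'
#' @aliases ThresholdParams-class
#' @exportClass ThresholdParams
setClass("ThresholdParams",
    representation(
        cutoffGradient = "numeric", cutoffArea = "numeric",
        cutoffAreaSat = "numeric", windowSize = "integer",
        limit1 = "integer", limit2 = "integer",
        c1 = "integer", c2 = "integer", minBlobArea = "integer"),
    validity = function(object) {
        if (object@cutoffGradient < 0 || object@cutoffArea < 0 ||
            object@cutoffAreaSat < 0)
            return("cutoffs must be >= 0")
        if (object@windowSize < 1L || object@windowSize %% 2L == 0L)
            return("windowSize must be an odd integer >= 1")
        if (object@limit1 < 1L || object@limit2 < 1L)
            return("limit1 and limit2 must be >= 1")
        if (object@c1 < 0L || object@c2 < 0L)
            return("c1 and c2 must be >= 0")
        if (object@minBlobArea < 1L)
            return("minBlobArea must be >= 1")
        TRUE
    })

#' Construct ThresholdParams
#'
#' @param preset `"pca"` or `"skin"`; fills `limit1`, `limit2`, `c1`, `c2`.
#'   Explicit arguments override the preset.
#' @param cutoffGradient,cutoffArea,cutoffAreaSat,windowSize nomination
#'   settings; see [ThresholdParams-class].
#' @param limit1,limit2 run-continuity limits (hue, saturation).
#' @param c1,c2 local confinement slacks (hue, saturation).
#' @param minBlobArea blob bounding-box area floor in pixels.
#' @return A [ThresholdParams-class] object.
#' @examples
#' thresholdParams("pca")
#' thresholdParams("skin", c1 = 10)
#' @export
thresholdParams <- function(preset = c("pca", "skin"),
                            cutoffGradient = 0.001,
                            cutoffArea = 1 / 180,
                            cutoffAreaSat = 1 / 180,
                            windowSize = 5L,
                            limit1 = NULL, limit2 = NULL,
                            c1 = NULL, c2 = NULL,
                            minBlobArea = 500L) {
    preset <- match.arg(preset)
    def <- switch(preset,
        pca  = list(limit1 = 2L, limit2 = 4L, c1 = 6L, c2 = 12L),
        skin = list(limit1 = 4L, limit2 = 4L, c1 = 12L, c2 = 12L))
    if (is.null(limit1)) limit1 <- def$limit1
    if (is.null(limit2)) limit2 <- def$limit2
    if (is.null(c1)) c1 <- def$c1
    if (is.null(c2)) c2 <- def$c2
    new("ThresholdParams",
        cutoffGradient = as.numeric(cutoffGradient),
        cutoffArea = as.numeric(cutoffArea),
        cutoffAreaSat = as.numeric(cutoffAreaSat),
        windowSize = as.integer(windowSize),
        limit1 = as.integer(limit1), limit2 = as.integer(limit2),
        c1 = as.integer(c1), c2 = as.integer(c2),
        minBlobArea = as.integer(minBlobArea))
}

#' Result of the global thresholding stage
#'
#' Holds the globally thresholded binary mask together with the derived
#' background hue and saturation ranges and the peak hue bin, which the local
#' stage needs as its starting point.
#'
#' @slot mask integer matrix over \{0, 255\}; 0 = background, 255 = foreground.
#' @slot hueRange [BinRange-class], global background hue range (contains
#'   `peakHue` by construction).
#' @slot satRange [BinRange-class], global background saturation range.
#' @slot peakHue integer, argmax bin of the smoothed hue PMF.
#'
#' @aliases GlobalResult-class
#' @exportClass GlobalResult
setClass("GlobalResult",
    representation(mask = "matrix", hueRange = "BinRange",
                   satRange = "BinRange", peakHue = "integer"),
    validity = function(object) {
        if (!all(object@mask %in% c(0L, 255L)))
            return("mask must contain only the levels 0 and 255")
        if (object@peakHue < object@hueRange@low ||
            object@peakHue > object@hueRange@high)
            return("peakHue must lie inside hueRange")
        TRUE
    })
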