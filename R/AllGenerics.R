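#' @rdname BinRange-class
#' @param x a package object.
#' @export
setGeneric("rangeLow", function(x) standardGeneric("rangeLow"))

#' @rdname BinRange-class
#' @export
setGeneric("rangeHigh", function(x) standardGeneric("rangeHigh"))

#' @rdname HSVImage-class
#' @export
setGeneric("hueChannel", function(x) standardGeneric("hueChannel"))

#' @rdname HSVImage-class
#' @export
setGeneric("satChannel", function(x) standardGeneric("satChannel"))

#' @rdname HSVImage-class
#' @export
setGeneric("valChannel", function(x) standardGeneric("valChannel"))

#' @rdname GlobalResult-class
#' @export
setGeneric("globalMask", function(x) standardGeneric("globalMask"))

#' @rdname GlobalResult-class
#' @export
setGeneric("hueRange", function(x) standardGeneric("hueRange"))

#' @rdname GlobalResult-class
#' @export
setGeneric("satRange", function(x) standardGeneric("satRange"))

#' @rdname GlobalResult-class
#' @export
setGeneric("peakHue", function(x) standardGeneric("peakHue"))

#' Global (stage-1) thresholding
#'
#' Derives the image-wide background hue and saturation ranges from the
#' smoothed channel PMFs and thresholds the whole image with them. See
#' [globalHueRange()], [globalSatRange()] and [applyThreshold()] for the
#' individual steps.
#'
#' @param x an [HSVImage-class], or an `m x n x 3` numeric array of 8-bit RGB
#'   values (0--255), which is converted with [rgbToHsv()] first.
#' @param params a [ThresholdParams-class] object.
#' @return A [GlobalResult-class] object.
#' @examples
#' fx <- makeFixture(boardFixtureSpec(seed = 7))
#' gr <- globalThreshold(fx$hsv, thresholdParams("pca"))
#' hueRange(gr)
#' @export
setGeneric("globalThreshold",
    function(x, params = thresholdParams()) standardGeneric("globalThreshold"))

#' Local (stage-2) thresholding
#'
#' Refines a global thresholding result: foreground blobs are detected in the
#' global mask, blobs whose bounding box reaches `minBlobArea` are
#' re-thresholded with locally derived hue/saturation ranges (confined to the
#' global ranges widened by `c1`/`c2`), and the refined patches are composited
#' onto an all-background canvas. Pixels outside every relevant bounding box
#' are therefore background in the output.
#'
#' @param x the image the global result was computed from (an
#'   [HSVImage-class] or an RGB array, as in [globalThreshold()]).
#' @param global a [GlobalResult-class] from the same image.
#' @param params a [ThresholdParams-class] object.
#' @return An integer matrix over \{0, 255\}.
#' @examples
#' fx <- makeFixture(boardFixtureSpec(seed = 7))
#' p <- thresholdParams("pca")
#' gr <- globalThreshold(fx$hsv, p)
#' lt <- localThreshold(fx$hsv, gr, p)
#' table(lt)
#' @export
setGeneric("localThreshold",
    function(x, global, params = thresholdParams())
        standardGeneric("localThreshold"))
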