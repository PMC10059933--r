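#' @rdname BinRange-class
setMethod("rangeLow", "BinRange", function(x) x@low)

#' @rdname BinRange-class
setMethod("rangeHigh", "BinRange", function(x) x@high)

#' @rdname BinRange-class
#' @param object a `BinRange`.
setMethod("show", "BinRange", function(object) {
    cat(sprintf("BinRange [%d, %d] (%d bins)\n",
                object@low, object@high, object@high - object@low + 1L))
    invisible(NULL)
})

setMethod("rangeLow", "GlobalResult", function(x) x@hueRange@low)
setMethod("rangeHigh", "GlobalResult", function(x) x@hueRange@high)

#' @rdname HSVImage-class
setMethod("hueChannel", "HSVImage", function(x) x@H)

#' @rdname HSVImage-class
setMethod("satChannel", "HSVImage", function(x) x@S)

#' @rdname HSVImage-class
setMethod("valChannel", "HSVImage", function(x) x@V)

#' @rdname HSVImage-class
#' @param x an `HSVImage`.
#' @export
setMethod("dim", "HSVImage", function(x) dim(x@H))

#' @rdname HSVImage-class
#' @param object an `HSVImage`.
setMethod("show", "HSVImage", function(object) {
    d <- dim(object@H)
    cat(sprintf("HSVImage %d x %d  (hue bins 0-179, S/V 0-255)\n", d[1], d[2]))
    cat(sprintf("  hue range in image: [%d, %d]; saturation: [%d, %d]\n",
                min(object@H), max(object@H), min(object@S), max(object@S)))
    invisible(NULL)
})

#' @rdname GlobalResult-class
setMethod("globalMask", "GlobalResult", function(x) x@mask)

#' @rdname GlobalResult-class
setMethod("hueRange", "GlobalResult", function(x) x@hueRange)

#' @rdname GlobalResult-class
setMethod("satRange", "GlobalResult", function(x) x@satRange)

#' @rdname GlobalResult-class
#' @param x a `GlobalResult`.
setMethod("peakHue", "GlobalResult", function(x) x@peakHue)

#' @rdname GlobalResult-class
#' @param object a `GlobalResult`.
setMethod("show", "GlobalResult", function(object) {
    d <- dim(object@mask)
    fg <- sum(object@mask == 255L)
    cat(sprintf("GlobalResult %d x %d\n", d[1], d[2]))
    cat(sprintf("  hue range [%d, %d] (peak %d); sat range [%d, %d]\n",
                object@hueRange@low, object@hueRange@high, object@peakHue,
                object@satRange@low, object@satRange@high))
    cat(sprintf("  foreground: %d px (%.1f%%)\n", fg, 100 * fg / length(object@mask)))
    invisible(NULL)
})
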