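## Color-space conversion and histogram/PMF construction.

#' Convert an 8-bit RGB image to HSV planes
#'
#' Standard RGB to HSV conversion with hue quantized to the half-degree
#' convention: `H = round(hue_degrees / 2)` in 0--179 (rounded half-up, with
#' 180 wrapping to 0), `S` and `V` scaled to 0--255. Pixels with zero
#' saturation (grays) have undefined hue and are assigned `H = 0`; such pixels
#' are classified through the saturation test anyway.
#'
#' @param image numeric `m x n x 3` array of RGB values in 0--255.
#' @return An [HSVImage-class].
#' @examples
#' px <- array(c(0, 255, 0), c(1, 1, 3))   # saturated green
#' hueChannel(rgbToHsv(px))                # 60
#' @export
rgbToHsv <- function(image) {
    if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
        stop("'image' must be an m x n x 3 array of 8-bit RGB values")
    if (anyNA(image) || min(image) < 0 || max(image) > 255)
        stop("RGB values must lie in [0, 255]")
    d <- dim(image)[1:2]
    hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                    as.vector(image[, , 2]),
                                    as.vector(image[, , 3])),
                              maxColorValue = 255)
    H <- as.integer(floor(hsv[1L, ] * 180 + 0.5))  # round half-up
    H[H >= 180L] <- H[H >= 180L] - 180L
    S <- as.integer(floor(hsv[2L, ] * 255 + 0.5))
    V <- as.integer(floor(hsv[3L, ] * 255 + 0.5))
    hsvImage(matrix(H, d[1], d[2]), matrix(S, d[1], d[2]),
             matrix(V, d[1], d[2]))
}

#' Histogram of an integer-valued plane
#'
#' @param plane integer matrix or vector with values in `0 .. nbins - 1`
#'   (bins are the pixel values themselves).
#' @param nbins number of histogram bins: 180 for hue, 256 for saturation.
#' @return Integer vector of length `nbins`; element `i` counts pixels with
#'   value `i - 1`.
#' @examples
#' computeHistogram(c(0, 0, 1, 2), 4)
#' @export
computeHistogram <- function(plane, nbins) {
    v <- as.integer(plane)
    nbins <- as.integer(nbins)
    if (length(v) == 0L)
        stop("'plane' is empty")
    if (anyNA(v) || min(v) < 0L || max(v) >= nbins)
        stop("plane values must lie in [0, nbins - 1]")
    tabulate(v + 1L, nbins)
}

#' Probability mass function of a histogram
#'
#' @param hist non-negative counts vector with a positive sum.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' computePmf(c(2, 1, 1))
#' @export
computePmf <- function(hist) {
    n <- sum(hist)
    if (n <= 0)
        stop("cannot normalize an all-zero histogram")
    hist / n
}

#' PMF of an integer-valued plane or value multiset
#'
#' Convenience composition of [computeHistogram()] and [computePmf()].
#'
#' @inheritParams computeHistogram
#' @return Numeric PMF of length `nbins`.
#' @export
channelPmf <- function(plane, nbins)
    computePmf(computeHistogram(plane, nbins))

#' Read an 8-bit color image
#'
#' Reads PNG/JPEG/TIFF through EBImage and returns a row-major
#' `m x n x 3` array of integer RGB values in 0--255. An alpha channel, if
#' present, is dropped with a warning; grayscale input is an error.
#'
#' @param path path to an image file.
#' @return Numeric `m x n x 3` array (rows = image height).
#' @export
readColorImage <- function(path) {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    if (length(dim(a)) != 3L)
        stop("expected a 3-channel color image: ", path)
    if (dim(a)[3] == 4L) {
        warning("dropping alpha channel: ", path)
        a <- a[, , 1:3, drop = FALSE]
    }
    if (dim(a)[3] != 3L)
        stop("expected a 3-channel color image: ", path)
    a <- aperm(a, c(2L, 1L, 3L))  # EBImage stores (x, y); we use (row, col)
    round(a * 255)
}

## internal: validate a {0,255} binary mask
.assertMask <- function(mask, what = "mask") {
    if (!is.matrix(mask))
        stop("'", what, "' must be a matrix")
    if (!all(mask == 0L | mask == 255L))
        stop("'", what, "' must contain only the levels 0 and 255")
    invisible(TRUE)
}
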