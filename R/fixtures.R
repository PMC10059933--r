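## Deterministic synthetic fixtures: board-like and lesion-like images with
## exact ground-truth masks, assembled in HSV space.

#' Convert integer HSV planes to an 8-bit RGB array
#'
#' Inverse of the half-degree hue convention used by [rgbToHsv()]: hue in
#' 0--179 (half degrees), saturation and value in 0--255. Output channels are
#' rounded to integers in 0--255.
#'
#' @param H,S,V integer matrices of identical dimensions.
#' @return Numeric `m x n x 3` RGB array.
#' @export
hsvPlanesToRgb <- function(H, S, V) {
    d <- dim(H)
    h <- (as.vector(H) * 2) / 60       # sector coordinate in [0, 6)
    s <- as.vector(S) / 255
    v <- as.vector(V) / 255
    i <- floor(h) %% 6
    f <- h - floor(h)
    p <- v * (1 - s)
    q <- v * (1 - f * s)
    t <- v * (1 - (1 - f) * s)
    r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
    g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
    b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
    out <- array(0, c(d[1], d[2], 3))
    out[, , 1] <- matrix(floor(r * 255 + 0.5), d[1], d[2])
    out[, , 2] <- matrix(floor(g * 255 + 0.5), d[1], d[2])
    out[, , 3] <- matrix(floor(b * 255 + 0.5), d[1], d[2])
    out
}

#' Describe a rectangular or disc foreground component
#'
#' @param shape `"rect"` or `"disc"`.
#' @param row,col 1-based position: top-left corner for rectangles, center for
#'   discs.
#' @param height,width rectangle extent in pixels (rectangles only).
#' @param radius disc radius in pixels (discs only).
#' @param hue,sat component chromaticity (hue bin 0--179, saturation 0--255).
#' @param confuser set `TRUE` to allow a hue within the background band margin
#'   (a deliberate confuser; otherwise such a component is a spec error).
#' @return A component description list for [fixtureSpec()].
#' @export
component <- function(shape = c("rect", "disc"), row, col,
                      height = NULL, width = NULL, radius = NULL,
                      hue, sat, confuser = FALSE) {
    shape <- match.arg(shape)
    list(shape = shape, row = as.integer(row), col = as.integer(col),
         height = if (!is.null(height)) as.integer(height),
         width = if (!is.null(width)) as.integer(width),
         radius = if (!is.null(radius)) as.integer(radius),
         hue = as.integer(hue), sat = as.integer(sat),
         confuser = isTRUE(confuser))
}

#' Specify a synthetic fixture
#'
#' Fixtures are assembled in HSV space: background hue and saturation are
#' sampled uniformly from the given bands (or from an explicit hue value set
#' for wrap-around backgrounds), components overwrite their footprints, an
#' optional shadow region shifts hue/saturation, per-channel Gaussian noise is
#' added, and the planes are converted to RGB for storage. The ground-truth
#' mask marks component pixels 255 by construction.
#'
#' @param width,height canvas size in pixels.
#' @param backgroundHue length-2 inclusive hue band (bins 0--179).
#' @param backgroundSat length-2 inclusive saturation band (0--255).
#' @param backgroundHueValues optional integer vector of allowed background
#'   hues, overriding `backgroundHue` (used for wrap-around red backgrounds).
#' @param components list of [component()] descriptions.
#' @param shadow optional `list(rows = c(r1, r2), cols = c(c1, c2),
#'   hueShift = , satShift = )`: all pixels in the rectangle get the shifts
#'   (before noise), emulating a shadow or illumination tint.
#' @param valueField `"constant"` or `"gradient"` (linear left-to-right ramp
#'   from 120 to 230).
#' @param valueLevel V plane level for `valueField = "constant"`.
#' @param noiseSd standard deviation of the per-channel Gaussian noise in
#'   bin/level units (rounded, clipped to the channel range).
#' @param seed integer PRNG seed; identical spec + seed gives identical
#'   fixtures.
#' @return A spec list for [makeFixture()].
#' @export
fixtureSpec <- function(width = 256L, height = 256L,
                        backgroundHue = c(72L, 93L),
                        backgroundSat = c(137L, 255L),
                        backgroundHueValues = NULL,
                        components = list(),
                        shadow = NULL,
                        valueField = c("constant", "gradient"),
                        valueLevel = 200L,
                        noiseSd = 1.5,
                        seed = 1L) {
    list(width = as.integer(width), height = as.integer(height),
         backgroundHue = as.integer(backgroundHue),
         backgroundSat = as.integer(backgroundSat),
         backgroundHueValues =
             if (!is.null(backgroundHueValues)) as.integer(backgroundHueValues),
         components = components, shadow = shadow,
         valueField = match.arg(valueField),
         valueLevel = as.integer(valueLevel),
         noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

## pixel margin (in hue bins) a non-confuser component hue must keep from the
## background hue population
.hueMargin <- 8L

.componentPixels <- function(comp, m, n) {
    if (comp$shape == "rect") {
        r2 <- comp$row + comp$height - 1L
        c2 <- comp$col + comp$width - 1L
        if (comp$row < 1L || comp$col < 1L || r2 > m || c2 > n)
            stop("component rectangle extends outside the canvas")
        as.matrix(expand.grid(row = comp$row:r2, col = comp$col:c2))
    } else {
        if (comp$row - comp$radius < 1L || comp$row + comp$radius > m ||
            comp$col - comp$radius < 1L || comp$col + comp$radius > n)
            stop("component disc extends outside the canvas")
        g <- expand.grid(row = (comp$row - comp$radius):(comp$row + comp$radius),
                         col = (comp$col - comp$radius):(comp$col + comp$radius))
        keep <- (g$row - comp$row)^2 + (g$col - comp$col)^2 <= comp$radius^2
        as.matrix(g[keep, ])
    }
}

#' Generate a synthetic image and its ground-truth mask
#'
#' @param spec a [fixtureSpec()].
#' @return `list(image = RGB array, hsv = HSVImage (pre-conversion planes),
#'   gt = binary mask, spec = spec)`.
#' @examples
#' fx <- makeFixture(boardFixtureSpec(seed = 3))
#' sum(fx$gt == 255)
#' @export
makeFixture <- function(spec) {
    set.seed(spec$seed)
    m <- spec$height
    n <- spec$width
    bgHues <- if (!is.null(spec$backgroundHueValues)) spec$backgroundHueValues
              else spec$backgroundHue[1]:spec$backgroundHue[2]
    H <- matrix(sample(bgHues, m * n, replace = TRUE), m, n)
    S <- matrix(sample(spec$backgroundSat[1]:spec$backgroundSat[2],
                       m * n, replace = TRUE), m, n)
    V <- if (spec$valueField == "constant") {
        matrix(spec$valueLevel, m, n)
    } else {
        matrix(rep(round(seq(120, 230, length.out = n)), each = m), m, n)
    }
    gt <- matrix(0L, m, n)
    for (comp in spec$components) {
        if (!comp$confuser && min(abs(comp$hue - bgHues)) < .hueMargin)
            stop("component hue ", comp$hue, " is within ", .hueMargin,
                 " bins of the background hues; flag it as a confuser ",
                 "if that is intended")
        px <- .componentPixels(comp, m, n)
        H[px] <- comp$hue
        S[px] <- comp$sat
        gt[px] <- 255L
    }
    if (!is.null(spec$shadow)) {
        sh <- spec$shadow
        rows <- sh$rows[1]:sh$rows[2]
        cols <- sh$cols[1]:sh$cols[2]
        H[rows, cols] <- H[rows, cols] + sh$hueShift
        S[rows, cols] <- S[rows, cols] + sh$satShift
    }
    clip <- function(x, hi) pmin(pmax(x, 0L), hi)
    if (spec$noiseSd > 0) {
        H <- H + as.integer(round(stats::rnorm(m * n, 0, spec$noiseSd)))
        S <- S + as.integer(round(stats::rnorm(m * n, 0, spec$noiseSd)))
        V <- V + as.integer(round(stats::rnorm(m * n, 0, spec$noiseSd)))
    }
    H <- clip(H, 179L)
    S <- clip(S, 255L)
    V <- clip(V, 255L)
    hsv <- hsvImage(H, S, V)
    list(image = hsvPlanesToRgb(H, S, V), hsv = hsv, gt = gt, spec = spec)
}

#' Default board fixture spec
#'
#' A board-like image: background hue band 72--93 with saturation 137--255
#' (the histogram geography of a green board whose peak hue sits near 83) and
#' six square components, three at hue 25 and three at hue 123, each 36 x 36
#' pixels.
#'
#' @param seed PRNG seed.
#' @param noiseSd per-channel noise level.
#' @return A [fixtureSpec()].
#' @export
boardFixtureSpec <- function(seed = 1L, noiseSd = 1.5) {
    comps <- list()
    pos <- cbind(row = c(30L, 30L, 110L, 110L, 190L, 190L),
                 col = c(30L, 150L, 60L, 180L, 30L, 150L))
    hues <- c(25L, 123L, 25L, 123L, 25L, 123L)
    for (k in 1:6)
        comps[[k]] <- component("rect", pos[k, 1], pos[k, 2],
                                height = 36L, width = 36L,
                                hue = hues[k], sat = 200L)
    fixtureSpec(components = comps, seed = seed, noiseSd = noiseSd)
}

#' Fixed catalogue of named fixtures
#'
#' Deterministic suite covering the histogram classes the method addresses:
#' \describe{
#'   \item{cleanBoard}{the default board (multimodal hue PMF).}
#'   \item{shadowBoard}{a board with a shadow band whose hue shift pushes part
#'     of the background outside the global ranges but inside the local
#'     confinement windows -- the stage-2 recovery target.}
#'   \item{speckBoard}{the board plus 4 x 4 specks whose bounding boxes stay
#'     below the 500 px blob floor, so stage 2 drops them.}
#'   \item{lesion}{a lesion-like disc on a skin-toned background (bimodal hue
#'     PMF); pair with `thresholdParams("skin")`.}
#'   \item{lowSat}{a near-gray degenerate image (unimodal PMF), no
#'     foreground.}
#'   \item{redWrap}{a red background straddling the 0/179 hue wrap -- the
#'     documented hue-wrap limitation: only one side of the wrap can be
#'     selected.}
#' }
#'
#' @param seed integer master seed (each fixture derives its own from it).
#' @return Named list of [makeFixture()] results.
#' @export
makeFixtureSuite <- function(seed = 1L) {
    seed <- as.integer(seed)
    board <- boardFixtureSpec(seed = seed)

    shadowComps <- list(
        component("rect", 30L, 20L, height = 36L, width = 36L,
                  hue = 25L, sat = 200L),
        component("rect", 120L, 60L, height = 36L, width = 36L,
                  hue = 123L, sat = 200L),
        component("rect", 200L, 20L, height = 36L, width = 36L,
                  hue = 25L, sat = 200L))
    shadowSpec <- fixtureSpec(
        backgroundHue = c(78L, 88L), backgroundSat = c(150L, 230L),
        components = shadowComps,
        shadow = list(rows = c(20L, 236L), cols = c(170L, 245L),
                      hueShift = 10L, satShift = -10L),
        seed = seed + 1L)

    speckSpec <- boardFixtureSpec(seed = seed + 2L)
    speckPos <- cbind(row = c(70L, 70L, 160L, 160L),
                      col = c(110L, 230L, 120L, 240L))
    for (k in 1:4)
        speckSpec$components[[6L + k]] <-
            component("rect", speckPos[k, 1], speckPos[k, 2],
                      height = 4L, width = 4L, hue = 25L, sat = 200L)

    lesionSpec <- fixtureSpec(
        backgroundHue = c(22L, 28L), backgroundSat = c(70L, 110L),
        components = list(component("disc", 128L, 128L, radius = 70L,
                                    hue = 5L, sat = 170L)),
        valueLevel = 220L, seed = seed + 3L)

    ## near-gray pixels: hue is undefined at zero saturation and set to 0
    lowSatSpec <- fixtureSpec(
        backgroundHue = c(0L, 0L), backgroundSat = c(0L, 8L),
        valueLevel = 180L, seed = seed + 4L)

    redWrapSpec <- fixtureSpec(
        backgroundHueValues = c(0:4, 175:179), backgroundSat = c(150L, 230L),
        components = list(
            component("rect", 40L, 40L, height = 40L, width = 40L,
                      hue = 90L, sat = 200L),
            component("rect", 160L, 160L, height = 40L, width = 40L,
                      hue = 90L, sat = 200L)),
        noiseSd = 0, seed = seed + 5L)

    list(cleanBoard = makeFixture(board),
         shadowBoard = makeFixture(shadowSpec),
         speckBoard = makeFixture(speckSpec),
         lesion = makeFixture(lesionSpec),
         lowSat = makeFixture(lowSatSpec),
         redWrap = makeFixture(redWrapSpec))
}

#' Count well-separated modes of a smoothed PMF
#'
#' A mode is a maximal run of consecutive bins whose smoothed PMF stays at or
#' above `heightFraction` of the PMF maximum; runs separated by bins below the
#' level count separately. This is robust to sampling wiggle on plateaus,
#' unlike strict local-maximum counting.
#'
#' @param pmf numeric (smoothed) PMF.
#' @param heightFraction level as a fraction of `max(pmf)` (default 0.1).
#' @return Integer mode count.
#' @export
countPmfModes <- function(pmf, heightFraction = 0.1) {
    above <- pmf >= heightFraction * max(pmf)
    r <- rle(above)
    sum(r$values)
}

#' Write a fixture suite to disk
#'
#' Writes `<name>.png` (image) and `<name>.gt.png` (mask) per fixture plus a
#' plain-text `manifest.txt` with name, seed and canvas size.
#'
#' @param suite result of [makeFixtureSuite()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeFixtures <- function(suite, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    lines <- character(0)
    for (nm in names(suite)) {
        fx <- suite[[nm]]
        EBImage::writeImage(EBImage::Image(aperm(fx$image / 255, c(2, 1, 3)),
                                           colormode = "Color"),
                            file.path(dir, paste0(nm, ".png")))
        writeMask(fx$gt, file.path(dir, paste0(nm, ".gt.png")))
        lines <- c(lines,
                   sprintf("name=%s seed=%d width=%d height=%d", nm,
                           fx$spec$seed, fx$spec$width, fx$spec$height))
    }
    manifest <- file.path(dir, "manifest.txt")
    writeLines(lines, manifest)
    invisible(manifest)
}
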