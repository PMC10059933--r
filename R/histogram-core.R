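## Histogram machinery: smoothing, the gradient/area nomination rule,
## max-continuous-range selection and saturation shortlisting.
##
## Bin arguments and return values are 0-based throughout (hue bins 0..179,
## saturation bins 0..255): bins are pixel values, not R indices.

#' Moving-average smoothing of a PMF
#'
#' Each bin is replaced by the mean of the PMF over a window of `windowSize`
#' bins centered on it, truncated at the histogram boundaries (the divisor is
#' the actual window length, so boundary bins average fewer values).
#'
#' @param pmf numeric PMF vector.
#' @param windowSize odd integer window width (default 5).
#' @return Numeric vector of the same length.
#' @examples
#' p <- c(0, 0, 1, 0, 0, 0)
#' smoothenPmf(p, 5)
#' @export
smoothenPmf <- function(pmf, windowSize = 5L) {
    windowSize <- as.integer(windowSize)
    if (windowSize < 1L || windowSize %% 2L == 0L)
        stop("'windowSize' must be an odd integer >= 1")
    K <- length(pmf)
    half <- windowSize %/% 2L
    out <- numeric(K)
    for (i in seq_len(K)) {
        lo <- max(1L, i - half)
        hi <- min(K, i + half)
        out[i] <- sum(pmf[lo:hi]) / (hi - lo + 1L)
    }
    out
}

#' Windowed mean area of a smoothed PMF
#'
#' Mean of the smoothed PMF over the boundary-clipped window centered at bin
#' `h` -- the "area" criterion of the nomination rule.
#'
#' @param pmf numeric (smoothed) PMF.
#' @param h 0-based bin at the window center.
#' @param windowSize odd integer window width.
#' @return A single numeric value.
#' @export
avgArea <- function(pmf, h, windowSize = 5L) {
    K <- length(pmf)
    half <- as.integer(windowSize) %/% 2L
    lo <- max(0L, h - half)
    hi <- min(K - 1L, h + half)
    sum(pmf[(lo:hi) + 1L]) / (hi - lo + 1L)
}

#' Windowed mean gradient of a smoothed PMF
#'
#' Mean of `atan(|pmf[i] - pmf[i+1]|)` over the boundary-clipped window
#' centered at bin `h`. When the window reaches the last histogram bin the
#' final forward difference does not exist and is omitted (the divisor then
#' shrinks by one); a single-bin window at the boundary has gradient 0.
#'
#' @inheritParams avgArea
#' @return A single numeric value.
#' @export
avgGradient <- function(pmf, h, windowSize = 5L) {
    K <- length(pmf)
    half <- as.integer(windowSize) %/% 2L
    lo <- max(0L, h - half)
    hi <- min(K - 1L, h + half)
    if (hi < K - 1L) {
        i <- lo:hi
        sum(atan(abs(pmf[i + 1L] - pmf[i + 2L]))) / (hi - lo + 1L)
    } else if (hi > lo) {
        i <- lo:(hi - 1L)
        sum(atan(abs(pmf[i + 1L] - pmf[i + 2L]))) / (hi - lo)
    } else {
        0
    }
}

#' Nominate candidate background bins of a smoothed PMF
#'
#' Scans bins in ascending order; a bin that is already nominated is not
#' re-used as a window anchor. When the window centered at the anchor
#' qualifies by either criterion (`avgGradient >= cutoffGradient` or
#' `avgArea >= cutoffArea`; both comparisons are inclusive) the entire clipped
#' window joins the nominated set.
#'
#' @param pmf smoothed PMF (callers smooth first).
#' @param cutoffGradient gradient cutoff (default 0.001).
#' @param cutoffArea area cutoff (default `1/180`).
#' @param windowSize odd integer window width (default 5).
#' @return Sorted integer vector of 0-based nominated bins (possibly empty).
#' @examples
#' p <- smoothenPmf(channelPmf(rep(83L, 100), 180))
#' nominatedRange(p)
#' @export
nominatedRange <- function(pmf, cutoffGradient = 0.001,
                           cutoffArea = 1 / 180, windowSize = 5L) {
    K <- length(pmf)
    half <- as.integer(windowSize) %/% 2L
    nominated <- logical(K)
    for (h in 0:(K - 1L)) {
        if (nominated[h + 1L])
            next
        if (avgGradient(pmf, h, windowSize) >= cutoffGradient ||
            avgArea(pmf, h, windowSize) >= cutoffArea) {
            lo <- max(0L, h - half)
            hi <- min(K - 1L, h + half)
            nominated[(lo:hi) + 1L] <- TRUE
        }
    }
    which(nominated) - 1L
}

#' Largest continuous run of nominated bins
#'
#' Sorts the nominated bins, partitions them into runs in which every gap
#' between consecutive bins is at most `limit`, and returns the run with the
#' most members. Ties are broken toward the run with the smallest low bin.
#'
#' @param bins integer vector of nominated bins (any order; duplicates
#'   ignored).
#' @param limit maximum allowed gap between consecutive bins within a run
#'   (inclusive comparison), `>= 1`.
#' @return Sorted integer vector: the selected run (empty for empty input).
#' @examples
#' maxContinuousRange(c(30:55, 75:90, 137:255), limit = 4)  # 137..255
#' @export
maxContinuousRange <- function(bins, limit) {
    limit <- as.integer(limit)
    if (limit < 1L)
        stop("'limit' must be >= 1")
    bins <- sort(unique(as.integer(bins)))
    if (length(bins) == 0L)
        return(integer(0))
    grp <- cumsum(c(1L, diff(bins) > limit))
    runs <- split(bins, grp)
    sizes <- lengths(runs)
    runs[[which.max(sizes)]]  # first maximum = smallest low bin
}

#' Largest continuous run containing a given peak bin
#'
#' Repeatedly extracts the largest run with [maxContinuousRange()]; if it does
#' not contain `peak`, that run is removed from the candidate set and the
#' selection is retried. Used for the global hue range, which must contain the
#' peak of the smoothed hue PMF.
#'
#' @inheritParams maxContinuousRange
#' @param peak 0-based bin that the returned run must contain; an error is
#'   raised if `peak` is not among `bins` (a pathological histogram).
#' @return Sorted integer vector: the first extracted run containing `peak`.
#' @examples
#' maxContinuousRangeWithPeak(c(18:35, 72:93, 116:130), peak = 83, limit = 2)
#' @export
maxContinuousRangeWithPeak <- function(bins, peak, limit) {
    cand <- sort(unique(as.integer(bins)))
    peak <- as.integer(peak)
    if (!(peak %in% cand))
        stop("peak bin ", peak, " is not in the nominated set; ",
             "the histogram is too degenerate for range selection")
    repeat {
        run <- maxContinuousRange(cand, limit)
        if (peak %in% run)
            return(run)
        cand <- setdiff(cand, run)
    }
}

#' Saturation values of pixels within a hue range
#'
#' Collects the multiset of saturation values at pixels whose hue lies in
#' `[hueLow, hueHigh]` inclusive (the shortlisting step feeding the global
#' saturation PMF).
#'
#' @param hueLow,hueHigh inclusive 0-based hue bounds.
#' @param H,S integer hue and saturation planes of identical dimensions.
#' @return Integer vector of saturation values (possibly empty).
#' @export
findSatValues <- function(hueLow, hueHigh, H, S) {
    if (!identical(dim(H), dim(S)))
        stop("'H' and 'S' must have identical dimensions")
    as.integer(S[H >= hueLow & H <= hueHigh])
}
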