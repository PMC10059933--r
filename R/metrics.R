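## Evaluation metrics over ground-truth vs. thresholded binary masks.
## Foreground = 255, background = 0 in both masks.

#' Pixel-level confusion counts
#'
#' @param gt,t binary masks (matrices over \{0, 255\}) of identical
#'   dimensions; `gt` is the ground truth.
#' @return Named list with `tp`, `fp`, `tn`, `fn` (foreground = positive).
#' @export
confusionCounts <- function(gt, t) {
    .assertMask(gt, "gt")
    .assertMask(t, "t")
    if (!identical(dim(gt), dim(t)))
        stop("'gt' and 't' must have identical dimensions")
    gtF <- gt == 255L
    tF <- t == 255L
    list(tp = sum(gtF & tF), fp = sum(!gtF & tF),
         tn = sum(!gtF & !tF), fn = sum(gtF & !tF))
}

#' Dice similarity index
#'
#' `2 |GT intersect T| / (|GT| + |T|)` over foreground pixels, equivalently
#' `2 tp / (2 tp + fp + fn)`. Defined as 1 when both masks have no foreground.
#'
#' @inheritParams confusionCounts
#' @return Numeric in \[0, 1\].
#' @export
diceIndex <- function(gt, t) {
    cc <- confusionCounts(gt, t)
    denom <- 2 * cc$tp + cc$fp + cc$fn
    if (denom == 0) 1 else 2 * cc$tp / denom
}

#' Matthews correlation coefficient
#'
#' Pearson phi correlation of the pixel-level confusion counts,
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; 0 when any factor
#' of the denominator is 0 (standard convention).
#'
#' @inheritParams confusionCounts
#' @return Numeric in \[-1, 1\].
#' @export
matthewsCC <- function(gt, t) {
    cc <- lapply(confusionCounts(gt, t), as.numeric)
    denom <- (cc$tp + cc$fp) * (cc$tp + cc$fn) *
             (cc$tn + cc$fp) * (cc$tn + cc$fn)
    if (denom == 0) 0 else (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(denom)
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' MSE is the per-pixel mean of squared intensity differences; PSNR is
#' `10 * log10(255^2 / MSE)` dB (peak intensity 255). Identical masks have
#' MSE 0 and PSNR `Inf`.
#'
#' @inheritParams confusionCounts
#' @return Named list with `mse` and `psnr` (dB).
#' @export
msePsnr <- function(gt, t) {
    .assertMask(gt, "gt")
    .assertMask(t, "t")
    if (!identical(dim(gt), dim(t)))
        stop("'gt' and 't' must have identical dimensions")
    mse <- mean((as.numeric(gt) - as.numeric(t))^2)
    psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
    list(mse = mse, psnr = psnr)
}

#' Full evaluation of one mask pair
#'
#' @inheritParams confusionCounts
#' @return A one-row `data.frame` with columns `dsi`, `mcc`, `mse`, `psnr`.
#' @export
evaluateMask <- function(gt, t) {
    mp <- msePsnr(gt, t)
    data.frame(dsi = diceIndex(gt, t), mcc = matthewsCC(gt, t),
               mse = mp$mse, psnr = mp$psnr)
}

#' Batch evaluation of paired masks
#'
#' @param gtList,maskList named lists of binary masks, matched by name.
#' @return A `data.frame` with one row per pair (column `name`) followed by
#'   `mean` and `sd` aggregate rows (PSNR aggregates skip infinite values).
#' @export
evaluateBatch <- function(gtList, maskList) {
    common <- intersect(names(gtList), names(maskList))
    if (length(common) == 0L)
        stop("no mask pairs share a name")
    rows <- lapply(common, function(nm)
        cbind(name = nm, evaluateMask(gtList[[nm]], maskList[[nm]])))
    perImage <- do.call(rbind, rows)
    num <- perImage[, c("dsi", "mcc", "mse", "psnr")]
    finPsnr <- num$psnr[is.finite(num$psnr)]
    agg <- data.frame(
        name = c("mean", "sd"),
        dsi = c(mean(num$dsi), stats::sd(num$dsi)),
        mcc = c(mean(num$mcc), stats::sd(num$mcc)),
        mse = c(mean(num$mse), stats::sd(num$mse)),
        psnr = c(mean(finPsnr), stats::sd(finPsnr)))
    rbind(perImage, agg)
}
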