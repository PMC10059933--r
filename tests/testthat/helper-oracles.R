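# Literal, unoptimized transcriptions used as independent oracles.

# nomination rule: explicit loops, recomputing window sums in place
oracleNominatedRange <- function(pmf, cutoffGradient = 0.001,
                                 cutoffArea = 1 / 180, windowSize = 5) {
  K <- length(pmf)
  half <- windowSize %/% 2
  nominated <- c()
  for (h in 0:(K - 1)) {
    if (h %in% nominated) next
    lo <- max(0, h - half)
    hi <- min(K - 1, h + half)
    area <- 0
    for (i in lo:hi) area <- area + pmf[i + 1]
    area <- area / (hi - lo + 1)
    grad <- 0
    if (hi < K - 1) {
      for (i in lo:hi) grad <- grad + atan(abs(pmf[i + 1] - pmf[i + 2]))
      grad <- grad / (hi - lo + 1)
    } else if (hi > lo) {
      for (i in lo:(hi - 1)) grad <- grad + atan(abs(pmf[i + 1] - pmf[i + 2]))
      grad <- grad / (hi - lo)
    }
    if (grad >= cutoffGradient || area >= cutoffArea)
      nominated <- union(nominated, lo:hi)
  }
  sort(nominated)
}

# largest gap-bounded run by exhaustive slice enumeration over sorted bins
oracleMaxRun <- function(bins, limit) {
  bins <- sort(unique(bins))
  n <- length(bins)
  if (n == 0) return(integer(0))
  best <- integer(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      slice <- bins[i:j]
      ok <- all(diff(slice) <= limit)
      if (ok && (length(slice) > length(best)))
        best <- slice
    }
  }
  best
}

# per-pixel confusion tally
oracleConfusion <- function(gt, t) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      if (gt[i, j] == 255 && t[i, j] == 255) tp <- tp + 1
      else if (gt[i, j] == 0 && t[i, j] == 255) fp <- fp + 1
      else if (gt[i, j] == 0 && t[i, j] == 0) tn <- tn + 1
      else fn <- fn + 1
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# per-pixel threshold classification
oracleThreshold <- function(H, S, hLow, hHigh, sLow, sHigh) {
  out <- matrix(255L, nrow(H), ncol(H))
  for (i in seq_len(nrow(H))) {
    for (j in seq_len(ncol(H))) {
      if (H[i, j] >= hLow && H[i, j] <= hHigh &&
          S[i, j] >= sLow && S[i, j] <= sHigh)
        out[i, j] <- 0L
    }
  }
  out
}

# recursive flood fill (8-connectivity) component counter
oracleComponentCount <- function(mask) {
  fg <- mask == 255
  seen <- matrix(FALSE, nrow(fg), ncol(fg))
  m <- nrow(fg); n <- ncol(fg)
  count <- 0
  for (i0 in seq_len(m)) {
    for (j0 in seq_len(n)) {
      if (fg[i0, j0] && !seen[i0, j0]) {
        count <- count + 1
        stack <- list(c(i0, j0))
        seen[i0, j0] <- TRUE
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (di in -1:1) for (dj in -1:1) {
            i <- p[1] + di; j <- p[2] + dj
            if (i >= 1 && i <= m && j >= 1 && j <= n &&
                fg[i, j] && !seen[i, j]) {
              seen[i, j] <- TRUE
              stack[[length(stack) + 1]] <- c(i, j)
            }
          }
        }
      }
    }
  }
  count
}

# random sparse PMF with localized bumps and flat zero regions
randomPmf <- function(K = 180) {
  p <- numeric(K)
  nBumps <- sample(1:4, 1)
  for (b in seq_len(nBumps)) {
    center <- sample(0:(K - 1), 1)
    width <- sample(2:15, 1)
    lo <- max(0, center - width); hi <- min(K - 1, center + width)
    p[(lo:hi) + 1] <- p[(lo:hi) + 1] + stats::runif(hi - lo + 1)
  }
  if (sum(p) == 0) p[sample(K, 1)] <- 1
  p / sum(p)
}

randomMask <- function(m = 15, n = 20, pFg = 0.4) {
  matrix(ifelse(stats::runif(m * n) < pFg, 255L, 0L), m, n)
}
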