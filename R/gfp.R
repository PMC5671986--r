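# Global field power (GFP), peak detection, and extraction of
# z-normalized peak topographies for clustering.

#' Compute the global field power series
#'
#' The GFP at a timepoint is the spatial (population) standard deviation of
#' the potential across channels,
#' \deqn{GFP(t) = \sqrt{\frac{1}{C}\sum_{i=1}^{C} (v_i(t) - \bar v(t))^2},}
#' a reference-free measure: adding any per-timepoint constant to all
#' channels leaves it unchanged. Local maxima of the GFP are the points of
#' highest topographic signal-to-noise ratio and are where template maps
#' are estimated.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return numeric vector of nonnegative GFP values, one per timepoint,
#'   with attribute `"sfreq"`.
#' @export
computeGFP <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  X <- rec@data
  if (nrow(X) < 2L) stop("GFP requires at least 2 channels")
  mu <- colMeans(X)
  g <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  attr(g, "sfreq") <- rec@sfreq
  g
}

#' Detect peaks of a GFP series
#'
#' In `"local_maxima"` mode an interior index t is a peak when
#' `values[t] > values[t-1]` and `values[t] > values[t+1]`; a maximal
#' plateau flanked by strictly smaller neighbours contributes its first
#' index. Endpoints are never peaks. In `"threshold"` mode, local maxima
#' must additionally reach a threshold given either in absolute GFP units
#' or as a quantile of the series.
#'
#' @param gfp numeric GFP series (from [computeGFP()]).
#' @param mode `"local_maxima"` (default) or `"threshold"`.
#' @param threshold for threshold mode: absolute GFP value, or if
#'   `thresholdType = "quantile"`, a probability in \[0, 1\].
#' @param thresholdType `"absolute"` or `"quantile"`.
#' @return sorted integer vector of peak indices with attribute `"mode"`.
#' @export
detectGFPPeaks <- function(gfp, mode = c("local_maxima", "threshold"),
                           threshold = NULL,
                           thresholdType = c("absolute", "quantile")) {
  mode <- match.arg(mode)
  thresholdType <- match.arg(thresholdType)
  v <- as.numeric(gfp)
  n <- length(v)
  if (n < 3L) stop("peak detection requires a series of length >= 3")

  # plateau-aware scan: a candidate runs from the start of a constant run;
  # it is a peak if the run rose into and falls out of the plateau
  peaks <- integer(0L)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  if (mode == "threshold") {
    if (is.null(threshold)) {
      stop("threshold mode requires a threshold")
    }
    thr <- if (thresholdType == "quantile") {
      stats::quantile(v, probs = threshold, names = FALSE)
    } else threshold
    peaks <- peaks[v[peaks] >= thr]
  }
  structure(peaks, mode = mode)
}

#' Extract z-normalized topographies at GFP peaks
#'
#' Builds the clustering input matrix: one row per peak, each row the
#' instantaneous scalp map z-normalized across channels (mean 0, sd 1).
#' Peaks whose map has zero spatial variance cannot be normalized and are
#' dropped with a warning.
#'
#' @param rec an [EEGRecording-class].
#' @param peaks integer peak indices (from [detectGFPPeaks()]).
#' @return N x C matrix with attributes `"sourceIndices"` (the surviving
#'   peak indices), `"subjectID"` and `"condition"`.
#' @export
extractPeakMaps <- function(rec, peaks) {
  stopifnot(is(rec, "EEGRecording"))
  peaks <- as.integer(peaks)
  if (length(peaks) == 0L) stop("no peaks supplied")
  if (any(peaks < 1L) || any(peaks > ncol(rec@data))) {
    stop("peak indices out of range")
  }
  M <- t(rec@data[, peaks, drop = FALSE])
  Z <- zNormalizeRows(M)
  degenerate <- attr(Z, "degenerate")
  if (any(degenerate)) {
    warning(sum(degenerate), " peak map(s) with zero spatial variance dropped")
    Z <- Z[!degenerate, , drop = FALSE]
    peaks <- peaks[!degenerate]
  }
  if (nrow(Z) == 0L) stop("all peak maps degenerate: empty output")
  attr(Z, "degenerate") <- NULL
  structure(Z, sourceIndices = peaks, subjectID = rec@subjectID,
            condition = rec@condition)
}
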