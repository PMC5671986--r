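# Uncertainty analyses over probabilistic state sequences: the ECDF of
# the MLE-label probability, per-subject summaries, and the subject-level
# GFP-versus-certainty regression.

#' ECDF of the maximum-likelihood-label probability
#'
#' Pools the per-timepoint MLE probabilities of one or more state
#' sequences (unlabeled/uniform-fallback timepoints excluded) and returns
#' the right-continuous empirical cumulative distribution function as
#' sorted (value, cumulative fraction) pairs. A curve lying above another
#' at a given probability means more timepoints were labeled with at most
#' that certainty, i.e. a less predictable condition.
#'
#' @param seqs a [StateSequence-class] or a list of them.
#' @return data.frame with columns `value` and `fraction` (reaching 1).
#' @export
mleEcdf <- function(seqs) {
  if (is(seqs, "StateSequence")) seqs <- list(seqs)
  vals <- unlist(lapply(seqs, function(s) s@mleProb[s@labeled]))
  if (!length(vals)) stop("no labeled timepoints: empty input")
  v <- sort(unique(vals))
  fraction <- cumsum(tabulate(match(sort(vals), v))) / length(vals)
  data.frame(value = v, fraction = fraction)
}

#' Evaluate an ECDF at a probe value
#'
#' @param ecdf data.frame from [mleEcdf()].
#' @param q probe value.
#' @return fraction of pooled values `<= q`.
#' @export
ecdfAt <- function(ecdf, q) {
  i <- findInterval(q, ecdf$value)
  if (i == 0L) 0 else ecdf$fraction[i]
}

#' Per-subject summary of GFP and labeling certainty
#'
#' Computes the subject's mean GFP over the whole recording and the mean
#' and variance of the MLE-label probability over labeled timepoints
#' (uniform-fallback timepoints excluded). These per-subject pairs feed
#' the GFP-certainty regression.
#'
#' @param rec the subject's [EEGRecording-class].
#' @param seq the [StateSequence-class] derived from `rec`.
#' @return data.frame row: `subjectID`, `condition`, `meanGFP`,
#'   `meanMLEProb`, `varMLEProb`, `nTimepoints`.
#' @export
summarizeSubject <- function(rec, seq) {
  stopifnot(is(rec, "EEGRecording"), is(seq, "StateSequence"))
  if (length(seq) != ncol(rec@data)) {
    stop("state sequence length does not match the recording")
  }
  p <- seq@mleProb[seq@labeled]
  if (!length(p)) stop("no labeled timepoints for subject ", rec@subjectID)
  data.frame(subjectID = rec@subjectID, condition = rec@condition,
             meanGFP = mean(computeGFP(rec)),
             meanMLEProb = mean(p),
             varMLEProb = if (length(p) > 1L) stats::var(p) else 0,
             nTimepoints = length(p),
             stringsAsFactors = FALSE)
}

#' Subject-level regression of labeling certainty on mean GFP
#'
#' Ordinary least squares with intercept relating each subject's mean
#' MLE-label probability to their mean GFP (orientation configurable);
#' the p-value is that of the slope's t statistic. Subjects with a mean
#' GFP above an optional cutoff can be excluded as outliers; exclusions
#' are reported in the fit.
#'
#' @param summaries data.frame of rows from [summarizeSubject()]
#'   (n >= 3, non-constant predictor).
#' @param orientation `"certainty_on_gfp"` (default; mean MLE probability
#'   regressed on mean GFP) or `"gfp_on_certainty"`.
#' @param gfpCutoff optional absolute mean-GFP value above which subjects
#'   are excluded.
#' @return list of class `gfpCertaintyGLM`: `slope`, `intercept`,
#'   `rSquared`, `pValue`, `n`, `orientation`, `excluded` (subject ids).
#' @export
gfpCertaintyGLM <- function(summaries,
                            orientation = c("certainty_on_gfp",
                                            "gfp_on_certainty"),
                            gfpCutoff = NULL) {
  orientation <- match.arg(orientation)
  df <- as.data.frame(summaries)
  excluded <- character(0L)
  if (!is.null(gfpCutoff)) {
    drop <- df$meanGFP > gfpCutoff
    excluded <- df$subjectID[drop]
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) < 3L) stop("need at least 3 subjects after exclusions")
  if (orientation == "certainty_on_gfp") {
    x <- df$meanGFP; yv <- df$meanMLEProb
  } else {
    x <- df$meanMLEProb; yv <- df$meanGFP
  }
  if (stats::sd(x) < 1e-300) stop("constant predictor: regression undefined")
  fit <- stats::lm(yv ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 rSquared = sm$r.squared,
                 pValue = unname(sm$coefficients[2L, 4L]),
                 n = nrow(df), orientation = orientation,
                 excluded = as.character(excluded)),
            class = "gfpCertaintyGLM")
}

#' @export
print.gfpCertaintyGLM <- function(x, ...) {
  cat(sprintf("GFP-certainty regression (%s): n = %d\n", x$orientation, x$n))
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 %.3f, p %.3g\n",
              x$slope, x$intercept, x$rSquared, x$pValue))
  if (length(x$excluded)) {
    cat("  excluded subjects:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
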