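# Template-map handling: polarity-duplicate merging, cross-model template
# correlation, optimal label alignment, and deterministic correlation
# backfitting of templates onto EEG timecourses.
#
# Microstate topographies are considered regardless of polarity: a map and
# its sign-flipped version are the same microstate. Plain K-means can
# therefore return two centroids that are near-perfect inversions of each
# other; these are detected by their strongly negative Pearson correlation
# and combined after clustering.

#' Merge polarity-inverted duplicate templates
#'
#' Scans the cluster centroids for pairs with Pearson correlation at or
#' below `-threshold` and merges each (most negative pair first): the
#' higher-index map is removed, its hard-label points reassigned to the
#' kept map, and, for fuzzy results, its membership column added into the
#' kept column. Repeats until no such pair remains (idempotent). Each
#' merge is recorded in the returned template set's merge log.
#'
#' @param result a [ClusterResult-class] with k >= 2.
#' @param threshold correlation magnitude in (0, 1] above which a negative
#'   pair counts as a polarity duplicate. Default 0.95: genuine inversions
#'   sit near -1, while distinct microstate maps correlate far more
#'   weakly.
#' @return list with elements `templates` (a [TemplateSet-class] of the
#'   merged, z-normalized maps) and `result` (the relabeled
#'   [ClusterResult-class] with contiguous labels 1..k').
#' @export
mergePolarityDuplicates <- function(result, threshold = 0.95) {
  stopifnot(is(result, "ClusterResult"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]")
  }
  centroids <- result@centroids
  if (nrow(centroids) < 2L) stop("merging requires at least 2 templates")
  U <- result@U
  ids <- seq_len(nrow(centroids))     # original ids, for the log
  log <- data.frame(kept = integer(), absorbed = integer(),
                    correlation = numeric())

  repeat {
    R <- rowCorMatrix(centroids, centroids)
    diag(R) <- 0
    R[upper.tri(R, diag = TRUE)] <- 0
    worst <- which(R == min(R), arr.ind = TRUE)[1L, ]
    rmin <- R[worst[1L], worst[2L]]
    if (rmin > -threshold) break
    i <- min(worst); j <- max(worst)
    log <- rbind(log, data.frame(kept = ids[i], absorbed = ids[j],
                                 correlation = rmin))
    U[, i] <- U[, i] + U[, j]
    U <- U[, -j, drop = FALSE]
    centroids <- centroids[-j, , drop = FALSE]
    ids <- ids[-j]
    if (nrow(centroids) < 2L) break
  }

  labels <- max.col(U, ties.method = "first")
  relabeled <- new("ClusterResult", centroids = centroids,
                   hardLabels = labels, U = U, objective = result@objective,
                   objectiveTrace = result@objectiveTrace,
                   replicateObjectives = result@replicateObjectives,
                   method = result@method, config = result@config)
  templates <- TemplateSet(centroids, labels = seq_len(nrow(centroids)),
                           method = result@method,
                           condition = if (!is.null(result@config$condition))
                             result@config$condition else "unknown",
                           configHash = configHash(result@config),
                           mergeLog = log)
  list(templates = templates, result = relabeled)
}

#' Correlate two template sets
#'
#' Pearson correlation between every map of `A` and every map of `B`
#' (maps as channel vectors, mean-centered). With
#' `polarityInvariant = TRUE` the absolute correlations are returned and
#' the signs recorded in the `"sign"` attribute.
#'
#' @param A,B [TemplateSet-class] objects with the same channel count.
#' @param polarityInvariant logical.
#' @return k_A x k_B correlation matrix.
#' @export
correlateTemplates <- function(A, B, polarityInvariant = FALSE) {
  stopifnot(is(A, "TemplateSet"), is(B, "TemplateSet"))
  if (ncol(A@maps) != ncol(B@maps)) {
    stop("channel count mismatch between template sets")
  }
  R <- rowCorMatrix(A@maps, B@maps)
  if (polarityInvariant) {
    structure(abs(R), sign = sign(R))
  } else R
}

#' Optimally align the labels of one template set onto another
#'
#' Finds the one-to-one assignment of B's maps onto A's maps maximizing
#' the total absolute correlation (exact assignment search), giving a
#' relabeling under which corresponding microstates carry the same label
#' across models. Sign flips needed to match polarity are reported.
#'
#' @param A reference [TemplateSet-class].
#' @param B [TemplateSet-class] to align; must have the same k as `A`.
#' @return list with `perm` (B's map index matched to each map of A),
#'   `signs` (polarity of each match), `matchedCor` (absolute correlation
#'   per matched pair) and `total`.
#' @export
alignTemplates <- function(A, B) {
  stopifnot(is(A, "TemplateSet"), is(B, "TemplateSet"))
  if (nrow(A@maps) != nrow(B@maps)) {
    stop("template sets have different k; cannot align")
  }
  R <- rowCorMatrix(A@maps, B@maps)
  fit <- solveAssignment(abs(R))
  perm <- fit$perm
  signs <- sign(R[cbind(seq_along(perm), perm)])
  list(perm = perm, signs = signs,
       matchedCor = abs(R[cbind(seq_along(perm), perm)]),
       total = fit$value)
}

#' Apply a template alignment to a template set (and its cluster result)
#'
#' Reorders (and sign-flips) the maps of `B` so that map j corresponds to
#' map j of the alignment's reference; relabels the hard labels and
#' membership columns of an accompanying [ClusterResult-class] to match.
#'
#' @param B the [TemplateSet-class] that was aligned.
#' @param alignment result of [alignTemplates()] against a reference.
#' @param result optional [ClusterResult-class] produced with `B`.
#' @return list with `templates` and (if supplied) `result`.
#' @export
applyAlignment <- function(B, alignment, result = NULL) {
  perm <- alignment$perm
  maps <- B@maps[perm, , drop = FALSE] * alignment$signs
  templates <- TemplateSet(maps, labels = seq_along(perm),
                           method = B@method, condition = B@condition,
                           configHash = B@configHash, mergeLog = B@mergeLog)
  out <- list(templates = templates)
  if (!is.null(result)) {
    # old label perm[j] becomes new label j
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    out$result <- new("ClusterResult",
                      centroids = result@centroids[perm, , drop = FALSE],
                      hardLabels = inv[result@hardLabels],
                      U = result@U[, perm, drop = FALSE],
                      objective = result@objective,
                      objectiveTrace = result@objectiveTrace,
                      replicateObjectives = result@replicateObjectives,
                      method = result@method, config = result@config)
  }
  out
}

#' Deterministic correlation backfitting
#'
#' The classical deterministic labeling: every timepoint is assigned the
#' template with the highest absolute spatial correlation to its
#' instantaneous scalp map (polarity-invariant; ties go to the lowest
#' template id). Zero-variance timepoints cannot be correlated and get an
#' `NA` label. The result is invariant under global sign flips and global
#' rescaling of the recording.
#'
#' @param rec an [EEGRecording-class].
#' @param templates a [TemplateSet-class] with matching channel count.
#' @return data.frame with columns `label` (integer, `NA` where
#'   undefined) and `abscor` (the winning absolute correlation).
#' @export
backfitTemplates <- function(rec, templates) {
  stopifnot(is(rec, "EEGRecording"), is(templates, "TemplateSet"))
  X <- rec@data
  if (nrow(X) != ncol(templates@maps)) {
    stop("channel count mismatch between recording and templates")
  }
  Xc <- sweep(X, 2L, colMeans(X))
  norms <- sqrt(colSums(Xc^2))
  ok <- norms > 1e-12
  Tm <- templates@maps
  Tc <- Tm - rowMeans(Tm)
  Tn <- Tc / sqrt(rowSums(Tc^2))

  n <- ncol(X)
  label <- rep(NA_integer_, n)
  abscor <- rep(NA_real_, n)
  if (any(ok)) {
    R <- abs(Tn %*% sweep(Xc[, ok, drop = FALSE], 2L, norms[ok], "/"))
    lbl <- max.col(t(R), ties.method = "first")
    label[ok] <- lbl
    abscor[ok] <- R[cbind(lbl, seq_len(sum(ok)))]
  }
  data.frame(label = label, abscor = abscor)
}
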