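# Fixtures built in code; all randomness behind explicit seeds.

# A small random recording.
tinyRecording <- function(nch = 4L, nt = 50L, sfreq = 100, seed = 1L) {
  set.seed(seed)
  EEGRecording(matrix(rnorm(nch * nt), nch, nt), sfreq = sfreq,
               subjectID = "T01", condition = "unknown")
}

# Well-separated spherical point clouds (rows = points).
makeClouds <- function(nPerCloud, centers, spread = 0.1, seed = 1L) {
  set.seed(seed)
  centers <- as.matrix(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    sweep(matrix(rnorm(nPerCloud * ncol(centers), sd = spread),
                 nPerCloud), 2L, centers[j, ], "+")
  }))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = nPerCloud),
       centers = centers)
}

# Linearly separable labeled data for MLP tests.
makeSeparable <- function(n = 300L, C = 10L, k = 3L, sep = 5, noise = 0.5,
                          seed = 1L) {
  set.seed(seed)
  means <- matrix(rnorm(k * C), k, C)
  means <- sep * means / sqrt(rowSums(means^2))
  y <- rep(seq_len(k), length.out = n)
  X <- means[y, ] + matrix(rnorm(n * C, sd = noise), n, C)
  list(X = X, y = y)
}

# Plain squared-distance helper, independent of package internals.
sqDistMatrixForTest <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

# Exhaustive-scan oracle for GFP peak detection, applying the definition
# index by index: a peak is the first index of a maximal run of equal
# values flanked on both sides by strictly smaller neighbours.
peakOracle <- function(v) {
  n <- length(v)
  peaks <- integer(0L)
  for (t in 2:(n - 1L)) {
    i <- t
    while (i > 1L && v[i - 1L] == v[t]) i <- i - 1L
    if (i != t) next              # not the first index of its run
    j <- t
    while (j < n && v[j + 1L] == v[t]) j <- j + 1L
    if (i > 1L && j < n && v[i - 1L] < v[t] && v[j + 1L] < v[t]) {
      peaks <- c(peaks, t)
    }
  }
  peaks
}

# Brute-force silhouette oracle (double loop over points).
silhouetteOracle <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n); a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    a[i] <- if (length(own)) mean(D[i, own]) else 0
    others <- setdiff(unique(labels), labels[i])
    b[i] <- min(vapply(others, function(g) mean(D[i, labels == g]),
                       numeric(1L)))
    s[i] <- if (length(own)) (b[i] - a[i]) / max(a[i], b[i]) else 0
    if (is.nan(s[i])) s[i] <- 0
  }
  list(a = a, b = b, s = s)
}

# Write a minimal EDF file from scratch (independent of the package's
# writer) containing the given integer channel data; optionally with an
# annotation channel and identity scaling.
writeRawEDF <- function(path, data = NULL, sfreq = 100,
                        labels = NULL, annotationOnly = FALSE) {
  pad <- function(s, w) formatC(substr(s, 1L, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)

  if (annotationOnly) {
    ns <- 1L
    labels <- "EDF Annotations"
    spr <- 4L
  } else {
    ns <- nrow(data)
    if (is.null(labels)) labels <- paste0("Ch", seq_len(ns))
    spr <- ncol(data)
  }
  wr(pad("0", 8)); wr(pad("patient", 80)); wr(pad("recording", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(as.character(256L + 256L * ns), 8))
  wr(pad("", 44)); wr(pad("1", 8))
  wr(pad(as.character(spr / sfreq), 8))
  wr(pad(as.character(ns), 4))
  for (l in labels) wr(pad(l, 16))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad("uV", 8))
  for (i in seq_len(ns)) wr(pad("-32767", 8))
  for (i in seq_len(ns)) wr(pad("32767", 8))
  for (i in seq_len(ns)) wr(pad("-32767", 8))
  for (i in seq_len(ns)) wr(pad("32767", 8))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(as.character(spr), 8))
  for (i in seq_len(ns)) wr(pad("", 32))
  if (annotationOnly) {
    writeBin(rep(0L, spr), con, size = 2L, endian = "little")
  } else {
    for (i in seq_len(ns)) {
      writeBin(as.integer(data[i, ]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
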