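#' Feature extraction configuration
#'
#' The feature bank computes, per channel, a fixed set of time-domain,
#' frequency-domain and wavelet statistics over each 40-sample window.
#' The pressure channel gets 13 features (mean, median, max, min, range,
#' variance, standard deviation, RMS, interquartile range, mean-crossing
#' count, kurtosis, skewness, FFT DC component); each of the 9 IMU
#' channels additionally gets zero-crossing count, spectral entropy, mean
#' signal power (energy) and three single-level Haar wavelet statistics,
#' for 19 features.  With the defaults the vector length is
#' `d = 13 + 9 * 19 = 184`.
#'
#' Conventions for quantities the feature names alone do not pin down:
#' * variance / std use the sample (n-1) denominator; kurtosis is excess
#'   kurtosis and skewness the population moment ratio, both defined as 0
#'   for a constant signal;
#' * FFT DC component is `|X(0)| / N`, the magnitude of the zeroth DFT
#'   coefficient over the window length;
#' * entropy is the Shannon entropy (nats) of the normalized one-sided
#'   power spectrum excluding DC, with `0 log 0 = 0`;
#' * energy is mean signal power `sum(x^2) / N`;
#' * crossing counts are strict sign changes between consecutive samples
#'   of `x` (zero crossing) or `x - mean(x)` (mean crossing);
#' * wavelet statistics come from an orthonormal Haar decomposition:
#'   sum of detail coefficients, sum of their squares, and the detail
#'   share of total wavelet energy.
#'
#' @param include_pressure keep the 13 pressure-channel features
#'   (disable to study the IMU-only model).
#' @param wavelet_level Haar decomposition depth (default 1); the detail
#'   statistics pool the detail coefficients of all levels.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(include_pressure = TRUE, wavelet_level = 1L) {
  stopifnot(wavelet_level >= 1L)
  structure(list(include_pressure = isTRUE(include_pressure),
                 wavelet_level = as.integer(wavelet_level)),
            class = "feature_config")
}

PRESSURE_FEATURES <- c("mean", "median", "max", "min", "range", "variance",
                       "std", "rms", "iqr", "mean_crossings", "kurtosis",
                       "skewness", "fft_dc")
IMU_FEATURES <- c("mean", "median", "max", "min", "range", "variance",
                  "std", "rms", "iqr", "zero_crossings", "mean_crossings",
                  "fft_dc", "entropy", "energy", "kurtosis", "skewness",
                  "wavelet_sum", "wavelet_sq_sum", "wavelet_energy")

#' @rdname feature_config
#' @param config a `feature_config`.
#' @return `feature_names()`: the ordered vector of `channel.feature`
#'   names; its length is the feature dimensionality `d`.
#' @export
feature_names <- function(config = feature_config()) {
  nm <- character(0)
  if (config$include_pressure)
    nm <- paste("pressure", PRESSURE_FEATURES, sep = ".")
  imu <- har_channels()[-1L]
  c(nm, as.vector(vapply(imu, function(ch) paste(ch, IMU_FEATURES, sep = "."),
                         character(length(IMU_FEATURES)))))
}

# multi-level orthonormal Haar transform of the columns of M (rows = time);
# returns list(detail = stacked detail coeffs of all levels, approx = final
# approximation).  Rows at odd lengths: the trailing sample stays in the
# approximation band untouched (N = 40 divides evenly for levels 1..3).
.haar <- function(M, level) {
  detail <- NULL
  A <- M
  for (l in seq_len(level)) {
    n <- nrow(A)
    if (n < 2L) break
    half <- n %/% 2L
    odd <- A[seq.int(1L, by = 2L, length.out = half), , drop = FALSE]
    even <- A[seq.int(2L, by = 2L, length.out = half), , drop = FALSE]
    d <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
    if (n %% 2L == 1L) a <- rbind(a, A[n, , drop = FALSE])
    detail <- rbind(detail, d)
    A <- a
  }
  list(detail = detail, approx = A)
}

# all per-channel statistics for a [w x n] matrix of windows (columns are
# windows); returns a named list of numeric vectors of length n
.channel_stats <- function(M, wavelet_level) {
  w <- nrow(M)
  mu <- colMeans(M)
  Mc <- sweep(M, 2L, mu)
  m2 <- colMeans(Mc^2)
  m3 <- colMeans(Mc^3)
  m4 <- colMeans(Mc^4)
  q <- matrix(matrixStats::colQuantiles(M, probs = c(0.25, 0.75)),
              ncol = 2L)
  pos <- m2 > 0
  kurt <- ifelse(pos, m4 / m2^2 - 3, 0)
  skew <- ifelse(pos, m3 / m2^1.5, 0)
  spec <- Mvfft_power(M)
  wl <- .haar(M, wavelet_level)
  wsq <- colSums(wl$detail^2)
  wtot <- wsq + colSums(wl$approx^2)
  list(
    mean = mu,
    median = matrixStats::colMedians(M),
    max = matrixStats::colMaxs(M),
    min = matrixStats::colMins(M),
    range = matrixStats::colMaxs(M) - matrixStats::colMins(M),
    variance = matrixStats::colVars(M),
    std = matrixStats::colSds(M),
    rms = sqrt(colMeans(M^2)),
    iqr = q[, 2L] - q[, 1L],
    zero_crossings = colSums(M[-w, , drop = FALSE] *
                               M[-1L, , drop = FALSE] < 0),
    mean_crossings = colSums(Mc[-w, , drop = FALSE] *
                               Mc[-1L, , drop = FALSE] < 0),
    fft_dc = abs(colSums(M)) / w,
    entropy = spec,
    energy = colMeans(M^2),
    kurtosis = kurt,
    skewness = skew,
    wavelet_sum = colSums(wl$detail),
    wavelet_sq_sum = wsq,
    wavelet_energy = ifelse(wtot > 0, wsq / wtot, 0)
  )
}

# spectral entropy (nats) of the one-sided power spectrum excluding DC;
# a spectrum that is zero up to FFT round-off (constant signal) scores 0
Mvfft_power <- function(M) {
  w <- nrow(M)
  S <- stats::mvfft(M)
  half <- S[2:(w %/% 2L + 1L), , drop = FALSE]
  P <- abs(half)^2
  tot <- colSums(P)
  full <- w * colSums(M^2)                  # Parseval: total power
  nonzero <- tot > 1e-20 * (1 + full)
  p <- sweep(P, 2L, ifelse(nonzero, tot, 1), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  ifelse(nonzero, -colSums(plogp), 0)
}

#' Extract the feature vector of one segment
#'
#' @param segment numeric matrix `[w x 10]` with columns in
#'   [har_channels()] order, or a `har_segments` object with one segment.
#' @param config a [feature_config()].
#' @return named numeric vector of length `d`.
#' @export
extract_features <- function(segment, config = feature_config()) {
  if (inherits(segment, "har_segments")) {
    stopifnot(n_segments(segment) == 1L)
    segment <- segment$values[, , 1L]
  }
  segment <- as.matrix(segment)
  if (ncol(segment) != 10L)
    stop("a segment must have 10 channels", call. = FALSE)
  if (any(!is.finite(segment)))
    stop("segment contains non-finite values", call. = FALSE)
  fake <- structure(
    list(values = array(segment, c(nrow(segment), 10L, 1L),
                        dimnames = list(NULL, har_channels(), NULL)),
         labels = UNLABELED, subject_id = "x"),
    class = "har_segments")
  drop(featurize_segments(fake, config)$X[, 1L])
}

#' Featurize a segment set
#'
#' Turns every window of a `har_segments` object into a feature-vector
#' column; column `i` of the result is `extract_features()` of segment
#' `i`, and segment labels and subject ids are carried through.
#'
#' @param segments a `har_segments` object (non-empty).
#' @param config a [feature_config()].
#' @param domain optional domain tag recycled over columns
#'   (`"source"`/`"target"`).
#' @return object of class `har_features`: list with `X` (`d x n` matrix,
#'   rownames = feature names), `y` (labels), `subject`, `domain`, `d`,
#'   `config`.
#' @export
featurize_segments <- function(segments, config = feature_config(),
                               domain = NA_character_) {
  stopifnot(inherits(segments, "har_segments"))
  n <- dim(segments$values)[3L]
  if (n == 0L) stop("cannot featurize an empty segment set", call. = FALSE)
  if (any(!is.finite(segments$values)))
    stop("segments contain non-finite values", call. = FALSE)
  channels <- har_channels()
  use <- if (config$include_pressure) channels else channels[-1L]
  blocks <- vector("list", length(use))
  names(blocks) <- use
  for (ch in use) {
    M <- segments$values[, ch, , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, ncol = n)
    st <- .channel_stats(M, config$wavelet_level)
    feats <- if (ch == "pressure") PRESSURE_FEATURES else IMU_FEATURES
    blocks[[ch]] <- do.call(rbind, st[feats])
  }
  X <- do.call(rbind, blocks)
  rownames(X) <- feature_names(config)
  colnames(X) <- NULL
  structure(
    list(X = X, y = segments$labels, subject = segments$subject_id,
         domain = rep_len(domain, n), d = nrow(X), config = config),
    class = "har_features")
}

#' @export
print.har_features <- function(x, ...) {
  cat("<har_features> d =", x$d, "features x", ncol(x$X), "segments\n")
  invisible(x)
}

#' Write / read a feature matrix as CSV + JSON sidecar
#'
#' The CSV stores one row per feature (first column `feature`), one
#' column per segment; the sidecar JSON carries labels, subjects, domain
#' tags and the feature configuration.
#'
#' @param features a `har_features` object.
#' @param path CSV output path; the sidecar is `<path>.meta.json`.
#' @return `path` invisibly / a `har_features` object.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "har_features"))
  df <- data.frame(feature = rownames(features$X), features$X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(y = features$y, subject = features$subject,
               domain = features$domain,
               config = unclass(features$config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  colnames(X) <- NULL
  cfg <- feature_config(include_pressure = meta$config$include_pressure,
                        wavelet_level = meta$config$wavelet_level)
  structure(list(X = X, y = meta$y, subject = meta$subject,
                 domain = meta$domain, d = nrow(X), config = cfg),
            class = "har_features")
}

# subset feature columns, keeping metadata aligned
subset_features <- function(features, idx) {
  structure(list(X = features$X[, idx, drop = FALSE],
                 y = features$y[idx],
                 subject = features$subject[idx],
                 domain = features$domain[idx],
                 d = features$d, config = features$config),
            class = "har_features")
}
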