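# shared fixtures, built once per test run and cached

.fixtures <- new.env()

# small featurized cohort: n subjects at the given difficulty; returns
# list(features = list of har_features, cohort = generate_cohort output)
small_cohort <- function(n_subjects = 3, difficulty = 1, seed = 42,
                         segments_per_class = 10) {
  key <- paste("cohort", n_subjects, difficulty, seed, segments_per_class,
               sep = "_")
  if (is.null(.fixtures[[key]])) {
    cohort <- generate_cohort(n_subjects = n_subjects,
                              difficulty = difficulty, seed = seed,
                              segments_per_class = segments_per_class)
    feats <- lapply(cohort$recordings, function(r)
      featurize_segments(segment_recording(r)))
    .fixtures[[key]] <- list(features = feats, cohort = cohort)
  }
  .fixtures[[key]]
}

# a reproducible random 40 x 10 segment with positive pressure channel
random_segment <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(400), 40, 10)
  m[, 1] <- abs(m[, 1]) + 1
  colnames(m) <- har_channels()
  m
}

# a small labeled recording with the given per-sample labels
toy_recording <- function(labels, seed = 1, subject_id = "T1") {
  set.seed(seed)
  n <- length(labels)
  vals <- matrix(rnorm(n * 10), n, 10)
  vals[, 1] <- abs(vals[, 1])
  sensor_recording(vals, labels, subject_id = subject_id)
}

# pool a list of har_features into one (test-side copy of the internal)
pool_features <- function(feature_list) {
  X <- do.call(cbind, lapply(feature_list, function(f) f$X))
  structure(list(X = X,
                 y = unlist(lapply(feature_list, function(f) f$y)),
                 subject = unlist(lapply(feature_list,
                                         function(f) f$subject)),
                 domain = rep("source", ncol(X)),
                 d = nrow(X), config = feature_list[[1]]$config),
            class = "har_features")
}
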