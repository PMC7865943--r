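#' Select the target subject's scored segments
#'
#' A new user contributes only a small probe set: `per_class` windows of
#' each activity (default 10, so 70 segments over the 7 activities).
#' Selection is a seeded draw without replacement within each class.
#'
#' @param features a `har_features` object for one subject.
#' @param per_class windows kept per class (default 10).
#' @param seed integer seed controlling the draw.
#' @return a `har_features` object with `per_class * C` columns.
#' @export
select_target_segments <- function(features, per_class = 10L, seed = 1L) {
  stopifnot(inherits(features, "har_features"))
  classes <- .default_classes(features$y)
  rng <- .local_rng(seed)
  keep <- integer(0)
  for (cl in classes) {
    idx <- which(features$y == cl)
    if (length(idx) < per_class)
      stop("subject ", features$subject[1L], " has only ", length(idx),
           " segments of class ", cl, " (need ", per_class, ")",
           call. = FALSE)
    keep <- c(keep, rng$sample(idx, per_class))
  }
  subset_features(features, sort(keep))
}

# class-stratified fold assignment; the fold count drops to the smallest
# class size when a class has fewer segments than requested folds
.stratified_folds <- function(y, cv_folds, seed = 1L) {
  counts <- table(y)
  folds_eff <- min(cv_folds, min(counts))
  if (folds_eff < cv_folds)
    message("reducing folds to ", folds_eff,
            " (smallest class has ", min(counts), " segments)")
  rng <- .local_rng(seed)
  fold <- integer(length(y))
  for (cl in names(counts)) {
    idx <- which(y == cl)
    idx <- idx[rng$sample(seq_along(idx), length(idx))]
    fold[idx] <- rep_len(seq_len(folds_eff), length(idx))
  }
  fold
}

# seeded RNG scoped away from the global stream
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(sample = function(x, size)
         with_state(function() x[sample.int(length(x), size)]),
       runif = function(n) with_state(function() stats::runif(n)),
       rnorm = function(n, mean = 0, sd = 1)
         with_state(function() stats::rnorm(n, mean, sd)),
       integer = function(n, max = .Machine$integer.max)
         with_state(function() sample.int(max, n)))
}

#' Run a baseline classifier under the OS or SS protocol
#'
#' OS ("other subjects"): train on the pooled source-group features and
#' predict the target subject's probe segments; the target labels are
#' used only for scoring.  SS ("self source"): stratified `cv_folds`-fold
#' cross-validation on the target subject's own labeled probe data; each
#' segment is predicted by the fold model that did not train on it, and
#' reported metrics are therefore fold averages.
#'
#' @param kind baseline kind, see [baseline_fit_predict()].
#' @param protocol `"OS"` or `"SS"`.
#' @param source_features pooled source-group `har_features` (OS only).
#' @param target_features the target subject's probe `har_features`.
#' @param cv_folds folds for SS (default 10; reduced with a message when
#'   a class has fewer segments than folds).
#' @param seed seed for the fold assignment.
#' @param ... passed to [baseline_fit_predict()].
#' @return character predictions for every target segment.
#' @export
baseline_protocol <- function(kind, protocol = c("OS", "SS"),
                              source_features = NULL, target_features,
                              cv_folds = 10L, seed = 1L, ...) {
  protocol <- match.arg(protocol)
  if (protocol == "OS") {
    if (is.null(source_features))
      stop("OS protocol needs source_features", call. = FALSE)
    return(baseline_fit_predict(kind, source_features$X,
                                source_features$y, target_features$X,
                                ...))
  }
  y <- target_features$y
  n <- length(y)
  fold <- .stratified_folds(y, cv_folds, seed)
  folds_eff <- max(fold)
  pred <- character(n)
  for (f in seq_len(folds_eff)) {
    test <- fold == f
    pred[test] <- baseline_fit_predict(
      kind, target_features$X[, !test, drop = FALSE], y[!test],
      target_features$X[, test, drop = FALSE], ...)
  }
  pred
}

#' Cross-subject group experiment
#'
#' The package's main benchmark protocol: split the cohort into a source
#' group (default 3 subjects, pooled as the labeled source domain) and a
#' target group; each target subject contributes `per_class` probe
#' windows per activity (default 10, i.e. 70 segments).  Every
#' configured model is scored per target subject with [evaluate()] and
#' the table reports the across-subject means of the four indicators,
#' with per-subject F-measures averaged as such (not recomputed from the
#' averaged precision/recall).
#'
#' @param recordings list of [sensor_recording()] objects (one per
#'   subject) or a cohort from [generate_cohort()].
#' @param n_source source-group size (default 3).
#' @param per_class probe windows per class per target subject.
#' @param models character vector among `"knn-os"`, `"knn-ss"`,
#'   `"svm-os"`, `"svm-ss"`, `"tree-os"`, `"tree-ss"`, `"ipl-jpda"`.
#' @param seed master seed (group split, probe draws, folds).
#' @param config feature configuration.
#' @param ... passed to [ipl_jpda()].
#' @return object of class `har_experiment`: list with `table` (one row
#'   per model, mean Accuracy/F/Precision/Recall in %), `per_subject`
#'   (list of `har_eval` by model and subject), `source_subjects`,
#'   `target_subjects`.
#' @export
run_group_experiment <- function(recordings, n_source = 3L,
                                 per_class = 10L,
                                 models = c("knn-os", "ipl-jpda"),
                                 seed = 1L, config = feature_config(),
                                 ...) {
  if (!is.null(recordings$recordings)) recordings <- recordings$recordings
  n_sub <- length(recordings)
  if (n_sub < n_source + 1L)
    stop("need at least n_source + 1 subjects", call. = FALSE)
  rng <- .local_rng(seed)
  src_idx <- sort(rng$sample(seq_len(n_sub), n_source))
  tgt_idx <- setdiff(seq_len(n_sub), src_idx)
  feats <- lapply(recordings, function(r)
    featurize_segments(segment_recording(r), config))
  source_feat <- .bind_features(feats[src_idx], domain = "source")
  subj_ids <- vapply(recordings, function(r) r$subject_id, character(1))

  per_subject <- list()
  rows <- list()
  for (mod in models) {
    evals <- list()
    for (ti in tgt_idx) {
      probe <- select_target_segments(feats[[ti]], per_class,
                                      seed = rng$integer(1, 1e6))
      pred <- switch(
        mod,
        "knn-os" = baseline_protocol("knn", "OS", source_feat, probe),
        "svm-os" = baseline_protocol("svm", "OS", source_feat, probe),
        "tree-os" = baseline_protocol("tree", "OS", source_feat, probe),
        "knn-ss" = baseline_protocol("knn", "SS",
                                     target_features = probe,
                                     seed = rng$integer(1, 1e6)),
        "svm-ss" = baseline_protocol("svm", "SS",
                                     target_features = probe,
                                     seed = rng$integer(1, 1e6)),
        "tree-ss" = baseline_protocol("tree", "SS",
                                      target_features = probe,
                                      seed = rng$integer(1, 1e6)),
        "ipl-jpda" = fitted(ipl_jpda(source_feat, x_target = probe,
                                     ...)),
        stop("unknown model: ", mod, call. = FALSE))
      evals[[subj_ids[ti]]] <- evaluate(probe$y, pred)
    }
    per_subject[[mod]] <- evals
    rows[[mod]] <- data.frame(
      model = mod,
      accuracy = mean(vapply(evals, function(e) e$accuracy, numeric(1))),
      f_measure = mean(vapply(evals, function(e) e$f_measure,
                              numeric(1))),
      precision = mean(vapply(evals, function(e) e$precision,
                              numeric(1))),
      recall = mean(vapply(evals, function(e) e$recall, numeric(1))))
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         per_subject = per_subject,
         source_subjects = subj_ids[src_idx],
         target_subjects = subj_ids[tgt_idx]),
    class = "har_experiment")
}

#' @export
print.har_experiment <- function(x, ...) {
  cat("source:", paste(x$source_subjects, collapse = ", "),
      "| targets:", paste(x$target_subjects, collapse = ", "), "\n")
  tab <- x$table
  tab[, -1L] <- round(tab[, -1L], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

.bind_features <- function(feature_list, domain = NA_character_) {
  X <- do.call(cbind, lapply(feature_list, function(f) f$X))
  structure(list(X = X,
                 y = unlist(lapply(feature_list, function(f) f$y)),
                 subject = unlist(lapply(feature_list,
                                         function(f) f$subject)),
                 domain = rep_len(domain, ncol(X)),
                 d = nrow(X),
                 config = feature_list[[1L]]$config),
            class = "har_features")
}

#' Source-group size sweep
#'
#' How many training subjects does personalization need?  For each
#' candidate source-group size, several random source combinations are
#' drawn from the non-test subjects, the adaptation is run against each
#' held-out test subject, and the mean and standard deviation of the
#' accuracy across combinations (and test subjects) are reported.
#'
#' @param recordings subject recordings or a [generate_cohort()] result.
#' @param sizes source-group sizes to try (default 1:5).
#' @param combos_per_size random combinations per size (default 5).
#' @param n_test_targets held-out test subjects (default 2).
#' @param per_class probe windows per class (default 10).
#' @param seed master seed.
#' @param config feature configuration.
#' @param ... passed to [ipl_jpda()].
#' @return data frame with `size`, `mean_accuracy`, `sd_accuracy` (%).
#' @export
run_source_size_sweep <- function(recordings, sizes = 1:5,
                                  combos_per_size = 5L,
                                  n_test_targets = 2L, per_class = 10L,
                                  seed = 1L, config = feature_config(),
                                  ...) {
  if (!is.null(recordings$recordings)) recordings <- recordings$recordings
  n_sub <- length(recordings)
  if (n_sub < max(sizes) + n_test_targets)
    stop("not enough subjects for the largest source size", call. = FALSE)
  rng <- .local_rng(seed)
  test_idx <- sort(rng$sample(seq_len(n_sub), n_test_targets))
  pool <- setdiff(seq_len(n_sub), test_idx)
  feats <- lapply(recordings, function(r)
    featurize_segments(segment_recording(r), config))
  probes <- lapply(test_idx, function(ti)
    select_target_segments(feats[[ti]], per_class,
                           seed = rng$integer(1, 1e6)))
  out <- data.frame()
  for (s in sizes) {
    accs <- c()
    for (b in seq_len(combos_per_size)) {
      src <- rng$sample(pool, s)
      source_feat <- .bind_features(feats[src], domain = "source")
      for (probe in probes) {
        fit <- ipl_jpda(source_feat, x_target = probe,
                        y_target = probe$y, ...)
        accs <- c(accs, 100 * mean(fitted(fit) == probe$y))
      }
    }
    out <- rbind(out, data.frame(size = s, mean_accuracy = mean(accs),
                                 sd_accuracy = stats::sd(accs)))
  }
  out
}
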