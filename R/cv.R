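# Cross-validated (channel, band, segment) selection and LDA accuracy.
#
# Classification is reference segment vs. one activity segment, per trial:
# every trial contributes one reference-class sample and one
# activity-class sample for each candidate segment, and the classifier is
# one-dimensional (a single log band-power value).  The searched grid is
# channels x bands x activity segments; fold assignments are drawn once
# per split and held constant across the whole grid so that all triples
# are compared on identical data.

# flatten a feature set into the matrices the CV engine works on
build_cv_matrices <- function(features) {
  v <- features$values
  d <- dim(v)
  n <- d[1]; nch <- d[2]; nbd <- d[3]
  segs <- features$activity_segments
  ref <- v[, , , features$ref_segment]
  dim(ref) <- c(n, nch * nbd)
  act <- v[, , , segs, drop = FALSE]
  dim(act) <- c(n, nch * nbd * length(segs))
  meta <- expand.grid(ci = seq_len(nch), bi = seq_len(nbd),
                      sj = seq_along(segs))
  meta$channel <- features$channels[meta$ci]
  meta$band <- features$bands$band[meta$bi]
  meta$segment <- segs[meta$sj]
  meta$midpoint_s <- features$midpoints[meta$segment]
  list(ref = ref, act = act, cb_of = meta$ci + (meta$bi - 1L) * nch,
       meta = meta)
}

# repeated k-fold inner CV, vectorized over the whole (channel, band,
# segment) grid; returns the accuracy per triple.  The 1-D LDA decision
# boundary is the pooled class midpoint, so only class means are needed;
# a zero mean difference predicts "reference" everywhere (decision value
# 0 is not > 0).
inner_accuracy <- function(mats, train_idx, reps, folds, fold_seed) {
  n <- length(train_idx)
  if (n < folds)
    stopf("fewer training trials (%d) than inner folds (%d)", n, folds)
  fold_mat <- with_seed(fold_seed,
    vapply(seq_len(reps),
           function(i) sample(rep_len(seq_len(folds), n)), integer(n)))
  R <- mats$ref[train_idx, , drop = FALSE]
  A <- mats$act[train_idx, , drop = FALSE]
  cb_of <- mats$cb_of
  ncbs <- ncol(A)
  correct <- numeric(ncbs); tested <- 0L
  for (rep_i in seq_len(reps)) for (f in seq_len(folds)) {
    te <- which(fold_mat[, rep_i] == f)
    tr <- which(fold_mat[, rep_i] != f)
    if (length(te) == 0 || length(tr) < 2) next
    mu_r <- colMeans(R[tr, , drop = FALSE])[cb_of]
    mu_a <- colMeans(A[tr, , drop = FALSE])
    dir <- mu_a - mu_r
    thr <- (mu_a + mu_r) / 2 * dir
    nte <- length(te)
    thr_m <- matrix(thr, nte, ncbs, byrow = TRUE)
    dir_m <- matrix(dir, nte, ncbs, byrow = TRUE)
    correct <- correct +
      colSums(R[te, cb_of, drop = FALSE] * dir_m <= thr_m) +
      colSums(A[te, , drop = FALSE] * dir_m > thr_m)
    tested <- tested + 2L * nte
  }
  correct / tested
}

# deterministic tie-break: best accuracy, then earlier segment, then lower
# band, then channel order (favours earlier detection)
select_triple <- function(acc, meta) {
  ord <- order(-acc, meta$sj, meta$bi, meta$ci)
  idx <- ord[1]
  list(index = idx, channel = meta$channel[idx], band = meta$band[idx],
       segment = meta$segment[idx], midpoint_s = meta$midpoint_s[idx],
       inner_accuracy = acc[idx])
}

empty_confusion <- function() {
  matrix(0L, 2, 2, dimnames = list(truth = c("reference", "activity"),
                                   predicted = c("reference", "activity")))
}

# train on train_idx at one triple, classify test_idx; returns a 2x2
# confusion count matrix (rows truth, columns prediction)
eval_triple <- function(mats, sel, train_idx, test_idx) {
  x_ref <- matrix(mats$ref[train_idx, mats$cb_of[sel$index]])
  x_act <- matrix(mats$act[train_idx, sel$index])
  model <- train_lda(x_ref, x_act)
  p_ref <- predict(model, matrix(mats$ref[test_idx, mats$cb_of[sel$index]]))
  p_act <- predict(model, matrix(mats$act[test_idx, sel$index]))
  conf <- empty_confusion()
  conf[1, 1] <- sum(p_ref == 0L); conf[1, 2] <- sum(p_ref == 1L)
  conf[2, 2] <- sum(p_act == 1L); conf[2, 1] <- sum(p_act == 0L)
  list(confusion = conf, model = model)
}

make_session_result <- function(scheme, selected, confusion, outer,
                                inner_grid = NULL) {
  total <- sum(confusion)
  accuracy <- 100 * sum(diag(confusion)) / total
  p <- accuracy_significance(confusion)
  structure(list(scheme = scheme, selected = selected,
                 confusion = confusion, accuracy = accuracy,
                 p_value = p, significance = significance_tag(p),
                 outer = outer, inner_grid = inner_grid),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s\n", x$scheme))
  cat(sprintf(" %.0f%% (%s, %s, %s)  [selected segment %d, midpoint %.1f s]\n",
              x$accuracy, x$selected$channel, x$selected$band,
              x$significance, x$selected$segment, x$selected$midpoint_s))
  print(x$confusion)
  invisible(x)
}

#' Nested block-wise cross-validation with feature selection
#'
#' Outer loop: leave one block (run) out.  Inner loop, on the training
#' blocks only: `inner_reps` repetitions of `inner_folds`-fold CV,
#' evaluated separately for every (channel, band, segment) triple with
#' fold assignments held constant across the grid; the triple with the
#' best inner accuracy is then trained on all training blocks and applied
#' to the held-out block.  Outer-fold confusion matrices are summed
#' (micro-averaged) into a single accuracy with an exact binomial
#' significance against chance.  The reported selected triple is the one
#' chosen by the same inner procedure run on all blocks (the triple an
#' online session would continue with); per-fold selections are kept in
#' `$outer`.
#'
#' @param features a `feature_set` with at least 2 blocks.
#' @param inner_reps repetitions of the inner k-fold CV (default 10).
#' @param inner_folds inner folds (default 10).
#' @param seed RNG seed for the fold assignments.
#' @return A `session_result`: selected triple, micro-averaged 2x2
#'   confusion matrix, accuracy (%), exact binomial p-value and the
#'   per-outer-fold selection table.
#' @export
nested_blockwise_cv <- function(features, inner_reps = 10,
                                inner_folds = 10, seed = 1) {
  stopifnot(inherits(features, "feature_set"))
  blocks <- sort(unique(features$run))
  if (length(blocks) < 2) stopf("need >= 2 blocks for block-wise CV")
  mats <- build_cv_matrices(features)
  conf <- empty_confusion()
  outer <- data.frame()
  for (o in seq_along(blocks)) {
    train_idx <- which(features$run != blocks[o])
    test_idx <- which(features$run == blocks[o])
    acc <- inner_accuracy(mats, train_idx, inner_reps, inner_folds,
                          fold_seed = seed + o)
    sel <- select_triple(acc, mats$meta)
    ev <- eval_triple(mats, sel, train_idx, test_idx)
    conf <- conf + ev$confusion
    outer <- rbind(outer, data.frame(
      block = blocks[o], channel = sel$channel, band = sel$band,
      segment = sel$segment, inner_accuracy = sel$inner_accuracy,
      test_correct = sum(diag(ev$confusion)),
      test_total = sum(ev$confusion)))
  }
  acc_all <- inner_accuracy(mats, seq_len(nrow(mats$ref)), inner_reps,
                            inner_folds, fold_seed = seed)
  sel_all <- select_triple(acc_all, mats$meta)
  make_session_result("nested block-wise CV", sel_all, conf, outer,
                      inner_grid = acc_all)
}

#' Leave-one-trial-out cross-validation with feature selection
#'
#' As [nested_blockwise_cv()], but the outer loop holds out one trial at
#' a time (used for initial runs where only a single block exists);
#' selection is still performed inside each training split.
#'
#' @inheritParams nested_blockwise_cv
#' @param features a `feature_set` with at least 10 trials.
#' @return A `session_result`.
#' @export
loto_cv <- function(features, inner_reps = 10, inner_folds = 10, seed = 1) {
  stopifnot(inherits(features, "feature_set"))
  n <- dim(features$values)[1]
  if (n < 10) stopf("need >= 10 trials for leave-one-trial-out CV")
  mats <- build_cv_matrices(features)
  conf <- empty_confusion()
  outer <- data.frame()
  for (t in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), t)
    acc <- inner_accuracy(mats, train_idx, inner_reps, inner_folds,
                          fold_seed = seed + t)
    sel <- select_triple(acc, mats$meta)
    ev <- eval_triple(mats, sel, train_idx, t)
    conf <- conf + ev$confusion
    outer <- rbind(outer, data.frame(
      block = t, channel = sel$channel, band = sel$band,
      segment = sel$segment, inner_accuracy = sel$inner_accuracy,
      test_correct = sum(diag(ev$confusion)),
      test_total = sum(ev$confusion)))
  }
  acc_all <- inner_accuracy(mats, seq_len(n), inner_reps, inner_folds,
                            fold_seed = seed)
  sel_all <- select_triple(acc_all, mats$meta)
  make_session_result("leave-one-trial-out CV", sel_all, conf, outer,
                      inner_grid = acc_all)
}

#' Exact binomial significance of a classification accuracy
#'
#' One-sided exact binomial test of the micro-averaged correct count
#' against chance level.  Note the p-value is not corrected for the
#' selection search over channels x bands x segments; use
#' [permutation_significance()] for a search-corrected estimate.
#'
#' @param confusion 2x2 confusion count matrix (or a `session_result`).
#' @param chance chance probability of a correct classification
#'   (default 0.5).
#' @return The one-sided p-value.
#' @export
accuracy_significance <- function(confusion, chance = 0.5) {
  if (inherits(confusion, "session_result")) confusion <- confusion$confusion
  total <- sum(confusion)
  if (total <= 0) stopf("empty confusion matrix")
  correct <- sum(diag(confusion))
  stats::binom.test(correct, total, p = chance,
                    alternative = "greater")$p.value
}

significance_tag <- function(p) {
  if (p <= 0.01) "0.01" else if (p <= 0.05) "0.05" else "n.s."
}

#' Permutation-corrected session significance
#'
#' Reruns the full nested selection-plus-CV procedure on label-permuted
#' feature sets (see [permute_labels()]) and reports the fraction of
#' permutations whose micro-averaged accuracy reaches the observed one.
#' Unlike the exact binomial p-value, this accounts for the selection
#' search over channels x bands x segments, which inflates the binomial
#' test's type-I error.
#'
#' @param features a `feature_set`.
#' @param scheme `"nested"` or `"loto"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param ... passed to the CV routine.
#' @return List with `p_value`, `observed` accuracy and the permutation
#'   `null` accuracies.
#' @export
permutation_significance <- function(features, scheme = c("nested", "loto"),
                                     n_perm = 50, seed = 1, ...) {
  scheme <- match.arg(scheme)
  cv_fun <- if (scheme == "nested") nested_blockwise_cv else loto_cv
  observed <- cv_fun(features, seed = seed, ...)$accuracy
  null_acc <- vapply(seq_len(n_perm), function(i) {
    cv_fun(permute_labels(features, seed = seed * 1000L + i),
           seed = seed + i, ...)$accuracy
  }, 0)
  list(p_value = (1 + sum(null_acc >= observed)) / (1 + n_perm),
       observed = observed, null = null_acc)
}

#' Permute the class structure of a feature set (null model)
#'
#' Shuffles, independently per trial, which 1-s segment plays which role:
#' the segment axis is permuted over the reference segment and the
#' activity segments (the same permutation for all channels and bands of
#' that trial, preserving the spatial structure).  Under the permutation
#' the reference and activity classes are exchangeable, so any systematic
#' reference-vs-activity difference is destroyed; segments outside the
#' classified set (before the reference) are left untouched.
#'
#' @param features a `feature_set`.
#' @param seed optional RNG seed for the permutation.
#' @return The permuted `feature_set`.
#' @export
permute_labels <- function(features, seed = NULL) {
  v <- features$values
  segs <- c(features$ref_segment, features$activity_segments)
  with_seed(seed, {
    for (t in seq_len(dim(v)[1]))
      v[t, , , segs] <- v[t, , , sample(segs)]
  })
  features$values <- v
  features
}
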