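# Template-correlation decoding with training-only voxel selection and
# leave-one-run-out cross-validation.

#' Decoding configuration
#'
#' @param problem Character pair of condition labels to discriminate,
#'   e.g. `c("L_low", "R_low")` (the eye-of-origin problem at low spatial
#'   frequency). Order defines the canonical tie-break order.
#' @param n_voxels_cutoff Number of voxels retained by training-set voxel
#'   selection (default 100; clamped to the available voxel count).
#' @param classifier `"pattern_correlation"` (multivoxel template
#'   correlation, voxels ranked by training-only |T|) or
#'   `"univariate_difference"` (samples averaged over the most responsive
#'   training voxels, classified by smaller absolute difference from the
#'   condition mean).
#' @param tie_break `"first"`: exact ties go to the first condition of
#'   `problem`; ties are counted in the result.
#' @return An object of class `"decoding_config"`.
#' @export
decoding_config <- function(problem = c("L_low", "R_low"),
                            n_voxels_cutoff = 100,
                            classifier = c("pattern_correlation",
                                           "univariate_difference"),
                            tie_break = "first") {
  if (length(problem) != 2L || problem[1] == problem[2]) {
    stop("problem must be two distinct condition labels")
  }
  stopif_not_scalar_number(n_voxels_cutoff, "n_voxels_cutoff", min = 1)
  structure(list(problem = problem,
                 n_voxels_cutoff = as.integer(n_voxels_cutoff),
                 classifier = match.arg(classifier),
                 tie_break = match.arg(tie_break, "first")),
            class = "decoding_config")
}

# Per-voxel absolute pooled-variance two-sample T. Conventions for
# degenerate voxels: zero pooled variance with zero mean difference -> 0
# (no signal); zero pooled variance with nonzero difference -> Inf (perfectly
# discriminative), so they rank first.
abs_tstat <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(xa^2) - na * ma^2   # (na-1) * var
  vb <- colSums(xb^2) - nb * mb^2
  sp2 <- (va + vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- abs(ma - mb)
  t <- d / se
  t[se == 0 & d == 0] <- 0
  t[se == 0 & d > 0] <- Inf
  t
}

#' Rank voxels by training-set discriminability
#'
#' Computes, for each voxel, the pooled-variance two-sample T statistic
#' comparing the two conditions across training samples, and returns the
#' indices of the `cutoff` voxels with the largest `|T|` (sign ignored).
#' Ties at the cutoff boundary are broken by lowest voxel index. Selection
#' must only ever see training data; [loro_cv()] re-runs it inside every
#' fold.
#'
#' @param samples A `"pattern_samples"` object (the training set).
#' @param cond_a,cond_b The two condition labels.
#' @param cutoff Number of voxels to keep; if larger than the voxel count,
#'   all voxels are returned (ranked).
#' @return Integer vector of selected voxel indices, most discriminative
#'   first.
#' @export
tstat_rank_voxels <- function(samples, cond_a, cond_b, cutoff) {
  ia <- samples$meta$condition == cond_a
  ib <- samples$meta$condition == cond_b
  if (sum(ia) < 2L || sum(ib) < 2L) {
    stop("need at least 2 training samples per condition")
  }
  t <- abs_tstat(samples$x[ia, , drop = FALSE], samples$x[ib, , drop = FALSE])
  ord <- order(-t, seq_along(t))
  ord[seq_len(min(cutoff, length(t)))]
}

#' Rank voxels by overall responsiveness
#'
#' Returns the indices of the `cutoff` voxels with the largest mean response
#' across all stimulation samples (samples are in z-units relative to the
#' run baseline, so large positive means indicate visually responsive
#' voxels). Used for the univariate mean-signal analysis; inside
#' cross-validation it is applied to training data only.
#'
#' @param samples A `"pattern_samples"` object.
#' @param cutoff Number of voxels to keep (clamped to the voxel count).
#' @return Integer vector of voxel indices, most responsive first.
#' @export
select_responsive_voxels <- function(samples, cutoff) {
  m <- colMeans(samples$x)
  ord <- order(-m, seq_along(m))
  ord[seq_len(min(cutoff, length(m)))]
}

#' Per-condition template patterns
#'
#' The template for a condition is the element-wise mean over all training
#' samples of that condition, restricted to the selected voxels.
#'
#' @param samples Training `"pattern_samples"`.
#' @param conditions Condition labels needing templates.
#' @param selected Integer voxel indices from voxel selection.
#' @return Matrix with one row per condition (rownames = condition labels)
#'   and one column per selected voxel.
#' @export
build_templates <- function(samples, conditions, selected) {
  tmpl <- vapply(conditions, function(cc) {
    idx <- samples$meta$condition == cc
    if (!any(idx)) stop("no training samples for condition ", cc)
    colMeans(samples$x[idx, selected, drop = FALSE])
  }, numeric(length(selected)))
  t(matrix(tmpl, ncol = length(conditions),
           dimnames = list(NULL, conditions)))
}

# correlations between one vector and each row of a matrix; NA when either
# side has zero variance
row_correlations <- function(tmpl, v) {
  apply(tmpl, 1L, function(row) {
    if (stats::sd(row) == 0 || stats::sd(v) == 0) NA_real_
    else stats::cor(row, v)
  })
}

#' Classify one test sample against condition templates
#'
#' `classify_correlation` assigns the test pattern to the condition whose
#' template has the larger Pearson correlation with it (correlation is
#' invariant to any positive-scale affine transform of the sample, so this
#' implicitly normalizes each sample). `classify_univariate` reduces the
#' sample and templates to their means across voxels and assigns the
#' condition with the smaller absolute difference. Exact ties — including
#' undefined correlations from zero-variance inputs — are resolved in favor
#' of the first condition (the canonical tie-break) and flagged.
#'
#' @param test Numeric voxel vector (already restricted to the selected
#'   voxels for `classify_correlation`; any vector for
#'   `classify_univariate`, which averages it).
#' @param templates Template matrix from [build_templates()].
#' @return List with `label` (predicted condition) and `tied` (logical).
#' @export
classify_correlation <- function(test, templates) {
  r <- row_correlations(templates, test)
  score <- ifelse(is.na(r), -Inf, r)
  best <- which(score == max(score))
  list(label = rownames(templates)[best[1L]],
       tied = length(best) > 1L || all(is.na(r)))
}

#' @rdname classify_correlation
#' @export
classify_univariate <- function(test, templates) {
  d <- abs(rowMeans(templates) - mean(test))
  best <- which(d == min(d))
  list(label = rownames(templates)[best[1L]], tied = length(best) > 1L)
}

# Lean CV core on raw matrices; everything user-facing wraps this.
# x: samples x voxels; cond: condition label per sample (problem samples
# only); run: run index per sample.
cv_core <- function(x, cond, run, problem, cutoff, classifier) {
  runs <- sort(unique(run))
  fold_acc <- numeric(length(runs))
  selected <- vector("list", length(runs))
  n_ties <- 0L
  ia_all <- cond == problem[1L]
  for (f in seq_along(runs)) {
    test_idx <- run == runs[f]
    tr <- !test_idx
    xa <- x[tr & ia_all, , drop = FALSE]
    xb <- x[tr & !ia_all, , drop = FALSE]
    if (nrow(xa) < 2L || nrow(xb) < 2L) {
      stop("fold ", runs[f], ": need >= 2 training samples per condition")
    }
    if (!any(test_idx)) stop("fold ", runs[f], ": empty test set")
    if (classifier == "pattern_correlation") {
      t <- abs_tstat(xa, xb)
      sel <- order(-t, seq_along(t))[seq_len(min(cutoff, length(t)))]
      ta <- colMeans(xa[, sel, drop = FALSE])
      tb <- colMeans(xb[, sel, drop = FALSE])
      # centered templates/samples for fast Pearson
      ca <- ta - mean(ta); cb <- tb - mean(tb)
      na_ <- sqrt(sum(ca^2)); nb_ <- sqrt(sum(cb^2))
      correct <- 0L
      for (i in which(test_idx)) {
        v <- x[i, sel]
        cv_ <- v - mean(v)
        nv <- sqrt(sum(cv_^2))
        ra <- if (na_ == 0 || nv == 0) -Inf else sum(ca * cv_) / (na_ * nv)
        rb <- if (nb_ == 0 || nv == 0) -Inf else sum(cb * cv_) / (nb_ * nv)
        if (ra == rb) {
          n_ties <- n_ties + 1L
          pred <- problem[1L]
        } else pred <- problem[if (ra > rb) 1L else 2L]
        correct <- correct + (pred == cond[i])
      }
    } else {
      m <- colMeans(rbind(xa, xb))
      sel <- order(-m, seq_along(m))[seq_len(min(cutoff, length(m)))]
      ta <- mean(colMeans(xa[, sel, drop = FALSE]))
      tb <- mean(colMeans(xb[, sel, drop = FALSE]))
      correct <- 0L
      for (i in which(test_idx)) {
        v <- mean(x[i, sel])
        da <- abs(v - ta); db <- abs(v - tb)
        if (da == db) {
          n_ties <- n_ties + 1L
          pred <- problem[1L]
        } else pred <- problem[if (da < db) 1L else 2L]
        correct <- correct + (pred == cond[i])
      }
    }
    fold_acc[f] <- correct / sum(test_idx)
    selected[[f]] <- sel
  }
  list(fold_accuracies = fold_acc, selected = selected, n_ties = n_ties,
       runs = runs)
}

#' Leave-one-run-out cross-validated decoding
#'
#' For each fold, one run's samples form the test set and all remaining runs
#' the training set. Voxel selection (training-only T-statistic ranking for
#' the pattern classifier; training-only responsiveness ranking for the
#' univariate classifier) and condition templates are computed inside the
#' fold from training data alone, and every test sample is classified.
#' Accuracy is the mean over folds of each fold's proportion correct.
#'
#' @param samples A `"pattern_samples"` object covering all runs.
#' @param config A [decoding_config()].
#' @return An object of class `"decoding_result"`: `accuracy`,
#'   `fold_accuracies` (one per run), `selected_voxels_per_fold`, `n_ties`,
#'   and the config.
#' @export
loro_cv <- function(samples, config = decoding_config()) {
  keep <- samples$meta$condition %in% config$problem
  if (!any(keep)) stop("no samples for problem conditions")
  x <- samples$x[keep, , drop = FALSE]
  cond <- samples$meta$condition[keep]
  run <- samples$meta$run[keep]
  if (length(unique(run)) < 2L) stop("need at least 2 runs for cross-validation")
  missing_cond <- setdiff(config$problem, unique(cond))
  if (length(missing_cond)) stop("condition(s) absent: ",
                                 paste(missing_cond, collapse = ", "))
  core <- cv_core(x, cond, run, config$problem, config$n_voxels_cutoff,
                  config$classifier)
  structure(list(
    accuracy = mean(core$fold_accuracies),
    fold_accuracies = core$fold_accuracies,
    folds = core$runs,
    selected_voxels_per_fold = core$selected,
    n_ties = core$n_ties,
    n_samples = nrow(x),
    config = config
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Leave-one-run-out decoding: %s vs %s (%s, %d-voxel cutoff)\n",
              x$config$problem[1], x$config$problem[2], x$config$classifier,
              x$config$n_voxels_cutoff))
  cat(sprintf("  accuracy = %.3f over %d folds (%d samples%s)\n",
              x$accuracy, length(x$fold_accuracies), x$n_samples,
              if (x$n_ties > 0) sprintf(", %d tie(s)", x$n_ties) else ""))
  invisible(x)
}

#' @export
summary.decoding_result <- function(object, ...) {
  cat(sprintf("Problem: %s vs %s\nClassifier: %s\nCutoff: %d voxels\n",
              object$config$problem[1], object$config$problem[2],
              object$config$classifier, object$config$n_voxels_cutoff))
  cat(sprintf("Overall accuracy: %.3f\n", object$accuracy))
  print(data.frame(fold = object$folds,
                   accuracy = object$fold_accuracies))
  invisible(object)
}
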