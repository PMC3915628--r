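# Strictly nested leave-one-out cross-validation, ROC/AUC analysis,
# diagnostic-performance metrics, and 0-1 feature-frequency maps.

#' 2x2 confusion matrix
#'
#' @param predictions predicted class labels.
#' @param truth true class labels (same length and label set).
#' @param positive the label counted as positive (cases).
#' @return an object of class `confusion_matrix` with integer fields `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(predictions, truth, positive) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  universe <- union(unique(truth), positive)
  if (length(universe) > 2) stop("unknown labels: more than two classes")
  if (!all(predictions %in% universe))
    stop("unknown labels in predictions: ",
         paste(setdiff(predictions, universe), collapse = ", "))
  p <- predictions == positive
  t <- truth == positive
  structure(list(tp = sum(p & t), fn = sum(!p & t),
                 fp = sum(p & !t), tn = sum(!p & !t)),
            class = "confusion_matrix")
}

new_confusion <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fn=%d fp=%d tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Diagnostic-performance metrics from a confusion matrix
#'
#' Overall diagnostic accuracy (DA), sensitivity, specificity, positive and
#' negative predictive value, all as percentages. Ratios with a zero
#' denominator are reported as `NA` (not available), never as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return a list of class `diagnostic_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (unrounded percentages).
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    accuracy = 100 * (cm$tp + cm$tn) / n,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn)),
    class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf("DA %s  sens %s  spec %s  PPV %s  NPV %s\n",
              f(x$accuracy), f(x$sensitivity), f(x$specificity),
              f(x$ppv), f(x$npv)))
  invisible(x)
}

#' ROC curve from continuous scores
#'
#' Staircase of (false-positive rate, true-positive rate) points, one per
#' distinct threshold between consecutive sorted scores plus the sentinel
#' endpoints (0,0) and (1,1); a subject is called positive when its score is
#' at or above the threshold.
#'
#' @param scores numeric classifier scores (higher = more patient-like).
#' @param truth true class labels.
#' @param positive label of the positive class.
#' @return a data frame of class `roc_curve` with columns `threshold`,
#'   `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, truth, positive) {
  t <- truth == positive
  if (!any(t) || all(t)) stop("both classes must be present")
  np <- sum(t); nn <- sum(!t)
  if (length(unique(scores)) == 1)
    warning("constant scores: degenerate two-point curve")
  o <- order(scores, decreasing = TRUE)
  ts <- t[o]; ss <- scores[o]
  # collapse tied scores into one threshold step
  last_of_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ts)[last_of_tie]
  fp <- cumsum(!ts)[last_of_tie]
  out <- data.frame(threshold = c(Inf, ss[last_of_tie]),
                    fpr = c(0, fp / nn),
                    tpr = c(0, tp / np))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' By definition equal to the probability that a randomly chosen positive
#' subject outscores a randomly chosen negative subject, with tied scores
#' counted as half-concordant. The `"rank"` method computes that pairwise
#' probability directly (Wilcoxon statistic); `"trapezoid"` integrates the
#' ROC staircase. The two agree exactly and are exposed separately as an
#' internal consistency check.
#'
#' @param scores numeric classifier scores.
#' @param truth true class labels.
#' @param positive label of the positive class.
#' @param method `"rank"` or `"trapezoid"`.
#' @return scalar in `[0, 1]`.
#' @export
auc_score <- function(scores, truth, positive,
                      method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  t <- truth == positive
  if (!any(t) || all(t)) stop("both classes must be present")
  np <- sum(t); nn <- sum(!t)
  if (method == "rank") {
    r <- rank(scores)  # midranks: ties contribute half-concordance
    (sum(r[t]) - np * (np + 1) / 2) / (np * nn)
  } else {
    rc <- suppressWarnings(roc_curve(scores, truth, positive))
    sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
  }
}

#' Score threshold maximizing overall accuracy
#'
#' Exhaustive sweep over all distinct thresholds of the score distribution;
#' the threshold with the highest overall classification accuracy is
#' returned, ties broken toward higher specificity (then toward the higher
#' threshold).
#'
#' @param scores numeric classifier scores.
#' @param truth true class labels.
#' @param positive label of the positive class.
#' @return list with `threshold`, `confusion` (a `confusion_matrix`), and
#'   `report` (a `diagnostic_report`).
#' @export
best_threshold <- function(scores, truth, positive) {
  t <- truth == positive
  if (!any(t) || all(t)) stop("both classes must be present")
  su <- sort(unique(scores))
  cand <- c(su, Inf)  # predict positive when score >= threshold
  best <- NULL
  for (th in cand) {
    p <- scores >= th
    cm <- new_confusion(sum(p & t), sum(!p & t), sum(p & !t), sum(!p & !t))
    rep <- diagnostic_metrics(cm)
    spec <- if (is.na(rep$specificity)) -1 else rep$specificity
    key <- c(rep$accuracy, spec, th)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] &&
         key[3] > best$key[3])) {
      best <- list(threshold = th, confusion = cm, report = rep, key = key)
    }
  }
  best$key <- NULL
  best
}

#' Feature-selection frequency map
#'
#' Per-voxel fraction of cross-validation folds in which a selected regional
#' element covered the voxel — the 0-1 spatial map of how consistently each
#' location contributed to the discriminative pattern.
#'
#' @param fold_selections list (one entry per fold) of lists of selected
#'   elements; each element is either a `regional_element` or a vector of
#'   linear voxel indices.
#' @param shape voxel triple of the map grid.
#' @return 3D array of class `feature_frequency_map` with values in
#'   `[0, 1]`.
#' @export
feature_frequency <- function(fold_selections, shape) {
  if (length(fold_selections) < 1) stop("need at least one fold")
  acc <- numeric(prod(shape))
  for (sel in fold_selections) {
    hit <- logical(prod(shape))
    for (el in sel) {
      idx <- if (inherits(el, "regional_element")) el$voxels else el
      hit[idx] <- TRUE
    }
    acc <- acc + hit
  }
  out <- array(acc / length(fold_selections), shape)
  class(out) <- c("feature_frequency_map", class(out))
  out
}

# One leave-one-out fold: the full adaptive regional feature extraction,
# selection, and training procedure on the training subjects, then a score
# for the held-out subject. Xlist holds full subjects-by-voxels matrices per
# compartment; only `train` rows ever reach a statistic.
compare_fold <- function(Xlist, y, test_i, shape, config) {
  n <- length(y)
  train <- setdiff(seq_len(n), test_i)
  ytr <- y[train]

  cands <- list()
  for (cp in names(Xlist)) {
    Xtr <- Xlist[[cp]][train, , drop = FALSE]
    cc <- compartment_candidates(Xtr, ytr, shape, config)
    for (c1 in cc) { c1$compartment <- cp; cands[[length(cands) + 1L]] <- c1 }
  }
  if (length(cands) == 0) {
    # degenerate fold (all voxels below the floor): fall back to the single
    # most discriminative voxel so a prediction always exists
    peak <- lapply(names(Xlist), function(cp) {
      r <- abs(col_cor(Xlist[[cp]][train, , drop = FALSE], ytr))
      list(compartment = cp, seed = which.max(r), region = which.max(r),
           peak = max(r))
    })
    cands <- peak[order(-vapply(peak, `[[`, numeric(1), "peak"))][1]
  }
  ord <- order(-vapply(cands, `[[`, numeric(1), "peak"),
               vapply(cands, `[[`, numeric(1), "seed"))
  cands <- cands[ord][seq_len(min(length(cands), config$max_candidates))]

  elements <- lapply(cands, function(c1) {
    Xtr <- Xlist[[c1$compartment]][train, , drop = FALSE]
    g <- grow_region_idx(c1$seed, Xtr, ytr, c1$region, shape,
                         config$max_region_voxels)
    el <- new_regional_element(g$voxels, c1$seed,
                               Xlist[[c1$compartment]], y, shape, g$power,
                               compartment = c1$compartment)
    # power and consistency must come from training subjects only
    el$discriminative_power <- g$power
    nbr <- intersect(c(c1$seed, neighbours26(c1$seed, shape)), g$voxels)
    el$consistency <- if (length(nbr) >= 2)
      suppressWarnings(spatial_consistency(Xtr[, nbr, drop = FALSE])) else 0
    el
  })
  # rank by discriminative power, consistency as tie-breaker, then order
  rk <- order(-vapply(elements, `[[`, numeric(1), "discriminative_power"),
              -vapply(elements, `[[`, numeric(1), "consistency"),
              seq_along(elements))
  elements <- elements[rk]

  F_all <- do.call(cbind, lapply(elements, `[[`, "feature_values"))
  Ftr <- F_all[train, , drop = FALSE]
  fs <- select_features(Ftr, ytr, config)
  sel <- fs$selected
  model <- train_svm(Ftr[, sel, drop = FALSE], ytr,
                     gamma = config$gamma, cost = config$cost,
                     class_weights = config$class_weights)
  sc <- classify(model, F_all[test_i, sel, drop = FALSE])
  list(score = as.numeric(sc),
       predicted = attr(sc, "predicted"),
       n_selected = length(sel),
       selected_voxels = lapply(elements[sel], `[[`, "voxels"))
}

#' Leave-one-out cross-validated regional classification
#'
#' For each subject in turn, the entire adaptive regional feature extraction
#' (voxelwise discrimination, watershed partitioning, region growing),
#' feature selection, and SVM training procedure is repeated on the
#' remaining subjects only, and the held-out subject is scored by the
#' resulting classifier — so no held-out subject influences any stage of its
#' own fold. Pooled held-out scores are standardized to Z scores (zero mean,
#' unit variance; positive = patient-like) for ROC analysis.
#'
#' @param cohort a `cohort` from [generate_cohort()] (or any list with
#'   `subjects`, `map_sets`, `spec`).
#' @param positive,negative the two diagnostic groups to compare; `positive`
#'   is the patient class.
#' @param config a [compare_config()].
#' @return an object of class `loocv_result`: per-subject `scores` (Z),
#'   `predicted` and `truth` labels, `accuracy` (proportion), `auc`,
#'   `confusion`, `roc`, per-fold `n_selected`, and the 0-1
#'   `frequency` map.
#' @export
loocv_compare <- function(cohort, positive, negative,
                          config = compare_config()) {
  subj <- cohort$subjects
  keep <- which(subj$group %in% c(positive, negative))
  if (sum(subj$group == positive) < 3 || sum(subj$group == negative) < 3)
    stop("leave-one-out needs at least 3 subjects per class")
  shape <- cohort$spec$volume_shape
  y <- as.numeric(subj$group[keep] == positive)
  Xlist <- lapply(structure(config$compartments, names = config$compartments),
                  function(cp) stack_compartment(cohort, cp, rows = keep))
  n <- length(keep)
  scores <- numeric(n); predicted <- integer(n); nsel <- integer(n)
  selections <- vector("list", n)
  for (i in seq_len(n)) {
    fold <- compare_fold(Xlist, y, i, shape, config)
    scores[i] <- fold$score
    predicted[i] <- fold$predicted
    nsel[i] <- fold$n_selected
    selections[[i]] <- fold$selected_voxels
  }
  z <- if (stats::sd(scores) > 0) (scores - mean(scores)) / stats::sd(scores)
       else { warning("constant scores"); scores * 0 }
  truth_lab <- subj$group[keep]
  pred_lab <- ifelse(predicted == 1, positive, negative)
  cm <- confusion_matrix(pred_lab, truth_lab, positive)
  structure(list(
    subject_id = subj$id[keep],
    scores = z, raw_scores = scores,
    predicted = pred_lab, truth = truth_lab,
    positive = positive, negative = negative,
    accuracy = mean(pred_lab == truth_lab),
    auc = auc_score(z, truth_lab, positive),
    confusion = cm,
    roc = suppressWarnings(roc_curve(z, truth_lab, positive)),
    n_selected = nsel,
    frequency = feature_frequency(selections, shape)),
    class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "<loocv_result> %s vs %s: n=%d, accuracy %.1f%%, AUC %.3f, median features %d\n",
    x$positive, x$negative, length(x$scores), 100 * x$accuracy, x$auc,
    as.integer(stats::median(x$n_selected))))
  invisible(x)
}
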