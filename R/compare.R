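# COMPARE-style adaptive regional feature extraction and RBF-SVM
# classification: voxelwise discriminative ranking, watershed partitioning
# of the discrimination map, spatial-consistency scoring, greedy region
# growing, SVM-criteria feature selection, and Gaussian-kernel SVM.

#' Pipeline configuration for the regional classifier
#'
#' @param watershed_floor voxels with `|r|` below this are background for the
#'   watershed partition (the paper gives no floor; 0.1 keeps candidate
#'   counts at the published scale).
#' @param max_candidates cap on the number of regional candidates carried
#'   into feature selection, taken in decreasing order of seed
#'   discriminative power, pooled across compartments.
#' @param max_region_voxels cap on grown region size (dimensionality
#'   control; the greedy stopping rule usually halts earlier).
#' @param gamma RBF kernel width; `NULL` means `1 / n_features` on
#'   standardized features.
#' @param cost SVM misclassification penalty C.
#' @param class_weights `"balanced"` (inverse class frequency; removes the
#'   majority-class bias that leave-one-out induces in the training folds)
#'   or `"none"`.
#' @param rfe_drop fraction of remaining features eliminated per backward
#'   elimination step.
#' @param cv_folds folds of the internal (training-only) cross-validation
#'   that picks the retained feature-subset size.
#' @param compartments which tissue maps contribute candidate regions.
#' @return a list of class `compare_config`.
#' @export
compare_config <- function(watershed_floor = 0.1,
                           max_candidates = 60,
                           max_region_voxels = 32,
                           gamma = NULL,
                           cost = 1,
                           class_weights = c("balanced", "none"),
                           rfe_drop = 0.25,
                           cv_folds = 5,
                           compartments = c("gm", "wm", "vent")) {
  class_weights <- match.arg(class_weights)
  stopifnot(watershed_floor >= 0, max_candidates >= 1,
            max_region_voxels >= 1, cost > 0,
            rfe_drop > 0, rfe_drop < 1, cv_folds >= 2)
  structure(list(watershed_floor = watershed_floor,
                 max_candidates = max_candidates,
                 max_region_voxels = max_region_voxels,
                 gamma = gamma, cost = cost, class_weights = class_weights,
                 rfe_drop = rfe_drop, cv_folds = cv_folds,
                 compartments = compartments),
            class = "compare_config")
}

check_binary_labels <- function(labels) {
  u <- unique(labels)
  if (length(u) != 2)
    stop("labels must contain exactly two classes")
  if (min(table(labels)) < 2)
    stop("need at least 2 subjects per group")
  invisible(labels)
}

#' Voxelwise discrimination map
#'
#' Per-voxel Pearson correlation between tissue density and 0/1 group
#' membership; `|r|` is the voxel's discriminative power. Voxels with zero
#' variance across subjects score 0 by convention.
#'
#' @param X subjects-by-voxels matrix of density values.
#' @param labels 0/1 group membership vector (or two-level factor).
#' @param shape optional voxel triple; when given the result is a 3D array.
#' @return numeric vector (or 3D array) of correlations in `[-1, 1]`.
#' @export
voxelwise_discrimination <- function(X, labels, shape = NULL) {
  y <- as_binary(labels)
  check_binary_labels(y)
  r <- col_cor(X, y)
  if (!is.null(shape)) r <- array(r, shape)
  r
}

as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (length(u) != 2) stop("labels must contain exactly two classes")
    as.numeric(labels == u[2])
  } else as.numeric(labels != 0)
}

#' Watershed partition of a discrimination map
#'
#' Partitions the voxels whose absolute discriminative score exceeds a floor
#' into catchment basins around local maxima of `|score|`, so that every
#' above-floor voxel belongs to exactly one region and every region contains
#' exactly one marker peak.
#'
#' @param dmap 3D array of voxelwise discrimination scores.
#' @param floor background threshold on `|score|`.
#' @return integer 3D array of region labels (0 = background).
#' @export
watershed_partition <- function(dmap, floor = 0.1) {
  dmap <- map_data(dmap)
  if (!all(is.finite(dmap))) stop("discrimination map must be finite")
  a <- abs(dmap)
  a[a < floor] <- 0
  if (all(a == 0)) {
    warning("all scores below the floor: empty partition")
    return(array(0L, dim(dmap)))
  }
  lab <- EBImage::watershed(a, tolerance = 0, ext = 1)
  array(as.integer(EBImage::imageData(lab)), dim(dmap))
}

#' Spatial consistency of neighbouring candidate features
#'
#' One-way random-effects intraclass correlation, ICC(1,1), over a matrix of
#' per-subject values of spatially adjacent candidate features. High values
#' mean the neighbouring features agree across subjects, i.e. the local
#' discriminative signal is spatially stable rather than a single-voxel
#' artifact.
#'
#' @param values subjects-by-features numeric matrix (>= 2 rows and
#'   columns).
#' @return scalar in `[-1/(k-1), 1]`; degenerate zero-variance input gives 0
#'   with a warning.
#' @export
spatial_consistency <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 features")
  row_m <- rowMeans(values)
  grand <- mean(values)
  msb <- k * sum((row_m - grand)^2) / (n - 1)
  msw <- sum((values - row_m)^2) / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom <= .Machine$double.eps * max(1, grand^2)) {
    warning("zero-variance input: consistency defined as 0")
    return(0)
  }
  (msb - msw) / denom
}

# Greedy growth engine. `region` is an integer vector of admissible linear
# indices (the seed's watershed basin); X is the training density matrix.
grow_region_idx <- function(seed, X, y, region, dm, max_voxels) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  admissible <- logical(prod(dm))
  admissible[region] <- TRUE
  if (!admissible[seed]) stop("seed must lie inside its region")
  member <- logical(prod(dm))
  member[seed] <- TRUE
  members <- seed
  S <- X[, seed]
  cur <- abs(vec_cor(S, yc, sy))
  frontier <- neighbours26(seed, dm)
  frontier <- frontier[admissible[frontier] & !member[frontier]]
  while (length(members) < max_voxels && length(frontier) > 0) {
    Z <- S + X[, frontier, drop = FALSE]
    cm <- .colMeans(Z, n, ncol(Z))
    ss <- .colSums(Z * Z, n, ncol(Z)) - n * cm^2
    num <- as.vector(crossprod(Z, yc))
    rr <- abs(ifelse(ss > n * pmax(cm^2, .Machine$double.eps) * 1e-9,
                     num / (sqrt(pmax(ss, 0)) * sy), 0))
    best <- which.max(rr)
    # neighbours are accepted as long as inclusion does not decrease the
    # regional power (ties accepted: a plateau of uniform effect grows)
    if (rr[best] < cur - 1e-12) break
    v <- frontier[best]
    cur <- rr[best]
    S <- S + X[, v]
    member[v] <- TRUE
    members <- c(members, v)
    nb <- neighbours26(v, dm)
    nb <- nb[admissible[nb] & !member[nb]]
    frontier <- c(frontier[-best], setdiff(nb, frontier))
  }
  list(voxels = members, power = cur)
}

#' Grow a regional element from a watershed seed
#'
#' Greedy accretion over the 26-neighbourhood inside the seed's watershed
#' region: at each step the neighbour that maximizes the discriminative
#' power of the summed regional feature (absolute Pearson correlation with
#' group membership) is added, as long as its inclusion does not decrease
#' that power; growth stops otherwise, so the element's power never falls
#' below the seed's.
#'
#' @param seed voxel coordinate triple (or linear index) of the region's
#'   peak.
#' @param dmap 3D discrimination map (used to delimit the watershed region
#'   when `region` is not supplied).
#' @param X subjects-by-voxels density matrix of the training subjects.
#' @param labels 0/1 group membership of the training subjects.
#' @param region optional integer vector of admissible linear indices.
#' @param floor watershed background floor (when `region` is derived).
#' @param max_voxels growth cap.
#' @return an object of class `regional_element` with fields `voxels`
#'   (linear indices), `seed_voxel`, `feature_values` (per-subject sum of
#'   density over the element), `discriminative_power`, and `consistency`.
#' @export
grow_region <- function(seed, dmap, X, labels, region = NULL, floor = 0.1,
                        max_voxels = 64) {
  dmap <- map_data(dmap)
  dm <- dim(dmap)
  if (length(seed) == 3) {
    if (any(seed < 1) || any(seed > dm)) stop("seed outside grid")
    seed <- seed[1] + (seed[2] - 1) * dm[1] + (seed[3] - 1) * dm[1] * dm[2]
  }
  if (seed < 1 || seed > prod(dm)) stop("seed outside grid")
  y <- as_binary(labels)
  if (is.null(region)) {
    part <- suppressWarnings(watershed_partition(dmap, floor))
    lab <- part[seed]
    region <- if (lab > 0) which(part == lab) else seed
  }
  g <- grow_region_idx(seed, X, y, region, dm, max_voxels)
  new_regional_element(g$voxels, seed, X, y, dm, g$power)
}

new_regional_element <- function(voxels, seed, X, y, dm, power,
                                 compartment = NA_character_) {
  fv <- if (length(voxels) == 1) X[, voxels] else
    rowSums(X[, voxels, drop = FALSE])
  nbr <- intersect(c(seed, neighbours26(seed, dm)), voxels)
  cons <- if (length(nbr) >= 2)
    suppressWarnings(spatial_consistency(X[, nbr, drop = FALSE])) else 0
  structure(list(voxels = voxels, seed_voxel = seed, feature_values = fv,
                 discriminative_power = power, consistency = cons,
                 compartment = compartment),
            class = "regional_element")
}

#' @export
print.regional_element <- function(x, ...) {
  cat(sprintf("<regional_element> %d voxels, power %.3f, consistency %.3f\n",
              length(x$voxels), x$discriminative_power, x$consistency))
  invisible(x)
}

# Extract ranked candidate elements from one compartment matrix.
compartment_candidates <- function(X, y, shape, config) {
  r <- col_cor(X, y)
  a <- abs(r)
  a[a < config$watershed_floor] <- 0
  if (all(a == 0)) return(list())
  lab <- EBImage::watershed(array(a, shape), tolerance = 0, ext = 1)
  lab <- as.integer(EBImage::imageData(lab))
  keep <- lab > 0
  regions <- split(which(keep), lab[keep])
  lapply(regions, function(idx) {
    seed <- idx[which.max(a[idx])]
    list(seed = seed, region = idx, peak = a[seed])
  })
}

# Deterministic stratified fold assignment (subjects of each class dealt
# cyclically, in order).
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    f[i] <- rep_len(seq_len(k), length(i))
  }
  f
}

standardize_train <- function(F) {
  ctr <- colMeans(F)
  scl <- apply(F, 2, stats::sd)
  scl[scl <= 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl,
       data = sweep(sweep(F, 2, ctr), 2, scl, "/"))
}

svm_class_weights <- function(yfac, mode) {
  if (mode == "none") return(NULL)
  tab <- table(yfac)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

fit_svm <- function(Fs, yfac, kernel, gamma, cost, cw) {
  e1071::svm(x = Fs, y = yfac, kernel = kernel, gamma = gamma, cost = cost,
             scale = FALSE, class.weights = cw)
}

# Backward elimination on squared linear-SVM weights; returns candidate
# indices ranked best-first and the subset-size path explored.
svm_rfe_rank <- function(Fs, yfac, cost, drop_frac, cw) {
  p <- ncol(Fs)
  remaining <- seq_len(p)
  elim <- integer(0)      # worst-first elimination order
  sizes <- p
  while (length(remaining) > 1) {
    fit <- fit_svm(Fs[, remaining, drop = FALSE], yfac, "linear",
                   gamma = 1 / length(remaining), cost = cost, cw = cw)
    w <- as.vector(crossprod(fit$coefs, fit$SV))
    crit <- w^2
    ndrop <- max(1L, floor(drop_frac * length(remaining)))
    ndrop <- min(ndrop, length(remaining) - 1L)
    worst <- order(crit, remaining)[seq_len(ndrop)]
    elim <- c(elim, remaining[worst])
    remaining <- remaining[-worst]
    sizes <- c(sizes, length(remaining))
  }
  list(ranking = c(remaining, rev(elim)), sizes = sort(unique(sizes)))
}

#' SVM-criteria feature selection
#'
#' Ranks candidate regional elements by backward elimination on the squared
#' weights of a linear SVM (recursive feature elimination), then retains the
#' top-ranked subset whose size maximizes internal cross-validated accuracy
#' of the Gaussian-RBF classifier on the training subjects only. Fold
#' assignment and tie-breaking (smaller subset wins) are deterministic, so
#' the selection is a pure function of the data and configuration.
#'
#' @param candidates list of `regional_element` objects, or a
#'   subjects-by-features numeric matrix of candidate feature values.
#' @param labels 0/1 group membership of the (training) subjects.
#' @param config a [compare_config()].
#' @return a list of class `feature_set`: `ranking` (candidate indices,
#'   best first), `n_selected`, `selected` (indices of the retained subset),
#'   and `cv_accuracy` (named by subset size).
#' @export
select_features <- function(candidates, labels, config = compare_config()) {
  F <- if (is.list(candidates) && !is.data.frame(candidates) &&
           !is.matrix(candidates)) {
    if (length(candidates) == 0) stop("empty candidate list")
    do.call(cbind, lapply(candidates, function(e) e$feature_values))
  } else {
    as.matrix(candidates)
  }
  if (ncol(F) == 0) stop("empty candidate list")
  y <- as_binary(labels)
  check_binary_labels(y)
  yfac <- factor(ifelse(y == 1, "pos", "neg"), levels = c("pos", "neg"))
  cw <- svm_class_weights(yfac, config$class_weights)
  std <- standardize_train(F)

  if (ncol(F) == 1) {
    fs <- list(ranking = 1L, n_selected = 1L, selected = 1L,
               cv_accuracy = c(`1` = NA_real_))
    class(fs) <- "feature_set"
    return(fs)
  }

  rfe <- svm_rfe_rank(std$data, yfac, config$cost, config$rfe_drop, cw)
  k <- min(config$cv_folds, min(table(y)))
  folds <- stratified_folds(y, k)
  acc <- vapply(rfe$sizes, function(s) {
    sub <- rfe$ranking[seq_len(s)]
    correct <- 0L
    for (fd in seq_len(k)) {
      tr <- folds != fd
      Ftr <- std$data[tr, sub, drop = FALSE]
      if (length(unique(yfac[tr])) < 2) next
      g <- config$gamma %||% (1 / s)
      fit <- fit_svm(Ftr, yfac[tr], "radial", g, config$cost,
                     svm_class_weights(yfac[tr], config$class_weights))
      pr <- stats::predict(fit, std$data[!tr, sub, drop = FALSE])
      correct <- correct + sum(pr == yfac[!tr])
    }
    correct / length(y)
  }, numeric(1))
  names(acc) <- rfe$sizes
  n_sel <- rfe$sizes[which.max(acc)]  # ties: smallest size (sizes ascend)
  fs <- list(ranking = rfe$ranking, n_selected = n_sel,
             selected = rfe$ranking[seq_len(n_sel)], cv_accuracy = acc)
  class(fs) <- "feature_set"
  fs
}

#' Train a Gaussian-RBF support-vector machine
#'
#' Features are standardized with training statistics (frozen into the
#' model), the kernel width defaults to `1 / n_features` on the standardized
#' scale, and classes are weighted inversely to their training frequency by
#' default. The positive (patient) class maps to positive decision values.
#'
#' @param F subjects-by-features numeric matrix of training feature values.
#' @param labels 0/1 group membership (1 = positive/patient class).
#' @param gamma,cost,class_weights see [compare_config()].
#' @return an object of class `trained_svm`.
#' @export
train_svm <- function(F, labels, gamma = NULL, cost = 1,
                      class_weights = c("balanced", "none")) {
  class_weights <- match.arg(class_weights)
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("non-finite features rejected")
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  yfac <- factor(ifelse(y == 1, "pos", "neg"), levels = c("pos", "neg"))
  std <- standardize_train(F)
  g <- gamma %||% (1 / ncol(F))
  cw <- svm_class_weights(yfac, class_weights)
  fit <- fit_svm(std$data, yfac, "radial", g, cost, cw)
  structure(list(svm = fit, center = std$center, scale = std$scale,
                 gamma = g, cost = cost, n_features = ncol(F)),
            class = "trained_svm")
}

#' Classify subjects with a trained SVM
#'
#' Returns the signed decision value of the Gaussian-RBF SVM for each row of
#' `F`; positive means patient-like. Pooled evaluation scores are
#' standardized to Z scores at the cross-validation level (see
#' [loocv_compare()]), not here.
#'
#' @param model a `trained_svm`.
#' @param F feature matrix (or single feature vector) with the model's
#'   feature count.
#' @return numeric vector of signed scores with attribute `"predicted"`
#'   (0/1 labels at the SVM's own threshold of 0).
#' @export
classify <- function(model, F) {
  stopifnot(inherits(model, "trained_svm"))
  if (is.null(dim(F))) F <- matrix(F, nrow = 1)
  F <- as.matrix(F)
  if (ncol(F) != model$n_features)
    stop(sprintf("feature count %d does not match model (%d)",
                 ncol(F), model$n_features))
  Fs <- sweep(sweep(F, 2, model$center), 2, model$scale, "/")
  pr <- stats::predict(model$svm, Fs, decision.values = TRUE)
  dv <- as.vector(attr(pr, "decision.values"))
  # e1071 orients decision values toward the first factor level ("pos");
  # guard against the reversed orientation it uses when the training call
  # happened to see the other level first.
  if (grepl("^neg/", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  structure(dv, predicted = as.integer(dv > 0))
}
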