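test_that("voxelwise discrimination is the per-voxel Pearson correlation", {
  y <- c(1, 1, 0, 0)
  X <- cbind(c(2, 3, 1, 0),   # hand computation: r = 2 / sqrt(5)
             y,               # tracks the labels exactly
             rep(3, 4))       # constant voxel
  r <- voxelwise_discrimination(X, y)
  expect_equal(r[1], 2 / sqrt(5))
  expect_equal(r[2], 1)
  expect_equal(r[3], 0)
  expect_error(voxelwise_discrimination(X, c(1, 1, 1, 1)), "two classes")
  # invariance under a common affine rescale of all densities
  expect_equal(voxelwise_discrimination(3.2 * X + 7, y), r)
  # 3D output when a shape is given
  X8 <- matrix(rnorm(4 * 8), 4)
  expect_equal(dim(voxelwise_discrimination(X8, y, shape = c(2, 2, 2))),
               c(2, 2, 2))
})

test_that("watershed partitions above-floor voxels around their peaks", {
  dm <- c(20, 10, 10)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  bump <- function(c0) 0.9 * exp(-rowSums(sweep(idx, 2, c0)^2) / 6)
  one <- array(bump(c(10, 5, 5)), dm)
  w1 <- watershed_partition(one, floor = 0.1)
  expect_equal(max(w1), 1)

  two <- array(bump(c(4, 5, 5)) + bump(c(16, 5, 5)), dm)
  w2 <- watershed_partition(two, floor = 0.1)
  expect_equal(max(w2), 2)
  expect_true(w2[4, 5, 5] > 0 && w2[16, 5, 5] > 0)
  expect_false(w2[4, 5, 5] == w2[16, 5, 5])

  # partition property: above-floor voxels labelled, background zero
  expect_true(all(w2[abs(two) >= 0.1] > 0))
  expect_true(all(w2[abs(two) < 0.1] == 0))

  expect_warning(w0 <- watershed_partition(array(0, dm)), "empty")
  expect_true(all(w0 == 0))
})

test_that("spatial consistency is ICC(1,1)", {
  v <- cbind(c(1, 5, 3, 2), c(1, 5, 3, 2), c(1, 5, 3, 2))
  expect_equal(spatial_consistency(v), 1)
  expect_equal(spatial_consistency(cbind(c(1, 2), c(1, 2))), 1)
  set.seed(7)
  noise <- matrix(rnorm(200 * 5), 200)
  expect_lt(abs(spatial_consistency(noise)), 0.2)
  expect_warning(z <- spatial_consistency(matrix(1, 4, 3)), "zero-variance")
  expect_equal(z, 0)
  expect_error(spatial_consistency(matrix(1, 1, 3)), "at least 2")
  # anova cross-check: ICC(1,1) from the one-way mean squares
  set.seed(8)
  m <- matrix(rnorm(30), 10, 3) + rnorm(10)
  df <- data.frame(v = as.vector(m), subj = factor(rep(1:10, 3)))
  an <- anova(stats::aov(v ~ subj, df))
  msb <- an$`Mean Sq`[1]; msw <- an$`Mean Sq`[2]
  expect_equal(spatial_consistency(m), (msb - msw) / (msb + 2 * msw))
})

test_that("region growing follows the non-decreasing power rule", {
  dm <- c(7, 7, 7)
  n <- 10
  y <- rep(c(1, 0), each = 5)
  # seed voxel tracks the labels; all neighbours orthogonal to labels and
  # seed, so any inclusion strictly lowers the power: element = {seed}
  set.seed(9)
  X <- matrix(rnorm(n * prod(dm)), n)
  X <- apply(X, 2, function(col) {
    res <- residuals(lm(col ~ y))
    res / sd(res)
  })
  seed_lin <- 4 + 3 * 7 + 3 * 49   # voxel (4,4,4)
  X[, seed_lin] <- y
  dmap <- array(voxelwise_discrimination(X, y), dm)
  el <- grow_region(c(4, 4, 4), dmap, X, y, floor = 0.1)
  expect_equal(el$voxels, seed_lin)
  expect_equal(el$discriminative_power, 1)

  # noiseless 3x3x3 cube of uniform effect: the grown element covers the
  # cube (plateau ties are accepted)
  Xc <- matrix(0, n, prod(dm))
  idx <- arrayInd(seq_len(prod(dm)), dm)
  cube <- which(apply(abs(sweep(idx, 2, c(4, 4, 4))) <= 1, 1, all))
  Xc[, cube] <- matrix(y, n, length(cube))
  dmapc <- array(voxelwise_discrimination(Xc, y), dm)
  elc <- grow_region(c(4, 4, 4), dmapc, Xc, y, floor = 0.1)
  expect_setequal(elc$voxels, cube)

  # stopping-rule invariant on noisy data: power never below the seed's
  set.seed(10)
  Xn <- matrix(rnorm(n * prod(dm)), n)
  dmapn <- array(voxelwise_discrimination(Xn, y), dm)
  seed2 <- which.max(abs(dmapn))
  el2 <- grow_region(arrayInd(seed2, dm)[1, ], dmapn, Xn, y, floor = 0.1)
  expect_gte(el2$discriminative_power, abs(dmapn[seed2]) - 1e-12)
  expect_error(grow_region(c(99, 1, 1), dmapn, Xn, y), "outside|subscript")
})

test_that("SVM-criteria selection ranks a separating feature first", {
  set.seed(11)
  n <- 40
  y <- rep(c(1, 0), each = 20)
  f_sep <- y + rnorm(n, 0, 0.05)
  noise <- matrix(rnorm(n * 20), n)
  fs <- select_features(cbind(f_sep, noise), y)
  expect_equal(fs$ranking[1], 1)
  expect_lte(fs$n_selected, 21)
  expect_true(1 %in% fs$selected)

  # a duplicated best feature still places one copy in the top 2
  fs2 <- select_features(cbind(f_sep, f_sep, noise), y)
  expect_true(any(fs2$ranking[1:2] %in% c(1, 2)))

  expect_error(select_features(list(), y), "empty")
})

test_that("the RBF SVM separates toy problems and honours conventions", {
  # separable pair at large cost
  m <- train_svm(matrix(c(0, 1), 2, 1), c(0, 1), cost = 1e3)
  sc <- classify(m, matrix(c(0, 1), 2, 1))
  expect_equal(attr(sc, "predicted"), c(0L, 1L))
  expect_lt(sc[1], 0); expect_gt(sc[2], 0)

  # XOR needs the nonlinear kernel
  Fx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c(0, 0, 1, 1)
  mx <- train_svm(Fx, yx, gamma = 2, cost = 100)
  expect_equal(attr(classify(mx, Fx), "predicted"), yx)

  # monotone score along the axis from negative to positive class mean,
  # in a linear-like regime (wide kernel relative to the data spread)
  set.seed(12)
  f1 <- c(rnorm(10, 2), rnorm(10, -2))
  y1 <- rep(c(1, 0), each = 10)
  m1 <- train_svm(matrix(f1, ncol = 1), y1, gamma = 0.1, cost = 10)
  sweep_scores <- classify(m1, matrix(seq(-2, 2, length.out = 9), ncol = 1))
  expect_true(all(diff(as.numeric(sweep_scores)) >= -1e-8))

  expect_error(train_svm(matrix(rnorm(4), 2), c(1, 1)), "both classes")
  expect_error(train_svm(matrix(c(0, NA), 2, 1), c(0, 1)), "non-finite")
  expect_error(classify(m, matrix(0, 1, 3)), "feature count")
})
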