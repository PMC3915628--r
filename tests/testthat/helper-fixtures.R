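# Shared fixtures, all generated in code.

# A small cohort on a coarse grid; d = 0 gives a pure-noise cohort.
tiny_cohort <- function(seed = 1, n = 5, d = 0, shape = c(10, 10, 10),
                        fwhm = 8, tbv = TRUE) {
  eff <- if (d != 0)
    list(effect_spec(round(shape / 2), 2, d, "GM")) else list()
  generate_cohort(cohort_spec(n_per_group = c(BD = n, HC = n),
                              volume_shape = shape, effects = eff,
                              smoothing_fwhm = fwhm, tbv_normalize = tbv,
                              seed = seed))
}

random_volume <- function(shape = c(7, 6, 8)) {
  array(stats::runif(prod(shape)), shape)
}

# A smooth random displacement field (each component Gaussian-smoothed
# white noise), small enough to stay well-behaved.
random_smooth_field <- function(shape, amplitude = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  field <- array(0, c(shape, 3))
  for (k in 1:3) {
    comp <- array(stats::rnorm(prod(shape)), shape)
    comp <- smooth_map(comp, fwhm_mm = 4, voxel_size = c(1, 1, 1))
    field[, , , k] <- amplitude * comp / max(abs(comp))
  }
  field
}

# Independent forward mass-splitting oracle: explicit loop over source
# voxels, distributing each voxel's mass over the 8 surrounding target
# voxels by trilinear weights (positions clamped to the grid).
splat_oracle <- function(arr, field) {
  dm <- dim(arr)
  out <- array(0, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    t <- c(i, j, k) + field[i, j, k, ]
    t <- pmin(pmax(t, 1), dm)
    lo <- pmin(floor(t), dm - 1)
    fr <- t - lo
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      idx <- lo + c(dx, dy, dz)
      out[idx[1], idx[2], idx[3]] <- out[idx[1], idx[2], idx[3]] +
        w * arr[i, j, k]
    }
  }
  out
}
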