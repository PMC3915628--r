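#' Tissue-density map
#'
#' A 3D grid of non-negative tissue amount per voxel in template space
#' (RAVENS-style map). Values are "density units": the amount of tissue from
#' the subject's image that was mapped into each template voxel, so that
#' regional sums are volumetric measurements and total mass is meaningful.
#'
#' @param data 3D numeric array, all values finite and `>= 0`.
#' @param compartment one of `"GM"`, `"WM"`, `"CSF"`, `"VENT"`.
#' @param voxel_size numeric triple, voxel edge lengths in mm.
#' @return an object of class `density_map`.
#' @export
density_map <- function(data, compartment = c("GM", "WM", "CSF", "VENT"),
                        voxel_size = c(1, 1, 1)) {
  compartment <- match.arg(compartment)
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("density values must be finite")
  if (any(data < 0))
    stop("density values must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(data = data, compartment = compartment,
                 voxel_size = voxel_size),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s  %s voxels  %.3g density units total\n",
              x$compartment, paste(dim(x$data), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

# Accept either a density_map or a bare 3D array.
map_data <- function(x) if (inherits(x, "density_map")) x$data else x

rewrap_map <- function(template, data) {
  if (inherits(template, "density_map"))
    density_map(data, template$compartment, template$voxel_size)
  else data
}

#' Per-subject set of tissue-density maps
#'
#' Bundles the grey-matter, white-matter and ventricular maps of one subject
#' on a common grid, together with the subject's total brain volume (the sum
#' of all brain-tissue and cerebrospinal-fluid voxels), which is the
#' normalization denominator.
#'
#' @param gm,wm,vent `density_map` objects (or 3D arrays) on one grid.
#' @param total_brain_volume positive scalar; if `NULL`, the sum of the three
#'   supplied maps is used (appropriate when the ventricular map stands in
#'   for the full CSF compartment).
#' @param voxel_size voxel edge lengths in mm (taken from `gm` when it is a
#'   `density_map`).
#' @return an object of class `tissue_map_set`.
#' @export
tissue_map_set <- function(gm, wm, vent, total_brain_volume = NULL,
                           voxel_size = NULL) {
  vs <- voxel_size %||% (if (inherits(gm, "density_map")) gm$voxel_size else c(1, 1, 1))
  g <- map_data(gm); w <- map_data(wm); v <- map_data(vent)
  if (!identical(dim(g), dim(w)) || !identical(dim(g), dim(v)))
    stop("gm, wm and vent maps must share one grid")
  tbv <- total_brain_volume %||% (sum(g) + sum(w) + sum(v))
  if (!is.finite(tbv) || tbv <= 0) stop("total_brain_volume must be > 0")
  structure(list(gm = density_map(g, "GM", vs),
                 wm = density_map(w, "WM", vs),
                 vent = density_map(v, "VENT", vs),
                 total_brain_volume = tbv),
            class = "tissue_map_set")
}

#' @export
print.tissue_map_set <- function(x, ...) {
  cat(sprintf("<tissue_map_set> %s voxels, TBV = %.4g\n",
              paste(dim(x$gm$data), collapse = "x"), x$total_brain_volume))
  invisible(x)
}

#' Convert a Gaussian FWHM in mm to a kernel sigma in voxels
#'
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_mm voxel edge length along the axis, in mm.
#' @return sigma in voxel units: `fwhm / (2 sqrt(2 ln 2)) / voxel`.
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}

# 1D Gaussian smoothing matrix, column-normalized so every source voxel's
# mass is fully redistributed: sum(K %*% x) == sum(x) exactly, which is the
# boundary rule that preserves the defining property of the maps.
smoothing_matrix <- function(n, sigma_vox) {
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma_vox^2))
  sweep(K, 2, colSums(K), "/")
}

apply_along_axis <- function(arr, ax, K) {
  dm <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = dm[ax])
  aperm(array(K %*% m, dm[perm]), order(perm))
}

gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size) {
  if (fwhm_mm == 0) return(arr)
  for (ax in 1:3) {
    sig <- fwhm_to_sigma(fwhm_mm, voxel_size[ax])
    arr <- apply_along_axis(arr, ax, smoothing_matrix(dim(arr)[ax], sig))
  }
  arr
}

#' Smooth a density map with a mass-conserving Gaussian kernel
#'
#' Separable Gaussian blur with per-axis sigma `fwhm/(2 sqrt(2 ln 2))`
#' converted from mm to voxels. At the volume edges the truncated kernel is
#' renormalized (each source voxel redistributes all of its mass to in-bounds
#' voxels), so the total tissue amount is conserved exactly.
#'
#' @param map a `density_map` or 3D array.
#' @param fwhm_mm kernel full width at half maximum in mm; `0` is the
#'   identity.
#' @param voxel_size voxel size in mm (ignored when `map` carries its own).
#' @return smoothed map of the same class as the input.
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  vs <- if (inherits(map, "density_map")) map$voxel_size else as.numeric(voxel_size)
  rewrap_map(map, gaussian_smooth_3d(map_data(map), fwhm_mm, vs))
}

#' Mass-preserving warp of a density map
#'
#' Applies a deformation field by forward mass splatting: every source
#' voxel's tissue amount is moved to its target position (source position
#' plus displacement, clamped to the grid) and distributed over the 8
#' surrounding target voxels with trilinear weights. Mass is conserved
#' exactly by construction; where the field compresses space, density rises,
#' and where it expands space, density falls.
#'
#' @param source a `density_map` or 3D array.
#' @param field a 4D array of voxel displacements, `dim = c(dim(source), 3)`,
#'   mapping each source voxel to template space.
#' @return warped map of the same class as `source`.
#' @export
mass_preserving_warp <- function(source, field) {
  arr <- map_data(source)
  dm <- dim(arr)
  if (any(dm < 2)) stop("warp requires at least 2 voxels per axis")
  if (!is.array(field) || length(dim(field)) != 4 ||
      !identical(dim(field)[1:3], dm) || dim(field)[4] != 3)
    stop("`field` must have dim c(dim(source), 3)")
  if (!all(is.finite(field))) stop("non-finite displacements rejected")

  co <- arrayInd(seq_len(prod(dm)), dm)
  tx <- pmin(pmax(co[, 1] + as.vector(field[, , , 1]), 1), dm[1])
  ty <- pmin(pmax(co[, 2] + as.vector(field[, , , 2]), 1), dm[2])
  tz <- pmin(pmax(co[, 3] + as.vector(field[, , , 3]), 1), dm[3])
  x0 <- pmin(floor(tx), dm[1] - 1); fx <- tx - x0
  y0 <- pmin(floor(ty), dm[2] - 1); fy <- ty - y0
  z0 <- pmin(floor(tz), dm[3] - 1); fz <- tz - z0

  v <- as.vector(arr)
  out <- numeric(prod(dm))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) *
      (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    li <- (x0 + dx) + (y0 + dy - 1) * dm[1] + (z0 + dz - 1) * dm[1] * dm[2]
    acc <- rowsum(w * v, li)
    out[as.integer(rownames(acc))] <- out[as.integer(rownames(acc))] + acc[, 1]
  }
  rewrap_map(source, array(out, dm))
}

#' Normalize a map set by total brain volume
#'
#' Scales all compartments of a subject by one common factor so that the
#' post-scaling total brain volume equals `reference`. Ratios between
#' compartments (and hence all correlation-based statistics downstream) are
#' unchanged; with the default reference of 1 the maps become fractions of
#' the subject's brain volume, which removes global head-size differences.
#'
#' @param maps a `tissue_map_set`.
#' @param reference positive scalar target total brain volume.
#' @return a `tissue_map_set` with `total_brain_volume == reference`.
#' @export
normalize_tbv <- function(maps, reference = 1) {
  stopifnot(inherits(maps, "tissue_map_set"))
  if (!is.finite(reference) || reference <= 0) stop("reference must be > 0")
  if (maps$total_brain_volume <= 0) stop("total brain volume must be > 0")
  f <- reference / maps$total_brain_volume
  tissue_map_set(rewrap_map(maps$gm, maps$gm$data * f),
                 rewrap_map(maps$wm, maps$wm$data * f),
                 rewrap_map(maps$vent, maps$vent$data * f),
                 total_brain_volume = reference)
}

#' Isolate the cerebral ventricles from a CSF map
#'
#' Intersects a CSF density map with a template-space ventricular mask
#' (lateral and third ventricles): the output equals the input inside the
#' mask and is zero elsewhere.
#'
#' @param csf a `density_map` or 3D array of CSF density.
#' @param ventricle_mask logical (or 0/1) array on the same grid.
#' @return ventricular map of the same class as `csf`.
#' @export
isolate_ventricles <- function(csf, ventricle_mask) {
  arr <- map_data(csf)
  msk <- map_data(ventricle_mask)
  if (!identical(dim(arr), dim(msk)))
    stop("mask grid does not match the CSF map")
  out <- arr * (msk != 0)
  if (inherits(csf, "density_map"))
    density_map(out, "VENT", csf$voxel_size)
  else out
}
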