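# Synthetic case-control cohorts: demographics drawn from the published
# group marginals, per-subject tissue-density phantoms with optional planted
# group effects, and hierarchical matched-control selection.

# Published group marginals used as sampling defaults: age mean/SD (years,
# truncated to the 18-50 inclusion window), proportion male, proportion
# right-handed. The HC row pools the two matched control subsamples
# (n = 33 and n = 38).
demographic_profiles <- data.frame(
  group = c("BD", "MDD", "HC"),
  age_mean = c(27.09, 29.05, 28.68),
  age_sd = c(8.87, 8.34, 7.30),
  p_male = c(9 / 23, 4 / 19, 21 / 71),
  p_right = c(23 / 23, 16 / 19, 67 / 71),
  stringsAsFactors = FALSE
)

#' Specification of one planted morphometric effect
#'
#' A localized group difference: an additive mean shift of
#' `effect_size * noise_sd` density units applied, before smoothing, to every
#' voxel of one tissue compartment inside a sphere, for all subjects of the
#' target group. This is the simplest model of a focal volumetric
#' abnormality.
#'
#' @param center voxel coordinate triple of the sphere center.
#' @param radius sphere radius in voxels, `>= 1`.
#' @param effect_size standardized mean difference (Cohen's d) of the shift
#'   relative to the per-voxel noise SD; may be negative (atrophy).
#' @param compartment which map carries the effect: `"GM"`, `"WM"` or
#'   `"VENT"`.
#' @param group diagnostic group that carries the effect; `NULL` means the
#'   first group of the cohort specification.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(center, radius, effect_size,
                        compartment = c("GM", "WM", "VENT"), group = NULL) {
  compartment <- match.arg(compartment)
  center <- as.numeric(center)
  stopifnot(length(center) == 3, radius >= 1, is.finite(effect_size))
  structure(list(center = center, radius = radius,
                 effect_size = effect_size, compartment = compartment,
                 group = group),
            class = "effect_spec")
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group named integer vector of group sizes, names among
#'   `"BD"`, `"MDD"`, `"HC"`; at least 2 subjects per group.
#' @param volume_shape voxel triple, at least 8 voxels per axis.
#' @param voxel_size voxel edge lengths in mm.
#' @param effects list of [effect_spec()] objects; empty means a null cohort.
#' @param noise_sd per-voxel subject noise SD in density units, `> 0`.
#' @param smoothing_fwhm Gaussian kernel FWHM in mm applied to the maps
#'   (`0` disables smoothing).
#' @param scanner1_fraction probability that a subject was acquired on
#'   scanner 1.
#' @param tbv_normalize scale each subject's maps to unit total brain volume.
#' @param seed integer driving every stochastic draw of the generator.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(BD = 23, HC = 33),
                        volume_shape = c(16, 16, 16),
                        voxel_size = c(2, 2, 2),
                        effects = list(),
                        noise_sd = 1,
                        smoothing_fwhm = 8,
                        scanner1_fraction = 0.55,
                        tbv_normalize = TRUE,
                        seed = 1) {
  n_per_group <- unlist(n_per_group)
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% demographic_profiles$group))
    stop("n_per_group must be named with groups among BD, MDD, HC")
  if (any(n_per_group < 2)) stop("at least 2 subjects per group")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 8))
    stop("degenerate volume shape: need >= 8 voxels per axis")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (smoothing_fwhm < 0) stop("smoothing_fwhm must be >= 0")
  if (scanner1_fraction < 0 || scanner1_fraction > 1)
    stop("scanner1_fraction must be in [0, 1]")
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (any(e$center - e$radius < 1) ||
        any(e$center + e$radius > volume_shape))
      stop("effect region does not fit within the volume bounds")
    if (!is.null(e$group) && !e$group %in% names(n_per_group))
      stop("effect group not present in n_per_group")
  }
  structure(list(n_per_group = n_per_group, volume_shape = volume_shape,
                 voxel_size = as.numeric(voxel_size), effects = effects,
                 noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
                 scanner1_fraction = scanner1_fraction,
                 tbv_normalize = tbv_normalize, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Smooth radial template profiles for the three generated compartments plus
# the ventricular mask, on a brain-sphere phantom that fills the grid.
phantom_templates <- function(shape) {
  c0 <- (shape + 1) / 2
  scale <- min(shape) / 16  # profiles defined on a 16-voxel reference grid
  co <- arrayInd(seq_len(prod(shape)), shape)
  d <- sqrt((co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2 +
              (co[, 3] - c0[3])^2) / scale
  gm <- 10 * exp(-0.5 * ((d - 4.5) / 1.5)^2)
  wm <- 10 * exp(-0.5 * (d / 2.5)^2)
  csf <- 6 * exp(-0.5 * ((d - 6.5) / 1.0)^2) + 8 * exp(-0.5 * (d / 1.2)^2)
  brain <- d <= 7.5
  vent <- d <= 2
  list(gm = array(gm, shape), wm = array(wm, shape),
       csf = array(csf, shape), brain = array(brain, shape),
       vent_mask = array(vent, shape))
}

#' Ventricular template mask of the synthetic phantom
#'
#' @param shape voxel triple.
#' @return logical 3D array marking the phantom's ventricular compartment.
#' @export
ventricle_template_mask <- function(shape) {
  phantom_templates(as.integer(shape))$vent_mask
}

#' Generate a seeded synthetic cohort
#'
#' Draws a subject table (age truncated-normal, gender/handedness/scanner
#' Bernoulli, with the published group marginals as defaults) and per-subject
#' grey-matter, white-matter and ventricular density maps on a common
#' template grid. Maps are a fixed smooth phantom plus i.i.d. per-voxel
#' Gaussian noise inside the brain mask; planted effects add
#' `effect_size * noise_sd` inside their sphere for subjects of the target
#' group before smoothing. Negative densities are clamped to zero, then each
#' subject is (optionally) normalized to unit total brain volume and
#' smoothed. One seed drives all draws, so identical specifications yield
#' bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: a list with `subjects` (data frame
#'   with columns id, group, age, gender, handedness, scanner), `map_sets`
#'   (list of [tissue_map_set()] per subject, in table order), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- phantom_templates(spec$volume_shape)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)

  with_seed(spec$seed, {
    prof <- demographic_profiles[match(groups, demographic_profiles$group), ]
    age <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- stats::rnorm(1, prof$age_mean[i], prof$age_sd[i])
        if (a >= 18 && a <= 50) break
      }
      age[i] <- a
    }
    gender <- ifelse(stats::runif(n) < prof$p_male, "M", "F")
    handed <- ifelse(stats::runif(n) < prof$p_right, "right", "left")
    scanner <- ifelse(stats::runif(n) < spec$scanner1_fraction, "S1", "S2")
    subjects <- data.frame(
      id = sprintf("%s%03d", groups, stats::ave(seq_len(n), groups,
                                                FUN = seq_along)),
      group = groups, age = age, gender = gender, handedness = handed,
      scanner = scanner, stringsAsFactors = FALSE)

    effect_delta <- lapply(c(gm = "GM", wm = "WM", vent = "VENT"), function(cp) {
      out <- list()
      for (e in spec$effects) {
        if (e$compartment != cp) next
        g <- e$group %||% names(spec$n_per_group)[1]
        co <- arrayInd(seq_len(prod(spec$volume_shape)), spec$volume_shape)
        inside <- (co[, 1] - e$center[1])^2 + (co[, 2] - e$center[2])^2 +
          (co[, 3] - e$center[3])^2 <= e$radius^2
        out[[length(out) + 1L]] <- list(
          group = g,
          delta = array(inside * e$effect_size * spec$noise_sd,
                        spec$volume_shape))
      }
      out
    })

    nb <- sum(tpl$brain)
    map_sets <- vector("list", n)
    for (i in seq_len(n)) {
      comp <- list(gm = tpl$gm, wm = tpl$wm, csf = tpl$csf)
      for (cp in names(comp)) {
        noise <- array(0, spec$volume_shape)
        noise[tpl$brain] <- stats::rnorm(nb, 0, spec$noise_sd)
        comp[[cp]] <- comp[[cp]] + noise
        key <- if (cp == "csf") "vent" else cp
        for (ef in effect_delta[[key]])
          if (ef$group == groups[i]) comp[[cp]] <- comp[[cp]] + ef$delta
        comp[[cp]][comp[[cp]] < 0] <- 0
      }
      vent <- comp$csf * tpl$vent_mask
      tbv <- sum(comp$gm) + sum(comp$wm) + sum(comp$csf)
      ms <- tissue_map_set(
        density_map(comp$gm, "GM", spec$voxel_size),
        density_map(comp$wm, "WM", spec$voxel_size),
        density_map(vent, "VENT", spec$voxel_size),
        total_brain_volume = tbv, voxel_size = spec$voxel_size)
      if (spec$tbv_normalize) ms <- normalize_tbv(ms, 1)
      if (spec$smoothing_fwhm > 0) {
        ms <- tissue_map_set(
          smooth_map(ms$gm, spec$smoothing_fwhm),
          smooth_map(ms$wm, spec$smoothing_fwhm),
          smooth_map(ms$vent, spec$smoothing_fwhm),
          total_brain_volume = ms$total_brain_volume,
          voxel_size = spec$voxel_size)
      }
      map_sets[[i]] <- ms
    }
    structure(list(subjects = subjects, map_sets = map_sets, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<cohort> %d subjects (%s), %s voxel maps\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              paste(x$spec$volume_shape, collapse = "x")))
  invisible(x)
}

# Stack one compartment of a cohort as a subjects-by-voxels matrix.
stack_compartment <- function(cohort, compartment = c("gm", "wm", "vent"),
                              rows = NULL) {
  compartment <- match.arg(compartment)
  rows <- rows %||% seq_along(cohort$map_sets)
  t(vapply(cohort$map_sets[rows],
           function(ms) as.vector(ms[[compartment]]$data),
           numeric(prod(cohort$spec$volume_shape))))
}

#' Hierarchical matched-control selection
#'
#' Selects controls for a set of cases from a pool, respecting the
#' hierarchical matching rank: gender first, then age within a 2-year range,
#' then handedness. Every candidate is scored against each case at one of
#' three levels (gender + age + handedness > gender + age > gender only;
#' candidates of the wrong gender are never taken), and cases draw their best
#' remaining candidate in round-robin order so that as many controls as
#' possible are accumulated, up to `max_controls` in total. Ties within a
#' level are broken by the smallest absolute age difference, then by the
#' lowest pool index; no control is selected twice.
#'
#' @param cases data frame with columns `gender`, `age`, `handedness` (one
#'   row per case).
#' @param pool data frame of candidate controls with the same columns,
#'   disjoint from `cases`.
#' @param max_controls maximum total number of controls to select.
#' @return the selected rows of `pool` (possibly empty).
#' @export
match_controls <- function(cases, pool, max_controls = nrow(pool)) {
  stopifnot(is.data.frame(cases), is.data.frame(pool))
  if (max_controls <= 0) return(pool[0, , drop = FALSE])
  if (nrow(pool) == 0) {
    warning("empty control pool: no controls selected")
    return(pool)
  }
  taken <- logical(nrow(pool))
  picked <- integer(0)
  for (level in 3:1) {
    repeat {
      if (length(picked) >= max_controls) break
      advanced <- FALSE
      for (ci in seq_len(nrow(cases))) {
        if (length(picked) >= max_controls) break
        ok <- !taken & pool$gender == cases$gender[ci]
        if (level >= 2) ok <- ok & abs(pool$age - cases$age[ci]) <= 2
        if (level >= 3) ok <- ok & pool$handedness == cases$handedness[ci]
        if (!any(ok)) next
        cand <- which(ok)
        d <- abs(pool$age[cand] - cases$age[ci])
        best <- cand[order(d, cand)][1]
        taken[best] <- TRUE
        picked <- c(picked, best)
        advanced <- TRUE
      }
      if (!advanced) break
    }
  }
  pool[picked, , drop = FALSE]
}
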