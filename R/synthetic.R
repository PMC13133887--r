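#' Menger sponge phantom
#'
#' Deterministic level-`level` Menger sponge on a `3^level` cube: a voxel is
#' retained iff at no recursion depth do at least two of its three base-3
#' digits equal 1. Voxel count is exactly `20^level`; box counts at scales
#' `3^j` are exactly `20^(level-j)`, so the fitted FD is `log(20)/log(3)`.
#'
#' @param level Positive integer <= 5.
#' @return Binary 3D array of edge `3^level`.
#' @export
menger_sponge <- function(level) {
  stopifnot(level >= 1, level <= 5, level == round(level))
  n <- 3^level
  idx <- 0:(n - 1)
  digit1 <- matrix(TRUE, n, level)  # base-3 digit of the coordinate == 1
  for (l in seq_len(level)) digit1[, l] <- ((idx %/% 3^(l - 1)) %% 3) == 1
  # voxel removed if at any depth >= 2 of the axis digits are 1
  m <- array(TRUE, dim = c(n, n, n))
  for (l in seq_len(level)) {
    dx <- digit1[, l]
    hit <- outer(outer(dx + 0, dx + 0, "+"), dx + 0, "+") >= 2
    m <- m & !hit
  }
  m + 0L
}

#' Random Cantor dust in 3D
#'
#' Recursively subdivides a cube into 27 subcubes and retains each
#' independently with probability `p`, for `levels` generations. The expected
#' box-counting dimension is `log(27 p) / log(3)` (valid for `p > 1/27`).
#' Deterministic for a fixed seed.
#'
#' @param p Retention probability, `1/27 < p <= 1`.
#' @param levels Number of subdivision levels (grid edge `3^levels`).
#' @param seed Integer RNG seed.
#' @return Binary 3D array of edge `3^levels`.
#' @export
random_cantor_3d <- function(p, levels, seed) {
  stopifnot(p > 1 / 27, p <= 1, levels >= 1, levels <= 5)
  n <- 3^levels
  set.seed(as.integer(seed))
  m <- array(1L, dim = c(n, n, n))
  for (l in seq_len(levels)) {
    sub <- n %/% (3^l)        # subcube edge at this level
    nblk <- 3^l
    keep <- array(stats::runif(nblk^3) < p, dim = c(nblk, nblk, nblk))
    # expand keep to voxel grid
    rep_idx <- rep(seq_len(nblk), each = sub)
    m <- m * (keep[rep_idx, rep_idx, rep_idx] + 0L)
  }
  m
}

#' Smoothed Gaussian noise field (marbling texture)
#'
#' @keywords internal
smoothed_noise <- function(dims, cluster_mm, spacing) {
  noise <- array(stats::rnorm(prod(dims)), dim = dims)
  if (cluster_mm > 0) {
    v <- ct_volume(noise, spacing = spacing)
    noise <- gaussian_smooth(v, cluster_mm)$data
  }
  noise
}

#' Synthetic CT leg phantom with ground-truth tissue masks
#'
#' Builds two parallel cylinders ("legs") on one isotropic grid. Each leg has
#' an outer subcutaneous-fat annulus, a muscle core, and IMAT marbling inside
#' the core obtained by thresholding a smoothed Gaussian noise field so that
#' an `imat_fraction` share of core voxels becomes fat. `cluster_mm` sets the
#' correlation length of the marbling: larger values give coarser, more
#' clustered fat strands. HU values: SAT and IMAT ~ N(-100, hu_noise_sd),
#' muscle ~ N(50, hu_noise_sd), background air -1000; `hu_noise_sd = 0`
#' gives exact tissue HU values.
#'
#' @param radius_vox Outer cylinder radius in voxels (default 20; large
#'   enough that each leg's bounding box supports four box-counting scales).
#' @param muscle_radius_vox Muscle-core radius in voxels (default 15).
#' @param length_vox Cylinder length along the third axis (default 40).
#' @param gap_vox Gap between the legs along the first axis (default 6).
#' @param imat_fraction Target IMAT share of the muscle core (default 0.2).
#' @param cluster_mm Marbling correlation length in mm (default 2).
#' @param hu_noise_sd HU noise standard deviation (default 10).
#' @param spacing_mm Isotropic voxel spacing in mm (default 1).
#' @param seed Integer RNG seed.
#' @return List with `volume` (a [ct_volume]), `masks` (ground-truth
#'   [tissue_mask_set] for the whole grid), `muscle_compartment` and
#'   `subcut_compartment` (binary arrays, the anatomical compartments).
#' @export
leg_phantom <- function(radius_vox = 20, muscle_radius_vox = 15,
                        length_vox = 40, gap_vox = 6,
                        imat_fraction = 0.2, cluster_mm = 2,
                        hu_noise_sd = 10, spacing_mm = 1, seed = 1) {
  stopifnot(muscle_radius_vox < radius_vox, radius_vox >= 4,
            imat_fraction >= 0, imat_fraction < 1, length_vox >= 8)
  set.seed(as.integer(seed))
  dia <- 2 * radius_vox + 1
  nx <- 2 * dia + gap_vox + 4
  ny <- dia + 4
  nz <- length_vox
  spacing <- rep(spacing_mm, 3)
  cy <- (ny + 1) / 2
  cx1 <- 2 + radius_vox + 0.5
  cx2 <- nx - 1 - radius_vox - 0.5

  xg <- array(rep(seq_len(nx), times = ny * nz), dim = c(nx, ny, nz))
  yg <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = c(nx, ny, nz))
  r1 <- sqrt((xg - cx1)^2 + (yg - cy)^2)
  r2 <- sqrt((xg - cx2)^2 + (yg - cy)^2)
  outer_m <- (r1 <= radius_vox) | (r2 <= radius_vox)
  core <- (r1 <= muscle_radius_vox) | (r2 <= muscle_radius_vox)
  sat <- outer_m & !core

  # IMAT marbling inside the core: threshold a smoothed noise field at the
  # core-wide quantile giving the requested fat fraction
  imat <- array(FALSE, dim = c(nx, ny, nz))
  if (imat_fraction > 0) {
    field <- smoothed_noise(c(nx, ny, nz), cluster_mm, spacing)
    thr <- stats::quantile(field[core], probs = 1 - imat_fraction,
                           names = FALSE, type = 7)
    imat <- core & (field > thr)
  }
  sm <- core & !imat

  hu <- array(-1000, dim = c(nx, ny, nz))
  nvox <- prod(c(nx, ny, nz))
  noise <- if (hu_noise_sd > 0) array(stats::rnorm(nvox, 0, hu_noise_sd),
                                      dim = c(nx, ny, nz)) else 0
  hu[sat] <- -100; hu[imat] <- -100; hu[sm] <- 50
  hu <- hu + noise * (outer_m + 0)

  list(
    volume = ct_volume(hu, spacing = spacing),
    masks = tissue_mask_set(sm + 0L, sat + 0L, imat + 0L, spacing = spacing,
                            provenance = list(kind = "leg_phantom",
                                              seed = seed,
                                              imat_fraction = imat_fraction,
                                              cluster_mm = cluster_mm)),
    muscle_compartment = core + 0L,
    subcut_compartment = sat + 0L
  )
}

#' Default synthetic-cohort scenario
#'
#' Scenario parameters for [synth_cohort()]: group means/SDs for the clinical
#' and radiological variables (values chosen to resemble a two-group
#' metabolic-syndrome screening cohort; they are scenario parameters, not
#' data) and the true per-SD log-odds coefficients of the generative
#' diagnostic model. By default only triglyceride, diabetes history, IMR,
#' IMAT FD and IMAT multifractal range carry signal.
#'
#' @param n Number of subjects (default 184).
#' @return A list with `n`, `continuous` (data.frame name/mean/sd), `binary`
#'   (data.frame name/prevalence), `beta` (named per-SD coefficients) and
#'   `intercept`.
#' @export
default_cohort_spec <- function(n = 184) {
  continuous <- data.frame(
    name = c("age", "weight_kg", "height_m", "bmi", "waist_cm", "hdl_c",
             "triglyceride", "total_cholesterol",
             "smi", "sati", "imati", "imr", "isr", "msr",
             "sm_fd", "sm_lacunarity", "sm_mfr",
             "sat_fd", "sat_lacunarity", "sat_mfr",
             "imat_fd", "imat_lacunarity", "imat_mfr"),
    mean = c(62, 64, 1.64, 23.7, 84.6, 0.99, 1.74, 4.03,
             2635, 2170, 421, 0.19, 0.23, 1.51,
             1.48, 11.9, 0.33, 1.37, 16.5, 0.31, 1.15, 39.5, 0.20),
    sd = c(12, 11, 0.08, 4.1, 10.5, 0.30, 1.05, 1.08,
           650, 945, 176, 0.075, 0.15, 0.97,
           0.048, 3.0, 0.09, 0.076, 5.4, 0.077, 0.058, 5.6, 0.042)
  )
  binary <- data.frame(
    name = c("sex_male", "diabetes", "hypertension", "smoking", "alcohol"),
    prevalence = c(0.60, 0.57, 0.52, 0.32, 0.21)
  )
  beta <- c(triglyceride = log(2.136), diabetes = log(7.774),
            imr = log(1.927), imat_fd = log(3.100), imat_mfr = log(3.613))
  list(n = n, continuous = continuous, binary = binary,
       beta = beta, intercept = 0)
}

#' Generate a synthetic subject cohort with a known diagnostic model
#'
#' Draws continuous covariates as independent normals with the scenario
#' means/SDs and binary covariates as Bernoulli with the scenario
#' prevalences, then draws the outcome from
#' `Bernoulli(plogis(intercept + sum(beta * z)))` where `z` are the
#' covariates standardized by the scenario means/SDs (binary covariates
#' enter unstandardized). All generative parameters are recorded in the
#' `generator` attribute of the returned table.
#'
#' @param spec A scenario list as from [default_cohort_spec()].
#' @param seed Integer RNG seed.
#' @return A data.frame with one row per subject (`subject_id`, covariates,
#'   `mets_label`); attribute `generator` carries the spec and seed.
#' @export
synth_cohort <- function(spec = default_cohort_spec(), seed = 1) {
  stopifnot(all(spec$continuous$sd > 0),
            all(spec$binary$prevalence >= 0 & spec$binary$prevalence <= 1))
  set.seed(as.integer(seed))
  n <- spec$n
  tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)))
  for (i in seq_len(nrow(spec$continuous)))
    tab[[spec$continuous$name[i]]] <-
      stats::rnorm(n, spec$continuous$mean[i], spec$continuous$sd[i])
  for (i in seq_len(nrow(spec$binary)))
    tab[[spec$binary$name[i]]] <-
      as.integer(stats::runif(n) < spec$binary$prevalence[i])
  lp <- rep(spec$intercept, n)
  for (v in names(spec$beta)) {
    if (!v %in% names(tab)) stop("beta names a variable not generated: ", v)
    i <- match(v, spec$continuous$name)
    z <- if (!is.na(i)) {
      (tab[[v]] - spec$continuous$mean[i]) / spec$continuous$sd[i]
    } else tab[[v]]
    lp <- lp + spec$beta[[v]] * z
  }
  tab$mets_label <- as.integer(stats::runif(n) < stats::plogis(lp))
  attr(tab, "generator") <- list(spec = spec, seed = seed)
  tab
}
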