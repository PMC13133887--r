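#' Default box-size ladder for a mask shape
#'
#' Powers of 2 from 1 up to `floor(min(shape) / 4)`, so that even the largest
#' box tiles the shortest axis at least four times. At least four sizes are
#' required (two >= 2-point half-fits for the multifractal range), which
#' implies a minimum dimension of 32.
#'
#' @param mask_shape Integer length-3 vector of mask dimensions.
#' @return Ascending integer vector of box edge lengths (voxels).
#' @export
default_box_sizes <- function(mask_shape) {
  mask_shape <- as.integer(mask_shape)
  stopifnot(length(mask_shape) == 3L, all(mask_shape >= 1L))
  if (min(mask_shape) < 8L)
    stop("mask too small for box counting: min dimension ", min(mask_shape))
  emax <- floor(min(mask_shape) / 4)
  sizes <- 2^(0:floor(log2(emax)))
  if (length(sizes) < 4L)
    stop("mask supports only ", length(sizes),
         " box sizes; >= 4 needed (min dimension >= 32)")
  as.integer(sizes)
}

#' Box-counting profile of a binary mask
#'
#' Tiles the mask with a fixed grid of cubical boxes of edge `eps` anchored at
#' the array origin (partial edge boxes included). For each scale it records
#' the occupied-box count `N(eps)` (boxes holding >= 1 foreground voxel), and
#' the mean and population variance of the box masses (foreground voxels per
#' occupied box).
#'
#' @param mask Binary 3D array with at least one foreground voxel.
#' @param box_sizes Ascending vector of box edge lengths (voxels, >= 1).
#' @return An object of class `box_count_profile`: list with `box_sizes`,
#'   `counts`, `mass_mean`, `mass_var`, `total_fg`.
#' @export
box_counts <- function(mask, box_sizes) {
  mask <- as.array(mask)
  stopifnot(length(dim(mask)) == 3L)
  box_sizes <- as.integer(sort(unique(box_sizes)))
  if (any(box_sizes < 1L)) stop("box sizes must be >= 1")
  d <- dim(mask)
  fg <- which(mask != 0)
  if (length(fg) == 0) stop("empty mask: fractal indices are undefined")
  co <- arrayInd(fg, d)  # 1-based voxel coordinates of foreground
  n <- length(box_sizes)
  counts <- integer(n); mmean <- numeric(n); mvar <- numeric(n)
  for (s in seq_len(n)) {
    eps <- box_sizes[s]
    bx <- (co[, 1] - 1L) %/% eps
    by <- (co[, 2] - 1L) %/% eps
    bz <- (co[, 3] - 1L) %/% eps
    nbx <- (d[1] + eps - 1L) %/% eps
    nby <- (d[2] + eps - 1L) %/% eps
    id <- bx + nbx * (by + nby * bz)
    masses <- rle(sort(id))$lengths
    counts[s] <- length(masses)
    mmean[s] <- mean(masses)
    mvar[s] <- mean((masses - mmean[s])^2)  # population variance
  }
  structure(list(box_sizes = box_sizes, counts = counts,
                 mass_mean = mmean, mass_var = mvar,
                 total_fg = length(fg)),
            class = "box_count_profile")
}

ols_slope <- function(x, y) {
  # slope, intercept, r^2 of y ~ x by ordinary least squares
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate regression: no spread in x")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy == 0) NA_real_ else 1 - sum((y - intercept - slope * x)^2) / syy
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Box-counting fractal dimension
#'
#' Ordinary least-squares fit of `log N(eps)` against `log(1/eps)` (natural
#' logarithms); the slope is the fractal dimension FD. If all counts are equal
#' (e.g. a single voxel) the fit is degenerate: FD is 0 and `r_squared` is
#' `NA`.
#'
#' @param profile A [box_counts()] profile with >= 2 scales.
#' @return List with `fd`, `intercept`, `r_squared`.
#' @export
fractal_dimension <- function(profile) {
  stopifnot(inherits(profile, "box_count_profile"))
  if (length(profile$box_sizes) < 2L) stop("need >= 2 scales for the FD fit")
  x <- log(1 / profile$box_sizes)
  y <- log(profile$counts)
  if (length(unique(profile$counts)) == 1L)
    return(list(fd = 0, intercept = y[1], r_squared = NA_real_))
  fit <- ols_slope(x, y)
  list(fd = fit$slope, intercept = fit$intercept, r_squared = fit$r_squared)
}

#' Lacunarity of a box-count profile
#'
#' Per-scale lacunarity is the variance-to-squared-mean ratio of the occupied
#' box masses, `Lambda(eps) = var[M(eps)] / mean[M(eps)]^2` (population
#' variance, occupied boxes only); the reported value is the arithmetic mean
#' over all scales in the profile.
#'
#' @param profile A [box_counts()] profile with >= 1 scale.
#' @return Scalar lacunarity (>= 0).
#' @export
lacunarity <- function(profile) {
  stopifnot(inherits(profile, "box_count_profile"))
  if (length(profile$box_sizes) < 1L) stop("empty profile")
  mean(profile$mass_var / profile$mass_mean^2)
}

#' Multifractal range of a box-count profile
#'
#' Splits the ascending box sizes into a lower half (first `ceiling(k/2)`)
#' and an upper half (last `ceiling(k/2)`; the middle point is shared when
#' `k` is odd so both halves have >= 2 points), fits the log-log regression
#' of the FD fit to each half, and returns the absolute slope difference
#' `|slope_lower - slope_upper|`. A monofractal (pure power law) yields 0.
#'
#' @param profile A [box_counts()] profile with >= 4 scales.
#' @return Scalar `delta_fd` >= 0.
#' @export
multifractal_range <- function(profile) {
  stopifnot(inherits(profile, "box_count_profile"))
  k <- length(profile$box_sizes)
  if (k < 4L) stop("need >= 4 scales for the multifractal range")
  x <- log(1 / profile$box_sizes)
  y <- log(profile$counts)
  lo <- seq_len(ceiling(k / 2))
  hi <- (k - ceiling(k / 2) + 1L):k
  abs(ols_slope(x[lo], y[lo])$slope - ols_slope(x[hi], y[hi])$slope)
}

#' All fractal indices of one tissue mask
#'
#' Composes [default_box_sizes()], [box_counts()] and the three index
#' computations: fractal dimension, lacunarity and multifractal range.
#'
#' @param mask Nonempty binary 3D array, min dimension >= 16 (>= 32 for the
#'   default scale ladder).
#' @param box_sizes Optional explicit scale set; defaults to
#'   [default_box_sizes()] of the mask shape.
#' @return An object of class `fractal_indices`: list with `fd`, `lacunarity`,
#'   `multifractal_range`, `intercept`, `r_squared`, `n_scales`.
#' @export
tissue_fractal_indices <- function(mask, box_sizes = NULL) {
  mask <- as.array(mask)
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(dim(mask))
  prof <- box_counts(mask, box_sizes)
  fdfit <- fractal_dimension(prof)
  structure(list(
    fd = fdfit$fd,
    lacunarity = lacunarity(prof),
    multifractal_range = multifractal_range(prof),
    intercept = fdfit$intercept,
    r_squared = fdfit$r_squared,
    n_scales = length(prof$box_sizes)
  ), class = "fractal_indices")
}

#' @export
print.fractal_indices <- function(x, ...) {
  cat(sprintf(
    "<fractal_indices> FD %.4f, lacunarity %.4f, multifractal range %.4f (%d scales, R2 %s)\n",
    x$fd, x$lacunarity, x$multifractal_range, x$n_scales,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Per-subject fractal features averaged over both legs
#'
#' Computes per-tissue fractal indices for the left and right leg mask sets
#' and returns their arithmetic mean per tissue. A tissue that is empty in
#' either leg yields `NA` indices for that tissue (flagged missing); the
#' other tissues are still produced.
#'
#' @param left,right [tissue_mask_set] objects for the two legs.
#' @param box_sizes Optional explicit scale set passed to
#'   [tissue_fractal_indices()].
#' @return A one-row data.frame with columns
#'   `<tissue>_fd`, `<tissue>_lacunarity`, `<tissue>_mfr` for
#'   tissue in sm, sat, imat.
#' @export
subject_fractal_features <- function(left, right, box_sizes = NULL) {
  stopifnot(inherits(left, "tissue_mask_set"),
            inherits(right, "tissue_mask_set"))
  out <- list()
  for (t in c("sm", "sat", "imat")) {
    vals <- c(fd = NA_real_, lacunarity = NA_real_, mfr = NA_real_)
    if (sum(left[[t]]) > 0 && sum(right[[t]]) > 0) {
      fl <- tissue_fractal_indices(left[[t]], box_sizes)
      fr <- tissue_fractal_indices(right[[t]], box_sizes)
      vals <- c(fd = (fl$fd + fr$fd) / 2,
                lacunarity = (fl$lacunarity + fr$lacunarity) / 2,
                mfr = (fl$multifractal_range + fr$multifractal_range) / 2)
    }
    out[[paste0(t, "_fd")]] <- vals[["fd"]]
    out[[paste0(t, "_lacunarity")]] <- vals[["lacunarity"]]
    out[[paste0(t, "_mfr")]] <- vals[["mfr"]]
  }
  as.data.frame(out)
}
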