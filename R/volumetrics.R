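#' Tissue volume of a binary mask
#'
#' @param mask Binary 3D array.
#' @param spacing Voxel spacing in mm (length 3, positive).
#' @return Volume in cm^3: voxel count x voxel volume (mm^3) / 1000.
#' @export
mask_volume <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  sum(as.array(mask) != 0) * prod(spacing) / 1000
}

#' Height-normalized body-composition indices
#'
#' Normalizes per-tissue volumes (cm^3) by the cube of height (m^3), yielding
#' the Skeletal Muscle Index (SMI), Subcutaneous Adipose Tissue Index (SATI)
#' and Intramuscular Adipose Tissue Index (IMATI), plus the inter-tissue
#' ratios IMR = IMATI/SMI, MSR = SMI/SATI and ISR = IMATI/SATI. A ratio whose
#' denominator is zero is reported as `NA` (undefined), not zero.
#'
#' @param volumes Named list or vector with elements `sm`, `sat`, `imat`
#'   (cm^3, per subject, i.e. both legs summed).
#' @param height_m Subject height in metres (> 0).
#' @return An object of class `body_composition_indices`: a list with
#'   `smi`, `sati`, `imati` (cm^3/m^3), `imr`, `msr`, `isr`, `height_m` and
#'   `raw_volumes`.
#' @export
body_indices <- function(volumes, height_m) {
  if (!is.numeric(height_m) || length(height_m) != 1L || height_m <= 0)
    stop("height_m must be a positive scalar")
  v <- as.list(volumes)
  for (nm in c("sm", "sat", "imat")) {
    if (is.null(v[[nm]]) || v[[nm]] < 0)
      stop("volumes must contain nonnegative 'sm', 'sat', 'imat'")
  }
  h3 <- height_m^3
  smi <- v$sm / h3; sati <- v$sat / h3; imati <- v$imat / h3
  safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    smi = smi, sati = sati, imati = imati,
    imr = safe_ratio(imati, smi),
    msr = safe_ratio(smi, sati),
    isr = safe_ratio(imati, sati),
    height_m = height_m,
    raw_volumes = list(sm = v$sm, sat = v$sat, imat = v$imat)
  ), class = "body_composition_indices")
}

#' @export
print.body_composition_indices <- function(x, ...) {
  cat(sprintf(
    "<body_composition_indices> SMI %.1f, SATI %.1f, IMATI %.1f cm3/m3; IMR %.3f, MSR %.3f, ISR %.3f\n",
    x$smi, x$sati, x$imati, x$imr, x$msr, x$isr))
  invisible(x)
}

#' Volumetric indices straight from a bilateral mask set
#'
#' Convenience wrapper: sums tissue volumes over one or more mask sets
#' (e.g. left and right leg) and computes [body_indices()].
#'
#' @param ... One or more [tissue_mask_set] objects.
#' @param height_m Subject height in metres.
#' @return A `body_composition_indices` object.
#' @export
subject_volumetrics <- function(..., height_m) {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1),
                                          "tissue_mask_set")))
  vols <- list(sm = 0, sat = 0, imat = 0)
  for (s in sets) {
    for (t in names(vols))
      vols[[t]] <- vols[[t]] + mask_volume(s[[t]], s$spacing)
  }
  body_indices(vols, height_m)
}
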