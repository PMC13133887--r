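#' CT volume container
#'
#' A `ct_volume` wraps a 3D array of Hounsfield units (or a binary mask)
#' together with its voxel spacing and physical origin, both in millimetres.
#' Physical position of voxel index `(i, j, k)` (1-based in R) is
#' `origin + (index - 1) * spacing`.
#'
#' @param data 3D numeric array (HU values, or 0/1 for masks).
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm.
#' @param origin Numeric length-3 vector of physical offsets in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("ct_volume requires a 3D array, got ", length(dim(data)), " dims")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume data must be finite everywhere")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

is_binary_array <- function(a) all(a == 0 | a == 1)

#' Read a volumetric image or mask from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind `"image"` for HU volumes, `"mask"` for binary masks; masks are
#'   additionally validated to contain only 0/1.
#' @return A [ct_volume].
#' @export
read_volume <- function(path, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))  # drop RNifti metadata attributes
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L]
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  hdr <- RNifti::niftiHeader(img)
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (kind == "mask" && !is_binary_array(a))
    stop("mask file contains values other than 0/1: ", path)
  ct_volume(a, spacing = spacing, origin = origin)
}

#' Write a volume or mask to NIfTI
#'
#' Masks (binary volumes) are stored as unsigned 8-bit, images as 32-bit float.
#'
#' @param vol A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  dtype <- if (is_binary_array(vol$data)) "uint8" else "float"
  hdr <- list(pixdim = c(-1, vol$spacing, 1, 1, 1, 1),
              qoffset_x = vol$origin[1], qoffset_y = vol$origin[2],
              qoffset_z = vol$origin[3], qform_code = 1L)
  img <- RNifti::asNifti(vol$data, reference = hdr, datatype = dtype)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Images are interpolated trilinearly, masks by nearest neighbour (so they
#' stay binary). The output covers the same physical extent; an output grid of
#' `round(dim * spacing / target_mm)` voxels per axis is sampled at physical
#' positions `origin + (i - 1) * target_mm`.
#'
#' @param vol A [ct_volume].
#' @param target_mm Positive scalar target voxel edge length in mm.
#' @param kind `"image"` (trilinear) or `"mask"` (nearest neighbour).
#' @return A [ct_volume] with spacing `rep(target_mm, 3)`.
#' @export
resample_isotropic <- function(vol, target_mm, kind = c("image", "mask")) {
  stopifnot(inherits(vol, "ct_volume"))
  kind <- match.arg(kind)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  if (all(abs(vol$spacing - target_mm) < 1e-9)) return(vol)

  d <- dim(vol$data)
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing / target_mm)))
  # continuous input index (1-based) of each output sample per axis
  ix <- lapply(1:3, function(ax)
    1 + (seq_len(out_dim[ax]) - 1) * target_mm / vol$spacing[ax])

  if (kind == "mask") {
    near <- lapply(1:3, function(ax) pmin(pmax(round(ix[[ax]]), 1L), d[ax]))
    out <- vol$data[near[[1]], near[[2]], near[[3]], drop = FALSE]
    dim(out) <- out_dim
  } else {
    lo <- lapply(1:3, function(ax) pmin(pmax(floor(ix[[ax]]), 1L), d[ax]))
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, d[ax]))
    fr <- lapply(1:3, function(ax) pmin(pmax(ix[[ax]] - lo[[ax]], 0), 1))
    # trilinear blend, one corner at a time (8 gathered sub-arrays)
    out <- array(0, out_dim)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      gi <- if (cx) hi[[1]] else lo[[1]]
      gj <- if (cy) hi[[2]] else lo[[2]]
      gk <- if (cz) hi[[3]] else lo[[3]]
      wx <- if (cx) fr[[1]] else 1 - fr[[1]]
      wy <- if (cy) fr[[2]] else 1 - fr[[2]]
      wz <- if (cz) fr[[3]] else 1 - fr[[3]]
      w <- outer(outer(wx, wy), wz)
      out <- out + w * vol$data[gi, gj, gk, drop = FALSE]
    }
  }
  ct_volume(out, spacing = rep(target_mm, 3), origin = vol$origin)
}

reflect_index <- function(q, n) {
  if (n == 1L) return(rep(1L, length(q)))
  # symmetric reflection about the edges: ... 2 1 | 1 2 ... n | n n-1 ...
  p <- (q - 1) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with physical bandwidth `sigma_mm`; the per-axis
#' kernel width in voxels is `sigma_mm / spacing`. Boundaries are handled by
#' symmetric reflection. `sigma_mm = 0` is the exact identity.
#'
#' @param vol A [ct_volume].
#' @param sigma_mm Nonnegative scalar standard deviation in mm.
#' @return A smoothed [ct_volume] of identical shape and spacing.
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm < 0)
    stop("sigma_mm must be a nonnegative scalar")
  if (sigma_mm == 0) return(vol)
  a <- vol$data
  d <- dim(a)
  for (ax in 1:3) {
    sig <- sigma_mm / vol$spacing[ax]
    if (sig < 1e-8) next
    rad <- max(1L, ceiling(4 * sig))
    k <- exp(-(seq(-rad, rad))^2 / (2 * sig^2))
    k <- k / sum(k)
    acc <- array(0, d)
    base <- seq_len(d[ax])
    for (j in seq(-rad, rad)) {
      idx <- reflect_index(base + j, d[ax])
      shifted <- switch(ax,
                        a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE],
                        a[, , idx, drop = FALSE])
      acc <- acc + k[j + rad + 1] * shifted
    }
    a <- acc
  }
  ct_volume(a, spacing = vol$spacing, origin = vol$origin)
}

#' Normalize HU using skeletal muscle as internal reference
#'
#' Applies a global additive shift so that the median HU inside the muscle
#' mask equals `target_muscle_hu` exactly. Additive (not multiplicative)
#' because inter-scanner HU offsets are approximately additive.
#'
#' @param vol A [ct_volume].
#' @param muscle_mask Binary 3D array, same shape as `vol`, marking reference
#'   muscle voxels; must be nonempty.
#' @param target_muscle_hu Scalar reference HU (default 50).
#' @return A shifted [ct_volume].
#' @export
normalize_hu <- function(vol, muscle_mask, target_muscle_hu = 50) {
  stopifnot(inherits(vol, "ct_volume"))
  muscle_mask <- as.array(muscle_mask)
  if (!identical(dim(muscle_mask), dim(vol$data)))
    stop("muscle_mask shape must match the volume")
  if (sum(muscle_mask) == 0) stop("muscle mask is empty")
  shift <- target_muscle_hu - stats::median(vol$data[muscle_mask == 1])
  ct_volume(vol$data + shift, spacing = vol$spacing, origin = vol$origin)
}

#' HU classification ranges for muscle and adipose tissue
#'
#' Default ranges are the widely used CT body-composition windows:
#' muscle \[-29, 150\] HU, adipose \[-190, -30\] HU. The two ranges must be
#' disjoint with the fat range below the muscle range.
#'
#' @param muscle_lo,muscle_hi Muscle HU bounds.
#' @param fat_lo,fat_hi Adipose HU bounds.
#' @return An object of class `hu_ranges`.
#' @export
hu_ranges <- function(muscle_lo = -29, muscle_hi = 150,
                      fat_lo = -190, fat_hi = -30) {
  if (!(muscle_lo < muscle_hi) || !(fat_lo < fat_hi))
    stop("each HU range needs lo < hi")
  if (!(fat_hi < muscle_lo))
    stop("fat and muscle HU ranges must be disjoint (fat_hi < muscle_lo)")
  structure(list(muscle_lo = muscle_lo, muscle_hi = muscle_hi,
                 fat_lo = fat_lo, fat_hi = fat_hi),
            class = "hu_ranges")
}

#' Tissue mask set container
#'
#' Mutually exclusive binary masks for skeletal muscle (SM), subcutaneous
#' adipose tissue (SAT) and intramuscular adipose tissue (IMAT) on one grid.
#'
#' @param sm,sat,imat Binary 3D arrays of identical shape.
#' @param spacing Voxel spacing in mm (length 3).
#' @param provenance Optional list recording thresholds/compartments used.
#' @return An object of class `tissue_mask_set`.
#' @export
tissue_mask_set <- function(sm, sat, imat, spacing = c(1, 1, 1),
                            provenance = list()) {
  sm <- as.array(sm); sat <- as.array(sat); imat <- as.array(imat)
  if (!identical(dim(sm), dim(sat)) || !identical(dim(sm), dim(imat)))
    stop("sm/sat/imat masks must share one shape")
  for (m in list(sm, sat, imat))
    if (!is_binary_array(m)) stop("tissue masks must be binary 0/1")
  if (any(sm + sat + imat > 1))
    stop("tissue masks overlap: a voxel is set in more than one mask")
  structure(list(sm = sm, sat = sat, imat = imat,
                 spacing = as.numeric(spacing), provenance = provenance),
            class = "tissue_mask_set")
}

#' @export
print.tissue_mask_set <- function(x, ...) {
  cat(sprintf("<tissue_mask_set> %s grid: SM %d, SAT %d, IMAT %d voxels\n",
              paste(dim(x$sm), collapse = "x"),
              sum(x$sm), sum(x$sat), sum(x$imat)))
  invisible(x)
}

#' Threshold a CT volume into tissue masks
#'
#' Within the (anatomically delineated) muscle compartment, voxels in the
#' muscle HU range become SM and voxels in the adipose range become IMAT;
#' within the subcutaneous compartment, voxels in the adipose range become
#' SAT. Disjoint compartments plus disjoint HU ranges guarantee mutual
#' exclusivity of the output masks.
#'
#' @param vol A [ct_volume] (HU-normalized).
#' @param muscle_compartment,subcut_compartment Binary 3D arrays, same shape
#'   as `vol`, and mutually disjoint.
#' @param ranges A [hu_ranges] object.
#' @return A [tissue_mask_set].
#' @export
threshold_tissues <- function(vol, muscle_compartment, subcut_compartment,
                              ranges = hu_ranges()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(ranges, "hu_ranges"))
  mc <- as.array(muscle_compartment); sc <- as.array(subcut_compartment)
  if (!identical(dim(mc), dim(vol$data)) || !identical(dim(sc), dim(vol$data)))
    stop("compartment masks must match the volume shape")
  if (any(mc + sc > 1)) stop("muscle and subcutaneous compartments overlap")
  hu <- vol$data
  in_muscle <- hu >= ranges$muscle_lo & hu <= ranges$muscle_hi
  in_fat <- hu >= ranges$fat_lo & hu <= ranges$fat_hi
  tissue_mask_set(
    sm   = (mc == 1 & in_muscle) + 0,
    sat  = (sc == 1 & in_fat) + 0,
    imat = (mc == 1 & in_fat) + 0,
    spacing = vol$spacing,
    provenance = list(ranges = unclass(ranges))
  )
}

#' 26-connected components of a binary 3D mask
#'
#' @param mask Binary 3D array.
#' @return Integer array of component labels (0 = background), with an
#'   attribute `sizes` giving voxel counts per label.
#' @keywords internal
connected_components_3d <- function(mask) {
  mask <- as.array(mask)
  d <- dim(mask)
  fg <- which(mask != 0)
  lab <- array(0L, d)
  if (length(fg) == 0) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  pos <- match(seq_len(prod(d)), fg)  # linear index -> fg ordinal (NA if bg)
  co <- arrayInd(fg, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
          (offs[, 1] == 0 & (offs[, 2] > 0 |
          (offs[, 2] == 0 & offs[, 3] > 0)))), , drop = FALSE]  # 13 half-offsets
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    tgt <- pos[lin]
    src <- which(ok)[!is.na(tgt)]
    tgt <- tgt[!is.na(tgt)]
    if (length(tgt)) edges[[length(edges) + 1L]] <- rbind(src, tgt)
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  attr(lab, "sizes") <- as.integer(comp$csize)
  lab
}

#' Split bilateral masks into left and right legs
#'
#' Labels 26-connected components of the union mask, requires exactly two
#' dominant components (>= `dominance` of foreground voxels each), assigns
#' left/right by centroid along the first image axis (smaller coordinate =
#' left), and crops each output mask set to its component's bounding box.
#'
#' @param masks A [tissue_mask_set] covering both legs.
#' @param dominance Minimum foreground fraction for a component to count as a
#'   leg (default 0.05; smaller components are ignored as debris).
#' @return A list with elements `left` and `right`, each a [tissue_mask_set].
#' @export
split_legs <- function(masks, dominance = 0.05) {
  stopifnot(inherits(masks, "tissue_mask_set"))
  uni <- (masks$sm + masks$sat + masks$imat > 0) + 0L
  lab <- connected_components_3d(uni)
  sizes <- attr(lab, "sizes")
  total <- sum(sizes)
  dom <- which(sizes >= dominance * total)
  if (length(dom) != 2L)
    stop("expected 2 dominant connected components, found ", length(dom))
  cx <- vapply(dom, function(l) mean(arrayInd(which(lab == l), dim(lab))[, 1]),
               numeric(1))
  dom <- dom[order(cx)]  # left first
  crop <- function(label) {
    idx <- arrayInd(which(lab == label), dim(lab))
    rng <- lapply(1:3, function(ax) min(idx[, ax]):max(idx[, ax]))
    inside <- array(0L, dim(lab)); inside[lab == label] <- 1L
    take <- function(m) {
      out <- (m * inside)[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      array(out, dim = vapply(rng, length, integer(1)))
    }
    tissue_mask_set(take(masks$sm), take(masks$sat), take(masks$imat),
                    spacing = masks$spacing, provenance = masks$provenance)
  }
  list(left = crop(dom[1]), right = crop(dom[2]))
}
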