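#' Construct a 3-D scalar brain volume
#'
#' A `volume_grid` is the package's container for any spatially normalized
#' 3-D scalar map: a fractional-anisotropy (FA) map, a tissue map (gray
#' matter, white matter, cerebrospinal fluid), a population mean or SD
#' reference image, or a quotient image. All maps of a cohort are assumed to
#' live on the same lattice (the generator produces them pre-aligned by
#' construction).
#'
#' @param values numeric 3-D array of voxel values. `NA` marks missing
#'   (out-of-mask) voxels in quotient images.
#' @param voxel_size_mm voxel edge length in mm; a single positive number
#'   (isotropic) or one value per axis.
#' @param modality one of `"fa"`, `"gm"`, `"wm"`, `"csf"`, `"quotient"`,
#'   `"mean"`, `"sd"`.
#' @return an object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(runif(8^3), dim = c(8, 8, 8)), 2, "fa")
#' dim(v$values)
#' @export
volume_grid <- function(values, voxel_size_mm = 2,
                        modality = c("fa", "gm", "wm", "csf",
                                     "quotient", "mean", "sd")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array", call. = FALSE)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be one or three positive numbers", call. = FALSE)
  if (any(is.infinite(values)))
    stop("volume contains non-finite (infinite) values", call. = FALSE)
  if (modality == "fa") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("FA values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(values = values,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 modality = modality),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %s, %d x %d x %d voxels @ %s mm, range [%.4g, %.4g]\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

# 1-D discrete Gaussian convolution matrix with reflecting boundary.
# Rows are renormalized to sum to 1 so that a constant image is exactly
# invariant and total intensity is conserved under reflection.
smoothing_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma_vox))
  offs <- -radius:radius
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    # whole-sample reflection (0 -> 1, n+1 -> n, ...), repeated until every
    # index is in range; with a symmetric kernel this operator is symmetric,
    # so constants are invariant and total intensity is conserved exactly
    while (any(j < 1L) || any(j > n)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    for (k in seq_along(j)) M[i, j[k]] <- M[i, j[k]] + w[k]
  }
  M
}

fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / sqrt(8 * log(2))

#' Smooth a volume with a separable Gaussian kernel
#'
#' Applies a separable discrete Gaussian with standard deviation
#' `sigma = fwhm / sqrt(8 * ln 2)` per axis, converted from mm to voxels using
#' the volume's voxel size. Boundaries are handled by whole-sample
#' reflection; the resulting operator is symmetric, so constant volumes are
#' invariant and total intensity is conserved exactly.
#'
#' @param v a [volume_grid()].
#' @param fwhm_mm full width at half maximum of the kernel in mm; `0` is the
#'   identity.
#' @return a smoothed `volume_grid` of the same shape and modality.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "volume_grid"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("'fwhm_mm' must be a nonnegative number", call. = FALSE)
  if (fwhm_mm == 0) return(v)
  d <- dim(v$values)
  sig <- fwhm_to_sigma(fwhm_mm) / v$voxel_size_mm   # voxels, per axis
  x <- v$values
  # axis 1
  x <- array(smoothing_matrix(d[1], sig[1]) %*% matrix(x, d[1]), dim = d)
  # axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- array(smoothing_matrix(d[2], sig[2]) %*% matrix(x, d[2]),
             dim = d[c(2, 1, 3)])
  x <- aperm(x, c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- array(smoothing_matrix(d[3], sig[3]) %*% matrix(x, d[3]),
             dim = d[c(3, 1, 2)])
  x <- aperm(x, c(2, 3, 1))
  out <- v
  out$values <- x
  out
}

# Factor by which iid voxel noise SD shrinks under the separable kernel
# (interior voxels; product over axes of sqrt(sum of squared weights)).
kernel_noise_factor <- function(fwhm_mm, voxel_size_mm) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (fwhm_mm == 0) return(1)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  f <- vapply(sig, function(s) {
    if (s <= 0) return(1)
    radius <- max(1L, ceiling(4 * s))
    w <- exp(-(-radius:radius)^2 / (2 * s^2))
    w <- w / sum(w)
    sqrt(sum(w^2))
  }, numeric(1))
  prod(f)
}

#' Intracranial volume from tissue maps
#'
#' ICV is the total (voxel-sum) of the gray-matter, white-matter and
#' cerebrospinal-fluid maps of one participant; dividing a smoothed GM map by
#' it removes head-size differences.
#'
#' @param gm,wm,csf `volume_grid`s on a common lattice, nonnegative.
#' @return a single nonnegative number.
#' @export
compute_icv <- function(gm, wm, csf) {
  stopifnot(inherits(gm, "volume_grid"), inherits(wm, "volume_grid"),
            inherits(csf, "volume_grid"))
  stop_if_grid_mismatch(gm, wm, "tissue maps")
  stop_if_grid_mismatch(gm, csf, "tissue maps")
  if (min(gm$values) < 0 || min(wm$values) < 0 || min(csf$values) < 0)
    stop("tissue maps must be nonnegative", call. = FALSE)
  sum(gm$values) + sum(wm$values) + sum(csf$values)
}

#' Head-size-proportional map
#'
#' Divides a (smoothed) gray-matter map voxelwise by the participant's
#' intracranial volume.
#'
#' @param gm_smoothed a `volume_grid`.
#' @param icv positive scalar, typically from [compute_icv()].
#' @return a `volume_grid` of modality `"gm"`.
#' @export
proportional_map <- function(gm_smoothed, icv) {
  stopifnot(inherits(gm_smoothed, "volume_grid"))
  if (!is.finite(icv) || icv <= 0)
    stop("'icv' must be a positive number (all-zero tissue maps?)",
         call. = FALSE)
  out <- gm_smoothed
  out$values <- gm_smoothed$values / icv
  out
}
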