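#' Voxelwise population reference field
#'
#' Computes voxelwise mean and SD images across a stack of aligned maps, plus
#' a validity mask. The quotient transform standardizes each participant's
#' map against this field. By default the SD is the population SD (divide by
#' N), which makes the defining cohort's voxelwise quotient mean exactly 100
#' and SD exactly 15; the sample convention (N - 1) is available.
#'
#' Voxels with SD at or below `sd_floor`, or mean at or below
#' `mean_threshold`, are excluded from the mask rather than producing
#' divide-by-zero artifacts.
#'
#' @param maps list of `volume_grid`s on a common lattice (at least 2).
#' @param sd_floor smallest admissible voxel SD; default `1e-6`.
#' @param mean_threshold mask voxels whose mean is <= this value; default `0`,
#'   which drops empty background in nonnegative maps.
#' @param sd_convention `"population"` (divide by N, default) or `"sample"`.
#' @return an object of class `reference_field` with elements `mean`, `sd`
#'   (both `volume_grid`), `mask` (logical array), `n_source_maps`,
#'   `sd_convention`.
#' @export
reference_field <- function(maps, sd_floor = 1e-6, mean_threshold = 0,
                            sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  if (!is.list(maps) || length(maps) < 2L)
    stop("need at least 2 maps to build a reference field", call. = FALSE)
  for (m in maps) {
    stopifnot(inherits(m, "volume_grid"))
    stop_if_grid_mismatch(maps[[1]], m, "reference maps")
  }
  n <- length(maps)
  d <- dim(maps[[1]]$values)
  stack <- vapply(maps, function(m) as.numeric(m$values),
                  numeric(prod(d)))
  mu <- rowMeans(stack)
  ss <- rowSums((stack - mu)^2)
  v <- if (sd_convention == "population") ss / n else ss / (n - 1)
  sdv <- sqrt(v)
  mask <- sdv > sd_floor & mu > mean_threshold
  vs <- maps[[1]]$voxel_size_mm
  structure(list(
    mean = volume_grid(array(mu, dim = d), vs, "mean"),
    sd = volume_grid(array(sdv, dim = d), vs, "sd"),
    mask = array(mask, dim = d),
    n_source_maps = n,
    sd_convention = sd_convention
  ), class = "reference_field")
}

#' @export
print.reference_field <- function(x, ...) {
  cat(sprintf("<reference_field> n = %d maps, %s SD, %d/%d voxels in mask\n",
              x$n_source_maps, x$sd_convention,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Voxelwise quotient image
#'
#' Standardizes a map against a reference field on the IQ-like quotient
#' scale: `100 + 15 * (x - mean) / sd` at every masked voxel. Voxels outside
#' the mask are `NA` (missing) and are excluded from downstream regional
#' averages.
#'
#' @param m a `volume_grid` on the reference field's lattice.
#' @param ref a [reference_field()].
#' @return a `volume_grid` of modality `"quotient"`.
#' @export
quotient_map <- function(m, ref) {
  stopifnot(inherits(m, "volume_grid"), inherits(ref, "reference_field"))
  stop_if_grid_mismatch(m, ref$mean, "map and reference")
  q <- 100 + 15 * (m$values - ref$mean$values) / ref$sd$values
  q[!ref$mask] <- NA_real_
  volume_grid(q, m$voxel_size_mm, "quotient")
}
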