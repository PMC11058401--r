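#' The eight white-matter tract regions reported by the regional analysis
#' @keywords internal
wm_tract_names <- c("corpus_callosum", "internal_capsule", "corona_radiata",
                    "posterior_thalamic_radiation", "external_capsule",
                    "cingulum", "superior_longitudinal_fasciculus",
                    "uncinate_fasciculus")

#' Construct a labeled atlas volume
#'
#' @param labels integer 3-D array; `0` is background, labels `1..K` are
#'   regions.
#' @param names character vector naming labels `1..K`.
#' @return an object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D integer array", call. = FALSE)
  lab <- sort(unique(as.integer(labels)))
  lab <- lab[lab > 0L]
  if (length(lab) == 0L)
    stop("atlas has no labeled voxels", call. = FALSE)
  k <- max(lab)
  if (!identical(lab, seq_len(k)))
    stop("labels must be contiguous 1..K (0 = background)", call. = FALSE)
  if (is.null(names)) names <- sprintf("region_%02d", seq_len(k))
  if (length(names) != k)
    stop("'names' must have one entry per label", call. = FALSE)
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 names = names),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("<atlas_volume> %d regions, %d labeled voxels on %s grid\n",
              length(x$names), sum(x$labels > 0L),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Generate a synthetic labeled atlas
#'
#' Produces a stand-in for a standard anatomical parcellation on a small
#' lattice: an ellipsoidal brain mask is split into `n_regions` connected
#' blobs by nearest-seed (Voronoi) assignment, so every region is nonempty
#' and spatially contiguous. With `n_regions = 8` (the default downstream),
#' regions carry the names of the eight white-matter tracts analyzed
#' regionally; otherwise generic names are used.
#'
#' @param grid_shape integer vector of 3 lattice dimensions.
#' @param n_regions number of regions (>= 1, at most the mask size).
#' @param seed integer seed controlling seed-voxel placement.
#' @return an `atlas_volume`.
#' @export
generate_atlas <- function(grid_shape = c(24, 24, 24), n_regions = 8,
                           seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("'grid_shape' must be 3 integers >= 2", call. = FALSE)
  if (n_regions < 1L)
    stop("'n_regions' must be >= 1", call. = FALSE)
  ctr <- (grid_shape + 1) / 2
  semi <- grid_shape * 0.45
  ix <- expand.grid(x = seq_len(grid_shape[1]),
                    y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  inside <- ((ix$x - ctr[1]) / semi[1])^2 +
            ((ix$y - ctr[2]) / semi[2])^2 +
            ((ix$z - ctr[3]) / semi[3])^2 <= 1
  n_in <- sum(inside)
  if (n_regions > n_in)
    stop(sprintf("n_regions (%d) exceeds the %d in-mask voxels",
                 n_regions, n_in), call. = FALSE)
  labels <- array(0L, dim = grid_shape)
  pts <- as.matrix(ix[inside, ])
  set.seed(seed)
  seeds <- pts[sample.int(n_in, n_regions), , drop = FALSE]
  # nearest seed; Voronoi cells of an ellipsoid-restricted lattice are
  # connected (convex cells intersected with a convex mask)
  d2 <- vapply(seq_len(n_regions), function(k)
    (pts[, 1] - seeds[k, 1])^2 + (pts[, 2] - seeds[k, 2])^2 +
    (pts[, 3] - seeds[k, 3])^2, numeric(n_in))
  assign <- max.col(-d2, ties.method = "first")
  labels[inside] <- assign
  nms <- if (n_regions == 8L) wm_tract_names
         else sprintf("region_%02d", seq_len(n_regions))
  atlas_volume(labels, nms)
}

#' Regional means of a quotient image
#'
#' For each atlas label, the unweighted mean of the non-missing quotient
#' voxels carrying that label. Labels whose voxels are all missing are
#' reported as `NA`.
#'
#' @param q a quotient `volume_grid`.
#' @param atlas an `atlas_volume` on the same lattice.
#' @return named numeric vector, one entry per region.
#' @export
regional_quotients <- function(q, atlas) {
  stopifnot(inherits(q, "volume_grid"), inherits(atlas, "atlas_volume"))
  if (!identical(dim(q$values), dim(atlas$labels)))
    stop("atlas and quotient image are not on the same grid", call. = FALSE)
  if (!any(atlas$labels > 0L))
    stop("atlas has no labeled voxels", call. = FALSE)
  k <- length(atlas$names)
  lab <- as.integer(atlas$labels)
  val <- as.numeric(q$values)
  keep <- lab > 0L & !is.na(val)
  sums <- rep(0, k); cnt <- rep(0L, k)
  if (any(keep)) {
    tb <- tapply(val[keep], lab[keep], sum)
    nb <- tapply(rep(1L, sum(keep)), lab[keep], sum)
    ids <- as.integer(names(tb))
    sums[ids] <- tb; cnt[ids] <- nb
  }
  out <- ifelse(cnt > 0L, sums / pmax(cnt, 1L), NA_real_)
  names(out) <- atlas$names
  out
}

#' Whole-brain quotient from regional values
#'
#' The unweighted mean over non-missing regions.
#'
#' @param per_region named numeric vector from [regional_quotients()].
#' @return a single number.
#' @export
whole_brain_bhq <- function(per_region) {
  if (all(is.na(per_region)))
    stop("all regions missing; cannot form a whole-brain quotient",
         call. = FALSE)
  mean(per_region, na.rm = TRUE)
}
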