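#' Score a cohort of brain maps into BHQ values
#'
#' Runs the full quotient pipeline over a cohort of aligned scans and returns
#' tidy per-region and whole-brain quotient scores.
#'
#' For `modality = "gm"` each scan's gray-matter map is smoothed, divided by
#' the participant's intracranial volume (sum of the unsmoothed GM, WM and
#' CSF maps) to remove head-size differences, and the resulting proportional
#' maps define the voxelwise mean/SD reference. For `modality = "fa"` the
#' (optionally smoothed) FA maps are referenced directly. Each map is then
#' standardized to `100 + 15 * (x - mean)/sd`, averaged within atlas regions,
#' and the regional quotients are averaged (unweighted) into the whole-brain
#' score.
#'
#' @param scans list of scans; each element is a list with fields
#'   `participant`, `time` (`"pre"`/`"post"`), and for FA scoring `fa`, for GM
#'   scoring `gm`, `wm`, `csf` (all [volume_grid()]s on one lattice).
#' @param atlas an [atlas_volume()] on the same lattice.
#' @param modality `"fa"` or `"gm"`.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8; `0` disables).
#' @param sd_convention `"population"` or `"sample"`, see [reference_field()].
#' @param reference_pool `"all"` (default: every scan of every participant at
#'   both timepoints defines the reference) or `"pre"` (baseline scans only).
#' @param sd_floor,mean_threshold mask controls passed to [reference_field()].
#' @return a data.frame with columns `participant`, `time`, `modality`
#'   (`"fa_bhq"` or `"gm_bhq"`), `region` (region names plus `"whole_brain"`),
#'   `value`.
#' @export
score_cohort <- function(scans, atlas, modality = c("fa", "gm"),
                         fwhm_mm = 8,
                         sd_convention = c("population", "sample"),
                         reference_pool = c("all", "pre"),
                         sd_floor = 1e-6, mean_threshold = 0) {
  modality <- match.arg(modality)
  sd_convention <- match.arg(sd_convention)
  reference_pool <- match.arg(reference_pool)
  stopifnot(inherits(atlas, "atlas_volume"))
  if (length(scans) < 2L)
    stop("need at least 2 scans to score a cohort", call. = FALSE)

  prepped <- lapply(scans, function(s) {
    if (is.null(s$participant) || is.null(s$time))
      stop("every scan needs 'participant' and 'time'", call. = FALSE)
    if (modality == "fa") {
      if (is.null(s$fa)) stop("FA scoring requires an 'fa' map per scan",
                              call. = FALSE)
      m <- gaussian_smooth(s$fa, fwhm_mm)
    } else {
      if (is.null(s$gm) || is.null(s$wm) || is.null(s$csf))
        stop("GM scoring requires 'gm', 'wm' and 'csf' maps per scan",
             call. = FALSE)
      icv <- compute_icv(s$gm, s$wm, s$csf)
      m <- proportional_map(gaussian_smooth(s$gm, fwhm_mm), icv)
    }
    list(participant = s$participant, time = s$time, map = m)
  })

  pool <- if (reference_pool == "all") prepped
          else Filter(function(s) s$time == "pre", prepped)
  if (length(pool) < 2L)
    stop("reference pool has fewer than 2 scans", call. = FALSE)
  ref <- reference_field(lapply(pool, `[[`, "map"),
                         sd_floor = sd_floor,
                         mean_threshold = mean_threshold,
                         sd_convention = sd_convention)
  if (!any(ref$mask))
    stop(paste("reference field has an empty mask (zero SD everywhere;",
               "identical maps cannot be quotient-scored)"), call. = FALSE)

  out <- lapply(prepped, function(s) {
    per_region <- regional_quotients(quotient_map(s$map, ref), atlas)
    data.frame(participant = s$participant,
               time = s$time,
               modality = paste0(modality, "_bhq"),
               region = c(names(per_region), "whole_brain"),
               value = c(unname(per_region), whole_brain_bhq(per_region)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reference") <- ref
  res
}
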