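behavioral_measures <- c("poms_ah", "poms_cb", "poms_dd", "poms_fi",
                         "poms_ta", "poms_va", "poms_f",
                         "tmt_a_sec", "tmt_b_sec")

# Baseline behavioral distributions the generator emulates: mood-state
# subscale sums (bounded, small means) and trail-making completion times
# (positive seconds, Part B slower than Part A on average).
default_behavioral_baseline <- list(
  poms_ah   = c(mean = 2.8,  sd = 2.4),
  poms_cb   = c(mean = 2.0,  sd = 2.0),
  poms_dd   = c(mean = 1.5,  sd = 2.1),
  poms_fi   = c(mean = 3.0,  sd = 2.7),
  poms_ta   = c(mean = 3.3,  sd = 2.7),
  poms_va   = c(mean = 11.6, sd = 4.4),
  poms_f    = c(mean = 12.2, sd = 3.6),
  tmt_a_sec = c(mean = 22.4, sd = 5.4),
  tmt_b_sec = c(mean = 49.0, sd = 18.5)
)

default_behavioral_noise_sd <- c(
  poms_ah = 1.8, poms_cb = 1.8, poms_dd = 1.8, poms_fi = 1.9,
  poms_ta = 1.8, poms_va = 2.8, poms_f = 2.2,
  tmt_a_sec = 4.0, tmt_b_sec = 9.0
)

# practice effect on trail-making Part A applied to both groups
tmt_practice_effect <- c(tmt_a_sec = -2.5)

#' Configuration for the synthetic longitudinal cohort generator
#'
#' The defaults encode the study conditions the package emulates: two groups
#' of 35 participants measured pre and post, a baseline group offset on the
#' FA quotient scale (control above intervention), a modest pre-to-post
#' improvement in the intervention group with a slight drift in controls, and
#' brain-behavior change-score couplings of about .35 through a single shared
#' latent factor per participant.
#'
#' All brain-side magnitudes are expressed in BHQ points on the latent
#' (subject-level) scale; the voxel renderer maps them into raw map units via
#' `render_scale` and adds voxelwise Gaussian noise.
#'
#' @param n_per_group participants per group (>= 2); default 35.
#' @param grid_shape 3 lattice dimensions; default `c(24, 24, 24)`.
#' @param voxel_size_mm voxel edge length in mm; default 4.
#' @param n_regions atlas regions; default 8.
#' @param baseline_group_offset control-minus-intervention baseline
#'   difference in BHQ points, applied to FA only; default 2.
#' @param intervention_effect mean pre-to-post latent change (BHQ points) in
#'   the intervention group's FA; default 0.5.
#' @param control_drift mean latent FA change in controls; default -0.4.
#' @param subject_sd between-subject SD of the latent baseline quotient
#'   (points); default 4.
#' @param region_jitter_sd SD of region-by-subject baseline jitter (points);
#'   default 1.5.
#' @param change_sd total SD of the latent subject-level change (points);
#'   default 1.7.
#' @param region_change_jitter_sd SD of region-level change jitter (points);
#'   default 0.5.
#' @param latent_loading fraction of the change SD carried by the shared
#'   latent factor (the `a / change_sd` ratio); default 0.8. Couplings must
#'   satisfy `|r| < latent_loading`.
#' @param latent_coupling_r named vector of population change-score
#'   correlations between whole-brain FA quotient change and behavioral
#'   change in the intervention group (controls receive variance-matched
#'   uncoupled noise), one entry per coupled measure; default
#'   `c(poms_va = 0.35, tmt_b_sec = -0.35)`, all others 0.
#' @param behavioral_noise_sd named vector of residual change-noise SDs per
#'   behavioral measure (the `sigma_f` of the coupling construction).
#' @param voxel_noise_sd SD of voxelwise Gaussian noise in raw map units;
#'   default 0.04.
#' @param render_scale raw map units per latent BHQ point; default 0.002.
#' @param scoring_fwhm_mm smoothing FWHM (mm) the downstream scorer is
#'   expected to apply; used only to report the predicted measured-scale
#'   factor in the manifest; default 8.
#' @param cesd_exclusion_rate expected proportion of recruits screened out by
#'   the depression-scale threshold (must be < 0.5); default 0.2.
#' @param seed integer seed; identical seed and configuration give a
#'   bit-identical cohort.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 35,
                       grid_shape = c(24, 24, 24),
                       voxel_size_mm = 4,
                       n_regions = 8,
                       baseline_group_offset = 2,
                       intervention_effect = 0.5,
                       control_drift = -0.4,
                       subject_sd = 4,
                       region_jitter_sd = 1.5,
                       change_sd = 1.7,
                       region_change_jitter_sd = 0.5,
                       latent_loading = 0.8,
                       latent_coupling_r = c(poms_va = 0.35,
                                             tmt_b_sec = -0.35),
                       behavioral_noise_sd = default_behavioral_noise_sd,
                       voxel_noise_sd = 0.04,
                       render_scale = 0.002,
                       scoring_fwhm_mm = 8,
                       cesd_exclusion_rate = 0.2,
                       seed = 1) {
  cfg <- list(n_per_group = n_per_group, grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, n_regions = n_regions,
              baseline_group_offset = baseline_group_offset,
              intervention_effect = intervention_effect,
              control_drift = control_drift,
              subject_sd = subject_sd, region_jitter_sd = region_jitter_sd,
              change_sd = change_sd,
              region_change_jitter_sd = region_change_jitter_sd,
              latent_loading = latent_loading,
              latent_coupling_r = latent_coupling_r,
              behavioral_noise_sd = behavioral_noise_sd,
              voxel_noise_sd = voxel_noise_sd,
              render_scale = render_scale,
              scoring_fwhm_mm = scoring_fwhm_mm,
              cesd_exclusion_rate = cesd_exclusion_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_per_group) || cfg$n_per_group < 2)
    stop("n_per_group must be >= 2", call. = FALSE)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L))
    stop("grid_shape must be 3 integers >= 4", call. = FALSE)
  if (cfg$voxel_size_mm <= 0) stop("voxel_size_mm must be > 0", call. = FALSE)
  if (cfg$n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  if (cfg$voxel_noise_sd <= 0 || cfg$render_scale <= 0)
    stop("voxel_noise_sd and render_scale must be > 0", call. = FALSE)
  if (cfg$change_sd <= 0 || cfg$subject_sd <= 0)
    stop("change_sd and subject_sd must be > 0", call. = FALSE)
  if (cfg$latent_loading <= 0 || cfg$latent_loading >= 1)
    stop("latent_loading must be in (0, 1)", call. = FALSE)
  r <- cfg$latent_coupling_r
  if (length(r) && is.null(names(r)))
    stop("latent_coupling_r must be a named vector over behavioral measures",
         call. = FALSE)
  if (!all(names(r) %in% behavioral_measures))
    stop("unknown behavioral measure in latent_coupling_r: ",
         paste(setdiff(names(r), behavioral_measures), collapse = ", "),
         call. = FALSE)
  if (any(abs(r) >= 1))
    stop("|latent_coupling_r| must be < 1", call. = FALSE)
  if (any(abs(r) >= cfg$latent_loading))
    stop("|latent_coupling_r| must be < latent_loading for the coupling ",
         "construction to be solvable", call. = FALSE)
  if (cfg$cesd_exclusion_rate < 0 || cfg$cesd_exclusion_rate >= 0.5)
    stop("cesd_exclusion_rate must be in [0, 0.5)", call. = FALSE)
  sf <- cfg$behavioral_noise_sd
  if (!all(behavioral_measures %in% names(sf)) || any(sf[behavioral_measures] <= 0))
    stop("behavioral_noise_sd must name every behavioral measure with a ",
         "positive SD", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' The emulated-study preset configuration
#'
#' Explicit alias for the default study conditions: n = 35 per group,
#' baseline FA offset ~2 points, intervention change ~0.5 points against a
#' -0.4 drift, change correlations of .35.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_study <- function(...) sim_config(...)

# Variance of the latent voxel signal (BHQ points^2) across the full
# reference pool (both groups, both timepoints), from the generative model.
latent_pool_variance <- function(cfg) {
  cell_means <- c(0, cfg$intervention_effect,
                  cfg$baseline_group_offset,
                  cfg$baseline_group_offset + cfg$control_drift)
  cfg$subject_sd^2 + cfg$region_jitter_sd^2 +
    (cfg$change_sd^2 + cfg$region_change_jitter_sd^2) / 2 +
    mean(cell_means^2) - mean(cell_means)^2
}

# Predicted slope of measured regional quotient per latent BHQ point, for a
# scorer using `fwhm_mm` smoothing: 15 c / sqrt(c^2 V + g^2 sigma_v^2).
# Exact (interior voxels) when fwhm_mm = 0; an interior-voxel approximation
# otherwise, since smoothing mixes latent values across region boundaries.
measured_scale_factor <- function(cfg, fwhm_mm = cfg$scoring_fwhm_mm) {
  g <- kernel_noise_factor(fwhm_mm, cfg$voxel_size_mm)
  v <- latent_pool_variance(cfg)
  c_ <- cfg$render_scale
  15 * c_ / sqrt(c_^2 * v + g^2 * cfg$voxel_noise_sd^2)
}

# b and sigma_f of the coupling construction
#   r = a b / sqrt((a^2 + s_e^2)(b^2 + s_f^2)),  a = loading * change_sd,
# solved for b given r and sigma_f; requires |r| < loading.
coupling_slopes <- function(cfg) {
  a <- cfg$latent_loading * cfg$change_sd
  sigma_e <- cfg$change_sd * sqrt(1 - cfg$latent_loading^2)
  r <- structure(numeric(length(behavioral_measures)),
                 names = behavioral_measures)
  r[names(cfg$latent_coupling_r)] <- cfg$latent_coupling_r
  sigma_f <- cfg$behavioral_noise_sd[behavioral_measures]
  b <- r * cfg$change_sd * sigma_f /
    sqrt(a^2 - r^2 * cfg$change_sd^2)
  list(a = a, sigma_e = sigma_e, b = b, sigma_f = sigma_f, r = r)
}

#' Generate a synthetic longitudinal neuroimaging cohort
#'
#' Simulates a two-group pre/post study: participant recruitment with a
#' depression-screen exclusion stream, balanced randomized group assignment,
#' a subject-level latent model of regional FA and GM quotients in which a
#' single latent factor per participant drives both the brain change and the
#' behavioral change (yielding the configured population change-score
#' correlations), and - optionally - voxel-level rendering of FA and tissue
#' maps on a labeled synthetic atlas.
#'
#' The latent scores are generated before any map rendering, so a cohort's
#' participants, behavior and latent scores are identical whether or not
#' maps are rendered under the same seed.
#'
#' @param config a [sim_config()].
#' @param render_maps render voxel maps (`TRUE`, default) or stop at the
#'   subject-level latent scores (`FALSE`; much faster, used for large
#'   Monte-Carlo studies of the downstream statistics).
#' @return a list of class `bhq_cohort` with elements `participants`
#'   (recruits including screened-out ones; columns id, group, age, sex,
#'   cesd, imaging_ok), `behavior` (wide pre/post behavioral table for
#'   retained participants), `latent_scores` (tidy participant/time/modality/
#'   region/value latent quotients), `atlas`, `scans` (list of per-scan map
#'   sets, `NULL` when `render_maps = FALSE`), and `manifest` (the config and
#'   every derived coupling parameter).
#' @export
generate_cohort <- function(config, render_maps = TRUE) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_per_group * 2L

  ## --- recruitment and screening -------------------------------------
  p_ex <- cfg$cesd_exclusion_rate
  n_excluded <- if (p_ex > 0) stats::rbinom(1L, n, p_ex / (1 - p_ex)) else 0L
  n_rec <- n + n_excluded
  ids <- sprintf("P%03d", seq_len(n_rec))
  group <- sample(rep(c("intervention", "control"),
                      length.out = n_rec))        # assigned before screening
  age <- round(stats::runif(n_rec, 40, 68))
  sex <- sample(c("female", "male"), n_rec, replace = TRUE)
  excl <- rep(FALSE, n_rec)
  if (n_excluded > 0) excl[sample.int(n_rec, n_excluded)] <- TRUE
  cesd <- integer(n_rec)
  cesd[excl] <- 16L + stats::rpois(sum(excl), 4)
  cesd[!excl] <- pmin(15L, stats::rpois(sum(!excl), 5))
  participants <- data.frame(id = ids, group = group, age = age, sex = sex,
                             cesd = cesd, imaging_ok = TRUE,
                             stringsAsFactors = FALSE)
  retained <- participants[!excl, , drop = FALSE]
  # balance the retained groups exactly at n_per_group each
  for (g in c("intervention", "control")) {
    idx <- which(retained$group == g)
    if (length(idx) > cfg$n_per_group)
      retained <- retained[-idx[-seq_len(cfg$n_per_group)], , drop = FALSE]
  }
  while (nrow(retained) < n) {     # top up if screening unbalanced a group
    short <- names(which(table(factor(retained$group,
                                      c("intervention", "control"))) <
                         cfg$n_per_group))[1]
    extra_id <- sprintf("P%03d", n_rec + 1L); n_rec <- n_rec + 1L
    newp <- data.frame(id = extra_id, group = short,
                       age = round(stats::runif(1, 40, 68)),
                       sex = sample(c("female", "male"), 1),
                       cesd = pmin(15L, stats::rpois(1, 5)),
                       imaging_ok = TRUE, stringsAsFactors = FALSE)
    participants <- rbind(participants, newp)
    retained <- rbind(retained, newp)
  }
  retained <- retained[order(retained$id), , drop = FALSE]
  is_int <- retained$group == "intervention"

  ## --- latent brain model --------------------------------------------
  k <- cfg$n_regions
  slp <- coupling_slopes(cfg)
  u <- stats::rnorm(n)                                  # shared latent factor
  s_fa <- stats::rnorm(n, 0, cfg$subject_sd)
  jit_fa <- matrix(stats::rnorm(n * k, 0, cfg$region_jitter_sd), n, k)
  mu_g <- ifelse(is_int, cfg$intervention_effect, cfg$control_drift)
  delta <- mu_g + slp$a * u + stats::rnorm(n, 0, slp$sigma_e)
  eta <- matrix(stats::rnorm(n * k, 0, cfg$region_change_jitter_sd), n, k)
  off <- ifelse(is_int, 0, cfg$baseline_group_offset)
  fa_pre <- 100 + s_fa + off + jit_fa                   # n x k, BHQ points
  fa_post <- fa_pre + delta + eta

  s_gm <- stats::rnorm(n, 0, cfg$subject_sd)
  jit_gm <- matrix(stats::rnorm(n * k, 0, cfg$region_jitter_sd), n, k)
  delta_gm <- stats::rnorm(n, 0, cfg$change_sd)         # null GM effect
  eta_gm <- matrix(stats::rnorm(n * k, 0, cfg$region_change_jitter_sd), n, k)
  gm_pre <- 100 + s_gm + jit_gm
  gm_post <- gm_pre + delta_gm + eta_gm

  ## --- behavioral model ----------------------------------------------
  beh_pre <- beh_post <- matrix(NA_real_, n, length(behavioral_measures),
                                dimnames = list(NULL, behavioral_measures))
  for (m in behavioral_measures) {
    bl <- default_behavioral_baseline[[m]]
    pre_raw <- stats::rnorm(n, bl["mean"], bl["sd"])
    # coupling through the shared latent factor in the intervention group
    # only; controls receive variance-matched pure noise, so the two groups
    # differ in correlation structure but not in change variance
    sigma_y <- sqrt(slp$b[m]^2 + slp$sigma_f[m]^2)
    dy <- ifelse(is_int,
                 slp$b[m] * u + stats::rnorm(n, 0, slp$sigma_f[m]),
                 stats::rnorm(n, 0, sigma_y))
    if (m %in% names(tmt_practice_effect))
      dy <- dy + tmt_practice_effect[[m]]
    post_raw <- pre_raw + dy
    if (startsWith(m, "poms_")) {
      beh_pre[, m] <- pmin(20, pmax(0, round(pre_raw)))
      beh_post[, m] <- pmin(20, pmax(0, round(post_raw)))
    } else {
      beh_pre[, m] <- pmax(5, pre_raw)
      beh_post[, m] <- pmax(5, post_raw)
    }
  }
  behavior <- rbind(
    data.frame(participant = retained$id, time = "pre", beh_pre,
               stringsAsFactors = FALSE),
    data.frame(participant = retained$id, time = "post", beh_post,
               stringsAsFactors = FALSE))
  rownames(behavior) <- NULL

  ## --- tidy latent scores --------------------------------------------
  atlas <- generate_atlas(cfg$grid_shape, k, seed = cfg$seed + 1L)
  region_names <- atlas$names
  tidy_block <- function(mat, tp, modality) {
    # mat: n x k latent points; emit regions plus the whole-brain mean
    vals <- cbind(mat, rowMeans(mat))
    data.frame(participant = rep(retained$id, each = k + 1L),
               time = tp, modality = modality,
               region = rep(c(region_names, "whole_brain"), n),
               value = as.numeric(t(vals)), stringsAsFactors = FALSE)
  }
  latent_scores <- rbind(tidy_block(fa_pre, "pre", "fa_bhq"),
                         tidy_block(fa_post, "post", "fa_bhq"),
                         tidy_block(gm_pre, "pre", "gm_bhq"),
                         tidy_block(gm_post, "post", "gm_bhq"))
  rownames(latent_scores) <- NULL

  ## --- voxel rendering -------------------------------------------------
  scans <- NULL
  if (render_maps) {
    lab <- atlas$labels
    inmask <- lab > 0L
    lab_in <- lab[inmask]
    fa_base <- stats::runif(k, 0.35, 0.65)
    gm_base <- stats::runif(k, 0.40, 0.70)
    c_ <- cfg$render_scale
    sv <- cfg$voxel_noise_sd
    vs <- cfg$voxel_size_mm
    d <- cfg$grid_shape
    head_factor <- exp(stats::rnorm(n, 0, 0.1))
    render_one <- function(base_r, latent_row, modality, scale_mult = 1) {
      x <- array(0, dim = d)
      vox <- base_r[lab_in] + c_ * (latent_row[lab_in] - 100) +
        stats::rnorm(sum(inmask), 0, sv)
      vox <- vox * scale_mult
      if (modality == "fa") vox <- pmin(1, pmax(0, vox))
      else vox <- pmax(0, vox)
      x[inmask] <- vox
      volume_grid(x, vs, modality)
    }
    flat100 <- matrix(100, 1, k)
    scans <- list()
    for (i in seq_len(n)) {
      for (tp in c("pre", "post")) {
        fa_lat <- if (tp == "pre") fa_pre[i, ] else fa_post[i, ]
        gm_lat <- if (tp == "pre") gm_pre[i, ] else gm_post[i, ]
        scans[[length(scans) + 1L]] <- list(
          participant = retained$id[i], time = tp,
          fa  = render_one(fa_base, fa_lat, "fa"),
          gm  = render_one(gm_base, gm_lat, "gm", head_factor[i]),
          wm  = render_one(rep(0.35, k), flat100[1, ], "wm", head_factor[i]),
          csf = render_one(rep(0.20, k), flat100[1, ], "csf", head_factor[i]))
      }
    }
  }

  manifest <- list(
    config = unclass(cfg),
    derived = list(a = slp$a, sigma_e = slp$sigma_e,
                   b = as.list(slp$b), sigma_f = as.list(slp$sigma_f),
                   coupling_r = as.list(slp$r),
                   latent_pool_variance = latent_pool_variance(cfg),
                   kernel_noise_factor =
                     kernel_noise_factor(cfg$scoring_fwhm_mm,
                                         cfg$voxel_size_mm),
                   measured_scale_factor_fwhm0 =
                     measured_scale_factor(cfg, 0),
                   measured_scale_factor_scoring_fwhm =
                     measured_scale_factor(cfg)))

  structure(list(participants = participants,
                 retained = retained,
                 behavior = behavior,
                 latent_scores = latent_scores,
                 atlas = atlas,
                 scans = scans,
                 manifest = manifest),
            class = "bhq_cohort")
}

#' @export
print.bhq_cohort <- function(x, ...) {
  cat(sprintf(paste0("<bhq_cohort> %d recruited, %d retained ",
                     "(%d intervention / %d control), maps %s\n"),
              nrow(x$participants), nrow(x$retained),
              sum(x$retained$group == "intervention"),
              sum(x$retained$group == "control"),
              if (is.null(x$scans)) "not rendered"
              else sprintf("rendered (%d scans)", length(x$scans))))
  invisible(x)
}

#' Apply the study's screening exclusions
#'
#' Retains participants whose depression-scale score is below the threshold
#' and whose imaging succeeded; everyone else goes to the exclusion log with
#' a reason.
#'
#' @param participants data.frame with columns `id`, `cesd`, `imaging_ok`.
#' @param cesd_threshold exclusion threshold (score at or above is excluded);
#'   default 16.
#' @return list with `retained` (data.frame) and `exclusions` (data.frame of
#'   id, reason).
#' @export
apply_exclusions <- function(participants, cesd_threshold = 16) {
  if (!all(c("id", "cesd", "imaging_ok") %in% names(participants)))
    stop("participants need columns id, cesd, imaging_ok", call. = FALSE)
  if (any(is.na(participants$cesd)))
    stop("missing CES-D scores", call. = FALSE)
  dep <- participants$cesd >= cesd_threshold
  img <- !participants$imaging_ok
  reason <- ifelse(dep, "cesd_at_or_above_threshold",
                   ifelse(img, "imaging_failure", NA_character_))
  excluded <- !is.na(reason)
  list(retained = participants[!excluded, , drop = FALSE],
       exclusions = data.frame(id = participants$id[excluded],
                               reason = reason[excluded],
                               stringsAsFactors = FALSE))
}
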