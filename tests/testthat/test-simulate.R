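small_cfg <- function(...) {
  sim_config(n_per_group = 8, grid_shape = c(12, 12, 12), n_regions = 4,
             seed = 101, ...)
}

test_that("configuration validation catches degenerate designs", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(grid_shape = c(2, 2, 2)), "grid_shape")
  expect_error(sim_config(latent_coupling_r = c(poms_va = 1.2)), "< 1")
  expect_error(sim_config(latent_coupling_r = c(poms_va = 0.9)),
               "latent_loading")
  expect_error(sim_config(latent_coupling_r = c(nonsense = 0.2)), "unknown")
  expect_error(sim_config(voxel_noise_sd = 0), "> 0")
  expect_error(sim_config(cesd_exclusion_rate = 0.6), "0.5")
})

test_that("identical seed and config give a bit-identical cohort", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(a, b)
  d <- generate_cohort(sim_config(n_per_group = 8,
                                  grid_shape = c(12, 12, 12),
                                  n_regions = 4, seed = 102))
  expect_false(identical(a$latent_scores, d$latent_scores))
})

test_that("latent scores and behavior do not depend on map rendering", {
  a <- generate_cohort(small_cfg(), render_maps = TRUE)
  b <- generate_cohort(small_cfg(), render_maps = FALSE)
  expect_null(b$scans)
  expect_identical(a$latent_scores, b$latent_scores)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$participants, b$participants)
})

test_that("generated maps respect their value domains", {
  coh <- generate_cohort(small_cfg())
  for (s in coh$scans[1:6]) {
    expect_true(all(s$fa$values >= 0 & s$fa$values <= 1))
    expect_true(all(s$gm$values >= 0))
    expect_true(all(s$wm$values >= 0))
    expect_true(all(s$csf$values >= 0))
  }
})

test_that("groups are balanced and assigned before screening", {
  coh <- generate_cohort(small_cfg())
  expect_identical(as.integer(table(coh$retained$group)[c("intervention",
                                                          "control")]),
                   c(8L, 8L))
  # every recruit, including screened-out ones, carries a group label
  expect_false(anyNA(coh$participants$group))
  expect_true(all(coh$participants$cesd >= 0))
  # POMS scores are integers inside the instrument's range
  pm <- as.matrix(coh$behavior[, grep("^poms_", names(coh$behavior))])
  expect_true(all(pm == round(pm) & pm >= 0 & pm <= 20))
  expect_true(all(coh$behavior$tmt_a_sec > 0 & coh$behavior$tmt_b_sec > 0))
  # Part B slower than Part A on average
  expect_gt(mean(coh$behavior$tmt_b_sec), mean(coh$behavior$tmt_a_sec))
})

test_that("manifest records the coupling construction parameters", {
  cfg <- small_cfg()
  coh <- generate_cohort(cfg, render_maps = FALSE)
  der <- coh$manifest$derived
  a <- der$a; se <- der$sigma_e
  expect_equal(a^2 + se^2, cfg$change_sd^2, tolerance = 1e-12)
  # r = a b / sqrt((a^2 + s_e^2)(b^2 + s_f^2)) recovers the configured r
  for (m in names(cfg$latent_coupling_r)) {
    b <- der$b[[m]]; sf <- der$sigma_f[[m]]
    r_implied <- a * b / sqrt((a^2 + se^2) * (b^2 + sf^2))
    expect_equal(r_implied, unname(cfg$latent_coupling_r[m]),
                 tolerance = 1e-10)
  }
})

test_that("screening exclusions follow the threshold rule", {
  participants <- data.frame(
    id = sprintf("P%03d", 1:89),
    cesd = c(rep(20L, 18), rep(5L, 71)),
    imaging_ok = c(rep(TRUE, 88), FALSE))
  res <- apply_exclusions(participants, cesd_threshold = 16)
  expect_identical(nrow(res$retained), 70L)
  expect_identical(sum(res$exclusions$reason == "cesd_at_or_above_threshold"),
                   18L)
  expect_identical(sum(res$exclusions$reason == "imaging_failure"), 1L)
  # all-zero scores: nobody excluded; threshold 0: everybody excluded
  ok <- data.frame(id = c("a", "b"), cesd = c(0L, 0L), imaging_ok = TRUE)
  expect_identical(nrow(apply_exclusions(ok)$retained), 2L)
  expect_identical(nrow(apply_exclusions(ok, cesd_threshold = 0)$retained),
                   0L)
  bad <- data.frame(id = "a", cesd = NA_integer_, imaging_ok = TRUE)
  expect_error(apply_exclusions(bad), "missing")
})

test_that("null generator yields calibrated interaction p-values (quick)", {
  # smoke-level calibration; the full 1000-replicate band is asserted in the
  # acceptance suite
  hits <- 0L
  for (i in 1:60) {
    coh <- generate_cohort(sim_config(
      n_per_group = 10, grid_shape = c(8, 8, 8), n_regions = 2,
      baseline_group_offset = 0, intervention_effect = 0, control_drift = 0,
      latent_coupling_r = c(poms_va = 0), seed = 500 + i),
      render_maps = FALSE)
    fr <- cohort_frame(coh$latent_scores, coh$behavior, coh$retained)
    hits <- hits + (mixed_anova_2x2(fr, "fa_bhq")$p_two_sided < 0.05)
  }
  expect_lte(hits, 9L)   # P(X > 9 | Binom(60, .05)) < 0.2%
})

test_that("preset effect sizes give majority power for the interaction", {
  # at the default conditions (0.5-point intervention change vs -0.4 drift,
  # change SD 1.7, n = 35/group) the whole-brain FA interaction should be
  # detected in well over half of replicates
  hits <- 0L
  n_rep <- 600
  for (i in seq_len(n_rep)) {
    coh <- generate_cohort(sim_config(grid_shape = c(8, 8, 8),
                                      n_regions = 2, seed = 7000 + i),
                           render_maps = FALSE)
    lat <- coh$latent_scores
    fr <- lat[lat$modality == "fa_bhq" & lat$region == "whole_brain", ]
    fr$measure <- "fa_bhq"
    fr$group <- coh$retained$group[match(fr$participant, coh$retained$id)]
    hits <- hits + (mixed_anova_2x2(fr, "fa_bhq")$p_two_sided < 0.05)
  }
  expect_gt(hits / n_rep, 0.5)
})

test_that("rendered group change difference matches its predicted scale", {
  # across replicates, the measured whole-brain FA-BHQ change difference
  # (intervention minus control) must converge on the generator's predicted
  # measured-scale image of (intervention_effect - control_drift), within
  # 2 SE; scored without smoothing, where the scale prediction is exact
  n_rep <- 10
  diffs <- numeric(n_rep)
  cfgs <- lapply(seq_len(n_rep), function(i)
    sim_config(n_per_group = 8, grid_shape = c(12, 12, 12), n_regions = 4,
               seed = 8000 + i))
  for (i in seq_len(n_rep)) {
    coh <- generate_cohort(cfgs[[i]])
    sc <- score_cohort(coh$scans, coh$atlas, "fa", fwhm_mm = 0)
    wb <- sc[sc$region == "whole_brain", ]
    w <- reshape(wb[, c("participant", "time", "value")],
                 idvar = "participant", timevar = "time",
                 direction = "wide")
    chg <- w$value.post - w$value.pre
    grp <- coh$retained$group[match(w$participant, coh$retained$id)]
    diffs[i] <- mean(chg[grp == "intervention"]) - mean(chg[grp == "control"])
  }
  cfg <- cfgs[[1]]
  kappa <- bhqpipe:::measured_scale_factor(cfg, 0)
  predicted <- kappa * (cfg$intervention_effect - cfg$control_drift)
  se <- sd(diffs) / sqrt(n_rep)
  expect_lt(abs(mean(diffs) - predicted), 2 * se + 0.05 * predicted)
})
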