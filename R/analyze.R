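#' Assemble the tidy cohort frame analyzed by the statistical battery
#'
#' Joins quotient scores and behavioral scores into one long table of
#' (participant, group, time, measure, value) rows. Whole-brain quotients
#' become measures `fa_bhq` / `gm_bhq`; regional FA quotients keep their
#' region name as the measure; behavioral columns become `poms_*`, `tmt_a`,
#' `tmt_b`, and the derived `tmt_b_a` difference score.
#'
#' @param scores tidy score table (`participant`, `time`, `modality`,
#'   `region`, `value`), e.g. from [score_cohort()] or a cohort's
#'   `latent_scores`.
#' @param behavior wide behavioral table (`participant`, `time`, one column
#'   per behavioral measure), e.g. a cohort's `behavior`.
#' @param participants data.frame with `id` and `group` for every scored
#'   participant.
#' @return a data.frame with columns `participant`, `group`, `time`,
#'   `measure`, `value`.
#' @export
cohort_frame <- function(scores, behavior, participants) {
  grp <- stats::setNames(participants$group, participants$id)
  sc <- scores
  sc$measure <- ifelse(sc$region == "whole_brain", sc$modality,
                       ifelse(sc$modality == "fa_bhq", sc$region,
                              paste0("gm_", sc$region)))
  out_sc <- data.frame(participant = sc$participant,
                       group = unname(grp[sc$participant]),
                       time = sc$time, measure = sc$measure,
                       value = sc$value, stringsAsFactors = FALSE)
  beh_cols <- intersect(behavioral_measures, names(behavior))
  out_beh <- do.call(rbind, lapply(beh_cols, function(m) {
    nm <- switch(m, tmt_a_sec = "tmt_a", tmt_b_sec = "tmt_b", m)
    data.frame(participant = behavior$participant,
               group = unname(grp[behavior$participant]),
               time = behavior$time, measure = nm,
               value = behavior[[m]], stringsAsFactors = FALSE)
  }))
  out <- rbind(out_sc, out_beh)
  if (all(c("tmt_a_sec", "tmt_b_sec") %in% beh_cols)) {
    ba <- data.frame(participant = behavior$participant,
                     group = unname(grp[behavior$participant]),
                     time = behavior$time, measure = "tmt_b_a",
                     value = tmt_b_minus_a(behavior$tmt_b_sec,
                                           behavior$tmt_a_sec),
                     stringsAsFactors = FALSE)
    out <- rbind(out, ba)
  }
  if (anyNA(out$group))
    stop("some participants in the scores/behavior tables are missing from ",
         "'participants'", call. = FALSE)
  dup <- duplicated(out[, c("participant", "time", "measure")])
  if (any(dup))
    stop("duplicate (participant, time, measure) rows", call. = FALSE)
  rownames(out) <- NULL
  out
}

# per-participant change scores (post - pre) for one measure
change_scores <- function(frame, measure) {
  fr <- frame[frame$measure == measure, , drop = FALSE]
  w <- stats::reshape(fr[, c("participant", "group", "time", "value")],
                      idvar = c("participant", "group"),
                      timevar = "time", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  w <- w[stats::complete.cases(w$pre, w$post), , drop = FALSE]
  data.frame(participant = w$participant, group = w$group,
             change = w$post - w$pre, pre = w$pre, post = w$post,
             stringsAsFactors = FALSE)
}

measure_families <- function(frame) {
  ms <- unique(frame$measure)
  regional_fa <- intersect(wm_tract_names, ms)
  list(
    brain = intersect(c("fa_bhq", "gm_bhq", regional_fa), ms),
    regional_fa = regional_fa,
    poms = intersect(c("poms_ah", "poms_cb", "poms_dd", "poms_fi",
                       "poms_ta", "poms_va", "poms_f"), ms),
    tmt = intersect(c("tmt_a", "tmt_b", "tmt_b_a"), ms))
}

#' Run the complete intervention-study statistical battery
#'
#' Reproduces the report structure of a two-group pre/post quotient study:
#' \itemize{
#'   \item baseline group comparisons (pooled two-sample t per measure, plus
#'     a sex chi-square when a participant table is supplied);
#'   \item Time-by-Group interaction per measure with partial eta squared,
#'     within-group paired t-tests with Cohen's d, and Benjamini-Hochberg
#'     adjustment over the regional-FA interaction p values;
#'   \item change-score correlation matrices (brain change vs behavioral
#'     change) per group, with the zero-correlation t-test;
#'   \item the Fisher r-to-z panel comparing each correlation between
#'     groups, with both one- and two-sided p values.
#' }
#'
#' @param frame tidy cohort frame from [cohort_frame()].
#' @param participants optional participant table (`id`, `group`, `sex`) for
#'   the baseline sex comparison.
#' @param bh_family measures whose interaction p values form the
#'   multiple-comparison family; default the regional FA measures present.
#' @param bh_q FDR level; default 0.05.
#' @param welch use Welch instead of pooled two-sample t at baseline.
#' @return a list of class `bhq_report` with data.frames `baseline`,
#'   `interaction`, `correlations`, `fisher`, and a `metadata` list (dropped
#'   cases, flagged analysis notes).
#' @export
analyze_study <- function(frame, participants = NULL, bh_family = NULL,
                          bh_q = 0.05, welch = FALSE) {
  fam <- measure_families(frame)
  groups <- sort(unique(frame$group))
  if (!identical(groups, c("control", "intervention")))
    stop("frame must contain exactly the groups 'intervention' and 'control'",
         call. = FALSE)

  ## baseline -----------------------------------------------------------
  base_measures <- c(fam$brain, fam$poms, fam$tmt)
  baseline <- do.call(rbind, lapply(base_measures, function(m) {
    pre <- frame[frame$measure == m & frame$time == "pre", ]
    xi <- pre$value[pre$group == "intervention"]
    xc <- pre$value[pre$group == "control"]
    tt <- two_sample_t(x1 = xi, x2 = xc, welch = welch)
    data.frame(measure = m,
               mean_intervention = mean(xi), sd_intervention = stats::sd(xi),
               mean_control = mean(xc), sd_control = stats::sd(xc),
               t = tt$statistic, df = tt$df, p = tt$p_two_sided,
               stringsAsFactors = FALSE)
  }))
  sex_test <- NULL
  if (!is.null(participants) && "sex" %in% names(participants)) {
    ids <- unique(frame$participant)
    pp <- participants[participants$id %in% ids, ]
    tab <- table(factor(pp$group, c("intervention", "control")),
                 factor(pp$sex, c("male", "female")))
    sex_test <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }

  ## interaction + within-group tests ------------------------------------
  int_measures <- c(fam$brain, fam$poms, fam$tmt)
  interaction <- do.call(rbind, lapply(int_measures, function(m) {
    an <- mixed_anova_2x2(frame, m)
    cs <- change_scores(frame, m)
    pi_ <- cs[cs$group == "intervention", ]
    pc <- cs[cs$group == "control", ]
    ti <- paired_t(pi_$pre, pi_$post)
    tc <- paired_t(pc$pre, pc$post)
    data.frame(measure = m, F = an$statistic, df1 = an$df[["df1"]],
               df2 = an$df[["df2"]], p = an$p_two_sided,
               partial_eta_sq = an$effect_size,
               t_intervention = ti$statistic, p_intervention = ti$p_two_sided,
               d_intervention = ti$effect_size,
               t_control = tc$statistic, p_control = tc$p_two_sided,
               d_control = tc$effect_size,
               change_intervention = mean(pi_$change),
               change_control = mean(pc$change),
               stringsAsFactors = FALSE)
  }))
  if (is.null(bh_family)) bh_family <- fam$regional_fa
  interaction$p_bh <- NA_real_
  interaction$bh_significant <- NA
  if (length(bh_family)) {
    idx <- match(bh_family, interaction$measure)
    idx <- idx[!is.na(idx)]
    bh <- benjamini_hochberg(interaction$p[idx], q = bh_q)
    interaction$p_bh[idx] <- bh$adjusted
    interaction$bh_significant[idx] <- bh$rejected
  }

  ## change correlations + Fisher panel ----------------------------------
  brain_ms <- c(intersect("fa_bhq", fam$brain), fam$regional_fa)
  beh_ms <- c(fam$poms, fam$tmt)
  corr_rows <- list(); fisher_rows <- list()
  for (bm in brain_ms) {
    dxf <- change_scores(frame, bm)
    for (ym in beh_ms) {
      dyf <- change_scores(frame, ym)
      merged <- merge(dxf[, c("participant", "group", "change")],
                      dyf[, c("participant", "change")],
                      by = "participant", suffixes = c("_brain", "_beh"))
      rg <- list()
      for (g in c("intervention", "control")) {
        mg <- merged[merged$group == g, ]
        ct <- pearson_change_correlation(mg$change_brain, mg$change_beh)
        rg[[g]] <- ct
        corr_rows[[length(corr_rows) + 1L]] <-
          data.frame(group = g, brain_measure = bm, behavioral_measure = ym,
                     r = ct$r, t = ct$statistic, df = ct$df,
                     p = ct$p_two_sided, n = ct$n, stringsAsFactors = FALSE)
      }
      fz <- fisher_z_compare(rg$intervention$r, rg$intervention$n,
                             rg$control$r, rg$control$n)
      fisher_rows[[length(fisher_rows) + 1L]] <-
        data.frame(brain_measure = bm, behavioral_measure = ym,
                   r_intervention = fz$r1, r_control = fz$r2,
                   z = fz$z, p_one_sided = fz$p_one_sided,
                   p_two_sided = fz$p_two_sided, stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corr_rows)
  fisher <- do.call(rbind, fisher_rows)

  structure(list(
    baseline = baseline,
    sex_test = sex_test,
    interaction = interaction,
    correlations = correlations,
    fisher = fisher,
    metadata = list(
      groups = groups,
      n_per_group = stats::setNames(
        as.integer(table(factor(
          unique(frame[, c("participant", "group")])$group, groups))),
        groups),
      bh_family = bh_family,
      welch = welch,
      notes = c(
        paste("Benjamini-Hochberg applied over the regional-FA interaction",
              "family; note that published regional p values of comparable",
              "magnitude need not survive the standard step-up."),
        paste("Fisher r-to-z panel reports both sidedness conventions;",
              "one-sided normal tails can differ materially from the",
              "two-sided values at these z magnitudes.")))),
    class = "bhq_report")
}

#' @export
print.bhq_report <- function(x, ...) {
  cat("<bhq_report>\n")
  cat(sprintf("  baseline comparisons : %d measures\n", nrow(x$baseline)))
  cat(sprintf("  interaction tests    : %d measures (%d in BH family)\n",
              nrow(x$interaction), length(x$metadata$bh_family)))
  cat(sprintf("  change correlations  : %d rows; Fisher panel: %d rows\n",
              nrow(x$correlations), nrow(x$fisher)))
  invisible(x)
}

# 3-decimal half-up rounding used for display tables
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
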