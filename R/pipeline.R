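#' Full-run configuration
#'
#' Bundles the simulation, scoring and analysis options of one reproducible
#' end-to-end run. Serializable to a single YAML (or JSON) file;
#' a persisted config plus its seed reproduces a run bit-identically.
#'
#' @param sim a [sim_config()] (or a list of its arguments).
#' @param fwhm_mm scoring smoothing kernel FWHM in mm; default 8.
#' @param sd_convention reference-field SD convention; default
#'   `"population"`.
#' @param reference_pool `"all"` or `"pre"`; default `"all"`.
#' @param sd_floor reference mask SD floor; default 1e-6.
#' @param bh_q FDR level of the multiple-comparison step; default 0.05.
#' @param welch Welch baseline t-tests; default FALSE.
#' @param write_volumes write every rendered map as NIfTI into the run
#'   directory (slower, larger); default FALSE.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), fwhm_mm = 8,
                       sd_convention = c("population", "sample"),
                       reference_pool = c("all", "pre"),
                       sd_floor = 1e-6, bh_q = 0.05, welch = FALSE,
                       write_volumes = FALSE) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, as.list(sim))
  structure(list(sim = sim,
                 fwhm_mm = fwhm_mm,
                 sd_convention = match.arg(sd_convention),
                 reference_pool = match.arg(reference_pool),
                 sd_floor = sd_floor, bh_q = bh_q, welch = welch,
                 write_volumes = write_volumes),
            class = "run_config")
}

#' Write / read a run configuration
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$latent_coupling_r <- as.list(x$sim$latent_coupling_r)
  x$sim$behavioral_noise_sd <- as.list(x$sim$behavioral_noise_sd)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$latent_coupling_r <- unlist(x$sim$latent_coupling_r)
  x$sim$behavioral_noise_sd <- unlist(x$sim$behavioral_noise_sd)
  x$sim <- do.call(sim_config, x$sim)
  do.call(run_config, x)
}

#' Run the whole pipeline: simulate, score, analyze, report
#'
#' Generates a synthetic cohort, scores FA and GM quotients through the full
#' voxel pipeline, assembles the cohort frame, runs the statistical battery,
#' and writes every artifact (config, manifest, scores CSV, behavioral CSV,
#' report CSVs, results JSON, artifact index) into `out_dir`. Reruns with
#' the same config and seed are bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; must be writable).
#' @param seed optional integer overriding `config$sim$seed`.
#' @return the output directory path, invisibly; the in-memory results as
#'   attribute `"results"`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", out_dir,
                        call. = FALSE)
  unlink(probe)

  cohort <- generate_cohort(config$sim, render_maps = TRUE)
  fa_scores <- score_cohort(cohort$scans, cohort$atlas, "fa",
                            fwhm_mm = config$fwhm_mm,
                            sd_convention = config$sd_convention,
                            reference_pool = config$reference_pool,
                            sd_floor = config$sd_floor)
  gm_scores <- score_cohort(cohort$scans, cohort$atlas, "gm",
                            fwhm_mm = config$fwhm_mm,
                            sd_convention = config$sd_convention,
                            reference_pool = config$reference_pool,
                            sd_floor = config$sd_floor)
  scores <- rbind(fa_scores, gm_scores)
  attr(scores, "reference") <- NULL
  frame <- cohort_frame(scores, cohort$behavior, cohort$retained)
  report <- analyze_study(frame, participants = cohort$retained,
                          bh_q = config$bh_q, welch = config$welch)
  verification <- verify_printed_statistics()

  artifacts <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    write_csv(df, p)
    artifacts[[length(artifacts) + 1L]] <<- name
  }
  put_csv(cohort$participants, "participants.csv")
  put_csv(cohort$behavior, "behavior.csv")
  put_csv(scores, "scores.csv")
  put_csv(frame, "cohort_frame.csv")
  put_csv(report$baseline, "report_baseline.csv")
  put_csv(report$interaction, "report_interaction.csv")
  put_csv(report$correlations, "report_correlations.csv")
  put_csv(report$fisher, "report_fisher.csv")
  put_csv(verification, "verification.csv")

  write_volume_nifti(cohort$atlas, file.path(out_dir, "atlas.nii.gz"))
  artifacts <- c(artifacts, "atlas.nii.gz")
  if (isTRUE(config$write_volumes)) {
    vol_dir <- file.path(out_dir, "volumes")
    dir.create(vol_dir, showWarnings = FALSE)
    for (s in cohort$scans) {
      for (mod in c("fa", "gm", "wm", "csf")) {
        nm <- sprintf("volumes/%s_%s_%s.nii.gz", s$participant, s$time, mod)
        write_volume_nifti(s[[mod]], file.path(out_dir, nm))
        artifacts <- c(artifacts, nm)
      }
    }
  }

  results <- list(report = report, verification = verification,
                  manifest = cohort$manifest)
  write_manifest_json(cohort$manifest, file.path(out_dir, "manifest.json"))
  write_manifest_json(
    list(fisher = report$fisher,
         interaction = report$interaction,
         baseline = report$baseline,
         metadata = report$metadata,
         verification_pass = all(verification$pass)),
    file.path(out_dir, "results.json"))
  artifacts <- c(artifacts, "manifest.json", "results.json")
  write_manifest_json(list(artifacts = artifacts),
                      file.path(out_dir, "index.json"))
  write_run_config(config, file.path(out_dir, "config.yaml"))

  out <- invisible(out_dir)
  attr(out, "results") <- results
  out
}
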