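#' Resolved configuration for a full pipeline run
#'
#' Collects the stage parameters of the analysis chain with their standard
#' defaults: CV-percentile 80, inconsistency cutoff 1.81,
#' nearest-neighbour factor 4.15, 4-peaks/8-timepoints timecourse rule,
#' 1000 simulated nulls per gene, q cutoff 0.05, in-phase window +/-2 h,
#' lag band (2, 8], antiphase band \[11, 13\], 2-fold control limit.
#'
#' @param sim a [sim_config()] describing the synthetic experiment.
#' @param cv_percentile,iir_cutoff,nn_factor,min_peaks,min_timepoints
#'   proteome rollup parameters.
#' @param n_sims,q_cutoff rhythm detection parameters.
#' @param in_phase_window,control_fold comparison parameters.
#' @param use_coverage run transcript quantification through simulated
#'   per-base coverage (default TRUE); otherwise the simulated mRNA
#'   timecourses feed the rhythm stage directly.
#' @param operating_characteristics estimate sensitivity/specificity and
#'   corrected cycling proportions (adds simulation time).
#' @param oc_n_rep simulated series per operating-characteristics arm.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       cv_percentile = 80, iir_cutoff = 1.81,
                       nn_factor = 4.15, min_peaks = 4, min_timepoints = 8,
                       n_sims = 1000, q_cutoff = 0.05,
                       in_phase_window = 2, control_fold = 2,
                       use_coverage = TRUE,
                       operating_characteristics = TRUE,
                       oc_n_rep = 200) {
  stopifnot(inherits(sim, "sim_config"))
  chk <- function(ok, msg) if (!ok) abort(paste0("Invalid run_config: ", msg))
  chk(cv_percentile > 0 && cv_percentile <= 100,
      "`cv_percentile` must lie in (0, 100].")
  chk(iir_cutoff > 0, "`iir_cutoff` must be > 0.")
  chk(nn_factor > 0, "`nn_factor` must be > 0.")
  chk(q_cutoff > 0 && q_cutoff < 1, "`q_cutoff` must lie in (0, 1).")
  chk(n_sims >= 100, "`n_sims` must be >= 100.")
  chk(min_peaks >= 1 && min_timepoints >= 3, "timecourse rule out of range.")
  structure(list(sim = sim, cv_percentile = cv_percentile,
                 iir_cutoff = iir_cutoff, nn_factor = nn_factor,
                 min_peaks = min_peaks, min_timepoints = min_timepoints,
                 n_sims = n_sims, q_cutoff = q_cutoff,
                 in_phase_window = in_phase_window,
                 control_fold = control_fold,
                 use_coverage = use_coverage,
                 operating_characteristics = operating_characteristics,
                 oc_n_rep = oc_n_rep),
            class = "run_config")
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[dielcycle] ", fmt), ...))

#' Run the full synthetic-to-report analysis chain
#'
#' Simulate -> protein rollup -> transcript quantification -> per-level
#' rhythm detection -> mRNA-protein pairing -> cohort report. Every stage's
#' outputs are written as headered TSV/JSON under `out_dir`; identical
#' config and seed give byte-identical outputs. One log line per stage
#' reports input/output record counts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`truth`,
#'   `proteome`, `abundances`, `cycling_mrna`, `cycling_protein`,
#'   `pairing`, `report`, `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$sim$seed

  # stage 1: synthetic data
  ds <- simulate_dataset(config$sim, coverage = config$use_coverage)
  stage_log("simulate: %d genes, %d timepoints, %d peaks",
            nrow(ds$truth), length(config$sim$times), nrow(ds$peaks$peaks))
  write_tsv_with_header(ds$truth, file.path(out_dir, "truth.tsv"),
                        "synthetic truth",
                        "phases/lags hours; halfamps log2 units", hash)
  write_peaks_tsv(ds$peaks$peaks, file.path(out_dir, "peaks.tsv"), hash)
  write_timecourse_tsv(ds$timecourses,
                       file.path(out_dir, "timecourses_true.tsv"), hash)

  # stage 2: proteome rollup
  prot <- quantify_proteome(ds$peaks$peaks,
                            cv_percentile = config$cv_percentile,
                            iir_cutoff = config$iir_cutoff,
                            nn_factor = config$nn_factor,
                            min_timepoints = config$min_timepoints,
                            start_threshold = config$min_peaks)
  stage_log("quant-protein: %d peaks in, %d retained (%.1f%%), %d proteins resolvable",
            prot$audit$peaks_in, prot$audit$retained,
            100 * prot$audit$retained_fraction,
            prot$audit$proteins_resolvable)
  write_tsv_with_header(prot$timecourses,
                        file.path(out_dir, "protein_timecourses.tsv"),
                        "protein timecourses",
                        "time_h hours; log2_ratio/ci log2 units", hash)
  audit_out <- prot$audit
  audit_out$timepoint_offsets <- as.list(
    setNames(audit_out$timepoint_offsets$offset,
             audit_out$timepoint_offsets$timepoint_index))
  jsonlite::write_json(audit_out, file.path(out_dir, "proteome_audit.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  # stage 3: transcript quantification
  if (config$use_coverage) {
    abund <- quantify_transcripts(ds$coverage, ds$genes)
    mrna_tc <- transcript_timecourses(abund, config$sim$times)
    anti <- antisense_stats(abund)
    stage_log("quant-transcript: %d genes x %d timepoints; antisense detected %.1f%%",
              dplyr::n_distinct(abund$gene_id),
              dplyr::n_distinct(abund$timepoint_index),
              100 * anti$summary$frac_antisense_mean)
    write_tsv_with_header(abund, file.path(out_dir, "gene_abundance.tsv"),
                          "gene abundance",
                          "sense/antisense normalized coverage (1/bp)", hash)
  } else {
    mrna_tc <- dplyr::filter(ds$timecourses, .data$level == "mRNA")
    abund <- NULL
    anti <- NULL
    stage_log("quant-transcript: skipped (direct timecourses)")
  }
  write_timecourse_tsv(mrna_tc, file.path(out_dir, "mrna_timecourses.tsv"),
                       hash)

  # stage 4: rhythm detection, both levels
  cyc_m <- detect_cycling(mrna_tc, n_sims = config$n_sims,
                          seed = derive_seed(seed, "cyc", "mRNA"),
                          q_cutoff = config$q_cutoff)
  prot_tc <- prot$timecourses |>
    mutate(gene_id = .data$protein_id, level = "protein",
           log2_abundance = .data$log2_ratio,
           mask = !.data$outlier_flag) |>
    dplyr::select("gene_id", "level", "timepoint_index", "time_h",
                  "log2_abundance", "mask")
  cyc_p <- detect_cycling(prot_tc, n_sims = config$n_sims,
                          seed = derive_seed(seed, "cyc", "protein"),
                          q_cutoff = config$q_cutoff)
  stage_log("detect-cycling: mRNA %d/%d significant; protein %d/%d",
            sum(cyc_m$results$significant), nrow(cyc_m$results),
            sum(cyc_p$results$significant), nrow(cyc_p$results))
  write_tsv_with_header(cyc_m$results, file.path(out_dir, "cycling_mrna.tsv"),
                        "cycling results",
                        "phase hours; halfamp/F log2 units", hash)
  write_tsv_with_header(cyc_p$results,
                        file.path(out_dir, "cycling_protein.tsv"),
                        "cycling results",
                        "phase hours; halfamp/F log2 units", hash)

  # stage 5: pairing and cohort report
  pairing <- pair_cycling(cyc_m, cyc_p)
  stage_log("compare: %d paired cycling genes", nrow(pairing$pairs))
  write_tsv_with_header(pairing$pairs, file.path(out_dir, "paired.tsv"),
                        "paired cycling summary",
                        "lag hours; amp ratios dimensionless", hash)

  report <- list(config_hash = hash)
  if (nrow(pairing$pairs) > 0) {
    coh <- summarize_cohort(pairing)
    report$cohort_counts <- as.list(coh$counts)
    report$cohort_medians <- as.list(coh$medians)
    report$lag_windows <- lag_by_peak_window(pairing)
  }
  if (!is.null(anti)) report$antisense <- as.list(anti$summary)
  if (config$operating_characteristics) {
    oc_m <- estimate_operating_characteristics(
      cyc_m, config$sim$times, n_rep = config$oc_n_rep,
      seed = derive_seed(seed, "oc", "mRNA"))
    oc_p <- estimate_operating_characteristics(
      cyc_p, config$sim$times, n_rep = config$oc_n_rep,
      seed = derive_seed(seed, "oc", "protein"))
    corr <- function(cyc, oc) {
      r <- dplyr::filter(cyc$results, .data$resolvable)
      if (is.na(oc$sensitivity)) return(NULL)
      as.list(estimate_cycling_proportion(sum(r$significant), nrow(r),
                                          oc$sensitivity, oc$specificity))
    }
    report$operating_characteristics <- list(
      mrna = as.list(oc_m), protein = as.list(oc_p))
    report$corrected_cycling <- list(mrna = corr(cyc_m, oc_m),
                                     protein = corr(cyc_p, oc_p))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  stage_log("report written to %s", file.path(out_dir, "report.json"))

  invisible(list(truth = ds$truth, proteome = prot, abundances = abund,
                 antisense = anti, cycling_mrna = cyc_m,
                 cycling_protein = cyc_p, pairing = pairing,
                 report = report, out_dir = out_dir))
}
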