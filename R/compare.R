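#' Protein-after-mRNA lag from two phases
#'
#' Maps the phase difference onto `(-2, 22]` hours:
#' `lag = ((phase_protein - phase_mrna + 2) mod 24) - 2`. Small negative
#' offsets (to -2 h) stay negative so the in-phase window is symmetric;
#' all larger offsets are positive, reflecting the convention that a protein
#' maximum is taken to follow the transcript peak — possibly the previous
#' cycle's.
#'
#' @param phase_mrna,phase_protein phases in \[0, 24) hours (vectorised).
#' @return lag in hours, in `(-2, 22]`; NA propagates.
#' @examples
#' compute_lag(14, 2)  # 12 h, antiphase
#' compute_lag(23, 1)  # 2 h
#' @export
compute_lag <- function(phase_mrna, phase_protein) {
  lag <- ((phase_protein - phase_mrna + 2) %% 24) - 2
  # half-open interval (-2, 22]: an offset of exactly -2 wraps to +22
  ifelse(!is.na(lag) & lag == -2, 22, lag)
}

#' Amplitude comparison between expression levels
#'
#' Two ratio metrics are reported because both are in common use: the ratio
#' of half-amplitudes in log2 units (`amp_ratio_log = H_mrna / H_protein`)
#' and the ratio of peak-to-trough fold changes
#' (`amp_ratio_fold = 2^(2 (H_mrna - H_protein))`). A gene is damped when
#' the protein oscillates less than its transcript (`amp_ratio_log > 1`).
#'
#' @param halfamp_mrna,halfamp_protein half-amplitudes (log2 units, > 0;
#'   a zero protein half-amplitude yields infinite ratios, flagged damped).
#' @return tibble: `amp_ratio_log`, `amp_ratio_fold`, `damped`.
#' @export
amplitude_ratio <- function(halfamp_mrna, halfamp_protein) {
  tibble(
    amp_ratio_log = halfamp_mrna / halfamp_protein,
    amp_ratio_fold = 2^(2 * (halfamp_mrna - halfamp_protein)),
    damped = halfamp_mrna / halfamp_protein > 1)
}

#' Classify the mRNA-protein phase relationship
#'
#' Bands: `|lag| <= 2` h in phase; `2 < lag <= 8` h lagged;
#' `11 <= lag <= 13` h antiphase; anything else "other" (the unnamed gap
#' bands). Every defined lag receives exactly one class.
#'
#' @param lag lag hours in `(-2, 22]` (vectorised).
#' @return factor with levels `in_phase`, `lagged_2_8`, `antiphase`,
#'   `other`.
#' @export
classify_phase_relationship <- function(lag) {
  cls <- dplyr::case_when(
    is.na(lag) ~ NA_character_,
    abs(lag) <= 2 ~ "in_phase",
    lag > 2 & lag <= 8 ~ "lagged_2_8",
    lag >= 11 & lag <= 13 ~ "antiphase",
    TRUE ~ "other")
  factor(cls, levels = c("in_phase", "lagged_2_8", "antiphase", "other"))
}

#' Call predominantly transcriptional control
#'
#' A gene is under predominantly transcriptional control when mRNA and
#' protein oscillate in phase (|lag| <= `lag_window` h) with fold-change
#' amplitudes within `fold_limit` of each other in either direction.
#'
#' @param lag lag hours.
#' @param amp_ratio_fold fold-change amplitude ratio (mRNA over protein).
#' @param lag_window in-phase half-window (default 2 h).
#' @param fold_limit maximum fold difference (default 2).
#' @return logical.
#' @export
classify_transcriptional_control <- function(lag, amp_ratio_fold,
                                             lag_window = 2,
                                             fold_limit = 2) {
  abs(lag) <= lag_window &
    pmax(amp_ratio_fold, 1 / amp_ratio_fold) <= fold_limit
}

#' Pair mRNA and protein cycling results per gene
#'
#' Joins two cycling result sets by gene, keeps genes with a significant,
#' phase-defined oscillation at both levels, and computes the lag, both
#' amplitude-ratio metrics, the phase-relationship class and the
#' transcriptional-control call for each.
#'
#' @param mrna,protein `diel_cycling` objects (or their `results` tibbles).
#' @param significant_only keep only genes significant at both levels
#'   (default TRUE).
#' @return object of class `diel_pairing`: `pairs` tibble (`gene_id`,
#'   per-level phase/halfamp/fold columns, `lag`, `amp_ratio_log`,
#'   `amp_ratio_fold`, `damped`, `phase_class`, `transcriptional_control`)
#'   and `n_input` bookkeeping.
#' @export
pair_cycling <- function(mrna, protein, significant_only = TRUE) {
  get_res <- function(x) if (inherits(x, "diel_cycling")) x$results else as_tibble(x)
  mr <- get_res(mrna)
  pr <- get_res(protein)
  pick <- function(df, suffix) {
    df <- dplyr::filter(df, .data$resolvable, !is.na(.data$phase))
    if (significant_only) df <- dplyr::filter(df, .data$significant)
    df |>
      dplyr::select("gene_id", "halfamp", "fold_change", "phase", "q") |>
      rename_with_suffix(suffix)
  }
  pairs <- inner_join(pick(mr, "_mrna"), pick(pr, "_protein"), by = "gene_id")
  pairs <- pairs |>
    mutate(lag = compute_lag(.data$phase_mrna, .data$phase_protein)) |>
    dplyr::bind_cols(amplitude_ratio(pairs$halfamp_mrna,
                                     pairs$halfamp_protein)) |>
    mutate(phase_class = classify_phase_relationship(.data$lag),
           transcriptional_control = classify_transcriptional_control(
             .data$lag, .data$amp_ratio_fold))
  structure(list(pairs = pairs,
                 n_input = c(mrna = nrow(get_res(mrna)),
                             protein = nrow(get_res(pr)))),
            class = "diel_pairing")
}

rename_with_suffix <- function(df, suffix) {
  nm <- names(df)
  nm[nm != "gene_id"] <- paste0(nm[nm != "gene_id"], suffix)
  stats::setNames(df, nm)
}

#' @export
print.diel_pairing <- function(x, ...) {
  p <- x$pairs
  cat("<diel_pairing>\n")
  cat(sprintf("  %d paired genes; classes: %s; %d transcriptional-control\n",
              nrow(p),
              paste(names(table(p$phase_class)), table(p$phase_class),
                    sep = "=", collapse = ", "),
              sum(p$transcriptional_control)))
  invisible(x)
}

#' Median lag within clock-time peak windows
#'
#' Groups paired genes by the clock time (hours since midnight) at which
#' their transcript peaks, using inclusive window bounds, and reports each
#' window's gene count and median protein-after-mRNA lag.
#'
#' @param pairing a `diel_pairing` (or its `pairs` tibble).
#' @param windows named list of `c(start, end)` clock-hour windows
#'   (default morning 02:00-05:00 and evening 16:00-20:00).
#' @return tibble: `window`, `n`, `median_lag`.
#' @export
lag_by_peak_window <- function(pairing,
                               windows = list(morning = c(2, 5),
                                              evening = c(16, 20))) {
  p <- if (inherits(pairing, "diel_pairing")) pairing$pairs else as_tibble(pairing)
  purrr::map_dfr(names(windows), function(w) {
    b <- windows[[w]]
    ph <- p$phase_mrna %% 24
    sel <- ph >= b[1] & ph <= b[2]
    tibble(window = w, n = sum(sel),
           median_lag = if (any(sel)) median(p$lag[sel]) else NA_real_)
  })
}

#' Cohort summary of paired cycling behaviour
#'
#' Headline counts and medians for a paired cohort: per-class counts,
#' number of damped genes, median amplitude-ratio metrics, median lag, and
#' the number of transcriptional-control genes.
#'
#' @param pairing a `diel_pairing` (or its `pairs` tibble).
#' @return list with `counts` (tibble) and `medians` (one-row tibble).
#' @export
summarize_cohort <- function(pairing) {
  p <- if (inherits(pairing, "diel_pairing")) pairing$pairs else as_tibble(pairing)
  if (nrow(p) == 0) abort("summarize_cohort(): empty cohort.")
  cls <- table(p$phase_class)
  counts <- tibble(
    n_paired = nrow(p),
    in_phase = as.integer(cls[["in_phase"]]),
    lagged_2_8 = as.integer(cls[["lagged_2_8"]]),
    antiphase = as.integer(cls[["antiphase"]]),
    other = as.integer(cls[["other"]]),
    damped = sum(p$damped, na.rm = TRUE),
    transcriptional_control = sum(p$transcriptional_control, na.rm = TRUE))
  medians <- tibble(
    median_amp_ratio_log = median(p$amp_ratio_log[is.finite(p$amp_ratio_log)]),
    median_amp_ratio_fold = median(p$amp_ratio_fold[is.finite(p$amp_ratio_fold)]),
    median_lag = median(p$lag))
  list(counts = counts, medians = medians)
}
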