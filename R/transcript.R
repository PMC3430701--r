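#' Gene-level sense/antisense abundances from strand coverage
#'
#' For each gene, coverage inside the gene body is summed on each strand,
#' divided by gene length, and normalized by the total number of aligned
#' bases at that timepoint: `sense = sum(depth over gene, gene strand) /
#' length / total_aligned_bp`, antisense the same on the opposite strand.
#'
#' @param coverage a `strand_coverage` object (one timepoint) as produced by
#'   [simulate_coverage()] or [read_bedgraph_pair()].
#' @param genes gene models tibble (0-based half-open `start`/`end`,
#'   `strand`, `length`).
#' @return tibble `gene_id`, `timepoint_index`, `sense`, `antisense`,
#'   `antisense_fraction` (NA when sense is 0).
#' @export
summarize_gene_coverage <- function(coverage, genes) {
  L <- length(coverage$depth_plus)
  if (any(genes$start < 0 | genes$end > L)) {
    bad <- genes$gene_id[genes$start < 0 | genes$end > L][1]
    abort(paste0("Gene '", bad, "' lies outside chromosome bounds (0, ",
                 L, ")."))
  }
  tot <- coverage$total_aligned_bp
  if (!is.finite(tot) || tot <= 0) abort("total_aligned_bp must be > 0.")
  cp <- cumsum(c(0, as.numeric(coverage$depth_plus)))
  cm <- cumsum(c(0, as.numeric(coverage$depth_minus)))
  sum_plus <- cp[genes$end + 1L] - cp[genes$start + 1L]
  sum_minus <- cm[genes$end + 1L] - cm[genes$start + 1L]
  sense_sum <- ifelse(genes$strand == "+", sum_plus, sum_minus)
  anti_sum <- ifelse(genes$strand == "+", sum_minus, sum_plus)
  sense <- sense_sum / genes$length / tot
  anti <- anti_sum / genes$length / tot
  tibble(gene_id = genes$gene_id,
         timepoint_index = coverage$timepoint_index,
         sense = sense,
         antisense = anti,
         antisense_fraction = ifelse(sense > 0, anti / sense, NA_real_))
}

#' Quantify all timepoints of a coverage set
#'
#' @param coverage_list list of `strand_coverage` objects (one per
#'   timepoint).
#' @param genes gene models tibble.
#' @return tibble of per-gene, per-timepoint abundances (rows of
#'   [summarize_gene_coverage()] stacked).
#' @export
quantify_transcripts <- function(coverage_list, genes) {
  purrr::map_dfr(coverage_list, summarize_gene_coverage, genes = genes)
}

#' Antisense detection and abundance summary
#'
#' Per timepoint: the fraction of genes with detected antisense coverage
#' (mean antisense depth above `detect_threshold`; default any nonzero
#' coverage), and the mean antisense:sense percentage over genes with
#' detected antisense and nonzero sense. Across timepoints the mean and sd
#' of both statistics are reported.
#'
#' @param abundances tibble from [quantify_transcripts()].
#' @param detect_threshold minimum normalized antisense abundance counted
#'   as detection (default 0: any nonzero coverage).
#' @return list: `per_timepoint` tibble (`timepoint_index`,
#'   `frac_antisense`, `mean_ratio_pct`) and `summary` (one-row tibble with
#'   means and sds across timepoints).
#' @export
antisense_stats <- function(abundances, detect_threshold = 0) {
  per_tp <- abundances |>
    group_by(.data$timepoint_index) |>
    summarise(
      frac_antisense = mean(.data$antisense > detect_threshold),
      mean_ratio_pct = {
        sel <- .data$antisense > detect_threshold & .data$sense > 0
        if (any(sel)) 100 * mean(.data$antisense[sel] / .data$sense[sel]) else 0
      },
      .groups = "drop")
  summary <- tibble(
    frac_antisense_mean = mean(per_tp$frac_antisense),
    frac_antisense_sd = sd(per_tp$frac_antisense),
    ratio_pct_mean = mean(per_tp$mean_ratio_pct),
    ratio_pct_sd = sd(per_tp$mean_ratio_pct))
  list(per_timepoint = per_tp, summary = summary)
}

#' Log2 sense-abundance timecourses for rhythm analysis
#'
#' Converts normalized sense abundances to log2 with a pseudo-floor for
#' zeros (default: half the smallest nonzero sense abundance in the
#' dataset), returning the timecourse layout the cycling detector consumes.
#'
#' @param abundances tibble from [quantify_transcripts()].
#' @param times time (hours) of each timepoint index, used to label rows.
#' @param floor pseudo-floor for zero abundances; `NULL` for the default.
#' @return tibble `gene_id`, `level` ("mRNA"), `timepoint_index`, `time_h`,
#'   `log2_abundance`.
#' @export
transcript_timecourses <- function(abundances, times, floor = NULL) {
  nz <- abundances$sense[abundances$sense > 0]
  if (is.null(floor)) floor <- if (length(nz)) min(nz) / 2 else 1e-12
  abundances |>
    mutate(level = "mRNA",
           time_h = times[.data$timepoint_index + 1L],
           log2_abundance = log2(pmax(.data$sense, floor))) |>
    dplyr::select("gene_id", "level", "timepoint_index", "time_h",
                  "log2_abundance") |>
    arrange(.data$gene_id, .data$timepoint_index)
}
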