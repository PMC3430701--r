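#' Synthetic gene models on a single chromosome
#'
#' Lays `n_genes` non-overlapping gene bodies of fixed length on one
#' chromosome, separated by intergenic gaps, with alternating strands.
#' Coordinates are 0-based half-open (the package-internal convention).
#'
#' @param config a [sim_config()].
#' @return tibble `gene_id`, `seqname`, `start`, `end`, `strand`, `length`.
#' @export
make_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_genes)
  pitch <- config$gene_length + config$gene_gap
  start <- (seq_len(n) - 1L) * pitch
  tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    seqname = "chr1",
    start = start,
    end = start + config$gene_length,
    strand = rep(c("+", "-"), length.out = n),
    length = config$gene_length)
}

#' Simulate strand-specific per-base coverage from mRNA timecourses
#'
#' Per-base sense depth inside each gene body is Poisson with mean
#' proportional to `2^log2_abundance`, scaled so an average-abundance gene
#' has mean depth `config$depth` at each timepoint. Genes flagged in the
#' truth table as antisense carriers additionally receive Poisson antisense
#' coverage on the opposite strand at their gene-specific antisense:sense
#' ratio. Intergenic positions carry no reads. The total number of aligned
#' bases per timepoint is recorded as the normalization denominator.
#'
#' @param mrna_tc mRNA rows of [simulate_timecourses()] output.
#' @param genes gene models from [make_gene_models()].
#' @param truth truth tibble from [generate_diel_truth()] (supplies
#'   `antisense_present` and `antisense_ratio`).
#' @param config the matching [sim_config()].
#' @return A list with one element per timepoint, each a `strand_coverage`
#'   list: `timepoint_index`, `time_h`, `depth_plus`, `depth_minus`
#'   (integer vectors over the chromosome), `total_aligned_bp`, `seqname`,
#'   `chrom_length`.
#' @export
simulate_coverage <- function(mrna_tc, genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  tc <- if ("level" %in% names(mrna_tc)) {
    dplyr::filter(mrna_tc, .data$level == "mRNA")
  } else mrna_tc
  chrom_len <- max(genes$end) + config$gene_gap
  if (any(genes$start < 0 | genes$end > chrom_len)) {
    abort("Gene models extend outside chromosome bounds.")
  }
  gidx <- match(genes$gene_id, truth$gene_id)
  anti_ratio <- truth$antisense_ratio[gidx]
  purrr::map(sort(unique(tc$timepoint_index)), function(ti) {
    sl <- tc[tc$timepoint_index == ti, ]
    sl <- sl[match(genes$gene_id, sl$gene_id), ]
    lin <- 2^sl$log2_abundance
    lambda_sense <- config$depth * lin / mean(lin)
    with_stream(config$seed, "cov", ti, code = {
      dp <- integer(chrom_len)
      dm <- integer(chrom_len)
      for (i in seq_len(nrow(genes))) {
        span <- (genes$start[i] + 1L):genes$end[i]
        sense <- rpois(length(span), lambda_sense[i])
        asense <- if (anti_ratio[i] > 0) {
          rpois(length(span), lambda_sense[i] * anti_ratio[i])
        } else integer(length(span))
        if (genes$strand[i] == "+") {
          dp[span] <- dp[span] + sense
          dm[span] <- dm[span] + asense
        } else {
          dm[span] <- dm[span] + sense
          dp[span] <- dp[span] + asense
        }
      }
      structure(
        list(timepoint_index = ti,
             time_h = sl$time_h[1],
             depth_plus = dp,
             depth_minus = dm,
             total_aligned_bp = sum(as.numeric(dp)) + sum(as.numeric(dm)),
             seqname = "chr1",
             chrom_length = chrom_len),
        class = "strand_coverage")
    })
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_diel_truth()],
#' [simulate_timecourses()], [simulate_peak_table()] and, optionally,
#' [simulate_coverage()].
#'
#' @param config a [sim_config()].
#' @param coverage also simulate strand-specific coverage (slower for large
#'   gene sets).
#' @return list with `truth`, `timecourses`, `peaks` (list from
#'   [simulate_peak_table()]), `genes`, and `coverage` (or `NULL`).
#' @export
simulate_dataset <- function(config, coverage = TRUE) {
  truth <- generate_diel_truth(config)
  tc <- simulate_timecourses(truth, config)
  pk <- simulate_peak_table(dplyr::filter(tc, .data$level == "protein"), config)
  genes <- make_gene_models(config)
  cov <- if (coverage) {
    simulate_coverage(dplyr::filter(tc, .data$level == "mRNA"),
                      genes, truth, config)
  }
  list(truth = truth, timecourses = tc, peaks = pk, genes = genes,
       coverage = cov, config = config)
}
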