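# Output tables carry comment headers naming units and the producing config
# hash; readers skip '#' lines.

tsv_header <- function(kind, units, hash = NULL) {
  c(paste0("# dielcycle ", kind),
    paste0("# units: ", units),
    if (!is.null(hash)) paste0("# config: ", hash))
}

write_tsv_with_header <- function(df, path, kind, units, hash = NULL) {
  readr::write_lines(tsv_header(kind, units, hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_checked_tsv <- function(path, col_types, what) {
  if (!file.exists(path)) abort(paste0("missing input: ", what, " (", path, ")"))
  df <- suppressWarnings(
    readr::read_tsv(path, comment = "#", col_types = col_types,
                    progress = FALSE)) # problems() is checked explicitly

  pb <- readr::problems(df)
  if (nrow(pb) > 0) {
    abort(paste0("Malformed ", what, " file '", path, "': ",
                 nrow(pb), " bad field(s), first at line ", pb$row[1] + 1,
                 " (", pb$expected[1], ")."))
  }
  df
}

#' Read and write timecourse tables
#'
#' Tab-separated timecourses with columns `gene_id`, `level`,
#' `timepoint_index`, `time_h` (hours), `log2_abundance` (log2 units).
#' Write-then-read is the identity on these columns; malformed numeric
#' fields are reported with their line number.
#'
#' @param tc timecourse tibble.
#' @param path file path.
#' @param hash optional config hash recorded in the header.
#' @return the tibble (readers) or the path, invisibly (writers).
#' @export
write_timecourse_tsv <- function(tc, path, hash = NULL) {
  write_tsv_with_header(tc, path, "timecourse",
                        "time_h hours; log2_abundance log2 units", hash)
}

#' @rdname write_timecourse_tsv
#' @export
read_timecourse_tsv <- function(path) {
  read_checked_tsv(path, readr::cols(
    gene_id = readr::col_character(), level = readr::col_character(),
    timepoint_index = readr::col_integer(), time_h = readr::col_double(),
    log2_abundance = readr::col_double()), "timecourse")
}

#' Read and write peak-ratio tables
#'
#' Tab-separated peptide peak tables with columns `peak_id`, `protein_id`,
#' `timepoint_index`, `time_h`, `ratio` (linear), `cv`.
#'
#' @param peaks peaks tibble.
#' @param path file path.
#' @param hash optional config hash recorded in the header.
#' @export
write_peaks_tsv <- function(peaks, path, hash = NULL) {
  write_tsv_with_header(
    dplyr::select(peaks, "peak_id", "protein_id", "timepoint_index",
                  "time_h", "ratio", "cv"),
    path, "peaks", "time_h hours; ratio linear heavy-light pair; cv proportion",
    hash)
}

#' @rdname write_peaks_tsv
#' @export
read_peaks_tsv <- function(path) {
  read_checked_tsv(path, readr::cols(
    peak_id = readr::col_character(), protein_id = readr::col_character(),
    timepoint_index = readr::col_integer(), time_h = readr::col_double(),
    ratio = readr::col_double(), cv = readr::col_double()), "peaks")
}

#' Read and write gene models as GFF3
#'
#' GFF3 uses 1-based closed coordinates; internally the package uses
#' 0-based half-open, so a GFF3 feature `1..100` becomes `(0, 100)` with
#' length 100. I/O goes through `rtracklayer`.
#'
#' @param genes gene models tibble (internal convention).
#' @param path file path.
#' @return `read_gff3()` returns the gene models tibble.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqname,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input: gene models (", path, ")"))
  gr <- rtracklayer::import(path, format = "gff3")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort(paste0("read_gff3(): feature(s) with undefined strand in ", path))
  }
  id <- S4Vectors::mcols(gr)$ID %||% paste0("feature", seq_along(gr))
  tibble(
    gene_id = as.character(id),
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    length = GenomicRanges::width(gr))
}

#' Read and write per-strand coverage as bedGraph
#'
#' bedGraph intervals are 0-based half-open, matching the internal
#' convention. `write_bedgraph()` run-length encodes a depth vector and
#' omits zero runs; `read_bedgraph()` validates every data line (negative
#' or non-numeric depths are parse errors naming the line) before importing
#' through `rtracklayer` and expanding back to a per-base vector.
#'
#' @param depth integer per-base depth vector.
#' @param path file path.
#' @param seqname chromosome name (default "chr1").
#' @param chrom_length expected chromosome length for the read-back vector.
#' @return `read_bedgraph()` returns a numeric depth vector of length
#'   `chrom_length`.
#' @export
write_bedgraph <- function(depth, path, seqname = "chr1") {
  r <- rle(as.numeric(depth))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, chrom_length, seqname = NULL) {
  if (!file.exists(path)) abort(paste0("missing input: coverage (", path, ")"))
  lines <- readr::read_lines(path, progress = FALSE)
  is_data <- !grepl("^(track|#|browser)", lines) & nzchar(lines)
  flds <- strsplit(lines[is_data], "[ \t]+")
  bad_n <- vapply(flds, length, integer(1)) != 4
  if (any(bad_n)) {
    abort(paste0("read_bedgraph(): line ", which(is_data)[which(bad_n)[1]],
                 " of '", path, "' does not have 4 fields."))
  }
  depth_chr <- vapply(flds, `[[`, character(1), 4)
  depth_num <- suppressWarnings(as.numeric(depth_chr))
  if (any(is.na(depth_num))) {
    abort(paste0("read_bedgraph(): non-numeric depth at line ",
                 which(is_data)[which(is.na(depth_num))[1]], " of '", path, "'."))
  }
  if (any(depth_num < 0)) {
    abort(paste0("read_bedgraph(): negative depth at line ",
                 which(is_data)[which(depth_num < 0)[1]], " of '", path, "'."))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(seqname)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seqname]
  }
  out <- numeric(chrom_length)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  if (any(en > chrom_length)) {
    abort("read_bedgraph(): interval extends past chrom_length.")
  }
  sc <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) out[st[i]:en[i]] <- out[st[i]:en[i]] + sc[i]
  out
}

#' Assemble a strand_coverage object from two bedGraph files
#'
#' @param plus_path,minus_path bedGraph files for the + and - strands.
#' @param chrom_length chromosome length (bp).
#' @param timepoint_index 0-based timepoint index.
#' @param time_h sampling time (hours).
#' @param total_aligned_bp normalization denominator; default the sum of
#'   both depth vectors.
#' @param seqname chromosome name.
#' @return a `strand_coverage` list.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_length,
                               timepoint_index, time_h = NA_real_,
                               total_aligned_bp = NULL, seqname = "chr1") {
  dp <- read_bedgraph(plus_path, chrom_length, seqname)
  dm <- read_bedgraph(minus_path, chrom_length, seqname)
  structure(list(
    timepoint_index = timepoint_index, time_h = time_h,
    depth_plus = dp, depth_minus = dm,
    total_aligned_bp = total_aligned_bp %||% (sum(dp) + sum(dm)),
    seqname = seqname, chrom_length = chrom_length),
    class = "strand_coverage")
}

#' Read/write the per-timepoint aligned-bases table
#'
#' @param totals tibble `timepoint_index`, `total_aligned_bp`.
#' @param path file path.
#' @export
write_totals_tsv <- function(totals, path) {
  write_tsv_with_header(totals, path, "aligned totals",
                        "total_aligned_bp bases")
}

#' @rdname write_totals_tsv
#' @export
read_totals_tsv <- function(path) {
  read_checked_tsv(path, readr::cols(
    timepoint_index = readr::col_integer(),
    total_aligned_bp = readr::col_double()), "aligned totals")
}
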