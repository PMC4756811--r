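# Plain-text readers/writers for the formats the pipeline exchanges:
# BED3/BED6 (0-based half-open), genome files ("chrom<TAB>length"),
# and probe-by-sample matrices as TSV.

#' Read a BED file
#'
#' Reads BED3 (chrom, start, end) or BED6 (plus name, score, strand) into a
#' region tibble; coordinates are kept 0-based half-open.
#'
#' @param path Path to a tab-separated BED file without header.
#' @return A region tibble with `chrom`, `start`, `end`, and `name`,
#'   `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  out <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (ncol(out) < 3) rlang::abort(sprintf("BED file %s has fewer than 3 columns", path))
  out <- out[, seq_len(min(6, ncol(out)))]
  names(out) <- cols[seq_len(ncol(out))]
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  if ("score" %in% names(out)) out$score <- suppressWarnings(as.numeric(out$score))
  validate_regions(out, path)
  out
}

#' Write a BED file
#'
#' @param regions Region tibble; `name`, `score`, `strand` columns are
#'   written when present (BED6), otherwise BED3.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  out <- regions[c("chrom", "start", "end")]
  if (any(c("name", "score", "strand") %in% names(regions))) {
    out$name <- if ("name" %in% names(regions)) regions$name else "."
    out$score <- if ("score" %in% names(regions)) regions$score else 0
    out$strand <- if ("strand" %in% names(regions)) regions$strand else "."
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genome file
#'
#' @param path Two-column tab-separated file: chromosome name and length.
#' @return A genome tibble (`chrom`, `length`).
#' @export
read_genome <- function(path) {
  out <- readr::read_tsv(
    path,
    col_names = c("chrom", "length"),
    col_types = readr::cols(readr::col_character(), readr::col_double()),
    progress = FALSE
  )
  validate_genome(out)
  out
}

#' Write a genome file
#' @param genome Genome tibble (`chrom`, `length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  readr::write_tsv(genome[c("chrom", "length")], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a probe-by-sample matrix from TSV
#'
#' Reads a beta-value or detection p-value matrix with probe ids in the
#' first column and one column per sample. Empty cells become `NA` (masked).
#'
#' @param path Path to a TSV with a header row.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (anyDuplicated(df[[1]])) rlang::abort(sprintf("duplicate probe ids in %s", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(colnames(m))) rlang::abort(sprintf("duplicate sample ids in %s", path))
  m
}

#' Write a probe-by-sample matrix to TSV
#'
#' Masked (`NA`) cells are written as empty fields.
#'
#' @param m Numeric matrix with rownames (probe ids) and colnames (samples).
#' @param path Output path.
#' @param id_col Name of the first (probe id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a window track as bedGraph
#'
#' @param track Window-track tibble from [window_means()]; windows with no
#'   probes are dropped.
#' @param path Output path.
#' @param value Name of the value column to export.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "mean_value") {
  stopifnot(value %in% names(track))
  out <- track[!is.na(track[[value]]), c("chrom", "start", "end", value)]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
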