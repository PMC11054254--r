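#' @importFrom rlang .data abort warn inform
#' @importFrom dplyr %>%
NULL

STAGES <- c("L", "N", "F")

#' Read a sample-to-stage design table
#'
#' The study design assigns each fecal sample to one of three developmental
#' stages: lactation (L), nursery (N) and fattening (F), ordered L < N < F.
#'
#' @param path Path to a TSV file with columns `sample_id` and `stage`.
#' @return A tibble with columns `sample_id` (character, unique) and `stage`
#'   (ordered factor with levels L < N < F).
#' @export
read_design <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_design(tab)
}

#' Validate a design table
#'
#' @param design A data frame with columns `sample_id` and `stage`.
#' @return The validated design as a tibble with `stage` as an ordered factor.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  if (!all(c("sample_id", "stage") %in% names(design))) {
    abort("design must have columns 'sample_id' and 'stage'")
  }
  if (nrow(design) == 0) abort("no samples in design")
  dup <- unique(design$sample_id[duplicated(design$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id in design: ", paste(dup, collapse = ", ")))
  }
  stage_chr <- as.character(design$stage)
  bad <- which(!stage_chr %in% STAGES)
  if (length(bad) > 0) {
    abort(sprintf("unknown stage token '%s' in design row %d (expected L, N or F)",
                  stage_chr[bad[1]], bad[1]))
  }
  design$stage <- factor(stage_chr, levels = STAGES, ordered = TRUE)
  n_per <- table(design$stage)
  if (any(n_per < 2)) {
    abort(sprintf("every stage needs at least 2 samples; got %s",
                  paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", ")))
  }
  design[, c("sample_id", "stage")]
}

#' Read contig sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id` and `length_bp`.
#' @export
read_contigs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate contig id in FASTA: ", paste(dup, collapse = ", ")))
  }
  len <- Biostrings::width(seqs)
  if (any(len == 0)) {
    abort(paste0("zero-length record in FASTA: ",
                 paste(ids[len == 0], collapse = ", ")))
  }
  tibble::tibble(contig_id = ids, length_bp = as.integer(len))
}

#' Write a result table to TSV
#'
#' All pipeline tables are exchanged as tab-separated UTF-8 text with a header
#' row and '.' as the decimal mark. Doubles are written with enough digits to
#' round-trip losslessly, so `read_result_table()` recovers identical values.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  is_dbl <- vapply(x, is.double, logical(1))
  x[is_dbl] <- lapply(x[is_dbl], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' Parses with base R so 17-significant-digit doubles are recovered exactly
#' (correctly rounded strtod).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  tibble::as_tibble(tab)
}

#' Validate a vOTU catalog
#'
#' @param catalog A data frame with columns `votu_id`, `representative_contig`,
#'   `length_bp`, and optionally `members` (list column of contig ids) and
#'   `novelty`.
#' @return The catalog as a tibble with `novelty` filled
#'   (default "unassessed").
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  need <- c("votu_id", "representative_contig", "length_bp")
  if (!all(need %in% names(catalog))) {
    abort(paste0("catalog must have columns ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(catalog$votu_id)) abort("duplicate votu_id in catalog")
  if (any(catalog$length_bp <= 0)) abort("catalog length_bp must be positive")
  if (!"novelty" %in% names(catalog)) catalog$novelty <- "unassessed"
  catalog
}

#' Read a long-format read-count table
#'
#' @param path TSV with columns `votu_id`, `sample_id`, `read_count`.
#' @return A tibble with those columns; `read_count` integer, non-negative.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    votu_id = readr::col_character(),
    sample_id = readr::col_character(),
    read_count = readr::col_double()
  ), progress = FALSE)
  if (any(tab$read_count < 0) || any(tab$read_count != floor(tab$read_count))) {
    abort("read_count must be a non-negative integer")
  }
  tab$read_count <- as.integer(tab$read_count)
  tab
}

#' Read a per-vOTU alignment interval table
#'
#' Intervals are 0-based half-open `[start, end)` on the vOTU representative.
#'
#' @param path TSV with columns `votu_id`, `sample_id`, `start`, `end`.
#' @return A tibble with those columns.
#' @export
read_intervals <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    votu_id = readr::col_character(),
    sample_id = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double()
  ), progress = FALSE)
}

# Pivot a long (votu_id, sample_id, value) table to a votu x sample matrix,
# missing cells filled with 0.
long_to_matrix <- function(tab, value_col, votus = NULL, samples = NULL) {
  if (is.null(votus)) votus <- sort(unique(tab$votu_id))
  if (is.null(samples)) samples <- sort(unique(tab$sample_id))
  m <- matrix(0, nrow = length(votus), ncol = length(samples),
              dimnames = list(votus, samples))
  m[cbind(match(tab$votu_id, votus), match(tab$sample_id, samples))] <-
    tab[[value_col]]
  m
}
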