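#' Coverage breadth from alignment intervals
#'
#' Breadth is the fraction of a vOTU's length covered by at least one aligned
#' read in a sample: the length of the union of its alignment intervals
#' divided by the vOTU length. Intervals are 0-based half-open; the union is
#' taken with `IRanges::reduce`, so breadth is invariant under permutation,
#' splitting and overlap of the input intervals.
#'
#' @param intervals Tibble with columns `votu_id`, `sample_id`, `start`,
#'   `end` (0-based half-open, within `[0, length_bp)`).
#' @param catalog vOTU catalog supplying `length_bp` per `votu_id`.
#' @param samples Optional character vector of sample ids to report (defaults
#'   to those present in `intervals`); vOTU x sample pairs with no intervals
#'   get breadth 0.
#' @return Tibble `votu_id`, `sample_id`, `breadth` for every vOTU in the
#'   catalog crossed with every sample.
#' @export
compute_breadth <- function(intervals, catalog, samples = NULL) {
  catalog <- validate_catalog(catalog)
  if (is.null(samples)) samples <- sort(unique(intervals$sample_id))
  grid <- tidyr::expand_grid(votu_id = catalog$votu_id, sample_id = samples)
  if (nrow(intervals) > 0) {
    li <- match(intervals$votu_id, catalog$votu_id)
    if (anyNA(li)) {
      abort(paste0("interval references unknown votu_id: ",
                   paste(unique(intervals$votu_id[is.na(li)]), collapse = ", ")))
    }
    if (any(intervals$end <= intervals$start)) {
      abort("interval end must be greater than start (0-based half-open)")
    }
    if (any(intervals$start < 0) ||
        any(intervals$end > catalog$length_bp[li])) {
      abort("interval outside [0, length_bp)")
    }
    key <- paste(intervals$votu_id, intervals$sample_id, sep = "\r")
    covered <- vapply(split(seq_len(nrow(intervals)), key), function(rows) {
      ir <- IRanges::IRanges(start = intervals$start[rows] + 1L,
                             end = intervals$end[rows])
      sum(IRanges::width(IRanges::reduce(ir)))
    }, numeric(1))
    cov_tab <- tibble::tibble(
      votu_id = sub("\r.*$", "", names(covered)),
      sample_id = sub("^.*\r", "", names(covered)),
      covered_bp = unname(covered)
    )
  } else {
    cov_tab <- tibble::tibble(votu_id = character(), sample_id = character(),
                              covered_bp = numeric())
  }
  out <- dplyr::left_join(grid, cov_tab, by = c("votu_id", "sample_id"))
  out$covered_bp[is.na(out$covered_bp)] <- 0
  out$breadth <- out$covered_bp /
    catalog$length_bp[match(out$votu_id, catalog$votu_id)]
  out[, c("votu_id", "sample_id", "breadth")]
}

#' TPM abundance normalization
#'
#' Computes, per sample, length-normalized relative abundance rescaled to one
#' million: `tpm_i = (N_i / L_i) * 1e6 / sum_j (N_j / L_j)` where `N_i` is the
#' mapped-read count of vOTU i in the sample and `L_i` its length in bp. Every
#' sample with at least one nonzero count sums to exactly 1e6; an all-zero
#' sample yields an all-zero column (reported with a warning rather than an
#' error, so parameter sweeps that empty a sample still run).
#'
#' @param counts Tibble `votu_id`, `sample_id`, `read_count`; vOTU x sample
#'   pairs absent from the table count as 0.
#' @param catalog vOTU catalog supplying `length_bp`.
#' @param samples Optional sample ids to report (default: those in `counts`).
#' @return Tibble `votu_id`, `sample_id`, `tpm` covering every catalog vOTU
#'   in every sample.
#' @export
compute_tpm <- function(counts, catalog, samples = NULL) {
  catalog <- validate_catalog(catalog)
  unknown <- setdiff(unique(counts$votu_id), catalog$votu_id)
  if (length(unknown) > 0) {
    abort(paste0("count references unknown votu_id: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(counts$read_count < 0)) abort("read_count must be non-negative")
  if (is.null(samples)) samples <- sort(unique(counts$sample_id))
  cnt <- long_to_matrix(counts, "read_count", votus = catalog$votu_id,
                        samples = samples)
  rate <- cnt / catalog$length_bp[match(rownames(cnt), catalog$votu_id)]
  denom <- colSums(rate)
  empty <- denom == 0
  if (any(empty)) {
    warn(paste0("sample(s) with no mapped reads get all-zero TPM: ",
                paste(colnames(cnt)[empty], collapse = ", ")))
    denom[empty] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  tibble::tibble(
    votu_id = rep(rownames(tpm), times = ncol(tpm)),
    sample_id = rep(colnames(tpm), each = nrow(tpm)),
    tpm = as.vector(tpm)
  )
}
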