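#' Alpha diversity of one abundance profile
#'
#' Richness is the number of taxa with positive abundance. With
#' `p_i = x_i / sum(x)`: Shannon is `-sum(p_i * ln p_i)` (natural log,
#' `0 * ln 0 := 0`) and Simpson is the Gini-Simpson index `1 - sum(p_i^2)`,
#' the conventions of `vegan::diversity`, which performs the computation.
#' All three indices are invariant under scaling of the input vector.
#'
#' @param x Non-negative abundance vector for one sample.
#' @return Named list `richness`, `shannon`, `simpson`. An all-zero vector
#'   gives richness 0 and `NaN` for the two indices, with a warning.
#' @export
alpha_diversity <- function(x) {
  if (any(x < 0)) abort("abundances must be non-negative")
  if (sum(x) == 0) {
    warn("all-zero abundance vector: shannon and simpson undefined")
    return(list(richness = 0L, shannon = NaN, simpson = NaN))
  }
  list(
    richness = sum(x > 0),
    shannon = unname(vegan::diversity(x, index = "shannon")),
    simpson = unname(vegan::diversity(x, index = "simpson"))
  )
}

#' Alpha diversity for every sample of an abundance matrix
#'
#' @param abundance Tibble `votu_id`, `sample_id`, `tpm` (or a votu x sample
#'   matrix).
#' @return Tibble with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `simpson`.
#' @export
alpha_diversity_table <- function(abundance) {
  m <- if (is.matrix(abundance)) abundance else long_to_matrix(abundance, "tpm")
  rows <- lapply(colnames(m), function(s) {
    a <- alpha_diversity(m[, s])
    tibble::tibble(sample_id = s, richness = a$richness,
                   shannon = a$shannon, simpson = a$simpson)
  })
  dplyr::bind_rows(rows)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, computed with
#' `vegan::vegdist`. Symmetric with a zero diagonal; a pair of all-zero
#' samples yields `NaN` with a warning.
#'
#' @param abundance Tibble `votu_id`, `sample_id`, `tpm` or a votu x sample
#'   matrix (samples in columns).
#' @return A symmetric sample x sample matrix of dissimilarities.
#' @export
bray_curtis <- function(abundance) {
  m <- if (is.matrix(abundance)) abundance else long_to_matrix(abundance, "tpm")
  if (any(m < 0)) abort("abundances must be non-negative")
  empty <- colSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(m), method = "bray")))
  if (any(empty)) {
    warn(paste0("all-zero sample(s): ", paste(colnames(m)[empty], collapse = ", "),
                "; dissimilarity to other empty samples is NaN"))
    d[empty, empty] <- NaN
  }
  diag(d) <- 0
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates scaled
#' by the square root of each positive eigenvalue. Negative eigenvalues (from
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported, never
#' silently dropped; coordinates are only produced for positive axes. For a
#' Euclidean-embeddable input the pairwise distances between coordinate rows
#' reproduce the input matrix.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of axes to return (default: all positive axes).
#' @return List with `coordinates` (samples x axes, axes ordered by
#'   eigenvalue), `eigenvalues` (all, descending) and `proportion_explained`
#'   (positive eigenvalues over the sum of positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) abort("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > 1e-8 * max(abs(eig), 1))
  if (is.null(k)) k <- max(npos, 1L)
  k <- min(k, max(npos, 1L))
  coords <- if (npos > 0) fit$points[, seq_len(k), drop = FALSE]
            else matrix(0, n, 1, dimnames = list(rownames(d), NULL))
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pos <- eig[eig > 0]
  prop <- if (length(pos) > 0) pos / sum(pos) else numeric(0)
  list(coordinates = coords,
       eigenvalues = sort(eig, decreasing = TRUE),
       proportion_explained = prop)
}
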