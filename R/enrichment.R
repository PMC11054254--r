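#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in the input
#' order (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in `[0, 1]`; `NA`/`NaN` entries are an error.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) abort("NA/NaN p-value passed to bh_adjust")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-category term enrichment of annotated genes
#'
#' For each trajectory category and annotation term, tests over-representation
#' of the term among foreground genes (genes on vOTUs assigned to that
#' category) against the background of all annotated genes, with an
#' upper-tail hypergeometric test: `p = P(X >= fg_hits)` for
#' `X ~ Hypergeom(bg_size, bg_hits, fg_size)`. Genes with no term are excluded
#' from both foreground and background. q-values are Benjamini-Hochberg
#' adjusted across terms within each category x term-level stratum, matching
#' a design that reports term levels separately.
#'
#' @param annotations Tibble `gene_id`, `votu_id`, `term_id`, `term_level`
#'   (integer), optionally `namespace`.
#' @param calls Trajectory call table (`votu_id`, `category`).
#' @param levels Optional integer vector restricting the term levels tested.
#' @return Tibble of [EnrichmentRow]-style records: `category`, `term_id`,
#'   `term_level`, `fg_hits`, `fg_size`, `bg_hits`, `bg_size`, `fold`, `p`,
#'   `q`, sorted by category, level, then p.
#' @export
enrich_terms <- function(annotations, calls, levels = NULL) {
  need <- c("gene_id", "votu_id", "term_id", "term_level")
  if (!all(need %in% names(annotations))) {
    abort(paste0("annotations must have columns ", paste(need, collapse = ", ")))
  }
  unknown <- setdiff(unique(annotations$votu_id), calls$votu_id)
  if (length(unknown) > 0) {
    abort(paste0("annotated gene maps to vOTU without a category: ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  ann <- tibble::as_tibble(annotations)
  if (!is.null(levels)) ann <- ann[ann$term_level %in% levels, ]
  if (nrow(ann) == 0) return(empty_enrichment())
  ann$category <- calls$category[match(ann$votu_id, calls$votu_id)]

  out <- list()
  for (lev in sort(unique(ann$term_level))) {
    al <- ann[ann$term_level == lev, ]
    bg_genes <- unique(al$gene_id)
    bg_size <- length(bg_genes)
    term_genes <- lapply(split(al$gene_id, al$term_id), unique)
    bg_hits <- lengths(term_genes)
    for (cat in sort(unique(al$category))) {
      fg_genes <- unique(al$gene_id[al$category == cat])
      fg_size <- length(fg_genes)
      if (fg_size == 0) {
        inform(sprintf("category %s has no annotated genes at level %d", cat, lev))
        next
      }
      fg_hits <- vapply(term_genes, function(g) sum(g %in% fg_genes), integer(1))
      # upper tail P(X >= fg_hits), X ~ Hypergeom(bg_size, bg_hits, fg_size)
      p <- stats::phyper(fg_hits - 1, bg_hits, bg_size - bg_hits, fg_size,
                         lower.tail = FALSE)
      fold <- (fg_hits / fg_size) / (bg_hits / bg_size)
      out[[length(out) + 1]] <- tibble::tibble(
        category = cat, term_id = names(term_genes), term_level = lev,
        fg_hits = unname(fg_hits), fg_size = fg_size,
        bg_hits = unname(bg_hits), bg_size = bg_size,
        fold = unname(fold), p = pmin(unname(p), 1),
        q = bh_adjust(pmin(unname(p), 1))
      )
    }
  }
  if (length(out) == 0) return(empty_enrichment())
  res <- dplyr::bind_rows(out)
  res[order(res$category, res$term_level, res$p, res$term_id), ]
}

empty_enrichment <- function() {
  tibble::tibble(category = character(), term_id = character(),
                 term_level = integer(), fg_hits = integer(),
                 fg_size = integer(), bg_hits = integer(), bg_size = integer(),
                 fold = numeric(), p = numeric(), q = numeric())
}
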