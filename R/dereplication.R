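#' Greedy dereplication of contigs into vOTUs
#'
#' Clusters viral contigs into viral operational taxonomic units (vOTUs) with
#' a deterministic greedy longest-first scheme (CD-HIT style): contigs are
#' sorted by length descending (ties broken by id ascending); each contig
#' joins the first earlier cluster representative it matches at both the
#' identity and coverage thresholds, otherwise it founds a new vOTU. The
#' representative of each vOTU is its longest (first) member. Coverage of a
#' hit is `aligned_length / length of the shorter contig of the pair`, the
#' convention that merges contained fragments. Both thresholds are applied as
#' greater-or-equal. When a pair has several hits, the best one (highest
#' identity, then longest alignment) is used.
#'
#' @param contigs Tibble with columns `contig_id`, `length_bp`.
#' @param hits Pairwise-hit tibble with columns `query_id`, `target_id`,
#'   `identity_pct` (0-100) and `aligned_length_bp`. Hits are undirected for
#'   clustering purposes.
#' @param min_identity Minimum percent identity, default 95.
#' @param min_coverage Minimum coverage fraction in (0, 1], default 0.85.
#' @return A vOTU catalog tibble: `votu_id`, `representative_contig`,
#'   `length_bp` (of the representative), `members` (list column of contig
#'   ids), `n_members`, `novelty` = "unassessed".
#' @export
cluster_votus <- function(contigs, hits, min_identity = 95, min_coverage = 0.85) {
  if (min_coverage <= 0 || min_coverage > 1) {
    abort("min_coverage must be in (0, 1]")
  }
  contigs <- as.data.frame(contigs)
  ids <- contigs$contig_id
  len <- as.numeric(contigs$length_bp)
  if (anyDuplicated(ids)) abort("duplicate contig_id")
  n <- length(ids)

  adj <- qualifying_pairs(ids, len, hits, min_identity, min_coverage)

  ord <- order(-len, ids)
  cluster_of <- integer(n)            # index into reps, 0 = unassigned
  reps <- integer(0)                  # contig index of each representative
  for (i in ord) {
    assigned <- 0L
    if (length(reps) > 0) {
      for (r in seq_along(reps)) {
        if (adj[i, reps[r]]) { assigned <- r; break }
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    cluster_of[i] <- assigned
  }

  members <- split(ids, cluster_of)
  # order members within cluster by length desc then id, representative first
  members <- lapply(seq_along(reps), function(r) {
    m <- members[[as.character(r)]]
    m[order(-len[match(m, ids)], m)]
  })
  tibble::tibble(
    votu_id = sprintf("vOTU_%05d", seq_along(reps)),
    representative_contig = ids[reps],
    length_bp = as.integer(len[reps]),
    members = members,
    n_members = lengths(members),
    novelty = "unassessed"
  )
}

# Boolean adjacency matrix of contig pairs linked by a qualifying hit.
qualifying_pairs <- function(ids, len, hits, min_identity, min_coverage) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  if (is.null(hits) || nrow(hits) == 0) return(adj)
  qi <- match(hits$query_id, ids)
  ti <- match(hits$target_id, ids)
  if (anyNA(qi) || anyNA(ti)) {
    bad <- unique(c(hits$query_id[is.na(qi)], hits$target_id[is.na(ti)]))
    abort(paste0("hit references unknown contig: ", paste(bad, collapse = ", ")))
  }
  keep <- qi != ti
  qi <- qi[keep]; ti <- ti[keep]
  idy <- hits$identity_pct[keep]
  alen <- hits$aligned_length_bp[keep]
  if (length(qi) == 0) return(adj)
  # best hit per unordered pair: highest identity, then longest alignment
  a <- pmin(qi, ti); b <- pmax(qi, ti)
  ord <- order(a, b, -idy, -alen)
  first <- !duplicated(cbind(a, b)[ord, , drop = FALSE])
  sel <- ord[first]
  shorter <- pmin(len[a[sel]], len[b[sel]])
  ok <- idy[sel] >= min_identity & alen[sel] / shorter >= min_coverage
  ia <- a[sel][ok]; ib <- b[sel][ok]
  adj[cbind(ia, ib)] <- TRUE
  adj[cbind(ib, ia)] <- TRUE
  adj
}

#' Classify vOTU novelty against a reference database hit table
#'
#' A vOTU is "reported" when at least one blast-style hit of its
#' representative against the reference meets both thresholds: identity >= 90
#' percent and coverage (aligned length over the vOTU length) >= 5 percent.
#' vOTUs with no qualifying hit, including those absent from the hit table,
#' are "unreported".
#'
#' @param catalog vOTU catalog from [cluster_votus()].
#' @param reference_hits Tibble with columns `query_id` (vOTU id or its
#'   representative contig id), `target_id`, `identity_pct`,
#'   `aligned_length_bp`. May be empty.
#' @param min_identity Minimum percent identity, default 90.
#' @param min_coverage Minimum fraction of the vOTU length aligned,
#'   default 0.05.
#' @return The catalog with `novelty` set to "reported"/"unreported".
#' @export
classify_novelty <- function(catalog, reference_hits, min_identity = 90,
                             min_coverage = 0.05) {
  catalog <- validate_catalog(catalog)
  catalog$novelty <- "unreported"
  if (is.null(reference_hits) || nrow(reference_hits) == 0) return(catalog)
  idx <- match(reference_hits$query_id, catalog$votu_id)
  alt <- match(reference_hits$query_id, catalog$representative_contig)
  idx[is.na(idx)] <- alt[is.na(idx)]
  keep <- !is.na(idx)
  idx <- idx[keep]
  ok <- reference_hits$identity_pct[keep] >= min_identity &
    reference_hits$aligned_length_bp[keep] / catalog$length_bp[idx] >= min_coverage
  catalog$novelty[unique(idx[ok])] <- "reported"
  catalog
}
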