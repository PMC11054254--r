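hit <- function(q, t, id, len) {
  tibble::tibble(query_id = q, target_id = t, identity_pct = id,
                 aligned_length_bp = len)
}

test_that("a qualifying pair merges into one vOTU with the longest representative", {
  contigs <- tibble::tibble(contig_id = c("short", "long"),
                            length_bp = c(2000L, 3000L))
  cat1 <- cluster_votus(contigs, hit("short", "long", 96, 1800))  # 90% of shorter
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$representative_contig, "long")
  expect_equal(cat1$length_bp, 3000L)
  expect_setequal(cat1$members[[1]], c("short", "long"))

  # below either threshold: two singletons
  expect_equal(nrow(cluster_votus(contigs, hit("short", "long", 94.9, 1800))), 2)
  expect_equal(nrow(cluster_votus(contigs, hit("short", "long", 96, 1699))), 2)
  # boundary cases are inclusive (>= 95, >= 0.85)
  expect_equal(nrow(cluster_votus(contigs, hit("short", "long", 95, 1700))), 1)
})

test_that("greedy chain resolution matches the brute-force greedy oracle", {
  # chain A-B and B-C qualify, A-C absent, lengths A > B > C -> {A,B},{C}
  contigs <- tibble::tibble(contig_id = c("A", "B", "C"),
                            length_bp = c(3000L, 2500L, 2000L))
  hits <- dplyr::bind_rows(hit("A", "B", 96, 2400), hit("B", "C", 96, 1900))
  cat1 <- cluster_votus(contigs, hits)
  expect_equal(catalog_signature(cat1), "A,B;C")

  edge_list <- list(list(q = "A", t = "B", id = 96, len = 2400),
                    list(q = "B", t = "C", id = 96, len = 1900))
  oracle <- oracle_greedy_clusters(contigs$contig_id, contigs$length_bp, edge_list)
  expect_equal(catalog_signature(cat1), cluster_signature(oracle))
})

test_that("clustering equals the greedy oracle on random instances and is hit-order invariant", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    ids <- paste0("c", seq_len(n))
    lens <- sample(1000:5000, n)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.5
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0) next
    idy <- round(runif(nrow(pairs), 90, 100), 1)
    alen <- as.integer(runif(nrow(pairs), 0.5, 1) *
                         pmin(lens[pairs[, 1]], lens[pairs[, 2]]))
    hits <- tibble::tibble(query_id = ids[pairs[, 1]], target_id = ids[pairs[, 2]],
                           identity_pct = idy, aligned_length_bp = alen)
    contigs <- tibble::tibble(contig_id = ids, length_bp = lens)
    cat1 <- cluster_votus(contigs, hits)
    edge_list <- lapply(seq_len(nrow(hits)), function(i) {
      list(q = hits$query_id[i], t = hits$target_id[i],
           id = hits$identity_pct[i], len = hits$aligned_length_bp[i])
    })
    oracle <- oracle_greedy_clusters(ids, lens, edge_list)
    expect_equal(catalog_signature(cat1), cluster_signature(oracle))
    # permuting hit rows never changes the catalog
    cat2 <- cluster_votus(contigs, hits[sample(nrow(hits)), ])
    expect_equal(catalog_signature(cat2), catalog_signature(cat1))
    # partition property
    expect_setequal(unlist(cat1$members), ids)
    expect_equal(length(unlist(cat1$members)), n)
  }
})

test_that("threshold tightening usually, but not always, increases cluster counts", {
  # Greedy longest-first clustering is NOT monotone in its thresholds: a
  # stricter threshold can free a long contig to found a new representative
  # that absorbs contigs which previously founded their own clusters. This
  # pins the known counterexample (checked against the greedy oracle at both
  # thresholds) so the behavior is documented, not mistaken for a bug.
  ids <- paste0("c", 1:6)
  lens <- c(4732L, 3712L, 3576L, 5832L, 3108L, 2970L)
  hits <- tibble::tibble(
    query_id  = c("c1", "c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4", "c5"),
    target_id = c("c2", "c3", "c6", "c5", "c6", "c4", "c6", "c5", "c6", "c6"),
    identity_pct = c(94.1, 92.7, 91.8, 94.2, 97.2, 92.9, 91.1, 92.9, 92.3, 92.8),
    aligned_length_bp = c(3101L, 3467L, 2928L, 2950L, 2893L, 2596L, 2327L,
                          2720L, 2053L, 2493L))
  contigs <- tibble::tibble(contig_id = ids, length_bp = lens)
  edge_list <- lapply(seq_len(nrow(hits)), function(i) {
    list(q = hits$query_id[i], t = hits$target_id[i],
         id = hits$identity_pct[i], len = hits$aligned_length_bp[i])
  })
  low <- cluster_votus(contigs, hits, 94, 0.75)
  high <- cluster_votus(contigs, hits, 94, 0.90)
  # both runs agree with the literal greedy rule ...
  expect_equal(catalog_signature(low),
               cluster_signature(oracle_greedy_clusters(ids, lens, edge_list,
                                                        94, 0.75)))
  expect_equal(catalog_signature(high),
               cluster_signature(oracle_greedy_clusters(ids, lens, edge_list,
                                                        94, 0.90)))
  # ... and the stricter coverage threshold yields FEWER clusters here:
  # c2 no longer joins c1, founds its own vOTU and absorbs c5 and c6
  expect_lt(nrow(high), nrow(low))
})

test_that("clustering input validation", {
  contigs <- tibble::tibble(contig_id = c("A", "B"), length_bp = c(3000L, 2000L))
  expect_error(cluster_votus(contigs, hit("A", "Z", 96, 1800)), "unknown contig")
  expect_error(cluster_votus(contigs, hit("A", "B", 96, 1800), min_coverage = 0),
               "min_coverage")
  expect_error(cluster_votus(contigs, hit("A", "B", 96, 1800), min_coverage = 1.2),
               "min_coverage")
  # no hits: every contig its own vOTU
  expect_equal(nrow(cluster_votus(contigs, hits = NULL)), 2)
})

test_that("novelty classification applies 90% identity / 5% coverage on the vOTU length", {
  cat1 <- tiny_catalog(lengths = c(10000L, 2000L, 4000L))
  ref <- tibble::tibble(
    query_id = c("vOTU_00001", "vOTU_00002", "vOTU_00003"),
    target_id = "ref",
    identity_pct = c(92, 89, 95),
    aligned_length_bp = c(600L, 1000L, 150L))  # 6%, 50%, 3.75% coverage
  out <- classify_novelty(cat1, ref)
  expect_equal(out$novelty, c("reported", "unreported", "unreported"))

  all_un <- classify_novelty(cat1, ref[0, ])
  expect_true(all(all_un$novelty == "unreported"))
  # representative contig ids are accepted as query ids too
  ref2 <- ref
  ref2$query_id <- cat1$representative_contig
  expect_equal(classify_novelty(cat1, ref2)$novelty, out$novelty)
})
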