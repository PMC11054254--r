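test_that("the generator is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_votus = 40)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_annotations(cfg, s1$catalog, s1$truth),
                   simulate_annotations(cfg, s2$catalog, s2$truth))
  expect_identical(simulate_vamg_table(cfg), simulate_vamg_table(cfg))
  expect_identical(simulate_lifestyle(cfg, s1$catalog),
                   simulate_lifestyle(cfg, s2$catalog))
  s3 <- simulate_study(sim_config(seed = 100, n_votus = 40))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("planted structure is realized by construction", {
  cfg <- sim_config(seed = 17, n_votus = 120)
  sim <- simulate_study(cfg)
  counts <- dplyr::inner_join(sim$counts, sim$design, by = "sample_id")
  counts$category <- sim$truth$category[match(counts$votu_id, sim$truth$votu_id)]
  # category a: zero counts in exactly two stages
  for (v in sim$truth$votu_id[sim$truth$category == "a"]) {
    by_stage <- tapply(counts$read_count[counts$votu_id == v],
                       counts$stage[counts$votu_id == v], sum)
    expect_equal(sum(by_stage == 0), 2)
  }
  # breadth is monotone non-decreasing in read count within each vOTU
  m <- dplyr::inner_join(sim$counts, sim$breadth, by = c("votu_id", "sample_id"))
  for (v in unique(m$votu_id)[1:40]) {
    sub <- m[m$votu_id == v, ]
    ord <- order(sub$read_count)
    expect_true(all(diff(sub$breadth[ord]) >= -1e-12))
    expect_true(all(sub$breadth[sub$read_count == 0] == 0))
    expect_true(all(sub$breadth >= 0 & sub$breadth <= 1))
  }
  # planted proportions respected exactly by construction
  s <- table(sim$truth$category)
  expect_equal(as.integer(s), as.integer(round(
    cfg$category_proportions[names(s)] * cfg$n_votus)))
})

test_that("intervals reproduce the generator's breadth through compute_breadth", {
  sim <- simulate_study(sim_config(seed = 23, n_votus = 30))
  br <- compute_breadth(sim$intervals, sim$catalog,
                        samples = sim$design$sample_id)
  key <- function(d) d[order(d$votu_id, d$sample_id), ]
  expect_equal(key(br)$breadth, key(sim$breadth)$breadth, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fold_change = 1), "fold_change")
  expect_error(sim_config(category_proportions = c(a = 0.5, b = 0.5)),
               "named a-f")
  expect_error(sim_config(category_proportions = c(a = 0.3, b = 0.3, c = 0.3,
                                                   d = 0.05, e = 0.05, f = 0.05)),
               "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(lytic_fraction = 1.5), "lytic_fraction")
  cfg <- sim_config(n_terms = 6, enriched_terms_per_category = 2)
  sim <- simulate_study(sim_config(n_votus = 10))
  expect_error(simulate_annotations(cfg, sim$catalog, sim$truth), "n_terms")
  # fold_change = 1 is allowed when only a and b are requested
  cfg_ab <- sim_config(fold_change = 1, category_proportions = c(
    a = 0.5, b = 0.5, c = 0, d = 0, e = 0, f = 0))
  expect_s3_class(cfg_ab, "sim_config")
})

test_that("null annotation tables keep the per-stratum false-discovery rate at alpha", {
  # BH is applied within each category x term-level stratum, so the
  # guarantee under the null is per stratum: P(any q < 0.05) <= 0.05 in each
  # BH family (and below it for discrete hypergeometric p-values)
  sim <- simulate_study(sim_config(seed = 41, n_votus = 200,
                                   enriched_terms_per_category = 0))
  n_strata <- 0; n_strata_hit <- 0
  for (seed in 1:10) {
    cfg_i <- sim_config(seed = seed, n_votus = 200,
                        enriched_terms_per_category = 0)
    ann <- simulate_annotations(cfg_i, sim$catalog, sim$truth)
    res <- enrich_terms(ann$annotations, sim$truth[, c("votu_id", "category")])
    strata <- split(res$q, paste(res$category, res$term_level))
    n_strata <- n_strata + length(strata)
    n_strata_hit <- n_strata_hit + sum(vapply(strata, function(q) any(q < 0.05),
                                              logical(1)))
  }
  expect_gt(n_strata, 100)
  expect_lte(n_strata_hit / n_strata, 0.05 + 0.04)  # binomial slack at n ~ 120
})

test_that("written study directories are complete and readable", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 3, n_votus = 25)
  write_simulated_study(cfg, dir)
  files <- c("design.tsv", "catalog.tsv", "counts.tsv", "intervals.tsv",
             "breadth.tsv", "annotations.tsv", "vamg.tsv", "lifestyle.tsv",
             "truth.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  d <- read_design(file.path(dir, "design.tsv"))
  expect_equal(nrow(d), 15)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(nrow(counts), 25 * 15)
})
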