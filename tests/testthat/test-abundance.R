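test_that("breadth is the interval-union fraction of the vOTU length", {
  cat1 <- tiny_catalog(lengths = 100L)
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(votu_id = "vOTU_00001", sample_id = "s1",
                   start = m[, 1], end = m[, 2])
  }
  get_b <- function(ivs) compute_breadth(ivs, cat1)$breadth
  expect_equal(get_b(iv(0, 50, 25, 75)), 0.75)      # overlapping pair
  expect_equal(get_b(iv(0, 100)), 1.0)
  expect_equal(get_b(iv(99, 100)), 0.01)
  # no intervals at all -> zero breadth for the declared sample
  none <- compute_breadth(iv(0, 50)[0, ], cat1, samples = "s1")
  expect_equal(none$breadth, 0)
})

test_that("breadth is invariant under permutation and splitting of intervals", {
  set.seed(3)
  cat1 <- tiny_catalog(lengths = 1000L)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    start <- sort(sample(0:990, k))
    end <- pmin(1000, start + sample(5:300, k, replace = TRUE))
    base <- tibble::tibble(votu_id = "vOTU_00001", sample_id = "s1",
                           start = start, end = end)
    b0 <- compute_breadth(base, cat1)$breadth
    # permute
    expect_equal(compute_breadth(base[sample(k), ], cat1)$breadth, b0)
    # split every interval at its midpoint where possible
    wide <- base[base$end - base$start >= 2, ]
    mid <- floor((wide$start + wide$end) / 2)
    split_tab <- dplyr::bind_rows(
      base[base$end - base$start < 2, ],
      tibble::tibble(votu_id = wide$votu_id, sample_id = wide$sample_id,
                     start = wide$start, end = mid),
      tibble::tibble(votu_id = wide$votu_id, sample_id = wide$sample_id,
                     start = mid, end = wide$end))
    expect_equal(compute_breadth(split_tab, cat1)$breadth, b0)
  }
})

test_that("breadth input validation", {
  cat1 <- tiny_catalog(lengths = 100L)
  bad_order <- tibble::tibble(votu_id = "vOTU_00001", sample_id = "s1",
                              start = 10, end = 10)
  expect_error(compute_breadth(bad_order, cat1), "end must be greater")
  beyond <- tibble::tibble(votu_id = "vOTU_00001", sample_id = "s1",
                           start = 50, end = 101)
  expect_error(compute_breadth(beyond, cat1), "outside")
  unknown <- tibble::tibble(votu_id = "nope", sample_id = "s1",
                            start = 0, end = 10)
  expect_error(compute_breadth(unknown, cat1), "unknown votu_id")
})

test_that("TPM matches the length-normalized equation on hand-computed cases", {
  cat2 <- tiny_catalog(lengths = c(100L, 100L))[1:2, ]
  counts <- function(n) tibble::tibble(votu_id = cat2$votu_id,
                                       sample_id = "s1", read_count = n)
  expect_equal(compute_tpm(counts(c(10L, 30L)), cat2)$tpm, c(250000, 750000))

  cat2b <- cat2
  cat2b$length_bp <- c(100L, 300L)
  expect_equal(compute_tpm(counts(c(10L, 30L)), cat2b)$tpm, c(500000, 500000))

  one <- compute_tpm(counts(c(7L, 0L)), cat2)
  expect_equal(one$tpm, c(1e6, 0))
})

test_that("TPM properties: normalization, scale invariance, length monotonicity", {
  set.seed(5)
  n <- 20
  cat_n <- tiny_catalog(lengths = sample(1000:8000, n))
  counts <- tibble::tibble(
    votu_id = rep(cat_n$votu_id, 3),
    sample_id = rep(c("s1", "s2", "s3"), each = n),
    read_count = rnbinom(3 * n, size = 5, mu = 50))
  tpm <- compute_tpm(counts, cat_n)
  sums <- tapply(tpm$tpm, tpm$sample_id, sum)
  expect_true(all(abs(sums - 1e6) <= 1e-9 * 1e6))

  # uniform count scaling within a sample leaves TPM unchanged
  scaled <- counts
  scaled$read_count <- scaled$read_count * 7L
  expect_equal(compute_tpm(scaled, cat_n)$tpm, tpm$tpm)

  # doubling one vOTU's length decreases its TPM, weakly increases the rest
  cat_mod <- cat_n
  cat_mod$length_bp[1] <- cat_mod$length_bp[1] * 2L
  tpm2 <- compute_tpm(counts, cat_mod)
  s1 <- tpm$sample_id == "s1" & tpm$tpm > 0
  v1 <- tpm$votu_id == cat_n$votu_id[1]
  expect_lt(tpm2$tpm[v1 & tpm$sample_id == "s1"][1],
            tpm$tpm[v1 & tpm$sample_id == "s1"][1])
  expect_true(all(tpm2$tpm[s1 & !v1] >= tpm$tpm[s1 & !v1]))
})

test_that("all-zero samples yield zero TPM with a warning, not an error", {
  cat2 <- tiny_catalog()[1:2, ]
  counts <- tibble::tibble(votu_id = rep(cat2$votu_id, 2),
                           sample_id = rep(c("s1", "s2"), each = 2),
                           read_count = c(5L, 5L, 0L, 0L))
  expect_warning(tpm <- compute_tpm(counts, cat2), "no mapped reads")
  expect_equal(tpm$tpm[tpm$sample_id == "s2"], c(0, 0))
  expect_error(compute_tpm(tibble::tibble(votu_id = "zz", sample_id = "s1",
                                          read_count = 1L), cat2),
               "unknown votu_id")
})
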