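#' Configuration for the synthetic study generator
#'
#' Defines the study conditions the generator emulates: a three-stage design
#' (lactation, nursery, fattening; 5 samples per stage), negative-binomial
#' read counts with planted stage-to-stage fold-changes realizing the six
#' trajectory categories, lognormal contig lengths around the vOTU length
#' scale of real gut viromes, planted enriched annotation terms per category,
#' a vAMG candidate table with a controlled pass/fail mixture, and lifestyle
#' tables with a planted lytic majority.
#'
#' @param seed Integer RNG seed; every generator draw derives from it.
#' @param n_votus Number of vOTUs.
#' @param samples_per_stage Samples per stage (default 5).
#' @param category_proportions Named fractions for categories a-f, summing
#'   to 1. Default `c(a=.1, b=.4, c=.2, d=.1, e=.1, f=.1)`: constant vOTUs
#'   most common, continuous growth next, as in stage-resolved gut viromes.
#' @param fold_change Planted stage-to-stage fold-change (> 1) for
#'   categories c-f (default 8).
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param base_mean Baseline NB mean read count (default 20).
#' @param read_length Read length in bp used to turn counts into depth for
#'   the breadth curve (default 150).
#' @param length_logmean,length_logsd Lognormal contig length parameters
#'   (defaults `log(4000)` and 0.5, matching few-kb viral contigs).
#' @param n_terms Annotation terms per term level (default 50).
#' @param genes_per_votu Mean genes per vOTU (default 3; at least 1 each).
#' @param enriched_terms_per_category Planted enriched terms per category and
#'   level (default 2).
#' @param enrichment_factor Within-category frequency of a planted term
#'   relative to the uniform background (default 8, i.e. >= 4x background).
#' @param term_levels Integer term levels generated (default `c(3, 4)`).
#' @param n_vamg Candidate vAMG records (default 200).
#' @param vamg_pass_fraction Fraction of candidates built to pass the filter
#'   (default 0.5).
#' @param lytic_fraction Probability a called vOTU is virulent (default 0.8).
#' @param unclassified_fraction,low_quality_fraction Fractions of lifestyle
#'   rows labelled unclassified / low quality (defaults 0.05, 0.1).
#' @param p2_fraction Fraction of vOTUs with complete genomes, eligible for
#'   the second predictor (default 0.3).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_votus = 600L,
                       samples_per_stage = 5L,
                       category_proportions = c(a = 0.1, b = 0.4, c = 0.2,
                                                d = 0.1, e = 0.1, f = 0.1),
                       fold_change = 8,
                       dispersion = 5,
                       base_mean = 20,
                       read_length = 150,
                       length_logmean = log(4000),
                       length_logsd = 0.5,
                       n_terms = 50L,
                       genes_per_votu = 3,
                       enriched_terms_per_category = 2L,
                       enrichment_factor = 8,
                       term_levels = c(3L, 4L),
                       n_vamg = 200L,
                       vamg_pass_fraction = 0.5,
                       lytic_fraction = 0.8,
                       unclassified_fraction = 0.05,
                       low_quality_fraction = 0.1,
                       p2_fraction = 0.3) {
  cfg <- list(seed = as.integer(seed), n_votus = as.integer(n_votus),
              samples_per_stage = as.integer(samples_per_stage),
              category_proportions = category_proportions,
              fold_change = fold_change, dispersion = dispersion,
              base_mean = base_mean, read_length = read_length,
              length_logmean = length_logmean, length_logsd = length_logsd,
              n_terms = as.integer(n_terms), genes_per_votu = genes_per_votu,
              enriched_terms_per_category = as.integer(enriched_terms_per_category),
              enrichment_factor = enrichment_factor,
              term_levels = as.integer(term_levels),
              n_vamg = as.integer(n_vamg),
              vamg_pass_fraction = vamg_pass_fraction,
              lytic_fraction = lytic_fraction,
              unclassified_fraction = unclassified_fraction,
              low_quality_fraction = low_quality_fraction,
              p2_fraction = p2_fraction)
  props <- cfg$category_proportions
  if (!setequal(names(props), letters[1:6])) {
    abort("category_proportions must be named a-f")
  }
  if (abs(sum(props) - 1) > 1e-8) abort("category_proportions must sum to 1")
  if (any(props < 0)) abort("category_proportions must be non-negative")
  if (cfg$fold_change <= 1 && any(props[c("c", "d", "e", "f")] > 0)) {
    abort("fold_change must exceed 1 when categories c/d/e/f are requested")
  }
  if (cfg$n_votus < 1 || cfg$samples_per_stage < 2) {
    abort("need n_votus >= 1 and samples_per_stage >= 2")
  }
  if (cfg$dispersion <= 0) abort("dispersion must be positive")
  if (cfg$lytic_fraction < 0 || cfg$lytic_fraction > 1) {
    abort("lytic_fraction must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Per-stage NB mean profile of a category, as multiples of base_mean.
stage_mean_profile <- function(category, fold, exclusive_stage = "L") {
  switch(category,
    a = { m <- c(L = 0, N = 0, F = 0); m[exclusive_stage] <- fold; m },
    b = c(L = 1, N = 1, F = 1) * fold / 2,
    c = c(L = 1, N = fold, F = fold^2),
    d = c(L = 1, N = fold, F = 1),
    e = c(L = fold^2, N = fold, F = 1),
    f = c(L = fold, N = 1, F = fold))
}

#' Simulate a complete stage-wise virome study
#'
#' Draws per-vOTU per-sample read counts from a negative binomial whose
#' stage-dependent means realize each vOTU's planted trajectory category
#' (`a` has structurally zero counts outside one stage), derives coverage
#' breadth through a saturating depth curve `1 - exp(-0.7 * depth)` with
#' multiplicative jitter, made monotone non-decreasing in the read count
#' within each vOTU, and lays down alignment intervals whose union realizes
#' that breadth exactly. Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `design` (StageDesign), `catalog` (VotuCatalog),
#'   `counts` (`votu_id`, `sample_id`, `read_count`), `intervals` (0-based
#'   half-open), `breadth` (`votu_id`, `sample_id`, `breadth`), and `truth`
#'   (`votu_id`, `category`, `exclusive_stage` for category a).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nps <- config$samples_per_stage
  design <- tibble::tibble(
    sample_id = sprintf("%s%02d", rep(STAGES, each = nps), rep(seq_len(nps), 3)),
    stage = factor(rep(STAGES, each = nps), levels = STAGES, ordered = TRUE))

  n <- config$n_votus
  cats <- plant_categories(n, config$category_proportions)
  excl <- rep(STAGES, length.out = n)  # rotating exclusive stage for category a
  votu_id <- sprintf("vOTU_%05d", seq_len(n))
  len <- pmax(500L, as.integer(round(
    stats::rlnorm(n, config$length_logmean, config$length_logsd))))
  catalog <- tibble::tibble(
    votu_id = votu_id,
    representative_contig = sprintf("ctg_%05d", seq_len(n)),
    length_bp = len,
    members = as.list(sprintf("ctg_%05d", seq_len(n))),
    n_members = 1L,
    novelty = "unassessed")

  ns <- nrow(design)
  mu <- matrix(0, n, ns, dimnames = list(votu_id, design$sample_id))
  for (i in seq_len(n)) {
    prof <- stage_mean_profile(cats[i], config$fold_change, excl[i])
    mu[i, ] <- config$base_mean * prof[as.character(design$stage)]
  }
  cnt <- matrix(0L, n, ns, dimnames = dimnames(mu))
  pos <- mu > 0
  cnt[pos] <- stats::rnbinom(sum(pos), size = config$dispersion, mu = mu[pos])

  depth <- cnt * config$read_length / len
  jit <- matrix(stats::runif(n * ns, 0.85, 1.15), n, ns)
  raw <- 1 - exp(-0.7 * depth * jit)
  covered <- matrix(0, n, ns, dimnames = dimnames(cnt))
  for (i in seq_len(n)) {
    covered[i, ] <- monotone_covered(cnt[i, ], raw[i, ], len[i])
  }
  breadth <- covered / len

  counts_tab <- tibble::tibble(
    votu_id = rep(votu_id, times = ns),
    sample_id = rep(design$sample_id, each = n),
    read_count = as.integer(cnt))
  breadth_tab <- tibble::tibble(
    votu_id = counts_tab$votu_id, sample_id = counts_tab$sample_id,
    breadth = as.vector(breadth))
  intervals <- intervals_from_covered(covered, len, votu_id)

  list(design = design, catalog = catalog, counts = counts_tab,
       intervals = intervals, breadth = breadth_tab,
       truth = tibble::tibble(votu_id = votu_id, category = cats,
                              exclusive_stage = ifelse(cats == "a", excl, NA)))
}

# Deterministic category assignment honoring the requested proportions.
plant_categories <- function(n, props) {
  props <- props[letters[1:6]]
  cnt <- floor(props * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- props * n - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  rep(letters[1:6], times = cnt)
}

# Covered-bp vector for one vOTU: monotone non-decreasing in count, equal
# counts share a value, zero count -> 0, capped at len.
monotone_covered <- function(counts, raw_breadth, len) {
  cov <- round(pmin(pmax(raw_breadth, 0), 1) * len)
  ord <- order(counts)
  cum <- cummax(cov[ord])
  # tie groups take their common (max) value so ties in counts stay ties
  grp <- as.integer(factor(counts[ord], levels = unique(counts[ord])))
  cum <- stats::ave(cum, grp, FUN = max)
  out <- numeric(length(counts))
  out[ord] <- cum
  out[counts == 0] <- 0
  out
}

# Two disjoint intervals per covered votu x sample whose union length equals
# the covered bp (0-based half-open).
intervals_from_covered <- function(covered, len, votu_id) {
  idx <- which(covered > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(votu_id = character(), sample_id = character(),
                          start = integer(), end = integer()))
  }
  v <- idx[, 1]; s <- idx[, 2]
  cov <- covered[idx]; L <- len[v]
  c1 <- ceiling(cov / 2); c2 <- cov - c1
  one <- tibble::tibble(votu_id = votu_id[v], sample_id = colnames(covered)[s],
                        start = 0L, end = as.integer(c1))
  two <- tibble::tibble(votu_id = votu_id[v], sample_id = colnames(covered)[s],
                        start = as.integer(L - c2), end = as.integer(L))
  out <- dplyr::bind_rows(one, two[two$end > two$start, ])
  out[order(out$votu_id, out$sample_id, out$start), ]
}

#' Simulate a gene-to-vOTU-to-term annotation table with planted enrichment
#'
#' Every vOTU carries one or more genes; at each term level every gene draws
#' one term. Genes on vOTUs of a planted term's target category draw that
#' term with probability `enrichment_factor / n_terms` (default 8x the
#' uniform background rate of `1 / n_terms`), so each planted term is
#' recoverable by over-representation analysis against the all-genes
#' background.
#'
#' @param config A [sim_config()]; set `enriched_terms_per_category = 0` for
#'   a null table with no planted signal.
#' @param catalog vOTU catalog (from [simulate_study()]).
#' @param truth Truth table (`votu_id`, `category`) from [simulate_study()].
#' @return List with `annotations` (`gene_id`, `votu_id`, `term_id`,
#'   `term_level`, `namespace`) and `planted` (`category`, `term_id`,
#'   `term_level`).
#' @export
simulate_annotations <- function(config, catalog, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(catalog) == 0) abort("catalog is empty")
  k <- config$enriched_terms_per_category
  if (config$n_terms < 6 * k) {
    abort("n_terms too small for the requested planted terms per category")
  }
  set.seed(config$seed + 1L)
  n_genes <- pmax(1L, stats::rpois(nrow(catalog), config$genes_per_votu))
  genes <- tibble::tibble(
    votu_id = rep(catalog$votu_id, times = n_genes),
    gene_id = sprintf("gene_%06d", seq_len(sum(n_genes))))
  genes$category <- truth$category[match(genes$votu_id, truth$votu_id)]

  planted <- list(); rows <- list()
  for (lev in config$term_levels) {
    terms <- sprintf("T%d_%03d", lev, seq_len(config$n_terms))
    pl <- if (k > 0) {
      tibble::tibble(category = rep(letters[1:6], each = k),
                     term_id = terms[seq_len(6 * k)], term_level = lev)
    } else {
      tibble::tibble(category = character(), term_id = character(),
                     term_level = integer())
    }
    planted[[as.character(lev)]] <- pl
    p_enr <- min(0.5, config$enrichment_factor / config$n_terms)
    term <- sample(terms, nrow(genes), replace = TRUE)
    if (k > 0) {
      for (cat in letters[1:6]) {
        in_cat <- which(genes$category == cat)
        cat_terms <- pl$term_id[pl$category == cat]
        for (tm in cat_terms) {
          hit <- in_cat[stats::runif(length(in_cat)) < p_enr]
          term[hit] <- tm
        }
      }
    }
    rows[[as.character(lev)]] <- tibble::tibble(
      gene_id = genes$gene_id, votu_id = genes$votu_id,
      term_id = term, term_level = lev, namespace = "GO")
  }
  list(annotations = dplyr::bind_rows(rows), planted = dplyr::bind_rows(planted))
}

#' Simulate a DRAM-v-style candidate vAMG table with truth labels
#'
#' Builds a controlled mixture: a `vamg_pass_fraction` share of records
#' satisfies every retention rule (auxiliary score < 4, metabolism flag only,
#' gene id/description and KEGG annotation present, non-blacklisted pathway,
#' no host contamination); the rest each violate exactly one rule, chosen
#' round-robin, so every rejection branch of the filter is exercised.
#'
#' @param config A [sim_config()].
#' @param catalog Optional catalog; carrier vOTUs are sampled from it
#'   (defaults to generic ids).
#' @return Tibble of VamgRecord columns plus `truth_retain` (logical) and
#'   `truth_rule` (the rule a failing record violates).
#' @export
simulate_vamg_table <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_vamg
  votus <- if (is.null(catalog)) sprintf("vOTU_%05d", seq_len(max(n, 1)))
           else catalog$votu_id
  pathways <- c("cysteine and methionine metabolism", "folate biosynthesis",
                "cofactor biosynthesis", "nicotinate and nicotinamide metabolism")
  descs <- c("DNA (cytosine-5)-methyltransferase 1",
             "6-pyruvoyltetrahydropterin synthase",
             "GTP cyclohydrolase 1", "7-cyano-7-deazaguanine synthase",
             "nicotinamide phosphoribosyltransferase")
  fail_rules <- c("auxiliary_score", "no_metabolism_flag", "attachment_flag",
                  "viral_flag", "transposon_flag", "no_gene_description",
                  "no_kegg_annotation", "pathway_blacklist", "host_contaminated")
  pass <- stats::runif(n) < config$vamg_pass_fraction
  rule <- rep(NA_character_, n)
  rule[!pass] <- rep(fail_rules, length.out = sum(!pass))

  tab <- tibble::tibble(
    gene_id = sprintf("amg_%05d", seq_len(n)),
    votu_id = sample(votus, n, replace = TRUE),
    auxiliary_score = sample(1:3, n, replace = TRUE),
    flags = "M",
    kegg_id = sprintf("K%05d", sample(1:20000, n, replace = TRUE)),
    gene_description = sample(descs, n, replace = TRUE),
    pathway = sample(pathways, n, replace = TRUE),
    host_contaminated = FALSE)
  bump <- function(sel, col, val) { tab[[col]][sel] <<- val }
  bump(rule %in% "auxiliary_score", "auxiliary_score", 4L)
  bump(rule %in% "no_metabolism_flag", "flags", "")
  bump(rule %in% "attachment_flag", "flags", "MA")
  bump(rule %in% "viral_flag", "flags", "MV")
  bump(rule %in% "transposon_flag", "flags", "MT")
  bump(rule %in% "no_gene_description", "gene_description", NA_character_)
  bump(rule %in% "no_kegg_annotation", "kegg_id", NA_character_)
  bump(rule %in% "pathway_blacklist", "pathway", "Nucleotide metabolism")
  bump(rule %in% "host_contaminated", "host_contaminated", TRUE)
  tab$truth_retain <- pass
  tab$truth_rule <- ifelse(pass, "retained", rule)
  tab
}

#' Simulate per-vOTU lifestyle prediction tables from two predictors
#'
#' Predictor P1 covers every phage-annotated vOTU; predictor P2 only the
#' complete-genome subset (a nested subset of P1's input). Calls are virulent
#' with probability `lytic_fraction`, temperate otherwise; a configurable
#' fraction of rows is labelled unclassified or low quality so the screening
#' step has work to do.
#'
#' @param config A [sim_config()].
#' @param catalog vOTU catalog.
#' @return LifestyleTable tibble: `votu_id`, `predictor`, `call`, `quality`,
#'   `is_phage`.
#' @export
simulate_lifestyle <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  draw <- function(votus, predictor, complete) {
    n <- length(votus)
    call <- ifelse(stats::runif(n) < config$lytic_fraction, "virulent", "temperate")
    call[stats::runif(n) < config$unclassified_fraction] <- "unclassified"
    qual <- if (complete) rep("complete", n)
            else sample(c("high", "medium"), n, replace = TRUE)
    qual[stats::runif(n) < config$low_quality_fraction] <- "low"
    tibble::tibble(votu_id = votus, predictor = predictor, call = call,
                   quality = qual, is_phage = TRUE)
  }
  votus <- catalog$votu_id
  n2 <- max(1L, round(config$p2_fraction * length(votus)))
  p2_votus <- sort(sample(votus, n2))
  dplyr::bind_rows(draw(votus, "P1", complete = FALSE),
                   draw(p2_votus, "P2", complete = TRUE))
}

#' Write a full simulated study to a directory of TSV files
#'
#' Emits design.tsv, catalog.tsv, counts.tsv, intervals.tsv, breadth.tsv,
#' annotations.tsv, vamg.tsv, lifestyle.tsv and truth.tsv.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_simulated_study <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config)
  ann <- simulate_annotations(config, study$catalog, study$truth)
  vamg <- simulate_vamg_table(config, study$catalog)
  life <- simulate_lifestyle(config, study$catalog)
  cat_flat <- study$catalog
  cat_flat$members <- vapply(cat_flat$members, paste, character(1), collapse = ",")
  write_result_table(study$design, file.path(outdir, "design.tsv"))
  write_result_table(cat_flat, file.path(outdir, "catalog.tsv"))
  write_result_table(study$counts, file.path(outdir, "counts.tsv"))
  write_result_table(study$intervals, file.path(outdir, "intervals.tsv"))
  write_result_table(study$breadth, file.path(outdir, "breadth.tsv"))
  write_result_table(ann$annotations, file.path(outdir, "annotations.tsv"))
  write_result_table(vamg, file.path(outdir, "vamg.tsv"))
  write_result_table(life, file.path(outdir, "lifestyle.tsv"))
  write_result_table(study$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
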