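#' Build and validate a pipeline configuration
#'
#' @param input_dir Directory of input TSVs (as written by
#'   [write_simulated_study()] or assembled from upstream tools). Ignored
#'   when `simulate = TRUE`.
#' @param outdir Output directory for stage tables and the run manifest.
#' @param simulate Generate the inputs with the synthetic-study generator
#'   instead of reading them (default FALSE).
#' @param seed RNG seed (integer), used by the simulator.
#' @param min_identity,min_coverage Dereplication thresholds (95, 0.85).
#' @param novelty_min_identity,novelty_min_coverage Novelty thresholds
#'   (90, 0.05).
#' @param alpha,alpha_dunn Trajectory significance levels (0.05 each).
#' @param dunn_adjust "bh" or "none".
#' @param q_threshold Enrichment reporting threshold on q (0.05).
#' @param sim Optional [sim_config()] overriding the default simulation.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, outdir, simulate = FALSE,
                            seed = 1L, min_identity = 95, min_coverage = 0.85,
                            novelty_min_identity = 90,
                            novelty_min_coverage = 0.05,
                            alpha = 0.05, alpha_dunn = 0.05,
                            dunn_adjust = "bh", q_threshold = 0.05,
                            sim = NULL) {
  cfg <- list(input_dir = input_dir, outdir = outdir, simulate = simulate,
              seed = as.integer(seed), min_identity = min_identity,
              min_coverage = min_coverage,
              novelty_min_identity = novelty_min_identity,
              novelty_min_coverage = novelty_min_coverage,
              alpha = alpha, alpha_dunn = alpha_dunn,
              dunn_adjust = dunn_adjust, q_threshold = q_threshold,
              sim = sim)
  for (nm in c("alpha", "alpha_dunn", "q_threshold")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) {
      abort(sprintf("%s must lie in (0, 1]; got %g", nm, cfg[[nm]]))
    }
  }
  if (cfg$min_coverage <= 0 || cfg$min_coverage > 1) {
    abort("min_coverage must lie in (0, 1]")
  }
  if (!cfg$dunn_adjust %in% c("bh", "none")) {
    abort("dunn_adjust must be 'bh' or 'none'")
  }
  if (!cfg$simulate && is.null(cfg$input_dir)) {
    abort("input_dir required unless simulate = TRUE")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()] (plus an optional `sim:` block of [sim_config()]
#'   arguments).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the full stage-wise virome pipeline
#'
#' Executes every stage in dependency order — input (or simulation), TPM and
#' breadth, diversity, trajectory classification, per-category enrichment,
#' vAMG curation, lifestyle contrasts — writing each stage's tables under
#' `outdir` plus a JSON run manifest (seed, parameters, per-stage record
#' counts) that makes the run reproducible. A failing stage halts the run
#' with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("sim", "input_dir", "outdir"))],
                   stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  inputs <- stage("input", {
    if (config$simulate) {
      sim <- if (is.null(config$sim)) sim_config(seed = config$seed) else config$sim
      study <- simulate_study(sim)
      ann <- simulate_annotations(sim, study$catalog, study$truth)
      list(design = study$design, catalog = study$catalog,
           counts = study$counts, intervals = study$intervals,
           annotations = ann$annotations,
           vamg = simulate_vamg_table(sim, study$catalog),
           lifestyle = simulate_lifestyle(sim, study$catalog),
           truth = study$truth)
    } else {
      read_study_inputs(config$input_dir)
    }
  })
  manifest$stages$input$n_votus <- nrow(inputs$catalog)
  manifest$stages$input$n_samples <- nrow(inputs$design)

  breadth <- stage("breadth", {
    compute_breadth(inputs$intervals, inputs$catalog,
                    samples = inputs$design$sample_id)
  })
  tpm <- stage("abundance", {
    compute_tpm(inputs$counts, inputs$catalog,
                samples = inputs$design$sample_id)
  })
  div <- stage("diversity", {
    alpha <- alpha_diversity_table(tpm)
    ord <- pcoa(bray_curtis(tpm), k = 2)
    list(alpha = alpha, ordination = ord)
  })
  calls <- stage("trajectory", {
    classify_trajectory(breadth, inputs$design, alpha = config$alpha,
                        alpha_dunn = config$alpha_dunn,
                        dunn_adjust = config$dunn_adjust)
  })
  enr <- stage("enrichment", {
    if (is.null(inputs$annotations)) empty_enrichment()
    else enrich_terms(inputs$annotations, calls)
  })
  vamg <- stage("vamg", {
    if (is.null(inputs$vamg)) {
      list(filtered = filter_vamgs(tibble::tibble(
        gene_id = character(), votu_id = character(),
        auxiliary_score = integer(), flags = character())),
        profile = NULL)
    } else {
      filtered <- filter_vamgs(inputs$vamg)
      profile <- vamg_abundance_profile(filtered, tpm, inputs$design)
      list(filtered = filtered, profile = profile)
    }
  })
  life <- stage("lifestyle", {
    if (is.null(inputs$lifestyle)) list(screened = NULL, compare = NULL)
    else {
      screened <- screen_lifestyle(inputs$lifestyle)
      list(screened = screened,
           compare = lifestyle_abundance_compare(screened, tpm, inputs$design))
    }
  })

  out <- config$outdir
  write_result_table(breadth, file.path(out, "breadth.tsv"))
  write_result_table(tpm, file.path(out, "abundance.tsv"))
  write_result_table(div$alpha, file.path(out, "alpha.tsv"))
  coords <- tibble::as_tibble(div$ordination$coordinates, rownames = "sample_id")
  write_result_table(coords, file.path(out, "pcoa.tsv"))
  write_result_table(calls, file.path(out, "trajectory.tsv"))
  write_result_table(summarize_categories(calls),
                     file.path(out, "category_counts.tsv"))
  write_result_table(enr[enr$q < config$q_threshold, ],
                     file.path(out, "enrichment_significant.tsv"))
  write_result_table(enr, file.path(out, "enrichment.tsv"))
  write_result_table(vamg$filtered, file.path(out, "vamg_verdicts.tsv"))
  if (!is.null(vamg$profile)) {
    write_result_table(vamg$profile$gene, file.path(out, "vamg_gene_stage.tsv"))
    write_result_table(vamg$profile$pathway,
                       file.path(out, "vamg_pathway_stage.tsv"))
  }
  if (!is.null(life$compare)) {
    write_result_table(life$compare$sums, file.path(out, "lifestyle_sums.tsv"))
    write_result_table(life$compare$stage_tests,
                       file.path(out, "lifestyle_stage_tests.tsv"))
    write_result_table(life$compare$across_stage_tests,
                       file.path(out, "lifestyle_kw.tsv"))
  }

  manifest$stages$trajectory$categories <-
    as.list(stats::setNames(summarize_categories(calls)$n, letters[1:6]))
  manifest$stages$vamg$n_retained <- sum(vamg$filtered$retained)
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(inputs = inputs, breadth = breadth, tpm = tpm,
                 diversity = div, trajectory = calls, enrichment = enr,
                 vamg = vamg, lifestyle = life, manifest = manifest))
}

# Read the TSV inputs of a study directory (the layout written by
# write_simulated_study, minus optional files).
read_study_inputs <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(sprintf("missing input file '%s'", p))
    p
  }
  catalog <- read_result_table(need("catalog.tsv"))
  if (is.character(catalog$members)) {
    catalog$members <- strsplit(catalog$members, ",", fixed = TRUE)
  }
  opt <- function(f, default) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_result_table(p) else default
  }
  list(design = read_design(need("design.tsv")),
       catalog = validate_catalog(catalog),
       counts = read_counts(need("counts.tsv")),
       intervals = read_intervals(need("intervals.tsv")),
       annotations = opt("annotations.tsv", NULL),
       vamg = opt("vamg.tsv", NULL),
       lifestyle = opt("lifestyle.tsv", NULL),
       truth = opt("truth.tsv", NULL))
}
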