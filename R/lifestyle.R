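#' Screen phage lifestyle prediction tables
#'
#' Post-processes per-vOTU lifestyle calls from two predictors (P1, broad
#' phage set; P2, complete genomes only): rows called `unclassified`, rows
#' labelled `low` quality, and rows not annotated as phage are removed.
#' Screening is idempotent and the two predictor streams are never merged.
#'
#' @param table Lifestyle tibble with columns `votu_id`, `predictor`
#'   (P1/P2), `call` (`temperate`/`virulent`/`unclassified`), `quality`
#'   (`complete`/`high`/`medium`/`low`), `is_phage` (logical, default TRUE).
#' @return The screened tibble; a warning if it is empty.
#' @export
screen_lifestyle <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("votu_id", "predictor", "call", "quality")
  if (!all(need %in% names(table))) {
    abort(paste0("lifestyle table must have columns ", paste(need, collapse = ", ")))
  }
  if (!"is_phage" %in% names(table)) table$is_phage <- TRUE
  keep <- table$call != "unclassified" & table$quality != "low" & table$is_phage
  out <- table[keep, ]
  if (nrow(out) == 0) warn("lifestyle table empty after screening")
  out
}

#' Temperate-versus-lytic abundance contrasts
#'
#' For each predictor separately: per sample, the TPM of called vOTUs is
#' summed within each lifestyle class (mass conservation: the two class sums
#' add up to the total TPM of that predictor's called vOTUs). Per-sample
#' class sums are log10-transformed; within each stage a two-sided Welch
#' t-test compares the temperate and virulent log-sums, and across stages a
#' Kruskal-Wallis test compares the per-sample lytic (virulent) sums.
#' Samples whose class sum is zero are excluded from that t-test
#' (log undefined); a stage with no temperate mass in any sample reports its
#' sums but skips the t-test with a reason.
#'
#' @param screened Screened lifestyle table from [screen_lifestyle()].
#' @param abundance TPM tibble `votu_id`, `sample_id`, `tpm`.
#' @param design Stage design.
#' @param pooled Use the pooled-variance t-test instead of Welch
#'   (default FALSE).
#' @return List with `sums` (tibble `predictor`, `sample_id`, `stage`,
#'   `temperate_sum`, `lytic_sum`, `log10_temperate`, `log10_lytic`),
#'   `stage_tests` (tibble `predictor`, `stage`, `t_p`, `skipped_reason`) and
#'   `across_stage_tests` (tibble `predictor`, `kw_H`, `kw_p` on lytic sums).
#' @export
lifestyle_abundance_compare <- function(screened, abundance, design,
                                        pooled = FALSE) {
  design <- validate_design(design)
  missing_v <- setdiff(unique(screened$votu_id), unique(abundance$votu_id))
  if (length(missing_v) > 0) {
    abort(paste0("screened vOTU absent from abundance: ",
                 paste(utils::head(missing_v, 5), collapse = ", ")))
  }
  sums_rows <- list(); stage_rows <- list(); kw_rows <- list()
  for (pred in sort(unique(screened$predictor))) {
    sub <- screened[screened$predictor == pred, ]
    ab <- abundance[abundance$votu_id %in% sub$votu_id, ]
    ab$call <- sub$call[match(ab$votu_id, sub$votu_id)]
    per_sample <- ab %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::summarize(
        temperate_sum = sum(.data$tpm[.data$call == "temperate"]),
        lytic_sum = sum(.data$tpm[.data$call == "virulent"]),
        .groups = "drop")
    per_sample <- dplyr::left_join(design, per_sample, by = "sample_id")
    per_sample$temperate_sum[is.na(per_sample$temperate_sum)] <- 0
    per_sample$lytic_sum[is.na(per_sample$lytic_sum)] <- 0
    per_sample$log10_temperate <- ifelse(per_sample$temperate_sum > 0,
                                         log10(per_sample$temperate_sum), NA_real_)
    per_sample$log10_lytic <- ifelse(per_sample$lytic_sum > 0,
                                     log10(per_sample$lytic_sum), NA_real_)
    sums_rows[[pred]] <- dplyr::bind_cols(tibble::tibble(predictor = pred),
                                          per_sample)
    for (st in STAGES) {
      ss <- per_sample[per_sample$stage == st, ]
      x <- ss$log10_temperate[!is.na(ss$log10_temperate)]
      y <- ss$log10_lytic[!is.na(ss$log10_lytic)]
      if (length(x) < 2 || length(y) < 2) {
        stage_rows[[paste(pred, st)]] <- tibble::tibble(
          predictor = pred, stage = st, t_p = NA_real_,
          skipped_reason = "fewer than 2 samples with positive mass in a class")
        next
      }
      tt <- stats::t.test(x, y, var.equal = pooled)
      stage_rows[[paste(pred, st)]] <- tibble::tibble(
        predictor = pred, stage = st, t_p = unname(tt$p.value),
        skipped_reason = NA_character_)
    }
    kw <- kruskal_wallis(per_sample$lytic_sum, per_sample$stage)
    kw_rows[[pred]] <- tibble::tibble(predictor = pred, kw_H = kw$H, kw_p = kw$p)
  }
  list(sums = dplyr::bind_rows(sums_rows),
       stage_tests = dplyr::bind_rows(stage_rows),
       across_stage_tests = dplyr::bind_rows(kw_rows))
}
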