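#' Default pathway blacklist for vAMG curation
#'
#' Metabolic pathways expected in viruses regardless of auxiliary function,
#' removed manually from candidate vAMG lists: nucleotide metabolism,
#' glycosyl transferases and ribosomal proteins. Matching is case-insensitive
#' substring, and the list is editable/extensible by the caller.
#'
#' @return Character vector of blacklist entries.
#' @export
default_pathway_blacklist <- function() {
  c("nucleotide metabolism", "glycosyl transferase", "ribosomal protein")
}

#' Filter candidate viral auxiliary metabolic genes
#'
#' A candidate gene is retained as a putative vAMG iff all of:
#' auxiliary score < 4; metabolism flag `M` present; none of the attachment
#' (`A`), viral (`V`) or transposon (`T`) flags present; gene id and gene
#' description present; a KEGG annotation present; its pathway not matching
#' the blacklist; and its carrier vOTU not flagged as host-contaminated.
#' Every record receives a verdict and, if rejected, the first failing rule
#' (rules checked in the order above). The filter is deterministic,
#' order-independent and idempotent.
#'
#' @param records Tibble with columns `gene_id`, `votu_id`, `auxiliary_score`
#'   (integer >= 1), `flags` (string over the alphabet M/A/V/T, e.g. "MF" --
#'   characters outside the alphabet are ignored), `kegg_id`,
#'   `gene_description`, `pathway` (optional strings; `NA`/"" = absent) and
#'   optionally `host_contaminated` (logical, default FALSE).
#' @param pathway_blacklist Character vector, case-insensitive substring
#'   match against `pathway`; default [default_pathway_blacklist()].
#' @return The records tibble with added columns `retained` (logical) and
#'   `reason` ("retained" or the first failing rule).
#' @export
filter_vamgs <- function(records, pathway_blacklist = default_pathway_blacklist()) {
  records <- tibble::as_tibble(records)
  need <- c("gene_id", "votu_id", "auxiliary_score", "flags")
  if (!all(need %in% names(records))) {
    abort(paste0("vAMG records must have columns ", paste(need, collapse = ", ")))
  }
  for (col in c("kegg_id", "gene_description", "pathway")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  if (!"host_contaminated" %in% names(records)) records$host_contaminated <- FALSE
  records$host_contaminated[is.na(records$host_contaminated)] <- FALSE

  absent <- function(x) is.na(x) | trimws(as.character(x)) == ""
  has_flag <- function(flags, f) {
    flags <- toupper(ifelse(is.na(flags), "", flags))
    grepl(f, flags, fixed = TRUE)
  }
  blacklisted <- function(pathway) {
    pw <- tolower(ifelse(is.na(pathway), "", pathway))
    hit <- rep(FALSE, length(pw))
    for (b in pathway_blacklist) hit <- hit | grepl(tolower(b), pw, fixed = TRUE)
    hit
  }

  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(reason, cond, label) ifelse(is.na(reason) & cond, label, reason)
  score <- suppressWarnings(as.numeric(records$auxiliary_score))
  reason <- mark(reason, is.na(score), "malformed")
  reason <- mark(reason, records$host_contaminated, "host_contaminated")
  reason <- mark(reason, !is.na(score) & score >= 4, "auxiliary_score")
  reason <- mark(reason, !has_flag(records$flags, "M"), "no_metabolism_flag")
  reason <- mark(reason, has_flag(records$flags, "A"), "attachment_flag")
  reason <- mark(reason, has_flag(records$flags, "V"), "viral_flag")
  reason <- mark(reason, has_flag(records$flags, "T"), "transposon_flag")
  reason <- mark(reason, absent(records$gene_id), "no_gene_id")
  reason <- mark(reason, absent(records$gene_description), "no_gene_description")
  reason <- mark(reason, absent(records$kegg_id), "no_kegg_annotation")
  reason <- mark(reason, blacklisted(records$pathway), "pathway_blacklist")

  records$retained <- is.na(reason)
  records$reason <- ifelse(records$retained, "retained", reason)
  records
}

#' Per-stage abundance profile of retained vAMGs
#'
#' Each retained gene inherits the TPM of its carrier vOTU; per-sample TPM is
#' summed within each stage, so a gene's stage value is the cumulative TPM of
#' its vOTU over that stage's samples. Heatmap-style values apply log10 to
#' the sums, with zero mass rendered as `NA` (a sentinel; an optional
#' pseudocount is added before the log when `pseudocount > 0`). The pathway
#' matrix aggregates its genes' stage sums before the log; genes annotated to
#' several pathways contribute to each of their pathway rows.
#'
#' @param retained Output of [filter_vamgs()] restricted to retained rows (a
#'   table containing non-retained rows is filtered automatically).
#' @param abundance TPM tibble `votu_id`, `sample_id`, `tpm`.
#' @param design Stage design.
#' @param pseudocount Added to stage sums before log10 (default 0 = off).
#' @return List of two tibbles, `gene` (`gene_id`, `votu_id`, `stage`, `tpm_sum`,
#'   `log10_tpm_sum`) and `pathway` (`pathway`, `stage`, `tpm_sum`,
#'   `log10_tpm_sum`).
#' @export
vamg_abundance_profile <- function(retained, abundance, design, pseudocount = 0) {
  design <- validate_design(design)
  if ("retained" %in% names(retained)) retained <- retained[retained$retained, ]
  unknown <- setdiff(unique(retained$votu_id), unique(abundance$votu_id))
  if (length(unknown) > 0) {
    abort(paste0("retained vAMG on vOTU absent from abundance: ",
                 paste(unknown, collapse = ", ")))
  }
  ab <- dplyr::inner_join(abundance, design, by = "sample_id")
  votu_stage <- ab %>%
    dplyr::group_by(.data$votu_id, .data$stage) %>%
    dplyr::summarize(tpm_sum = sum(.data$tpm), .groups = "drop")

  logf <- function(s) {
    v <- s + pseudocount
    ifelse(v > 0, log10(v), NA_real_)
  }
  gene <- dplyr::inner_join(
    retained[, c("gene_id", "votu_id", "pathway")], votu_stage,
    by = "votu_id", relationship = "many-to-many")
  gene_tab <- gene[, c("gene_id", "votu_id", "stage", "tpm_sum")]
  gene_tab$log10_tpm_sum <- logf(gene_tab$tpm_sum)

  path_tab <- gene %>%
    dplyr::filter(!is.na(.data$pathway), trimws(.data$pathway) != "") %>%
    dplyr::group_by(pathway = .data$pathway, stage = .data$stage) %>%
    dplyr::summarize(tpm_sum = sum(.data$tpm_sum), .groups = "drop")
  path_tab$log10_tpm_sum <- logf(path_tab$tpm_sum)

  list(gene = tibble::as_tibble(gene_tab), pathway = tibble::as_tibble(path_tab))
}
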