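# Small in-code fixtures shared across test files.

tiny_design <- function(n_per = 5) {
  tibble::tibble(
    sample_id = sprintf("%s%02d", rep(c("L", "N", "F"), each = n_per),
                        rep(seq_len(n_per), 3)),
    stage = rep(c("L", "N", "F"), each = n_per))
}

tiny_catalog <- function(lengths = c(2000L, 2500L, 3000L)) {
  n <- length(lengths)
  tibble::tibble(
    votu_id = sprintf("vOTU_%05d", seq_len(n)),
    representative_contig = sprintf("ctg_%d", seq_len(n)),
    length_bp = lengths,
    members = as.list(sprintf("ctg_%d", seq_len(n))),
    novelty = "unassessed")
}

write_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# A vAMG fixture covering every retention rule and the pathway blacklist.
vamg_rule_fixture <- function() {
  base <- tibble::tibble(
    gene_id = "g", votu_id = "v", auxiliary_score = 3L, flags = "M",
    kegg_id = "K00001", gene_description = "desc",
    pathway = "folate biosynthesis", host_contaminated = FALSE)
  rows <- list(
    pass_score1     = transform(base, auxiliary_score = 1L),
    pass_score3     = base,
    fail_score4     = transform(base, auxiliary_score = 4L),
    fail_score5     = transform(base, auxiliary_score = 5L),
    fail_no_M       = transform(base, flags = ""),
    fail_A          = transform(base, flags = "MA"),
    fail_V          = transform(base, flags = "MV"),
    fail_T          = transform(base, flags = "MT"),
    fail_AVT        = transform(base, flags = "MAVT"),
    fail_no_geneid  = transform(base, gene_id = NA_character_),
    fail_no_desc    = transform(base, gene_description = NA_character_),
    fail_empty_desc = transform(base, gene_description = "  "),
    fail_no_kegg    = transform(base, kegg_id = NA_character_),
    fail_nucleotide = transform(base, pathway = "Nucleotide metabolism"),
    fail_glycosyl   = transform(base, pathway = "Glycosyl transferases"),
    fail_ribosomal  = transform(base, pathway = "ribosomal proteins, large subunit"),
    fail_contam     = transform(base, host_contaminated = TRUE),
    pass_other_path = transform(base, pathway = "cofactor biosynthesis"))
  tab <- dplyr::bind_rows(rows)
  tab$case <- names(rows)
  tab$expect_retained <- startsWith(names(rows), "pass")
  tab
}
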