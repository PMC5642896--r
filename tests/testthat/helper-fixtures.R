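# Small builders shared across the suite. Fixtures are always generated in
# code; nothing is read from disk except explicit I/O round-trip tests.

# a geno_matrix from a plain dosage matrix, with generic variant metadata
make_geno <- function(calls, ids = NULL) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  }
  ids <- ids %||% sprintf("snp%03d", seq_len(ncol(calls)))
  variants <- tibble::tibble(
    id = ids, chrom = "1", pos = seq_len(ncol(calls)) * 100L,
    counted_allele = "A", other_allele = "G", gene = NA_character_
  )
  geno_matrix(calls, variants)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# geno_matrix holding the 4 NAT2 panel SNPs (+ optionally the tag SNP),
# with the panel's counted-allele orientation
make_panel_geno <- function(dosages, tag = NULL) {
  vt <- nat2_variant_table()
  ids <- colnames(dosages)
  if (!is.null(tag)) {
    dosages <- cbind(dosages, rs1495741 = tag)
    ids <- colnames(dosages)
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  }
  geno_matrix(dosages, vt[match(ids, vt$id), ])
}

# one sample sheet row per entry of each count, for contingency rebuilds
sheet_from_counts <- function(...) {
  groups <- list(...)
  purrr::imap_dfr(groups, function(g, nm) {
    tibble::tibble(
      status = g$status, sex = g$sex %||% "M",
      ethnicity = g$ethnicity %||% "Chinese",
      n = g$n
    ) %>% tidyr::uncount(n)
  }) %>%
    dplyr::mutate(sample_id = sprintf("S%03d", dplyr::row_number()),
                  grade = ifelse(status == "case", 2L, 0L),
                  age = 50)
}

# quick small simulation config for module tests
quick_config <- function(...) {
  sim_config(n_background_snps = 0, missing_rate = 0, ...)
}
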