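#' Genotype matrix container
#'
#' A light container for biallelic genotype calls: an integer matrix of
#' counted-allele dosages (samples in rows, variants in columns, values in
#' \{0, 1, 2\} with `NA` for missing calls) plus a variant annotation table.
#' Dosage counts the *counted allele* declared per variant (for NAT2 panel
#' SNPs this is the acetylation-slowing allele; for the tag SNP rs1495741 it
#' is the G allele, so dosage 0 is the AA risk genotype).
#'
#' @param calls Integer matrix, samples x variants, entries 0/1/2/NA, with
#'   rownames (sample ids) and colnames matching `variants$id`.
#' @param variants A data frame with columns `id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele` and optionally `gene`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants) {
  variants <- as_tibble(variants)
  stopifnot(is.matrix(calls))
  if (!all(c("id", "chrom", "pos", "counted_allele", "other_allele") %in%
           names(variants))) {
    abort("`variants` needs columns id, chrom, pos, counted_allele, other_allele.")
  }
  if (anyDuplicated(variants$id)) abort("Variant ids must be unique.")
  if (!all(variants$counted_allele %in% c("A", "C", "G", "T"))) {
    abort("Counted alleles must be single bases A/C/G/T.")
  }
  if (ncol(calls) != nrow(variants)) {
    abort("Number of call columns must equal number of variants.")
  }
  if (is.null(rownames(calls))) abort("`calls` must have sample-id rownames.")
  colnames(calls) <- variants$id
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) abort("Dosages must be 0, 1, 2 or NA.")
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants; %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Sample ids or indices to keep.
#' @param j Variant ids or indices to keep.
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the requested samples/variants.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(j)) abort("Unknown variant id in subset.")
  geno_matrix(x$calls[i, j, drop = FALSE], x$variants[j, , drop = FALSE])
}

#' Tidy a genotype matrix into long format
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per sample x variant call
#'   (`sample_id`, `id`, `dosage`).
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$calls), times = ncol(x$calls)),
    id = rep(colnames(x$calls), each = nrow(x$calls)),
    dosage = as.integer(x$calls)
  )
}

#' Extract dosages for one variant
#'
#' @param x A [geno_matrix()].
#' @param id Variant id (e.g. `"rs1041983"`).
#' @return Named integer vector of dosages (NA = missing).
#' @export
dosage_of <- function(x, id) {
  stopifnot(inherits(x, "geno_matrix"))
  if (!id %in% x$variants$id) abort(sprintf("Variant %s not in matrix.", id))
  x$calls[, id]
}

#' Write genotype calls to a VCF file
#'
#' Writes a minimal VCFv4.2 text file with GT genotypes (unphased; missing
#' calls as `./.`). REF is the variant's other allele and ALT the counted
#' allele, so ALT dosage equals the stored dosage.
#'
#' @param x A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n_var <- ncol(x$calls)
  body <- vapply(seq_len(n_var), function(j) {
    v <- x$variants[j, ]
    gt <- gt_codes[as.character(x$calls[, j])]
    gt[is.na(gt)] <- "./."
    paste(c(v$chrom, v$pos, v$id, v$other_allele, v$counted_allele,
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nat2pgx",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(x$calls)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype calls from a VCF file
#'
#' Reads GT genotypes with [vcfR::read.vcfR()] and converts them to
#' counted-allele dosage. By default the ALT allele is counted; a panel
#' table with `id` and `counted_allele` columns can re-orient specific
#' variants, and a mismatch between the panel allele and the VCF REF/ALT
#' pair is an error.
#'
#' @param path VCF file path.
#' @param panel Optional data frame (`id`, `counted_allele`) fixing the
#'   counted-allele orientation of listed variants.
#' @return A [geno_matrix()].
#' @export
read_genotype_vcf <- function(path, panel = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), fix$ID))
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), integer(1)))
  }
  for (j in seq_len(nrow(gt))) dos[, j] <- alt_count(gt[j, ])
  variants <- tibble(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    counted_allele = fix$ALT, other_allele = fix$REF
  )
  if (!is.null(panel)) {
    panel <- as_tibble(panel)
    for (k in seq_len(nrow(panel))) {
      i <- match(panel$id[k], variants$id)
      if (is.na(i)) next
      want <- panel$counted_allele[k]
      if (want == variants$counted_allele[i]) next
      if (want == variants$other_allele[i]) {
        dos[, i] <- 2L - dos[, i]
        tmp <- variants$counted_allele[i]
        variants$counted_allele[i] <- variants$other_allele[i]
        variants$other_allele[i] <- tmp
      } else {
        abort(sprintf(
          "Panel counted allele %s for %s matches neither REF nor ALT.",
          want, panel$id[k]))
      }
    }
  }
  geno_matrix(dos, variants)
}

#' Write a sample sheet TSV
#'
#' @param samples Sample tibble with columns `sample_id`, `sex`,
#'   `ethnicity`, `status`, `grade`, `age`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  cols <- c("sample_id", "sex", "ethnicity", "status", "grade", "age")
  stopifnot(all(cols %in% names(samples)))
  write.table(samples[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' @param path Path to a tab-separated sample sheet written by
#'   [write_sample_sheet()].
#' @return A tibble of sample records.
#' @export
read_sample_sheet <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
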