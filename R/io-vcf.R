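#' Read a VCF file into a genotype matrix
#'
#' Parses diploid GT fields from a VCF (plain or gzipped, via \pkg{vcfR}),
#' keeping only biallelic SNP records. Multiallelic and non-SNP (indel,
#' symbolic) records are skipped and counted in a message. Genotypes are coded
#' as the count of the ALT allele; `./.` (or `.`) becomes `NA`.
#'
#' @param path Path to a VCF file.
#' @param pop Population label to attach to every sample (VCF carries none).
#' @param cohort Optional cohort label for every sample.
#' @param verbose Emit a message with the skipped-record count.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, pop = "pop1", cohort = NA_character_, verbose = TRUE) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records")

  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0 && verbose) {
    inform(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)", n_skip))
  }
  if (!any(is_snp)) abort("VCF contains no biallelic SNP records")

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  # "0/0"->0, "0/1","1/0","0|1"->1, "1/1"->2, anything with "." -> NA
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  G <- t(apply(gt, 2, code))  # rows = samples after transpose
  G <- matrix(as.integer(G), nrow = ncol(gt), ncol = nrow(gt))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  loci <- tibble(locus = ids, chrom = fix$CHROM, pos = as.integer(fix$POS))
  individuals <- tibble(id = colnames(gt), pop = pop, cohort = cohort)
  geno_matrix(G, loci = loci, individuals = individuals)
}

#' Write a genotype matrix to a plain-text VCF
#'
#' Minimal VCF 4.2 writer: one biallelic SNP record per locus with GT-only
#' genotype columns (`0/0`, `0/1`, `1/1`, `./.`). REF/ALT are written as A/T
#' placeholders (allele identity is not tracked by [geno_matrix()]; r2-based
#' estimation is invariant to it).
#'
#' @param x A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldne",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$individuals$id), collapse = "\t")
  )
  gt_str <- matrix("./.", nrow(x$G), ncol(x$G))
  gt_str[!is.na(x$G) & x$G == 0L] <- "0/0"
  gt_str[!is.na(x$G) & x$G == 1L] <- "0/1"
  gt_str[!is.na(x$G) & x$G == 2L] <- "1/1"
  rows <- vapply(seq_len(ncol(x$G)), function(j) {
    paste(c(x$loci$chrom[j], x$loci$pos[j], x$loci$locus[j], "A", "T", ".",
            "PASS", ".", "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read/write a TSV genotype table
#'
#' Individuals x loci table of alternate-allele counts with `NA` for missing;
#' first column `id`, remaining columns named by locus.
#'
#' @param x A [geno_matrix()].
#' @param path File path.
#' @return `read_geno_tsv()` returns a [geno_matrix()]; `write_geno_tsv()`
#'   returns `path` invisibly.
#' @export
write_geno_tsv <- function(x, path) {
  df <- as.data.frame(x$G)
  df <- cbind(id = x$individuals$id, df)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_geno_tsv
#' @param pop,cohort Labels attached to all individuals on read.
#' @export
read_geno_tsv <- function(path, pop = "pop1", cohort = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  geno_matrix(G,
              loci = tibble(locus = colnames(df)[-1]),
              individuals = tibble(id = as.character(df$id), pop = pop, cohort = cohort))
}
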