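#' SNP genotype matrix with locus and individual metadata
#'
#' `geno_matrix()` bundles a diploid, biallelic SNP genotype matrix
#' (individuals in rows, loci in columns, entries coded as the count of the
#' alternate allele: 0, 1, 2, or `NA` for missing) with per-locus and
#' per-individual metadata. It is the common currency of the package: readers
#' produce it, filters and the LD estimator consume it, simulators emit it.
#'
#' @param genotypes Integer (or numeric) matrix of alternate-allele counts,
#'   individuals x loci. Values must be 0, 1, 2 or `NA`.
#' @param loci Data frame with one row per locus: columns `locus` (unique id),
#'   `chrom` (chromosome label, opaque string), `pos` (1-based position).
#'   Missing columns are filled with defaults.
#' @param individuals Data frame with one row per individual: columns `id`
#'   (unique), `pop` (population label), `cohort` (e.g. `"YOY-2016"` or
#'   `"mixed-adult"`), optional `age` in years. Missing columns are filled.
#'
#' @return An object of class `geno_matrix`: a list with elements `G`
#'   (the genotype matrix, dimnames set from the metadata), `loci` and
#'   `individuals` (tibbles).
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                  loci = data.frame(locus = c("L1", "L2")),
#'                  individuals = data.frame(id = c("i1", "i2")))
#' g
geno_matrix <- function(genotypes, loci = NULL, individuals = NULL) {
  G <- as.matrix(genotypes)
  storage.mode(G) <- "integer"
  bad <- !(G %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    abort("genotypes must be 0, 1, 2 or NA (count of the alternate allele)")
  }
  n <- nrow(G); L <- ncol(G)

  if (is.null(loci)) loci <- tibble(locus = default_ids("locus", L))
  loci <- as_tibble(loci)
  if (nrow(loci) != L) abort("locus metadata length does not match matrix columns")
  if (!"locus" %in% names(loci)) loci$locus <- default_ids("locus", L)
  if (!"chrom" %in% names(loci)) loci$chrom <- "chr1"
  if (!"pos" %in% names(loci)) loci$pos <- seq_len(L)
  loci$locus <- as.character(loci$locus)
  loci$chrom <- as.character(loci$chrom)

  if (is.null(individuals)) individuals <- tibble(id = default_ids("ind", n))
  individuals <- as_tibble(individuals)
  if (nrow(individuals) != n) abort("individual metadata length does not match matrix rows")
  if (!"id" %in% names(individuals)) individuals$id <- default_ids("ind", n)
  if (!"pop" %in% names(individuals)) individuals$pop <- "pop1"
  if (!"cohort" %in% names(individuals)) individuals$cohort <- NA_character_
  if (!"age" %in% names(individuals)) individuals$age <- NA_real_
  individuals$id <- as.character(individuals$id)

  if (anyDuplicated(loci$locus)) abort("duplicated locus identifiers")
  if (anyDuplicated(individuals$id)) abort("duplicated individual identifiers")

  dimnames(G) <- list(individuals$id, loci$locus)
  structure(list(G = G, loci = loci, individuals = individuals),
            class = "geno_matrix")
}

default_ids <- function(prefix, k) {
  if (k == 0) return(character(0))
  sprintf("%s_%0*d", prefix, nchar(as.character(k)), seq_len(k))
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$G))
  cat(sprintf("<geno_matrix> %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$G), ncol(x$G), 100 * miss))
  pops <- table(x$individuals$pop)
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$G)

#' Number of individuals / loci in a genotype matrix
#' @param x A [geno_matrix()].
#' @return An integer count.
#' @export
n_indiv <- function(x) nrow(x$G)

#' @rdname n_indiv
#' @export
n_loci <- function(x) ncol(x$G)

#' Subset a genotype matrix
#'
#' Row (individual) and column (locus) subsetting that keeps the metadata
#' tibbles aligned with the genotype matrix.
#'
#' @param x A [geno_matrix()].
#' @param i Individual index (integer/logical vector), or `NULL` for all.
#' @param j Locus index, or `NULL` for all.
#' @return A [geno_matrix()].
#' @export
subset_geno <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$G))
  if (is.null(j)) j <- seq_len(ncol(x$G))
  geno_matrix(x$G[i, j, drop = FALSE],
              loci = x$loci[j, , drop = FALSE],
              individuals = x$individuals[i, , drop = FALSE])
}

#' Genotypes as a long tibble
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `id`, `locus`, `genotype` (one row per cell).
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(id = rep(x$individuals$id, times = ncol(x$G)),
         locus = rep(x$loci$locus, each = nrow(x$G)),
         genotype = as.integer(x$G))
}

#' Per-locus allele frequencies and counts
#'
#' @param x A [geno_matrix()].
#' @return A tibble with per-locus `locus`, `chrom`, `n` (non-missing
#'   individuals), `p_alt` (alternate-allele frequency), `maf` (minor-allele
#'   frequency) and `mac` (minor-allele count in copies).
#' @export
locus_stats <- function(x) {
  G <- x$G
  n <- unname(colSums(!is.na(G)))
  alt <- unname(colSums(G, na.rm = TRUE))
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  mac <- pmin(alt, 2 * n - alt)
  tibble(locus = x$loci$locus, chrom = x$loci$chrom, n = n,
         p_alt = p, maf = pmin(p, 1 - p), mac = mac)
}
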