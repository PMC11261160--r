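#' Remove individuals with excess missing genotypes
#'
#' Drops every individual whose fraction of missing genotype calls (over the
#' loci currently in the matrix) is strictly greater than `max_missing`.
#' The default threshold of 0.20 is the conventional ">20% missing" cutoff
#' used in SNP quality control of RAD datasets.
#'
#' @param x A [geno_matrix()].
#' @param max_missing Maximum tolerated missingness fraction in `[0, 1]`.
#' @return The filtered [geno_matrix()], with a [filter_report()] attached as
#'   attribute `"filter_report"`.
#' @export
filter_individuals <- function(x, max_missing = 0.20) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- unname(rowMeans(is.na(x$G)))
  drop <- miss > max_missing
  if (all(drop)) abort("all individuals exceed the missingness threshold")
  out <- subset_geno(x, i = which(!drop))
  rep <- tibble(
    step = "individual_missingness",
    unit = "individual",
    id = x$individuals$id[drop],
    value = miss[drop],
    reason = sprintf("missingness %.3f > %.2f", miss[drop], max_missing)
  )
  attr(out, "filter_report") <- bind_filter_report(
    attr(x, "filter_report"), rep,
    before = c(n_indiv(x), n_loci(x)), after = c(n_indiv(out), n_loci(out)))
  out
}

#' Locus quality-control filters
#'
#' Configurable per-locus screens: minimum call rate (fraction of individuals
#' with a non-missing genotype), minimum minor-allele count (in allele
#' copies), and a biallelic/variant requirement. Each removal is logged in
#' the attached filter report. These defaults are deliberately mild; the
#' function exists so a pipeline can state and log its locus QC explicitly.
#'
#' @param x A [geno_matrix()].
#' @param min_call_rate Minimum per-locus call rate (default 0.8).
#' @param min_mac Minimum minor-allele count in copies (default 1, i.e. the
#'   locus must be variant in the sample).
#' @return The filtered [geno_matrix()] with `"filter_report"` attribute.
#' @export
filter_loci <- function(x, min_call_rate = 0.8, min_mac = 1) {
  st <- locus_stats(x)
  call_rate <- st$n / n_indiv(x)
  drop_cr <- call_rate < min_call_rate
  drop_mac <- !drop_cr & st$mac < min_mac
  drop <- drop_cr | drop_mac
  if (all(drop)) abort("all loci removed by locus filters")
  out <- subset_geno(x, j = which(!drop))
  rep <- tibble(
    step = "locus_qc",
    unit = "locus",
    id = st$locus[drop],
    value = ifelse(drop_cr[drop], call_rate[drop], st$mac[drop]),
    reason = ifelse(drop_cr[drop],
                    sprintf("call rate %.3f < %.2f", call_rate[drop], min_call_rate),
                    sprintf("minor-allele count %d < %d", st$mac[drop], min_mac))
  )
  attr(out, "filter_report") <- bind_filter_report(
    attr(x, "filter_report"), rep,
    before = c(n_indiv(x), n_loci(x)), after = c(n_indiv(out), n_loci(out)))
  out
}

#' Drop named loci (e.g. an externally supplied outlier list)
#'
#' Removes the given loci, preserving the order of the remainder. The typical
#' use is excluding loci flagged as under selection by an external outlier
#' scan before effective-size estimation.
#'
#' @param x A [geno_matrix()].
#' @param locus_ids Character vector of locus identifiers to remove; every id
#'   must be present in `x`.
#' @param reason Reason string recorded in the filter report.
#' @return The filtered [geno_matrix()] with `"filter_report"` attribute.
#' @export
drop_loci <- function(x, locus_ids, reason = "outlier list") {
  locus_ids <- as.character(locus_ids)
  unknown <- setdiff(locus_ids, x$loci$locus)
  if (length(unknown)) {
    abort(paste0("unknown locus id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  if (!length(locus_ids)) return(x)
  keep <- !(x$loci$locus %in% locus_ids)
  out <- subset_geno(x, j = which(keep))
  rep <- tibble(step = "drop_loci", unit = "locus", id = locus_ids,
                value = NA_real_, reason = reason)
  attr(out, "filter_report") <- bind_filter_report(
    attr(x, "filter_report"), rep,
    before = c(n_indiv(x), n_loci(x)), after = c(n_indiv(out), n_loci(out)))
  out
}

#' Retrieve the filter report of a genotype matrix
#'
#' @param x A [geno_matrix()] that has passed through one or more filters.
#' @return A tibble with one row per removed unit (`step`, `unit`, `id`,
#'   `value`, `reason`) and attributes `n_before`/`n_after` giving
#'   (individuals, loci) counts around the most recent step.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||%
    tibble(step = character(), unit = character(), id = character(),
           value = double(), reason = character())
}

bind_filter_report <- function(prev, rep, before, after) {
  out <- if (is.null(prev)) rep else dplyr::bind_rows(prev, rep)
  attr(out, "n_before") <- before
  attr(out, "n_after") <- after
  out
}
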