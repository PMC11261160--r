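#' Per-sample genomic diversity: Ho, He, FIS
#'
#' For each population label: per-locus observed heterozygosity (fraction of
#' heterozygotes among non-missing individuals), Nei's unbiased expected
#' heterozygosity `2*p*q * 2n/(2n-1)` (n = non-missing individuals, so 2n
#' gene copies), and the population inbreeding coefficient
#' `FIS = 1 - Ho/He` per locus, each averaged over loci variant within the
#' sample. A sample with no variant loci gets `NA` FIS with a warning.
#'
#' @param x A [geno_matrix()].
#' @param by Column of `x$individuals` defining the samples (default `"pop"`).
#' @return A tibble with one row per sample: `sample`, `n`, `n_variant_loci`,
#'   `ho`, `he`, `fis`.
#' @export
diversity_summary <- function(x, by = "pop") {
  labs <- x$individuals[[by]]
  purrr::map_dfr(unique(labs), function(lab) {
    G <- x$G[labs == lab, , drop = FALSE]
    if (nrow(G) < 2) abort("each sample needs at least 2 individuals")
    n <- colSums(!is.na(G))
    p <- colSums(G, na.rm = TRUE) / (2 * n)
    variant <- n > 0 & p > 0 & p < 1
    if (!any(variant)) {
      warn(sprintf("sample '%s' has no variant loci; FIS undefined", lab))
      return(tibble(sample = lab, n = nrow(G), n_variant_loci = 0L,
                    ho = 0, he = 0, fis = NA_real_))
    }
    ho <- colMeans(G == 1L, na.rm = TRUE)[variant]
    nv <- n[variant]; pv <- p[variant]
    he <- 2 * pv * (1 - pv) * (2 * nv) / (2 * nv - 1)
    fis <- 1 - ho / he
    tibble(sample = lab, n = nrow(G), n_variant_loci = sum(variant),
           ho = mean(ho), he = mean(he), fis = mean(fis))
  })
}

# Weir-Cockerham variance components for one biallelic locus across r
# populations. n_i = sample sizes (individuals), p_i = alt-allele freqs,
# h_i = observed heterozygote proportions. Returns c(a, b, c).
wc_components <- function(n_i, p_i, h_i) {
  keep <- n_i > 0
  n_i <- n_i[keep]; p_i <- p_i[keep]; h_i <- h_i[keep]
  r <- length(n_i)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  if (n_bar <= 1) return(c(a = 0, b = 0, c = 0))
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# Multi-locus ratio-of-sums Weir-Cockerham FST between two genotype matrices.
wc_fst_two <- function(G1, G2) {
  n1 <- colSums(!is.na(G1)); n2 <- colSums(!is.na(G2))
  p1 <- ifelse(n1 > 0, colSums(G1, na.rm = TRUE) / (2 * n1), 0)
  p2 <- ifelse(n2 > 0, colSums(G2, na.rm = TRUE) / (2 * n2), 0)
  h1 <- ifelse(n1 > 0, colSums(G1 == 1L, na.rm = TRUE) / n1, 0)
  h2 <- ifelse(n2 > 0, colSums(G2 == 1L, na.rm = TRUE) / n2, 0)
  num <- den <- 0
  for (j in seq_along(n1)) {
    comp <- wc_components(c(n1[j], n2[j]), c(p1[j], p2[j]), c(h1[j], h2[j]))
    num <- num + comp[1]
    den <- den + sum(comp)
  }
  if (den == 0) 0 else unname(num / den)
}

#' Pairwise Weir-Cockerham FST with permutation significance
#'
#' Multi-locus (ratio-of-sums) Weir-Cockerham theta for every pair of
#' populations, with significance from permuting individuals between the two
#' populations of each pair: `p = (1 + #{perm >= observed}) / (1 + n_perm)`,
#' then Benjamini-Hochberg adjustment across all pairs.
#'
#' @param x A [geno_matrix()] with >= 2 populations (column `pop`), each with
#'   >= 2 individuals.
#' @param permutations Number of label permutations per pair (default 1000).
#' @param seed Integer seed for the permutation RNG.
#' @return A list of class `fst_result`: `fst` (symmetric matrix, zero
#'   diagonal), `p_value` and `p_adjusted` matrices, `permutations`, and a
#'   tidy `pairs` tibble. [tidy()] returns the tibble.
#' @export
pairwise_fst <- function(x, permutations = 1000, seed = 1L) {
  if (permutations < 1) abort("permutations must be >= 1")
  pops <- unique(x$individuals$pop)
  if (length(pops) < 2) abort("need at least 2 populations")
  counts <- table(x$individuals$pop)
  if (any(counts < 2)) abort("each population needs at least 2 individuals")
  set.seed(seed)

  k <- length(pops)
  fst <- pmat <- matrix(0, k, k, dimnames = list(pops, pops))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    idx1 <- which(x$individuals$pop == pops[i])
    idx2 <- which(x$individuals$pop == pops[j])
    G1 <- x$G[idx1, , drop = FALSE]; G2 <- x$G[idx2, , drop = FALSE]
    obs <- wc_fst_two(G1, G2)
    Gall <- rbind(G1, G2); n1 <- length(idx1); ntot <- nrow(Gall)
    perm <- vapply(seq_len(permutations), function(b) {
      sh <- sample.int(ntot)
      wc_fst_two(Gall[sh[seq_len(n1)], , drop = FALSE],
                 Gall[sh[-seq_len(n1)], , drop = FALSE])
    }, numeric(1))
    p <- (1 + sum(perm >= obs)) / (1 + permutations)
    fst[i, j] <- fst[j, i] <- obs
    pmat[i, j] <- pmat[j, i] <- p
    rows[[length(rows) + 1L]] <- tibble(pop1 = pops[i], pop2 = pops[j],
                                        fst = obs, p_value = p)
  }
  pairs <- dplyr::bind_rows(rows)
  pairs$p_adjusted <- p.adjust(pairs$p_value, method = "BH")
  padj <- pmat
  for (r in seq_len(nrow(pairs))) {
    padj[pairs$pop1[r], pairs$pop2[r]] <- pairs$p_adjusted[r]
    padj[pairs$pop2[r], pairs$pop1[r]] <- pairs$p_adjusted[r]
  }
  structure(list(fst = fst, p_value = pmat, p_adjusted = padj,
                 permutations = permutations, pairs = pairs),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %d population pair(s), %d permutations\n",
              nrow(x$pairs), x$permutations))
  print(x$pairs)
  invisible(x)
}

#' @rdname pairwise_fst
#' @param ... Unused.
#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) x$pairs

#' PCA of genotypes with modal-genotype imputation
#'
#' Missing genotypes are replaced by the most common genotype at that locus
#' (ties broken toward the smaller allele count, deterministically), columns
#' are mean-centred, and principal components are extracted with
#' [stats::prcomp()]. Scores are deterministic up to component sign.
#'
#' @param x A [geno_matrix()].
#' @param components Number of components to return.
#' @return A tibble of class `ldne_pca` with `id`, `pop`, and score columns
#'   `PC1..PCk`; the proportion of variance explained is in attribute
#'   `"var_explained"`.
#' @export
pca_imputed <- function(x, components = 2) {
  stopifnot(components >= 1, components <= min(dim(x$G)))
  G <- x$G
  all_missing <- colSums(!is.na(G)) == 0
  if (any(all_missing)) abort("locus with all genotypes missing")
  modal <- apply(G, 2, function(g) {
    tab <- tabulate(g + 1L, nbins = 3L)  # counts of 0,1,2 among non-missing
    which.max(tab) - 1L                  # which.max takes the first (lowest) on ties
  })
  miss <- which(is.na(G), arr.ind = TRUE)
  if (nrow(miss)) G[miss] <- modal[miss[, 2]]
  pc <- prcomp(G, center = TRUE, scale. = FALSE)
  k <- min(components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out <- dplyr::bind_cols(tibble(id = x$individuals$id, pop = x$individuals$pop), scores)
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  class(out) <- c("ldne_pca", class(out))
  out
}

#' Scatterplot of genotype PCA scores
#'
#' @param object A [pca_imputed()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ldne_pca
#' @export
autoplot.ldne_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  lab <- function(k) {
    pct <- if (length(ve) >= k) sprintf(" (%.1f%%)", 100 * ve[k]) else ""
    paste0("PC", k, pct)
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$pop)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = "population") +
    ggplot2::theme_minimal()
}
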