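# Brute-force composite-r2 oracle: builds the 3x3 joint genotype count table
# and evaluates Burrows' Delta and the variance terms by explicit enumeration
# over the nine cells. Independent of the matrix-algebra path in the package.
oracle_r2 <- function(a, b, correct = TRUE) {
  ok <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[ok], levels = 0:2), factor(b[ok], levels = 0:2))
  n <- sum(tab)
  if (n < 2) return(NA_real_)
  pA <- pB <- PAA <- PBB <- S <- 0
  for (i in 0:2) for (j in 0:2) {
    f <- tab[i + 1, j + 1] / n
    pA <- pA + i * f / 2
    pB <- pB + j * f / 2
    if (i == 2) PAA <- PAA + f
    if (j == 2) PBB <- PBB + f
    S <- S + i * j * f / 2
  }
  D <- S - 2 * pA * pB
  if (correct) D <- D * n / (n - 1)
  tA <- pA * (1 - pA) + (PAA - pA^2)
  tB <- pB * (1 - pB) + (PBB - pB^2)
  if (tA <= 1e-12 || tB <= 1e-12) return(NA_real_)  # monomorphic in subset
  D^2 / (tA * tB)
}

# Genotypes drawn at Hardy-Weinberg proportions from independent loci.
hwe_geno <- function(n, L, p = NULL, miss = 0, seed = NULL, pop = "pop1") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p)) p <- runif(L, 0.1, 0.9)
  G <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  if (miss > 0) G[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  geno_matrix(G, individuals = tibble::tibble(id = sprintf("i%03d", seq_len(n)), pop = pop))
}

# Row-bind two genotype matrices on their shared loci (mixture sampling).
combine_geno <- function(g1, g2) {
  shared <- intersect(g1$loci$locus, g2$loci$locus)
  j1 <- match(shared, g1$loci$locus); j2 <- match(shared, g2$loci$locus)
  ind <- rbind(
    tibble::tibble(id = paste0("a_", g1$individuals$id), pop = "mix"),
    tibble::tibble(id = paste0("b_", g2$individuals$id), pop = "mix")
  )
  geno_matrix(rbind(g1$G[, j1, drop = FALSE], g2$G[, j2, drop = FALSE]),
              loci = g1$loci[j1, ], individuals = ind)
}

# estimate_raw with the small-sample warning muffled (tests often use n < 30)
est_quiet <- function(x, config = estimator_config(), ci = "none") {
  suppressWarnings(estimate_raw(x, config, ci = ci))
}
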