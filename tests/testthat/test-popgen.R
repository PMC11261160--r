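test_that("diversity matches a hand-counted two-individual example", {
  # ind1 = (0,1,2), ind2 = (0,1,0) over 3 loci:
  # locus 1 monomorphic (dropped); locus 2: Ho=1, p=0.5, He=2*.25*(4/3)=2/3;
  # locus 3: Ho=0, p=0.5, He=2/3. Means: Ho=0.5, He=2/3, Fis=((1-3/2)+(1-0))/2
  g <- geno_matrix(rbind(c(0L, 1L, 2L), c(0L, 1L, 0L)))
  d <- diversity_summary(g)
  expect_identical(d$n_variant_loci, 2L)
  expect_equal(d$ho, 0.5)
  expect_equal(d$he, 2 / 3)
  expect_equal(d$fis, ((1 - 1 / (2 / 3)) + 1) / 2)
})

test_that("FIS is near zero under Hardy-Weinberg and negative with excess heterozygotes", {
  g <- hwe_geno(10000, 30, seed = 401)
  d <- diversity_summary(g)
  expect_lt(abs(d$fis), 0.02)
  het <- geno_matrix(matrix(1L, 20, 4))
  # all-heterozygous loci: p = 0.5, Ho = 1 -> strongly negative FIS
  dh <- diversity_summary(het)
  expect_equal(dh$ho, 1)
  expect_lt(dh$fis, 0)
})

test_that("sample with no variant loci flags undefined FIS", {
  mono <- geno_matrix(matrix(0L, 5, 4))
  expect_warning(d <- diversity_summary(mono), "FIS undefined")
  expect_true(is.na(d$fis))
})

test_that("Weir-Cockerham theta matches per-allele variance-components arithmetic", {
  # worked example: one locus, two populations, explicit genotype counts
  g <- geno_matrix(
    matrix(c(rep(0L, 3), rep(1L, 4), rep(2L, 3),       # pop A: n=10, p=.5, h=.4
             rep(0L, 6), rep(1L, 5), rep(2L, 3)), ncol = 1),  # pop B: n=14
    individuals = data.frame(id = sprintf("i%02d", 1:24),
                             pop = rep(c("A", "B"), c(10, 14)))
  )
  res <- pairwise_fst(g, permutations = 9, seed = 1)

  wc_allele <- function(n, p, h) {   # scalar WC84 components for one allele
    r <- 2
    nbar <- (n[1] + n[2]) / 2
    nc <- (r * nbar - (n[1]^2 + n[2]^2) / (r * nbar)) / (r - 1)
    pbar <- (n[1] * p[1] + n[2] * p[2]) / (r * nbar)
    s2 <- (n[1] * (p[1] - pbar)^2 + n[2] * (p[2] - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n[1] * h[1] + n[2] * h[2]) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
  }
  n <- c(10, 14); h <- c(0.4, 5 / 14)
  alt <- wc_allele(n, c(0.5, 11 / 28), h)
  ref <- wc_allele(n, c(0.5, 17 / 28), h)
  theta <- (alt[1] + ref[1]) / sum(alt + ref)
  expect_equal(res$pairs$fst, theta, tolerance = 1e-10)
})

test_that("populations fixed for alternate alleles give FST = 1", {
  g <- geno_matrix(rbind(matrix(0L, 5, 10), matrix(2L, 5, 10)),
                   individuals = data.frame(id = sprintf("i%02d", 1:10),
                                            pop = rep(c("A", "B"), each = 5)))
  f <- pairwise_fst(g, permutations = 19, seed = 2)
  expect_equal(f$pairs$fst, 1)
  expect_lt(f$pairs$p_value, 0.06)
})

test_that("null FST is centred on zero with valid permutation p-values", {
  set.seed(402)
  fsts <- numeric(200); ps <- numeric(200)
  for (k in 1:200) {
    g <- hwe_geno(40, 25, pop = "x")
    g$individuals$pop <- rep(c("A", "B"), each = 20)
    f <- pairwise_fst(g, permutations = 99, seed = k)
    fsts[k] <- f$pairs$fst; ps[k] <- f$pairs$p_value
  }
  expect_lt(abs(mean(fsts)), 3 * sd(fsts) / sqrt(200))
  expect_lte(mean(ps <= 0.05), 0.08)
  expect_gt(mean(ps), 0.35)  # roughly uniform, not piled near 0
})

test_that("BH adjustment follows the step-up rule across pairs", {
  # three populations with graded differentiation -> three ordered p-values
  set.seed(403)
  base <- hwe_geno(60, 30, pop = "x")
  g <- base
  g$individuals$pop <- rep(c("A", "B", "C"), each = 20)
  g$G[41:60, 1:12] <- 2L - g$G[41:60, 1:12]  # C strongly diverged
  f <- pairwise_fst(g, permutations = 99, seed = 3)
  expect_equal(f$pairs$p_adjusted, p.adjust(f$pairs$p_value, "BH"))
  expect_true(all(f$pairs$p_adjusted >= f$pairs$p_value))
  # the step-up arithmetic on the canonical example
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  expect_identical(dim(f$p_adjusted), c(3L, 3L))
  expect_true(isSymmetric(f$fst))
  expect_equal(diag(f$fst), rep(0, 3), ignore_attr = TRUE)
})

test_that("PCA imputation is a no-op on complete data and deterministic on ties", {
  g <- hwe_geno(30, 15, seed = 404)
  sc <- pca_imputed(g, components = 3)
  direct <- prcomp(g$G, center = TRUE)$x[, 1:3]
  expect_equal(unname(as.matrix(sc[, c("PC1", "PC2", "PC3")])), unname(direct))

  # tie between genotypes 0 and 2 -> impute the smaller
  G <- rbind(c(0L, 0L), c(0L, 1L), c(2L, 2L), c(2L, 1L), c(NA, 1L))
  modal_path <- pca_imputed(geno_matrix(G), components = 1)
  G0 <- G; G0[5, 1] <- 0L
  expect_equal(modal_path$PC1, prcomp(G0, center = TRUE)$x[, 1],
               ignore_attr = TRUE)
  expect_error(pca_imputed(geno_matrix(cbind(G[, 1], NA_integer_)), components = 1),
               "all genotypes missing")
})

test_that("PCA separates diverged populations and distances ignore component signs", {
  s1 <- simulate_discrete_wf(sim_config(N_adults = 40, L = 60, burn_in = 40),
                             sample_size = 25, seed = 405)$sample
  s2 <- simulate_discrete_wf(sim_config(N_adults = 40, L = 60, burn_in = 40),
                             sample_size = 25, seed = 406)$sample
  g <- combine_geno(s1, s2)
  g$individuals$pop <- rep(c("P1", "P2"), each = 25)
  sc <- pca_imputed(g, components = 2)
  sep <- abs(mean(sc$PC1[sc$pop == "P1"]) - mean(sc$PC1[sc$pop == "P2"]))
  pooled_sd <- sd(c(sc$PC1[sc$pop == "P1"] - mean(sc$PC1[sc$pop == "P1"]),
                    sc$PC1[sc$pop == "P2"] - mean(sc$PC1[sc$pop == "P2"])))
  expect_gt(sep, 2 * pooled_sd)

  m <- as.matrix(sc[, c("PC1", "PC2")])
  m2 <- m; m2[, 2] <- -m2[, 2]
  expect_equal(as.numeric(dist(m)), as.numeric(dist(m2)))
})
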