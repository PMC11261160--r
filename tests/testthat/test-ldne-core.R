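test_that("pair_r2 matches the 3x3 genotype-count oracle on random instances", {
  set.seed(101)
  for (k in 1:60) {
    n <- sample(10:60, 1)
    a <- rbinom(n, 2, runif(1, 0.1, 0.9))
    b <- rbinom(n, 2, runif(1, 0.1, 0.9))
    if (k %% 3 == 0) a[sample(n, 2)] <- NA_integer_
    for (corr in c(TRUE, FALSE)) {
      got <- pair_r2(a, b, correct = corr)
      want <- oracle_r2(a, b, correct = corr)
      if (is.na(want)) {
        expect_true(is.na(got$r2))
      } else {
        expect_lt(abs(got$r2 - want), 1e-12)
      }
    }
  }
})

test_that("self-correlation is exactly 1 uncorrected, (n/(n-1))^2 corrected", {
  set.seed(102)
  a <- rbinom(50, 2, 0.5)
  expect_equal(pair_r2(a, a, correct = FALSE)$r2, 1, tolerance = 1e-9)
  expect_equal(pair_r2(a, a, correct = TRUE)$r2, (50 / 49)^2, tolerance = 1e-9)
})

test_that("r2 is invariant to allele relabelling and pairs degrade gracefully", {
  set.seed(103)
  a <- rbinom(40, 2, 0.3); b <- rbinom(40, 2, 0.6)
  expect_equal(pair_r2(2L - a, b)$r2, pair_r2(a, b)$r2, tolerance = 1e-12)
  expect_equal(pair_r2(a, 2L - b)$r2, pair_r2(a, b)$r2, tolerance = 1e-12)
  # monomorphic within the pairwise-complete subset -> undefined pair
  mono <- rep(1L, 40)
  expect_true(is.na(pair_r2(mono, b)$r2))
  expect_identical(pair_r2(c(0L, NA), c(1L, 0L))$n, 1L)
})

test_that("sampling expectation takes the documented branches and decreases in n", {
  expect_equal(expected_sample_r2(100), 0.010319)
  d <- expected_sample_r2(c(29, 30), detail = TRUE)
  expect_identical(d$branch, c("n<30", "n>=30"))
  expect_equal(d$value[1], 0.0018 + 0.907 / 29 + 4.44 / 29^2)
  expect_equal(d$value[2], 1 / 30 + 3.19 / 900)
  grid <- expected_sample_r2(seq(10, 2000, by = 7))
  expect_true(all(diff(grid) < 0))
  expect_lt(expected_sample_r2(1e7), 1e-6)
})

test_that("drift-to-Ne transform matches direct evaluation and handles indeterminacy", {
  expect_equal(ne_from_r2drift(0.001),
               (1 / 3 + sqrt(1 / 9 - 2.76 * 0.001)) / (2 * 0.001),
               tolerance = 1e-12)
  expect_equal(round(ne_from_r2drift(0.001), 1), 331.3)
  expect_identical(ne_from_r2drift(0), Inf)
  expect_identical(ne_from_r2drift(-1e-6), Inf)
  # monotone decreasing over the admissible drift range
  grid <- seq(1e-5, 1 / (2.76 * 9), length.out = 200)
  expect_true(all(diff(ne_from_r2drift(grid)) < 0))
  # small-sample branch uses its own coefficients
  expect_equal(ne_from_r2drift(0.01, n = 20),
               (0.308 + sqrt(0.308^2 - 2.08 * 0.01)) / 0.02)
})

test_that("allele screening implements none / no-singletons / pcrit", {
  g <- hwe_geno(100, 20, seed = 104)
  g$G[, 1] <- 0L; g$G[1, 1] <- 1L                   # singleton: MAC 1
  g$G[, 2] <- 0L; g$G[1:2, 2] <- 1L                 # MAF 0.01
  expect_identical(n_loci(screen_loci(g, estimator_config("none"))), 20L)
  ns <- screen_loci(g, estimator_config("no_singletons"))
  expect_false(g$loci$locus[1] %in% ns$loci$locus)
  expect_true(g$loci$locus[2] %in% ns$loci$locus)
  pc2 <- screen_loci(g, estimator_config("pcrit", pcrit = 0.02))
  expect_false(g$loci$locus[2] %in% pc2$loci$locus)
  pc05 <- screen_loci(g, estimator_config("pcrit", pcrit = 0.005))
  expect_true(g$loci$locus[2] %in% pc05$loci$locus)
  expect_error(estimator_config("pcrit", pcrit = 0.7), "pcrit")
})

test_that("estimate is invariant to locus order, individual order and relabelling", {
  sim <- simulate_discrete_wf(sim_config(N_adults = 60, L = 80, burn_in = 40),
                              sample_size = 40, seed = 105)
  g <- sim$sample
  base <- estimate_raw(g, ci = "none")

  perm_loci <- subset_geno(g, j = sample(n_loci(g)))
  expect_equal(estimate_raw(perm_loci, ci = "none")$point, base$point)

  perm_ind <- subset_geno(g, i = sample(n_indiv(g)))
  expect_equal(estimate_raw(perm_ind, ci = "none")$point, base$point)

  flip <- g
  cols <- sample(n_loci(g), 25)
  flip$G[, cols] <- 2L - flip$G[, cols]
  expect_equal(estimate_raw(flip, ci = "none")$point, base$point)
})

test_that("duplicating every individual shrinks the sampling correction and the estimate", {
  sim <- simulate_discrete_wf(sim_config(N_adults = 50, L = 100, burn_in = 30),
                              sample_size = 40, seed = 106)
  g <- sim$sample
  dup <- geno_matrix(rbind(g$G, g$G),
                     loci = g$loci,
                     individuals = tibble::tibble(
                       id = c(g$individuals$id, paste0(g$individuals$id, "_dup")),
                       pop = "wf"))
  e1 <- estimate_raw(g, ci = "none")
  e2 <- estimate_raw(dup, ci = "none")
  expect_lt(e2$expected_r2, e1$expected_r2)
  expect_gt(e2$r2_drift, e1$r2_drift)
  expect_lt(e2$point, e1$point)
})

test_that("excluding same-chromosome pairs raises the estimate under tight linkage", {
  pts <- sapply(1:5, function(s) {
    sim <- simulate_discrete_wf(
      sim_config(N_adults = 80, L = 120, chromosomes = 4, recomb_fraction = 0.02,
                 burn_in = 80),
      sample_size = 50, seed = 200 + s
    )
    all_pairs <- estimate_raw(sim$sample, ci = "none")$point
    split_pairs <- estimate_raw(
      sim$sample,
      estimator_config(exclude_same_chromosome_pairs = TRUE), ci = "none"
    )$point
    c(all_pairs, split_pairs)
  })
  expect_gte(median(pts[2, ]), median(pts[1, ]))
})

test_that("degenerate jackknife variance collapses the CI to the point, flagged", {
  a <- rep(c(0L, 1L, 2L), 4)
  g <- geno_matrix(cbind(a, 2L - a))  # perfectly anticorrelated pair, r2 = 1
  g <- subset_geno(g, i = seq_len(12))
  est <- suppressWarnings(estimate_raw(g, estimator_config("none")))
  expect_true(est$ci_degenerate)
  expect_identical(est$ci_lower, est$point)
  expect_identical(est$ci_upper, est$point)
})

test_that("estimator guards its preconditions", {
  g <- hwe_geno(5, 10, seed = 107)
  expect_error(estimate_raw(g), "fewer than 10 individuals")
  mono <- geno_matrix(matrix(0L, 20, 5))
  expect_error(estimate_raw(mono, estimator_config("none")), "polymorphic")
  g2 <- hwe_geno(25, 30, seed = 108)
  expect_warning(estimate_raw(g2, ci = "none"), "fewer than 30")
})

test_that("tidy and glance expose the estimate as one-row tibbles", {
  sim <- simulate_discrete_wf(sim_config(N_adults = 40, L = 60, burn_in = 20),
                              sample_size = 30, seed = 109)
  est <- estimate_raw(sim$sample)
  td <- tidy(est)
  expect_identical(nrow(td), 1L)
  expect_true(all(c("estimate", "ci_lower", "ci_upper", "r2_drift") %in% names(td)))
  gl <- glance(est)
  expect_identical(gl$n_individuals, 30L)
  expect_identical(gl$screening, "no_singletons")
})
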