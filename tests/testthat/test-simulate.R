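test_that("seeded runs are bit-reproducible; seeds change genotypes not shape", {
  cfg <- sim_config(N_adults = 30, L = 40, burn_in = 15, missing_rate = 0.02)
  a <- simulate_discrete_wf(cfg, sample_size = 20, seed = 5)
  b <- simulate_discrete_wf(cfg, sample_size = 20, seed = 5)
  expect_identical(a$sample$G, b$sample$G)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_discrete_wf(cfg, sample_size = 20, seed = 6)
  expect_identical(dim(c2$sample$G)[1], 20L)
  expect_false(identical(a$sample$G[, 1:5], c2$sample$G[, 1:5]))

  st1 <- simulate_age_structured(snapper_sim_config(L = 30, burn_in = 30), seed = 9)
  st2 <- simulate_age_structured(snapper_sim_config(L = 30, burn_in = 30), seed = 9)
  expect_identical(st1$H1, st2$H1)
  expect_identical(sample_yoy_cohort(st1, 10, seed = 2)$G,
                   sample_yoy_cohort(st2, 10, seed = 2)$G)
})

test_that("one-generation drift variance matches binomial sampling theory", {
  set.seed(501)
  N <- 50; L <- 2000
  # parents constructed at exactly p = 0.5 per locus
  H1 <- matrix(rep(seq_len(N) <= N / 2, L), N, L)
  H2 <- matrix(rep(seq_len(N) %% 2 == 0, L), N, L)
  loci <- tibble::tibble(locus = as.character(seq_len(L)), chrom = "c1", pos = seq_len(L))
  pa <- sample.int(N, N, replace = TRUE); ma <- sample.int(N, N, replace = TRUE)
  O1 <- ldne:::draw_gametes(H1[pa, ], H2[pa, ], loci, 0.5)
  O2 <- ldne:::draw_gametes(H1[ma, ], H2[ma, ], loci, 0.5)
  p1 <- (colSums(O1) + colSums(O2)) / (2 * N)
  expect_equal(mean((p1 - 0.5)^2), 0.5 * 0.5 / (2 * N), tolerance = 0.1)
})

test_that("heterozygosity decays like (1 - 1/(2N))^t", {
  N <- 30; t_gen <- 30
  ratios <- sapply(1:30, function(s) {
    st <- simulate_discrete_wf(
      sim_config(N_adults = N, L = 150, burn_in = t_gen, fixed_loci = "keep",
                 init_freq_range = c(0.5, 0.5)),
      sample_size = 10, seed = 600 + s
    )$state
    p <- (colSums(st$H1) + colSums(st$H2)) / (2 * N)
    mean(2 * p * (1 - p))
  })
  # one extra factor for the binomial founding draw
  expected <- 0.5 * (1 - 1 / (2 * N))^(t_gen + 1)
  expect_equal(mean(ratios), expected, tolerance = 0.1)
})

test_that("offspring genotypes are consistent with their recorded parents", {
  cfg <- sim_config(mode = "age_structured", cohort_size = 15, alpha = 1,
                    max_age = 6, survival = 0.95, L = 12, burn_in = 6)
  st <- simulate_age_structured(cfg, seed = 11)
  last <- st$pedigree[st$pedigree$year == st$year, ]
  G <- st$H1 + st$H2
  id_row <- match(last$id, st$indiv$id)
  fa_row <- match(last$father, st$indiv$id)
  mo_row <- match(last$mother, st$indiv$id)
  ok <- !is.na(fa_row) & !is.na(mo_row)   # parents may have died post-breeding
  expect_gt(sum(ok), 0)
  allele_set <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)  # possible gamete alleles
  for (r in which(ok)) {
    for (l in seq_len(ncol(G))) {
      possible <- outer(allele_set(G[fa_row[r], l]), allele_set(G[mo_row[r], l]), "+")
      expect_true(G[id_row[r], l] %in% possible)
    }
  }
})

test_that("age distribution settles to the analytic survivorship curve", {
  counts <- 0
  for (s in 1:3) {
    st <- simulate_age_structured(
      snapper_sim_config(cohort_size = 100, L = 10, burn_in = 120), seed = 700 + s)
    counts <- counts + table(factor(pmin(st$indiv$age, 10) %/% 5,
                                    levels = 0:2))
  }
  surv <- 0.85^(0:40)
  expected <- c(sum(surv[1:5]), sum(surv[6:10]), sum(surv[11:41]))
  expected <- expected / sum(expected)
  observed <- as.numeric(counts) / sum(counts)
  expect_true(all(abs(observed - expected) / expected < 0.10))
})

test_that("overdispersed reproduction lowers the pedigree effective number of breeders", {
  cfgs <- lapply(c(1, 10), function(phi)
    sim_config(mode = "age_structured", cohort_size = 80, alpha = 2, max_age = 8,
               survival = 0.8, dispersion = phi, L = 10, burn_in = 25))
  nb <- vapply(cfgs, function(cc)
    true_nb(simulate_age_structured(cc, seed = 12))$true_nb, numeric(1))
  expect_lt(nb[2], nb[1])
})

test_that("degenerate life history reduces to discrete Wright-Fisher LD behaviour", {
  # maturity at 1, certain survival to age 1, certain death after breeding:
  # each year's adults are exactly the previous cohort
  drift_as <- sapply(1:20, function(s) {
    cfg <- sim_config(mode = "age_structured", cohort_size = 60, alpha = 1,
                      max_age = 1, survival = 1, L = 100, burn_in = 60)
    st <- simulate_age_structured(cfg, seed = 800 + s)
    est_quiet(sample_yoy_cohort(st, 30, seed = s))$r2_drift
  })
  drift_wf <- sapply(1:20, function(s) {
    sim <- simulate_discrete_wf(
      sim_config(N_adults = 60, L = 100, burn_in = 60), sample_size = 30,
      seed = 900 + s)
    est_quiet(sim$sample)$r2_drift
  })
  expect_gt(stats::ks.test(drift_as, drift_wf)$p.value, 0.01)
})

test_that("samplers respect cohort membership, age ranges and missingness", {
  st <- simulate_age_structured(snapper_sim_config(cohort_size = 50, L = 40,
                                                   burn_in = 40,
                                                   missing_rate = 0.1), seed = 13)
  yoy <- sample_yoy_cohort(st, 30, seed = 1)
  expect_true(all(yoy$individuals$age == 0))
  expect_identical(unique(yoy$individuals$cohort), "YOY")
  expect_equal(mean(is.na(yoy$G)), 0.1, tolerance = 0.35)
  expect_error(sample_yoy_cohort(st, 1e5), "cohort has")

  ad <- sample_mixed_adults(st, 40, seed = 2)
  expect_true(all(ad$individuals$age >= st$config$alpha))
  expect_identical(unique(ad$individuals$cohort), "mixed-adult")
  expect_error(sample_mixed_adults(st, 1e5), "adults in range")
})

test_that("population extinction raises a diagnostic error", {
  cfg <- sim_config(mode = "age_structured", cohort_size = 4, alpha = 4,
                    max_age = 6, survival = 0.05, L = 5, burn_in = 40)
  expect_error(simulate_age_structured(cfg, seed = 14), "extinct")
})

test_that("fixed loci during burn-in are dropped and counted", {
  cfg <- sim_config(N_adults = 12, L = 60, burn_in = 60, fixed_loci = "drop")
  sim <- simulate_discrete_wf(cfg, sample_size = 10, seed = 15)
  expect_identical(n_loci(sim$sample), nrow(sim$state$loci))
  expect_identical(sim$state$fixed_dropped, 60L - n_loci(sim$sample))
  expect_gt(sim$state$fixed_dropped, 0L)  # heavy drift at N = 12 fixes some loci
  keep <- simulate_discrete_wf(
    sim_config(N_adults = 12, L = 60, burn_in = 60, fixed_loci = "keep"),
    sample_size = 10, seed = 15)
  expect_identical(n_loci(keep$sample), 60L)
})
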