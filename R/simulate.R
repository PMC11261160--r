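#' Configuration for the forward genotype simulators
#'
#' Two modes share one configuration. `discrete_wf`: non-overlapping
#' generations of `N_adults` monoecious adults, multinomial parent draws.
#' `age_structured`: overlapping generations with a fixed annual recruitment
#' (`cohort_size` newborns), breeding restricted to adults of age >=
#' `alpha`, annual survival `survival` up to `max_age`, and optional
#' overdispersion of reproductive success.
#'
#' Loci live on `chromosomes` chromosomes (round-robin assignment) and are
#' transmitted as haplotypes: adjacent loci on a chromosome recombine with
#' probability `recomb_fraction` (0.5 = free recombination, the default, i.e.
#' effectively unlinked loci); chromosomes assort independently.
#'
#' @param mode `"discrete_wf"` or `"age_structured"`.
#' @param N_adults Adult population size (discrete mode).
#' @param cohort_size Newborns recruited each year (age-structured mode).
#' @param alpha Age at maturity in years.
#' @param max_age Maximum age (longevity); individuals die after it.
#' @param survival Annual survival probability in (0, 1]; individuals die
#'   with certainty beyond `max_age` regardless.
#' @param dispersion Variance-inflation factor for reproductive success
#'   (>= 1). 1 = equal expected contributions (multinomial/Poisson-like);
#'   larger values draw per-adult, per-year gamma fecundity weights with
#'   variance `dispersion - 1`, inflating the variance in offspring number.
#' @param L Number of biallelic loci.
#' @param chromosomes Haploid chromosome number.
#' @param recomb_fraction Recombination fraction between adjacent loci on the
#'   same chromosome (default 0.5).
#' @param init_freq_range Initial allele-frequency range (uniform draw).
#' @param burn_in Burn-in length: generations (discrete; default `N_adults`)
#'   or years (age-structured; default `3 * max_age`).
#' @param missing_rate Fraction of genotype calls set missing at sampling
#'   time, in `[0, 0.2]`.
#' @param fixed_loci `"drop"` (default): loci fixed during burn-in are
#'   removed from emitted matrices, with a count recorded; `"keep"` retains
#'   them (they are ignored by the estimator anyway).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("discrete_wf", "age_structured"),
                       N_adults = 100, cohort_size = 60,
                       alpha = 5, max_age = 40, survival = 0.85,
                       dispersion = 1,
                       L = 300, chromosomes = 24, recomb_fraction = 0.5,
                       init_freq_range = c(0.05, 0.95),
                       burn_in = NULL, missing_rate = 0,
                       fixed_loci = c("drop", "keep")) {
  mode <- match.arg(mode)
  fixed_loci <- match.arg(fixed_loci)
  stopifnot(N_adults > 1, cohort_size > 0, alpha > 0, max_age >= alpha,
            survival > 0, survival <= 1, dispersion >= 1, L >= 2,
            chromosomes >= 1, recomb_fraction > 0, recomb_fraction <= 0.5,
            missing_rate >= 0, missing_rate <= 0.2)
  if (is.null(burn_in)) {
    burn_in <- if (mode == "discrete_wf") N_adults else 3 * max_age
  }
  structure(list(mode = mode, N_adults = N_adults, cohort_size = cohort_size,
                 alpha = alpha, max_age = max_age, survival = survival,
                 dispersion = dispersion, L = L, chromosomes = chromosomes,
                 recomb_fraction = recomb_fraction,
                 init_freq_range = init_freq_range, burn_in = burn_in,
                 missing_rate = missing_rate, fixed_loci = fixed_loci),
            class = "sim_config")
}

#' Snapper-like age-structured preset
#'
#' Age at maturity 5, longevity 40, annual adult survival 0.85, 24
#' chromosomes: the life history of a long-lived, early-maturing, heavily
#' iteroparous broadcast spawner, at desk scale.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
snapper_sim_config <- function(...) {
  defaults <- list(mode = "age_structured", alpha = 5, max_age = 40,
                   survival = 0.85, chromosomes = 24, L = 1000, cohort_size = 60)
  do.call(sim_config, modifyList(defaults, list(...)))
}

sim_loci_meta <- function(cfg) {
  chrom <- rep_len(paste0("chr", seq_len(cfg$chromosomes)), cfg$L)
  ord <- order(match(chrom, unique(chrom)))
  tibble(locus = sprintf("snp_%04d", seq_len(cfg$L)),
         chrom = chrom[ord],
         pos = as.integer(stats::ave(seq_len(cfg$L), chrom[ord], FUN = seq_along)))
}

# Recombination-aware gamete draw: one gamete per row of parent haplotypes.
# H1p, H2p: n x L haplotype matrices of the chosen parents.
draw_gametes <- function(H1p, H2p, loci, recomb) {
  n <- nrow(H1p); L <- ncol(H1p)
  if (recomb >= 0.5) {
    pick2 <- matrix(runif(n * L) < 0.5, n, L)
  } else {
    new_chrom <- c(TRUE, loci$chrom[-1] != loci$chrom[-L])
    pick2 <- matrix(FALSE, n, L)
    cur <- runif(n) < 0.5
    for (l in seq_len(L)) {
      sw <- runif(n) < (if (new_chrom[l]) 0.5 else recomb)
      cur <- xor(cur, sw)
      pick2[, l] <- cur
    }
  }
  out <- H1p
  out[pick2] <- H2p[pick2]
  out
}

new_sim_state <- function(H1, H2, indiv, loci, cfg, pedigree, year, fixed_dropped = 0L) {
  structure(list(H1 = H1, H2 = H2, indiv = indiv, loci = loci, config = cfg,
                 pedigree = pedigree, year = year, fixed_dropped = fixed_dropped),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %s | year %d | %d individuals | %d loci\n",
              x$config$mode, x$year, nrow(x$indiv), nrow(x$loci)))
  print(table(age = x$indiv$age))
  invisible(x)
}

#' Discrete Wright-Fisher simulation
#'
#' Non-overlapping generations of `N_adults` monoecious diploids: each
#' offspring draws a mother and a father uniformly at random (selfing
#' possible), and receives one recombination-aware gamete from each. After
#' `burn_in` generations (default `N_adults`), a sample of `sample_size`
#' individuals is returned together with the pedigree-derived truth for the
#' final breeding cycle. Seeded runs are reproducible.
#'
#' @param config A [sim_config()] with `mode = "discrete_wf"`.
#' @param sample_size Individuals to sample from the final generation.
#' @param seed Integer seed.
#' @return A list: `sample` (a [geno_matrix()]), `truth` (tibble with
#'   `true_ne` = `N_adults` and the pedigree-derived `true_nb` of the final
#'   cycle, see [true_nb()]), and `state` (the final `sim_state`).
#' @export
simulate_discrete_wf <- function(config = sim_config(), sample_size = 50, seed = 1L) {
  stopifnot(config$mode == "discrete_wf")
  set.seed(seed)
  N <- config$N_adults; L <- config$L
  loci <- sim_loci_meta(config)
  p0 <- runif(L, config$init_freq_range[1], config$init_freq_range[2])
  H1 <- matrix(runif(N * L) < rep(p0, each = N), N, L)
  H2 <- matrix(runif(N * L) < rep(p0, each = N), N, L)
  ped <- NULL
  for (g in seq_len(config$burn_in)) {
    pa <- sample.int(N, N, replace = TRUE)
    ma <- sample.int(N, N, replace = TRUE)
    H1n <- draw_gametes(H1[pa, , drop = FALSE], H2[pa, , drop = FALSE],
                        loci, config$recomb_fraction)
    H2n <- draw_gametes(H1[ma, , drop = FALSE], H2[ma, , drop = FALSE],
                        loci, config$recomb_fraction)
    H1 <- H1n; H2 <- H2n
    if (g == config$burn_in) ped <- tibble(id = seq_len(N), father = pa, mother = ma)
  }
  p_now <- (colSums(H1) + colSums(H2)) / (2 * N)
  fixed <- p_now %in% c(0, 1)
  keep <- if (config$fixed_loci == "drop") which(!fixed) else seq_len(L)
  indiv <- tibble(id = sprintf("wf_%04d", seq_len(N)), pop = "wf", age = 0,
                  cohort = "wf-final")
  state <- new_sim_state(H1[, keep, drop = FALSE], H2[, keep, drop = FALSE],
                         indiv, loci[keep, ], config,
                         pedigree = dplyr::mutate(ped, year = config$burn_in),
                         year = config$burn_in, fixed_dropped = sum(fixed))
  truth <- true_nb(state)
  truth$true_ne <- N
  idx <- sample.int(N, sample_size)
  samp <- state_to_geno(state, idx, cohort = "wf-final")
  list(sample = samp, truth = truth, state = state)
}

#' Age-structured forward simulation with pedigree
#'
#' Yearly cycle: adults (age >= alpha) breed, producing a fixed-size newborn
#' cohort whose parents are drawn with equal probability (or with
#' gamma-overdispersed weights, see [sim_config()]); all individuals then
#' survive to the next year with probability `survival`, dying with
#' certainty beyond `max_age`; survivors age by one year. The pedigree of
#' every cohort is recorded so the demographic effective number of breeders
#' can be computed per cycle ([true_nb()]).
#'
#' @param config A [sim_config()] with `mode = "age_structured"`.
#' @param seed Integer seed.
#' @return A `sim_state` holding haplotypes, ages, loci metadata and the
#'   full pedigree. Pass it to [sample_yoy_cohort()] / [sample_mixed_adults()].
#' @export
simulate_age_structured <- function(config = snapper_sim_config(), seed = 1L) {
  stopifnot(config$mode == "age_structured")
  set.seed(seed)
  L <- config$L
  loci <- sim_loci_meta(config)
  p0 <- runif(L, config$init_freq_range[1], config$init_freq_range[2])

  # initialise at the stable age distribution implied by constant recruitment
  ages <- rep(0:config$max_age,
              times = pmax(1, round(config$cohort_size * config$survival^(0:config$max_age))))
  n0 <- length(ages)
  H1 <- matrix(runif(n0 * L) < rep(p0, each = n0), n0, L)
  H2 <- matrix(runif(n0 * L) < rep(p0, each = n0), n0, L)
  indiv <- tibble(id = seq_len(n0), age = ages)
  next_id <- n0 + 1L
  ped <- list()

  for (year in seq_len(config$burn_in)) {
    adult <- which(indiv$age >= config$alpha)
    if (length(adult) < 2) abort(sprintf("population extinct in year %d (%d adults)",
                                         year, length(adult)))
    wts <- if (config$dispersion > 1) {
      sh <- 1 / (config$dispersion - 1)
      rgamma(length(adult), shape = sh, rate = sh)
    } else {
      rep(1, length(adult))
    }
    nb <- config$cohort_size
    fa <- adult[sample.int(length(adult), nb, replace = TRUE, prob = wts)]
    mo <- adult[sample.int(length(adult), nb, replace = TRUE, prob = wts)]
    Hb1 <- draw_gametes(H1[fa, , drop = FALSE], H2[fa, , drop = FALSE],
                        loci, config$recomb_fraction)
    Hb2 <- draw_gametes(H1[mo, , drop = FALSE], H2[mo, , drop = FALSE],
                        loci, config$recomb_fraction)
    ids <- next_id:(next_id + nb - 1L); next_id <- next_id + nb
    ped[[year]] <- tibble(id = ids, father = indiv$id[fa], mother = indiv$id[mo],
                          year = year)

    live <- runif(nrow(indiv)) < config$survival & indiv$age < config$max_age
    H1 <- rbind(H1[live, , drop = FALSE], Hb1)
    H2 <- rbind(H2[live, , drop = FALSE], Hb2)
    indiv <- dplyr::bind_rows(
      tibble(id = indiv$id[live], age = indiv$age[live] + 1L),
      tibble(id = ids, age = 0L)
    )
  }

  p_now <- (colSums(H1) + colSums(H2)) / (2 * nrow(H1))
  fixed <- p_now %in% c(0, 1)
  keep <- if (config$fixed_loci == "drop") which(!fixed) else seq_len(L)
  new_sim_state(H1[, keep, drop = FALSE], H2[, keep, drop = FALSE],
                indiv, loci[keep, ], config,
                pedigree = dplyr::bind_rows(ped), year = config$burn_in,
                fixed_dropped = sum(fixed))
}

#' Pedigree-derived demographic truth
#'
#' The demographic (inbreeding-type) effective number of breeders of a
#' breeding cycle, from realised offspring counts:
#' `Nb = (kbar * Np - 2) / (kbar - 1 + Vk / kbar)`, where `Np` is the number
#' of actual parents of the cohort, and `kbar`/`Vk` the mean and variance of
#' their offspring-gamete counts (each offspring contributes one count to
#' each of its two parents). For the age-structured model the tibble also
#' carries `adults_census`, the census number of mature adults in that year,
#' which under equal expected contributions approximates the generational
#' effective size the cohort's LD reflects.
#'
#' @param state A `sim_state`.
#' @param year Breeding year (default: the most recent cohort).
#' @return A one-row tibble: `year`, `n_parents`, `k_mean`, `k_var`,
#'   `true_nb`, and `adults_census` where applicable.
#' @export
true_nb <- function(state, year = max(state$pedigree$year)) {
  ped <- state$pedigree[state$pedigree$year == year, ]
  if (nrow(ped) == 0) abort(sprintf("no pedigree for year %d", year))
  k <- table(c(ped$father, ped$mother))
  np <- length(k)
  kbar <- mean(k); vk <- var(as.numeric(k)) * (np - 1) / np
  if (np == 1) vk <- 0
  nb <- (kbar * np - 2) / (kbar - 1 + vk / kbar)
  out <- tibble(year = year, n_parents = np, k_mean = kbar, k_var = vk,
                true_nb = nb)
  if (state$config$mode == "age_structured") {
    out$adults_census <- sum(state$indiv$age >= state$config$alpha)
  }
  out
}

state_to_geno <- function(state, idx, pop = "sim", cohort = NA_character_,
                          missing_rate = state$config$missing_rate) {
  G <- state$H1[idx, , drop = FALSE] + state$H2[idx, , drop = FALSE]
  storage.mode(G) <- "integer"
  if (missing_rate > 0) {
    G[matrix(runif(length(G)) < missing_rate, nrow(G))] <- NA_integer_
  }
  geno_matrix(G, loci = state$loci,
              individuals = tibble(id = paste0("ind_", state$indiv$id[idx]),
                                   pop = pop, cohort = cohort,
                                   age = as.numeric(state$indiv$age[idx])))
}

#' Sample a single newborn cohort (young of the year)
#'
#' Uniform sample without replacement from the most recent cohort (age 0).
#' An LD estimate from such a sample reflects the effective number of
#' breeders of the parental pool that produced the cohort.
#'
#' @param state A `sim_state` from [simulate_age_structured()].
#' @param s Sample size (<= cohort size).
#' @param seed Integer seed (controls sampling and missingness only).
#' @param pop Population label for the output.
#' @return A [geno_matrix()] with cohort label `"YOY"` and ages 0.
#' @export
sample_yoy_cohort <- function(state, s, seed = 1L, pop = "sim") {
  set.seed(seed)
  pool <- which(state$indiv$age == 0L)
  if (length(pool) < s) abort(sprintf("cohort has %d individuals, need %d", length(pool), s))
  state_to_geno(state, sample(pool, s), pop = pop, cohort = "YOY")
}

#' Sample mixed-age adults
#'
#' Uniform sample without replacement of adults across the given age range;
#' sampled ages are recorded in the individual metadata. LD estimates from
#' mixed-age samples of iteroparous species reflect generational Ne with an
#' expected downward bias.
#'
#' @param state A `sim_state` from [simulate_age_structured()].
#' @param s Sample size.
#' @param age_range Two-element numeric, default maturity to longevity.
#' @param seed Integer seed.
#' @param pop Population label for the output.
#' @return A [geno_matrix()] with cohort label `"mixed-adult"`.
#' @export
sample_mixed_adults <- function(state, s,
                                age_range = c(state$config$alpha, state$config$max_age),
                                seed = 1L, pop = "sim") {
  set.seed(seed)
  pool <- which(state$indiv$age >= age_range[1] & state$indiv$age <= age_range[2])
  if (length(pool) < s) abort(sprintf("only %d adults in range, need %d", length(pool), s))
  state_to_geno(state, sample(pool, s), pop = pop, cohort = "mixed-adult")
}
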