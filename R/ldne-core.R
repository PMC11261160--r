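#' Configuration for the LD effective-size estimator
#'
#' @param screening Rare-allele screen applied before estimation:
#'   `"no_singletons"` (default; drop loci whose minor allele occurs as
#'   exactly one copy in the sample), `"none"`, or `"pcrit"` (drop loci with
#'   minor-allele frequency below `pcrit`).
#' @param pcrit Minor-allele-frequency threshold in (0, 0.5], used when
#'   `screening = "pcrit"`.
#' @param exclude_same_chromosome_pairs If `TRUE`, locus pairs sharing a
#'   chromosome label are omitted from the mean r2 (physical linkage inflates
#'   within-chromosome LD; the default `FALSE` keeps all pairs, leaving that
#'   bias to the downstream chromosome-number correction).
#' @param confidence Jackknife confidence level (default 0.95).
#' @param small_sample_correction Apply the n/(n-1) small-sample factor to
#'   the composite disequilibrium (default `TRUE`; the sampling expectation
#'   of [expected_sample_r2()] is calibrated for this form).
#' @param rng_seed Optional integer seed recorded in the configuration (the
#'   estimator itself is deterministic).
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(screening = c("no_singletons", "none", "pcrit"),
                             pcrit = NULL,
                             exclude_same_chromosome_pairs = FALSE,
                             confidence = 0.95,
                             small_sample_correction = TRUE,
                             rng_seed = NULL) {
  screening <- match.arg(screening)
  if (screening == "pcrit") {
    if (is.null(pcrit) || pcrit <= 0 || pcrit > 0.5) {
      abort("pcrit must be in (0, 0.5] when screening = 'pcrit'")
    }
  }
  stopifnot(confidence > 0, confidence < 1)
  structure(list(screening = screening, pcrit = pcrit,
                 exclude_same_chromosome_pairs = exclude_same_chromosome_pairs,
                 mating_system = "random",
                 confidence = confidence,
                 small_sample_correction = small_sample_correction,
                 rng_seed = rng_seed),
            class = "estimator_config")
}

#' Screen rare alleles before LD estimation
#'
#' Rare alleles upwardly bias LD-based effective-size estimates; the standard
#' remedy is to drop loci whose minor allele is too rare before computing
#' pairwise r2.
#'
#' @param x A [geno_matrix()].
#' @param config An [estimator_config()]; its `screening` field selects the
#'   rule (see there).
#' @return The screened [geno_matrix()].
#' @export
screen_loci <- function(x, config = estimator_config()) {
  if (n_loci(x) == 0) abort("empty genotype matrix")
  st <- locus_stats(x)
  keep <- switch(config$screening,
    none = rep(TRUE, n_loci(x)),
    no_singletons = st$mac != 1L,
    pcrit = !is.na(st$maf) & st$maf >= config$pcrit
  )
  if (!any(keep)) abort("all loci removed by allele screening")
  if (all(keep)) return(x)
  subset_geno(x, j = which(keep))
}

#' Burrows composite-disequilibrium r2 for one locus pair
#'
#' Computes the squared composite-LD correlation between two biallelic loci
#' from unphased genotypes: Burrows' composite disequilibrium
#' \eqn{\hat\Delta} (the sum of the inter- and intra-gametic components,
#' estimable without phase) normalised by per-locus allele-frequency
#' variances that include the within-locus homozygote-excess (departure from
#' Hardy-Weinberg) term. Computed over individuals non-missing at both loci.
#'
#' With `correct = TRUE` (the default, and the form used by
#' [estimate_raw()]), \eqn{\hat\Delta} carries the n/(n-1) small-sample
#' factor for which the [expected_sample_r2()] calibration holds; with
#' `correct = FALSE` the plain moment estimator is returned, for which the
#' r2 of a locus against itself is exactly 1.
#'
#' @param a,b Integer genotype vectors (0/1/2/`NA`) of equal length.
#' @param correct Apply the n/(n-1) factor to \eqn{\hat\Delta}.
#' @return A tibble with one row: `r2` (NA when the pair is undefined, i.e.
#'   either locus is monomorphic within the pairwise-complete subset or
#'   fewer than 2 complete individuals), and `n` (pairwise-complete count).
#' @export
pair_r2 <- function(a, b, correct = TRUE) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- as.numeric(a[ok]); b <- as.numeric(b[ok])
  n <- length(a)
  if (n < 2) return(tibble(r2 = NA_real_, n = n))
  pa <- mean(a) / 2; pb <- mean(b) / 2
  c2a <- mean(a == 2); c2b <- mean(b == 2)
  tau_a <- pa * (1 - pa) + (c2a - pa^2)
  tau_b <- pb * (1 - pb) + (c2b - pb^2)
  # tau at floating-noise scale means the locus is monomorphic in the subset
  if (tau_a <= 1e-12 || tau_b <= 1e-12) return(tibble(r2 = NA_real_, n = n))
  D <- mean(a * b) / 2 - 2 * pa * pb
  if (correct) D <- D * n / (n - 1)
  tibble(r2 = D^2 / (tau_a * tau_b), n = n)
}

#' Expected r2 from finite sampling alone
#'
#' The expected contribution of sampling a finite number of individuals to
#' the mean composite r2 under random mating, as a function of the
#' pairwise-complete sample size n: `1/n + 3.19/n^2` for n >= 30, and
#' `0.0018 + 0.907/n + 4.44/n^2` below 30 (Waples' empirical calibration for
#' the small-sample-corrected Burrows estimator). Subtracting this from the
#' observed mean r2 isolates the drift signal that carries information about
#' effective size.
#'
#' @param n Vector of sample sizes (>= 2).
#' @param detail If `TRUE`, return a tibble with both branch values and the
#'   branch used at each n.
#' @return Numeric vector of expectations (or a detail tibble).
#' @export
expected_sample_r2 <- function(n, detail = FALSE) {
  stopifnot(all(n >= 2))
  large <- 1 / n + 3.19 / n^2
  small <- 0.0018 + 0.907 / n + 4.44 / n^2
  val <- ifelse(n >= 30, large, small)
  if (detail) {
    return(tibble(n = n, branch = ifelse(n >= 30, "n>=30", "n<30"),
                  value = val, value_large_n = large, value_small_n = small))
  }
  val
}

#' Effective size from drift r2
#'
#' Inverts the drift component of mean r2 into an effective-size point
#' estimate under random mating:
#' \eqn{\hat N = (1/3 + \sqrt{1/9 - 2.76 r^2_{drift}})/(2 r^2_{drift})} for
#' n >= 30 (coefficients 0.308 and 2.08 below 30). Non-positive drift means
#' the observed LD is fully explained by sampling, so the estimate is
#' indeterminate: `Inf`. A negative square-root argument is clamped to 0.
#'
#' @param r2_drift Mean r2 minus its sampling expectation.
#' @param n Sample size governing the coefficient branch (default large-n).
#' @return Positive number or `Inf`. Vectorised over `r2_drift`.
#' @export
ne_from_r2drift <- function(r2_drift, n = Inf) {
  a <- ifelse(n >= 30, 1 / 3, 0.308)
  b <- ifelse(n >= 30, 2.76, 2.08)
  out <- ifelse(r2_drift <= 0, Inf,
                (a + sqrt(pmax(0, a^2 - b * r2_drift))) / (2 * r2_drift))
  unname(out)
}

# Upper-triangle pairwise sufficient statistics from a genotype matrix.
# Returns vectors over locus pairs (i < j): counts and sums needed to form
# the composite r2, so leave-one-out updates are O(#pairs) per individual.
pair_sums <- function(G) {
  W <- !is.na(G); storage.mode(W) <- "double"
  X <- G; X[is.na(X)] <- 0L; storage.mode(X) <- "double"
  L <- ncol(G)
  ut <- which(upper.tri(matrix(0, L, L)))
  ia <- row(matrix(0, L, L))[ut]; ja <- col(matrix(0, L, L))[ut]
  N <- crossprod(W)
  SxW <- crossprod(X, W)        # [a,b] = sum over i of x_a * w_b
  SxxW <- crossprod(X * X, W)
  Sxy <- crossprod(X)
  list(ia = ia, ja = ja,
       n = N[ut],
       Sx = SxW[ut], Sy = t(SxW)[ut],
       Sxx = SxxW[ut], Syy = t(SxxW)[ut],
       Sxy = Sxy[ut])
}

# Composite r2 from pairwise sums; returns list(r2, valid).
r2_from_sums <- function(n, Sx, Sy, Sxx, Syy, Sxy, correct = TRUE) {
  pa <- Sx / (2 * n); pb <- Sy / (2 * n)
  c2a <- (Sxx - Sx) / 2; c2b <- (Syy - Sy) / 2   # homozygote-alt counts
  tau_a <- pa * (1 - pa) + (c2a / n - pa^2)
  tau_b <- pb * (1 - pb) + (c2b / n - pb^2)
  D <- Sxy / (2 * n) - 2 * pa * pb
  if (correct) D <- D * n / (n - 1)
  valid <- n >= 2 & tau_a > 1e-12 & tau_b > 1e-12
  r2 <- rep(NA_real_, length(n))
  r2[valid] <- (D[valid]^2) / (tau_a[valid] * tau_b[valid])
  list(r2 = r2, valid = valid)
}

#' Estimate effective size by the LD method
#'
#' The single-sample LD estimator: composite pairwise r2 over all retained
#' locus pairs, an n-weighted mean, subtraction of the finite-sampling
#' expectation, and inversion to an effective-size point estimate at the
#' harmonic mean pairwise sample size. A sample from a single cohort yields
#' the effective number of breeders (Nb) of the parental pool; a mixed-age
#' sample yields a (downwardly biased) generational Ne. 95% confidence
#' intervals come from a delete-one-individual jackknife (see
#' [jackknife_ci()]) unless `ci = "none"`.
#'
#' @param x A [geno_matrix()].
#' @param config An [estimator_config()].
#' @param ci `"jackknife"` (default) or `"none"`.
#' @return An object of class `ldne_estimate`: point estimate (`Inf` when
#'   the drift r2 is non-positive), CI bounds, LD statistics (weighted mean
#'   r2, sampling expectation, drift r2, harmonic mean S), locus/pair
#'   bookkeeping and the configuration. Use [tidy()] / [glance()] for tibble
#'   views.
#' @export
estimate_raw <- function(x, config = estimator_config(), ci = c("jackknife", "none")) {
  ci <- match.arg(ci)
  xs <- screen_loci(x, config)
  st <- locus_stats(xs)
  poly <- !is.na(st$maf) & st$maf > 0
  n_screened_out <- n_loci(x) - n_loci(xs)
  xs <- subset_geno(xs, j = which(poly))   # monomorphic loci form no valid pair
  if (n_loci(xs) < 2) abort("fewer than 2 usable polymorphic loci after screening")
  if (n_indiv(xs) < 10) abort("fewer than 10 individuals")
  if (n_indiv(xs) < 30) warn("fewer than 30 individuals: estimate will be imprecise")

  ps <- pair_sums(xs$G)
  keep_pair <- rep(TRUE, length(ps$n))
  if (config$exclude_same_chromosome_pairs) {
    keep_pair <- xs$loci$chrom[ps$ia] != xs$loci$chrom[ps$ja]
  }
  rr <- r2_from_sums(ps$n, ps$Sx, ps$Sy, ps$Sxx, ps$Syy, ps$Sxy,
                     correct = config$small_sample_correction)
  use <- keep_pair & rr$valid
  if (!any(use)) abort("no usable locus pairs")

  w <- ps$n[use]
  mean_r2 <- sum(w * rr$r2[use]) / sum(w)
  mean_exp <- sum(w * expected_sample_r2(ps$n[use])) / sum(w)
  r2_drift <- mean_r2 - mean_exp
  S_harm <- length(w) / sum(1 / w)
  point <- ne_from_r2drift(r2_drift, S_harm)

  est <- structure(list(
    point = point,
    ci_lower = NA_real_, ci_upper = NA_real_,
    mean_r2 = mean_r2, expected_r2 = mean_exp, r2_drift = r2_drift,
    harmonic_mean_S = S_harm,
    n_individuals = n_indiv(xs),
    n_loci_used = n_loci(xs),
    n_loci_screened_out = n_screened_out,
    n_pairs_used = sum(use),
    n_pairs_skipped = sum(keep_pair & !rr$valid),
    ci_method = ci, ci_degenerate = FALSE,
    config = config
  ), class = "ldne_estimate")

  if (ci == "jackknife") {
    jk <- jackknife_ci_impl(xs, config, ps, rr, keep_pair, est)
    est$ci_lower <- jk$lower; est$ci_upper <- jk$upper
    est$ci_degenerate <- jk$degenerate
  }
  est
}

#' Jackknife confidence interval for the LD estimate
#'
#' Delete-one-individual jackknife on the weighted mean r2: the jackknife
#' variance of the drift r2 is converted to an effective chi-square degrees
#' of freedom n' = 2 (mean r2)^2 / Var, a CI for the mean r2 is formed from
#' the scaled chi-square, the sampling expectation is subtracted, and both
#' bounds are mapped through the (monotone decreasing) effective-size
#' transform. The upper bound is `Inf` whenever the lower drift bound is
#' non-positive. Deleting individuals rather than loci addresses the
#' pseudoreplication across the O(L^2) non-independent locus pairs.
#'
#' @param x A [geno_matrix()] (>= 3 individuals).
#' @param config An [estimator_config()]; `config$confidence` sets the level.
#' @return A list with `lower`, `upper` and `degenerate` (TRUE when all
#'   leave-one-out values coincide and the CI collapses to the point).
#' @export
jackknife_ci <- function(x, config = estimator_config()) {
  est <- estimate_raw(x, config, ci = "jackknife")
  list(lower = est$ci_lower, upper = est$ci_upper, degenerate = est$ci_degenerate)
}

jackknife_ci_impl <- function(xs, config, ps, rr, keep_pair, est) {
  n_ind <- n_indiv(xs)
  if (n_ind < 3) abort("jackknife requires at least 3 individuals")
  G <- xs$G
  use0 <- keep_pair & rr$valid
  ia <- ps$ia[use0]; ja <- ps$ja[use0]
  n0 <- ps$n[use0]; Sx0 <- ps$Sx[use0]; Sy0 <- ps$Sy[use0]
  Sxx0 <- ps$Sxx[use0]; Syy0 <- ps$Syy[use0]; Sxy0 <- ps$Sxy[use0]
  corr <- config$small_sample_correction

  drift_i <- numeric(n_ind)
  for (i in seq_len(n_ind)) {
    g <- as.numeric(G[i, ]); w <- as.numeric(!is.na(G[i, ])); g[is.na(g)] <- 0
    xa <- g[ia]; xb <- g[ja]; wa <- w[ia]; wb <- w[ja]
    both <- wa * wb
    n1 <- n0 - both
    rr1 <- r2_from_sums(n1,
                        Sx0 - xa * wb, Sy0 - wa * xb,
                        Sxx0 - xa * xa * wb, Syy0 - wa * xb * xb,
                        Sxy0 - xa * xb, correct = corr)
    ok <- rr1$valid
    w1 <- n1[ok]
    drift_i[i] <- sum(w1 * rr1$r2[ok]) / sum(w1) -
      sum(w1 * expected_sample_r2(n1[ok])) / sum(w1)
  }

  V <- (n_ind - 1) / n_ind * sum((drift_i - mean(drift_i))^2)
  # below numerical noise, all leave-one-out values coincide
  if (!is.finite(V) || sqrt(V) <= 1e-12 * abs(est$mean_r2)) {
    return(list(lower = est$point, upper = est$point, degenerate = TRUE))
  }
  mean_r2 <- est$mean_r2
  df <- max(2 * mean_r2^2 / V, 2)
  alpha <- 1 - config$confidence
  r2_lo <- df * mean_r2 / qchisq(1 - alpha / 2, df)
  r2_hi <- df * mean_r2 / qchisq(alpha / 2, df)
  lower <- ne_from_r2drift(r2_hi - est$expected_r2, est$harmonic_mean_S)
  upper <- ne_from_r2drift(r2_lo - est$expected_r2, est$harmonic_mean_S)
  list(lower = lower, upper = upper, degenerate = FALSE)
}

#' @export
print.ldne_estimate <- function(x, ...) {
  cat("<ldne_estimate>\n")
  cat(sprintf("  point estimate : %s\n", format_estimate(x$point)))
  cat(sprintf("  %d%% CI         : %s\n", round(100 * x$config$confidence),
              format_ci(x$ci_lower, x$ci_upper)))
  cat(sprintf("  mean r2 %.6f | E[r2|S] %.6f | drift r2 %.6g\n",
              x$mean_r2, x$expected_r2, x$r2_drift))
  cat(sprintf("  S (harmonic) %.1f | %d loci | %d pairs used | %d pairs skipped\n",
              x$harmonic_mean_S, x$n_loci_used, x$n_pairs_used, x$n_pairs_skipped))
  invisible(x)
}

#' Tidy an LD effective-size estimate
#'
#' @param x An `ldne_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the point estimate, CI bounds, and LD
#'   statistics.
#' @method tidy ldne_estimate
#' @export
tidy.ldne_estimate <- function(x, ...) {
  tibble(estimate = x$point, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         mean_r2 = x$mean_r2, expected_r2 = x$expected_r2,
         r2_drift = x$r2_drift, harmonic_mean_S = x$harmonic_mean_S)
}

#' @rdname tidy.ldne_estimate
#' @return `glance()`: a one-row tibble of bookkeeping counts.
#' @method glance ldne_estimate
#' @export
glance.ldne_estimate <- function(x, ...) {
  tibble(n_individuals = x$n_individuals, n_loci_used = x$n_loci_used,
         n_loci_screened_out = x$n_loci_screened_out,
         n_pairs_used = x$n_pairs_used, n_pairs_skipped = x$n_pairs_skipped,
         screening = x$config$screening,
         confidence = x$config$confidence,
         ci_degenerate = x$ci_degenerate)
}

#' Format a point estimate or CI the way effective-size tables print them
#'
#' Indeterminate (infinite) values print as `"inf"`; finite values are
#' rounded to the nearest integer.
#'
#' @param x Numeric scalar (possibly `Inf`).
#' @return A string.
#' @export
format_estimate <- function(x) {
  if (!is.finite(x)) "inf" else format(round(x), scientific = FALSE)
}

#' @rdname format_estimate
#' @param lower,upper CI bounds.
#' @export
format_ci <- function(lower, upper) {
  if (is.na(lower) || is.na(upper)) return("NA")
  paste0("(", format_estimate(lower), "–", format_estimate(upper), ")")
}
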