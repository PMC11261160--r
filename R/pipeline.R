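#' Read a pipeline run configuration
#'
#' YAML key-value configuration for the end-to-end runs. Recognised keys:
#' `input` (VCF/Genepop/TSV path), `format` (`vcf`/`genepop`/`tsv`,
#' inferred from the extension when absent), `cohort_type` (`single_cohort`
#' or `mixed_age`), `screening`, `pcrit`, `ratio_convention`, `mixed_mode`,
#' `alpha`, `longevity`, `adult_lifespan`, `chromosomes`, `max_missing`,
#' `drop_loci` (list of outlier locus ids), `raw_override` (list with
#' `point`, `ci_lower`, `ci_upper` — lets the adjustment calculus run
#' without genotypes), `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

resolve_reader <- function(input, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", basename(input)))
    format <- switch(ext,
                     vcf = "vcf", gen = "genepop", txt = "genepop",
                     genepop = "genepop", tsv = "tsv",
                     abort(paste0("cannot infer input format from: ", input)))
  }
  switch(format, vcf = read_vcf, genepop = read_genepop, tsv = read_geno_tsv,
         abort(paste0("unknown format: ", format)))
}

pipeline_lh <- function(cfg) {
  life_history(alpha = cfg$alpha %||% 5,
               longevity = cfg$longevity %||% 40,
               adult_lifespan = cfg$adult_lifespan %||% ((cfg$longevity %||% 40) - (cfg$alpha %||% 5)),
               chromosomes = cfg$chromosomes %||% 24)
}

#' Run the full effective-size estimation pipeline
#'
#' Filters (individual missingness, optional outlier-locus removal), allele
#' screening, the raw LD estimate with jackknife CI, and the adjustment
#' chain appropriate to the sample type: single-cohort samples go through
#' linkage, age-structure and Nb-to-Ne corrections; mixed-age samples
#' through linkage and the mixed-age correction. Writes a table-shaped TSV
#' (integer-rounded `point (lower–upper)` strings), a full-precision JSON
#' report embedding the resolved configuration and package version, and a
#' log of every factor applied.
#'
#' If `cfg$raw_override` is present the genotype stages are skipped and the
#' adjustment calculus runs on the supplied `point`/`ci_lower`/`ci_upper`.
#'
#' @param cfg A [read_run_config()] list (or plain named list).
#' @return Invisibly, a list with the `adjusted_estimate`, the raw estimate
#'   (or override), and the report paths.
#' @export
run_estimate <- function(cfg) {
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lh <- pipeline_lh(cfg)
  cohort_type <- cfg$cohort_type %||% "single_cohort"
  log_lines <- c(sprintf("ldne %s | run_estimate", as.character(utils::packageVersion("ldne"))),
                 sprintf("cohort_type: %s", cohort_type))

  if (!is.null(cfg$raw_override)) {
    raw <- list(point = as.numeric(cfg$raw_override$point),
                ci_lower = as.numeric(cfg$raw_override$ci_lower %||% NA),
                ci_upper = as.numeric(cfg$raw_override$ci_upper %||% NA))
    raw <- lapply(raw, function(v) if (identical(v, "inf")) Inf else v)
    log_lines <- c(log_lines, "raw estimate supplied by override; genotype stages skipped")
  } else {
    reader <- resolve_reader(cfg$input, cfg$format)
    g <- reader(cfg$input)
    log_lines <- c(log_lines, sprintf("input: %s (%d individuals x %d loci)",
                                      cfg$input, n_indiv(g), n_loci(g)))
    if (!is.null(cfg$drop_loci)) {
      g <- drop_loci(g, unlist(cfg$drop_loci))
      log_lines <- c(log_lines, sprintf("dropped %d outlier loci", length(unlist(cfg$drop_loci))))
    }
    g <- filter_individuals(g, cfg$max_missing %||% 0.20)
    fr <- filter_report(g)
    log_lines <- c(log_lines, sprintf("individual missingness filter removed %d",
                                      sum(fr$step == "individual_missingness")))
    ec <- estimator_config(screening = cfg$screening %||% "no_singletons",
                           pcrit = cfg$pcrit,
                           rng_seed = cfg$seed)
    est <- estimate_raw(g, ec)
    raw <- est
    log_lines <- c(log_lines, sprintf("raw estimate %s %s from %d loci, %d pairs",
                                      format_estimate(est$point),
                                      format_ci(est$ci_lower, est$ci_upper),
                                      est$n_loci_used, est$n_pairs_used))
  }

  adj <- if (cohort_type == "single_cohort") {
    adjust_cohort_estimate(raw, lh, cfg$ratio_convention %||% "longevity_over_alpha")
  } else {
    adjust_mixed_estimate(raw, lh, cfg$mixed_mode %||% "as_tables")
  }
  for (k in seq_len(nrow(adj$chain))) {
    log_lines <- c(log_lines, sprintf("stage %-5s factor %.6f -> %s",
                                      adj$chain$stage[k], adj$chain$factor[k],
                                      format_estimate(adj$chain$point[k])))
  }

  tsv_path <- file.path(out_dir, "estimate_report.tsv")
  json_path <- file.path(out_dir, "estimate_report.json")
  log_path <- file.path(out_dir, "estimate_report.log")
  readr::write_tsv(format_adjusted(adj, label = cfg$label %||% "sample"), tsv_path)
  report <- list(
    package = "ldne", version = as.character(utils::packageVersion("ldne")),
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    chain = lapply(seq_len(nrow(adj$chain)), function(k) {
      row <- adj$chain[k, ]
      list(stage = row$stage, point = inf_chr(row$point),
           lower = inf_chr(row$lower), upper = inf_chr(row$upper),
           factor = row$factor)
    })
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, log_path)
  invisible(list(adjusted = adj, raw = raw,
                 paths = c(tsv = tsv_path, json = json_path, log = log_path)))
}

inf_chr <- function(x) {
  if (is.na(x)) NULL else if (is.infinite(x)) "inf" else x
}

#' Simulate a dataset and write it to disk
#'
#' Delegates to the simulators and writes VCF + Genepop genotype files and a
#' TSV truth/pedigree summary.
#'
#' @param cfg Named list: `mode`, simulator fields accepted by
#'   [sim_config()], plus `sample_size` (and `sample_type` =
#'   `"yoy"`/`"mixed"` for age-structured), `seed`, `out_dir`.
#' @return Invisibly, the file paths and the truth tibble.
#' @export
run_simulate <- function(cfg) {
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  sim_fields <- intersect(names(cfg), names(formals(sim_config)))
  sc <- do.call(sim_config, cfg[sim_fields])
  if (sc$mode == "discrete_wf") {
    res <- simulate_discrete_wf(sc, sample_size = cfg$sample_size %||% 50, seed = seed)
    g <- res$sample; truth <- res$truth
  } else {
    state <- simulate_age_structured(sc, seed = seed)
    g <- if ((cfg$sample_type %||% "yoy") == "yoy") {
      sample_yoy_cohort(state, cfg$sample_size %||% 50, seed = seed)
    } else {
      sample_mixed_adults(state, cfg$sample_size %||% 50, seed = seed)
    }
    truth <- true_nb(state)
  }
  vcf_path <- file.path(out_dir, "simulated.vcf")
  gen_path <- file.path(out_dir, "simulated.gen")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_vcf(g, vcf_path)
  write_genepop(g, gen_path)
  readr::write_tsv(truth, truth_path)
  invisible(list(paths = c(vcf = vcf_path, genepop = gen_path, truth = truth_path),
                 truth = truth, sample = g))
}

#' Run the population-genetic summary pipeline
#'
#' Per-sample diversity (Ho/He/FIS), pairwise Weir-Cockerham FST with
#' permutation significance and BH correction (skipped with a warning when
#' only one population is present), and PCA scores with modal-genotype
#' imputation; each written as TSV.
#'
#' @param cfg Named list: `input`, `format`, `permutations`, `components`,
#'   `seed`, `out_dir`.
#' @return Invisibly, a list of the three result objects and file paths.
#' @export
run_summaries <- function(cfg) {
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reader <- resolve_reader(cfg$input, cfg$format)
  g <- reader(cfg$input)
  div <- diversity_summary(g)
  readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))

  fst <- NULL
  if (length(unique(g$individuals$pop)) >= 2) {
    fst <- pairwise_fst(g, permutations = cfg$permutations %||% 1000,
                        seed = cfg$seed %||% 1L)
    readr::write_tsv(tidy(fst), file.path(out_dir, "fst.tsv"))
  } else {
    warn("single population: FST skipped")
  }
  pca <- pca_imputed(g, components = cfg$components %||% 2)
  readr::write_tsv(as_tibble(pca), file.path(out_dir, "pca_scores.tsv"))
  invisible(list(diversity = div, fst = fst, pca = pca, out_dir = out_dir))
}
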