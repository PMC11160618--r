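# End-to-end orchestration: simulate -> QC -> haplotypes -> counts/GLM ->
# interference fits -> hierarchical MCMC, with a structured report.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes every stage in order and returns a structured report: marker-QC
#' summary, the segment/crossover identity check, the crossover-count deviance
#' table, inter-crossover distance summaries, map-length bootstrap,
#' maximum-likelihood interference fits (gamma and gamma-escape, pooled and
#' per genotype) with model comparison, and the hierarchical posterior with
#' genotype and age contrasts. When `out_dir` is given, all tables are written
#' as TSV together with a YAML manifest (seed, configuration, versions) from
#' which every number is recomputable.
#'
#' @param config a [sim_config]; default [demo_config].
#' @param out_dir optional output directory.
#' @param n_boot bootstrap replicates for the per-genotype gamma fits and the
#'   map-length bootstrap.
#' @param fit_escape also fit the gamma-escape model (slower; default `TRUE`).
#' @param mcmc_iterations,mcmc_burnin,mcmc_chains MCMC run length for the
#'   hierarchical stage (defaults are reduced relative to the full-scale
#'   25000/5000/4 analysis so the bundled configuration completes quickly).
#' @return List of class `xo_report`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL, n_boot = 200,
                         fit_escape = TRUE, mcmc_iterations = 4000,
                         mcmc_burnin = 1000, mcmc_chains = 2) {
  sim <- with_stage("simulate", simulate_cohort(config))
  qc <- with_stage("qc", qc_pipeline(sim$genotypes, sim$founders, sim$map,
                                     sim$meta))
  hap <- with_stage("infer", haplotype_pipeline(sim, qc,
                                                error_rate = 0.01))
  xo <- hap$xo
  counts <- with_stage("counts", count_table(xo, sim$meta))
  identity_check <- list(
    segments = nrow(hap$segments),
    individual_chromosomes = nrow(xo),
    crossovers = sum(n_crossovers(xo)),
    ok = nrow(hap$segments) - nrow(xo) == sum(n_crossovers(xo)))
  deviance <- with_stage("glm", poisson_glm_deviance(counts))
  distances <- with_stage("distances", distance_summaries(xo, sim$meta))
  map_len <- with_stage("map_length",
                        map_length_bootstrap(counts, n_boot = max(n_boot, 100),
                                             seed = config$seed))

  meta <- sim$meta
  meta$genotype <- paste(meta$maternal_strain, "x", meta$paternal_strain)
  by_geno <- split(meta$individual, meta$genotype)
  xo_of <- function(ids) {
    s <- xo[xo$individual %in% ids, , drop = FALSE]
    class(s) <- c("xo_data", "data.frame")
    s
  }
  fits <- with_stage("fit", {
    f <- list()
    f[["gamma.null"]] <- fit_gamma(xo)
    gamma_by <- lapply(by_geno, function(ids)
      fit_gamma(xo_of(ids), n_boot = n_boot, seed = config$seed))
    f[["gamma.full"]] <- pool_fits(gamma_by)
    f$gamma_by_genotype <- gamma_by
    if (fit_escape) {
      f[["gamma-escape.null"]] <- fit_gamma_escape(xo)
      escape_by <- lapply(by_geno, function(ids) fit_gamma_escape(xo_of(ids)))
      f[["gamma-escape.full"]] <- pool_fits(escape_by)
      f$escape_by_genotype <- escape_by
    }
    f
  })
  comparison <- with_stage("compare", compare_models(
    fits[intersect(c("gamma.null", "gamma.full", "gamma-escape.null",
                     "gamma-escape.full"), names(fits))]))

  groups <- with_stage("mcmc_groups", hier_groups(xo, sim$meta))
  spec <- hier_spec(k = length(groups$genotypes), iterations = mcmc_iterations,
                    burnin = mcmc_burnin, chains = mcmc_chains,
                    seed = config$seed)
  posterior <- with_stage("mcmc", run_mcmc(spec, groups))
  contrasts <- with_stage("contrasts", posterior_contrasts(posterior))

  report <- structure(list(
    config = config, qc_summary = qc$summary, identity = identity_check,
    counts = counts, deviance = deviance, distances = distances,
    map_length = map_len, fits = fits, comparison = comparison,
    posterior = posterior, contrasts = contrasts), class = "xo_report")
  if (!is.null(out_dir)) write_report(report, sim, out_dir)
  report
}

#' @export
print.xo_report <- function(x, ...) {
  cat("crossover interference pipeline report\n")
  cat(sprintf("  %d individuals, %d segments - %d chromosomes = %d crossovers (%s)\n",
              length(unique(x$counts$individual)), x$identity$segments,
              x$identity$individual_chromosomes, x$identity$crossovers,
              if (x$identity$ok) "identity holds" else "IDENTITY VIOLATED"))
  cat(sprintf("  mean crossovers per meiosis: %.2f (range %d - %d)\n",
              mean(x$counts$count), min(x$counts$count), max(x$counts$count)))
  cat(sprintf("  pooled gamma fit: nu = %.2f\n", x$fits[["gamma.null"]]$nu_hat))
  print(x$comparison)
  invisible(x)
}

write_report <- function(report, sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(report$qc_summary, "qc_summary.tsv")
  wt(report$counts, "crossover_counts.tsv")
  wt(report$deviance, "analysis_of_deviance.tsv")
  wt(report$distances, "intercrossover_distances.tsv")
  wt(report$map_length, "map_length.tsv")
  wt(report$comparison$models, "model_fits.tsv")
  wt(report$comparison$lrt, "model_lrt.tsv")
  nu_mle <- do.call(rbind, lapply(names(report$fits$gamma_by_genotype),
                                  function(g) {
    f <- report$fits$gamma_by_genotype[[g]]
    data.frame(genotype = g, nu = f$nu_hat, loglik = f$loglik,
               ci95_lo = if (!is.null(f$boot)) f$boot$ci95["nu", 1] else NA,
               ci95_hi = if (!is.null(f$boot)) f$boot$ci95["nu", 2] else NA)
  }))
  wt(nu_mle, "nu_mle_by_genotype.tsv")
  wt(report$posterior$nu_summary, "nu_posterior.tsv")
  wt(report$contrasts, "nu_contrasts.tsv")
  cfg <- report$config
  cfg$groups <- as.list(cfg$groups)
  manifest <- list(package = "xointer",
                   version = as.character(utils::packageVersion("xointer")),
                   r_version = R.version.string,
                   seed = report$config$seed,
                   config = unclass(cfg),
                   identity = report$identity[c("segments",
                                                "individual_chromosomes",
                                                "crossovers")])
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
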