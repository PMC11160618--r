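#!/usr/bin/env Rscript
# Stage 5: maximum-likelihood interference fits.
#
# Gamma and gamma-escape models, fit pooled ("null": one parameter set) and
# per genotype ("full"), with 200 individual-level bootstrap replicates for
# the per-genotype gamma fits (the full-scale analysis used 1000), AIC and
# likelihood-ratio comparisons of the nested model pairs.

library(xointer)

xo <- read_crossovers("results/crossovers.tsv")
meta <- read.csv("results/data/meta.csv")
meta$genotype <- paste(meta$maternal_strain, "x", meta$paternal_strain)
n_boot <- 200L

xo_of <- function(ids) {
  s <- xo[xo$individual %in% ids, , drop = FALSE]
  class(s) <- c("xo_data", "data.frame")
  s
}
by_geno <- split(meta$individual, meta$genotype)

message("pooled fits ...")
fits <- list("gamma.null" = fit_gamma(xo),
             "gamma-escape.null" = fit_gamma_escape(xo))
message("per-genotype fits (", n_boot, " bootstrap replicates each) ...")
gamma_by <- lapply(by_geno, function(ids)
  fit_gamma(xo_of(ids), n_boot = n_boot, seed = 11))
escape_by <- lapply(by_geno, function(ids) fit_gamma_escape(xo_of(ids)))
fits[["gamma.full"]] <- pool_fits(gamma_by)
fits[["gamma-escape.full"]] <- pool_fits(escape_by)

cmp <- compare_models(fits)
print(cmp)

per_geno <- do.call(rbind, lapply(names(gamma_by), function(g) {
  fg <- gamma_by[[g]]; fe <- escape_by[[g]]
  data.frame(genotype = g, nu_gamma = fg$nu_hat,
             ci95_lo = fg$boot$ci95["nu", 1], ci95_hi = fg$boot$ci95["nu", 2],
             ci50_lo = fg$boot$ci50["nu", 1], ci50_hi = fg$boot$ci50["nu", 2],
             nu_escape = fe$nu_hat, p_escape = fe$p_hat)
}))
message("interference by genotype:")
print(per_geno, row.names = FALSE)

write.table(cmp$models, "results/model_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cmp$lrt, "results/model_lrt.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(per_geno, "results/nu_mle_by_genotype.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
boot_reps <- do.call(rbind, lapply(names(gamma_by), function(g)
  data.frame(genotype = g, nu = gamma_by[[g]]$boot$replicates[, "nu"])))
write.table(boot_reps, "results/nu_bootstrap_replicates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/model_fits.tsv, model_lrt.tsv, nu_mle_by_genotype.tsv, ",
        "nu_bootstrap_replicates.tsv")
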