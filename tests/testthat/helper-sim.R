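# simulate a group of gamete chromosomes directly from the crossover process
# (bypassing genotyping), for likelihood and fitting tests
sim_xo_group <- function(n_ind, lengths_cM, nu, p = 0, prefix = "i") {
  rows <- vector("list", n_ind * length(lengths_cM))
  r <- 0L
  for (i in seq_len(n_ind)) for (cc in seq_along(lengths_cM)) {
    s <- xointer:::simulate_chrom_crossovers(lengths_cM[cc] / 100, nu, p)
    r <- r + 1L
    rows[[r]] <- list(paste0(prefix, "_", i), paste0("c", cc), lengths_cM[cc],
                      s$pos * 100)
  }
  xo_data(vapply(rows, `[[`, character(1), 1),
          vapply(rows, `[[`, character(1), 2),
          vapply(rows, function(z) z[[3]], numeric(1)),
          lapply(rows, `[[`, 4))
}

# tiny two-genotype x two-platform configuration for pipeline-level tests
mini_config <- function(n = 10L, nu = 11.3, seed = 42L,
                        lengths = c(90, 70, 50)) {
  g <- expand.grid(maternal = c("PWK", "WSB"), paternal = c("WSB", "PWK"),
                   age = c("young", "old"), stringsAsFactors = FALSE)
  g <- g[g$maternal != g$paternal, ]
  g$platform <- c("dense", "sparse", "dense", "sparse")
  g$nu <- nu
  g$p <- 0
  g$n <- as.integer(n)
  sim_config(chromosome_lengths = lengths, groups = g, seed = seed)
}
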