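#!/usr/bin/env Rscript
# Stage 4: crossover-count modelling — Poisson log-link analysis of deviance
# (genotype, age, genotype x age, in that order) and inter-crossover distance
# summaries by genotype.

library(xointer)

xo <- read_crossovers("results/crossovers.tsv")
meta <- read.csv("results/data/meta.csv")
counts <- read.delim("results/crossover_counts.tsv")

dev <- poisson_glm_deviance(counts)
message("analysis of deviance for crossover counts:")
print(dev, row.names = FALSE)
p_geno <- dev$p[dev$term == "genotype"]
message(sprintf("genotype heterogeneity: p = %.2g (likelihood-ratio test)",
                p_geno))

dist <- distance_summaries(xo, meta)
message("inter-crossover distances (cM), chromosomes with >= 2 crossovers:")
print(dist, row.names = FALSE)

write.table(dev, "results/analysis_of_deviance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dist, "results/intercrossover_distances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/analysis_of_deviance.tsv, intercrossover_distances.tsv")
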