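#!/usr/bin/env Rscript
# Stage 3: haplotype segments and crossovers from the two-state Viterbi HMM
# (1% assumed genotyping error, Haldane transitions), plus the count-level
# summaries: segment/crossover identity, map-length bootstrap.

library(xointer)

genotypes <- read.csv("results/data/genotypes.csv", check.names = FALSE)
founders <- read.csv("results/data/founders.csv")
map <- read.delim("results/data/map.tsv")
meta <- read.csv("results/data/meta.csv")

qc <- qc_pipeline(genotypes, founders, map, meta)
cohort <- list(genotypes = genotypes, map = map, meta = meta)
hap <- haplotype_pipeline(cohort, qc, error_rate = 0.01)

n_xo <- sum(n_crossovers(hap$xo))
message(sprintf("%d haplotype segments define %d crossovers in %d gamete chromosomes",
                nrow(hap$segments), n_xo, nrow(hap$xo)))
stopifnot(n_xo == nrow(hap$segments) - nrow(hap$xo))

counts <- count_table(hap$xo, meta)
message(sprintf("crossovers per meiosis: mean %.2f (range %d-%d)",
                mean(counts$count), min(counts$count), max(counts$count)))

ml <- map_length_bootstrap(counts, n_boot = 1000, seed = 1)
print(ml)

write.table(hap$segments, "results/segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_crossovers(hap$xo, "results/crossovers.tsv")
write.table(counts, "results/crossover_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ml, "results/map_length.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/segments.tsv, crossovers.tsv, crossover_counts.tsv, map_length.tsv")
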