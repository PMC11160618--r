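# Synthetic meioses with crossover interference.
#
# Chiasmata are placed along each chromosome by a stationary gamma renewal
# process (shape nu, rate 2*nu per Morgan: mean gap 0.5 Morgan) and thinned by
# 1/2 to give transmitted crossovers, optionally superposed with a Poisson
# "escape" pathway carrying a proportion p of crossovers. Offspring are then
# genotyped in silico at map markers with a configurable error rate, emulating
# N2 progeny of F1 hybrid males on two array densities.

#' Default autosome lengths
#'
#' Nineteen genetic lengths decreasing from about 90 to about 40 cM and
#' summing to exactly 1230 cM, so that the expected number of transmitted
#' crossovers per meiosis is 12.3.
#'
#' @return Numeric vector of 19 lengths in cM.
#' @export
default_chromosome_lengths <- function() {
  x <- seq(90, 40, length.out = 19)
  x * 1230 / sum(x)
}

#' Default group table: a reference diallel-style breeding design
#'
#' The six reciprocal F1 genotypes between three wild-derived strains, split
#' by paternal age cohort and array platform, 503 offspring in total.
#' Interference defaults to the literature value nu = 11.3 for male mice,
#' with no escape pathway.
#'
#' @param nu interference strength assigned to every group.
#' @param p escape proportion assigned to every group.
#' @return Data frame with columns `maternal`, `paternal`, `age`, `platform`,
#'   `nu`, `p`, `n`.
#' @export
study_design <- function(nu = 11.3, p = 0) {
  g <- rbind(
    data.frame(maternal = "PWK",  paternal = "WSB",  age = "young", platform = "dense",  n = 14L),
    data.frame(maternal = "CAST", paternal = "WSB",  age = "young", platform = "sparse", n = 8L),
    data.frame(maternal = "PWK",  paternal = "WSB",  age = "old",   platform = "dense",  n = 12L),
    data.frame(maternal = "CAST", paternal = "WSB",  age = "old",   platform = "sparse", n = 52L),
    data.frame(maternal = "WSB",  paternal = "PWK",  age = "young", platform = "dense",  n = 48L),
    data.frame(maternal = "CAST", paternal = "PWK",  age = "young", platform = "dense",  n = 9L),
    data.frame(maternal = "WSB",  paternal = "PWK",  age = "old",   platform = "dense",  n = 47L),
    data.frame(maternal = "CAST", paternal = "PWK",  age = "old",   platform = "dense",  n = 7L),
    data.frame(maternal = "CAST", paternal = "PWK",  age = "old",   platform = "sparse", n = 45L),
    data.frame(maternal = "PWK",  paternal = "CAST", age = "young", platform = "dense",  n = 105L),
    data.frame(maternal = "WSB",  paternal = "CAST", age = "young", platform = "sparse", n = 31L),
    data.frame(maternal = "PWK",  paternal = "CAST", age = "old",   platform = "dense",  n = 75L),
    data.frame(maternal = "WSB",  paternal = "CAST", age = "old",   platform = "sparse", n = 11L),
    data.frame(maternal = "PWK",  paternal = "CAST", age = "old",   platform = "sparse", n = 39L))
  g$nu <- nu
  g$p <- p
  g
}

#' Simulation configuration
#'
#' @param chromosome_lengths genetic lengths in cM, one per autosome.
#' @param groups data frame with columns `maternal`, `paternal`, `age`,
#'   `platform`, `nu`, `p`, `n` (offspring per group); defaults to
#'   [study_design].
#' @param error_rate genotyping error probability per marker call.
#' @param missing_rate probability a call is set missing (arrays typically
#'   achieve ~99.8% genotyping rates, hence the 0.002 default).
#' @param noninformative_rate fraction of markers at which the founder strains
#'   carry the same allele.
#' @param marker_spacing named vector, mean inter-marker distance in cM for
#'   the `dense` and `sparse` platforms.
#' @param shared_fraction fraction of sparse-platform markers that also exist
#'   on the dense platform.
#' @param seed integer RNG seed; per-offspring substreams are derived from it
#'   so that changing `n` does not reshuffle earlier individuals.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(chromosome_lengths = default_chromosome_lengths(),
                       groups = study_design(),
                       error_rate = 0.01,
                       missing_rate = 0.002,
                       noninformative_rate = 0.05,
                       marker_spacing = c(dense = 0.5, sparse = 2.0),
                       shared_fraction = 0.3,
                       seed = 1L) {
  stopifnot(length(chromosome_lengths) >= 1,
            all(is.finite(chromosome_lengths)), all(chromosome_lengths > 0),
            is.data.frame(groups), nrow(groups) >= 1,
            all(c("maternal", "paternal", "age", "platform", "nu", "p", "n")
                %in% names(groups)),
            all(groups$nu > 0), all(groups$p >= 0), all(groups$p < 1),
            all(groups$n >= 1),
            error_rate >= 0, error_rate < 0.5,
            missing_rate >= 0, missing_rate < 1,
            all(c("dense", "sparse") %in% names(marker_spacing)),
            all(marker_spacing > 0))
  key <- paste(groups$maternal, groups$paternal, groups$age, groups$platform)
  if (anyDuplicated(key)) stop("group labels must be unique")
  structure(list(chromosome_lengths = as.numeric(chromosome_lengths),
                 groups = groups, error_rate = error_rate,
                 missing_rate = missing_rate,
                 noninformative_rate = noninformative_rate,
                 marker_spacing = marker_spacing,
                 shared_fraction = shared_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' A small two-genotype, two-age configuration
#'
#' Convenience configuration used by the worked examples and the end-to-end
#' pipeline demonstration: two reciprocal genotypes crossed at both ages, 50
#' offspring per cell (200 in total), true interference differing by genotype
#' and weakened in old males.
#'
#' @param seed RNG seed.
#' @return A [sim_config].
#' @export
demo_config <- function(seed = 1L) {
  g <- expand.grid(maternal = c("PWK", "WSB"), paternal = c("WSB", "PWK"),
                   age = c("young", "old"), stringsAsFactors = FALSE)
  g <- g[g$maternal != g$paternal, ]
  g$platform <- "dense"
  g$nu <- ifelse(g$maternal == "PWK", 14, 10) / ifelse(g$age == "old", 1.2, 1)
  g$p <- 0
  g$n <- 50L
  sim_config(groups = g, seed = seed)
}

#' Simulate chiasma positions by a stationary gamma renewal process
#'
#' Inter-event distances are gamma(shape `nu`, rate `chiasma_rate`) with the
#' default rate `2 nu` per Morgan (mean gap 0.5 Morgan). The first event is
#' drawn from the equilibrium (residual-life) distribution, sampled exactly as
#' `U * G` with `U ~ Uniform(0,1)` and `G` a length-biased gap, i.e.
#' gamma(shape `nu + 1`, same rate), so no burn-in is needed.
#'
#' @param length_morgans length of the interval (Morgans, > 0).
#' @param nu gamma shape (> 0).
#' @param chiasma_rate gamma rate per Morgan (default `2 * nu`).
#' @return Increasing vector of event positions in Morgans on `[0, length]`.
#' @export
simulate_chiasmata <- function(length_morgans, nu, chiasma_rate = 2 * nu) {
  if (!is.finite(length_morgans) || length_morgans <= 0)
    stop("length_morgans must be positive")
  if (!is.finite(nu) || nu <= 0) stop("nu must be positive")
  pos <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, rate = chiasma_rate)
  if (pos > length_morgans) return(numeric(0))
  out <- pos
  # draw gaps in blocks sized from the expected count
  block <- max(16L, ceiling(1.5 * length_morgans * chiasma_rate / nu))
  repeat {
    gaps <- stats::rgamma(block, shape = nu, rate = chiasma_rate)
    pos <- pos + cumsum(gaps)
    keep <- pos <= length_morgans
    out <- c(out, pos[keep])
    if (!all(keep)) break
    pos <- pos[length(pos)]
  }
  out
}

#' Thin chiasmata to transmitted crossovers
#'
#' Each chiasma on the four-strand bundle involves two of the four chromatids,
#' so it appears in a given gamete with probability 1/2, independently.
#'
#' @param chiasmata sorted positions.
#' @return The retained positions, order preserved.
#' @export
thin_to_crossovers <- function(chiasmata) {
  if (length(chiasmata) == 0L) return(chiasmata)
  if (is.unsorted(chiasmata)) stop("chiasma positions must be sorted")
  chiasmata[stats::runif(length(chiasmata)) < 0.5]
}

#' Simulate the non-interfering (escape) crossover pathway
#'
#' A homogeneous Poisson process with intensity `p` per Morgan. When combined
#' with an interfering pathway whose chiasma rate is scaled to `2 nu (1 - p)`
#' (then thinned by 1/2), the total crossover intensity stays at 1 per Morgan.
#'
#' @param length_morgans interval length (Morgans).
#' @param p escape proportion in `[0, 1)`.
#' @return Increasing vector of positions in Morgans.
#' @export
simulate_escape_pathway <- function(length_morgans, p) {
  if (!is.finite(length_morgans) || length_morgans <= 0)
    stop("length_morgans must be positive")
  if (!is.finite(p) || p < 0 || p >= 1) stop("p must be in [0, 1)")
  if (p == 0) return(numeric(0))
  n <- stats::rpois(1, p * length_morgans)
  sort(stats::runif(n, 0, length_morgans))
}

# one gamete chromosome: crossover positions (Morgans) and pathway labels
simulate_chrom_crossovers <- function(length_morgans, nu, p = 0) {
  xo_int <- thin_to_crossovers(
    simulate_chiasmata(length_morgans, nu, chiasma_rate = 2 * nu * (1 - p)))
  xo_esc <- simulate_escape_pathway_or_empty(length_morgans, p)
  pos <- c(xo_int, xo_esc)
  path <- rep(c("interfering", "escape"), c(length(xo_int), length(xo_esc)))
  o <- order(pos)
  pos <- pos[o]
  path <- path[o]
  # ties have probability zero; nudge apart if floating point produces one
  while (anyDuplicated(pos)) {
    i <- which(duplicated(pos))
    pos[i] <- pos[i] * (1 + .Machine$double.eps) + .Machine$double.xmin
  }
  list(pos = pos, pathway = path)
}

simulate_escape_pathway_or_empty <- function(length_morgans, p) {
  if (p == 0) return(numeric(0))
  simulate_escape_pathway(length_morgans, p)
}

# deterministic per-offspring RNG substream, independent of group sizes
offspring_seed <- function(seed, group_index, offspring_index) {
  (((seed %% 65011) * 32771 + group_index * 10007 + offspring_index * 101) %%
     2147483629L) + 1L
}

# marker map for both platforms over the configured chromosomes; physical
# positions are synthetic at 2 Mb per cM
build_marker_map <- function(config) {
  maps <- lapply(seq_along(config$chromosome_lengths), function(cc) {
    L <- config$chromosome_lengths[cc]
    sd_ <- config$marker_spacing[["dense"]]
    ss_ <- config$marker_spacing[["sparse"]]
    dense <- seq(sd_ / 2, L, by = sd_)
    sparse <- seq(ss_ / 2, L, by = ss_) + 0.21 * sd_
    sparse <- sparse[sparse < L]
    # a fraction of sparse markers coincide with (are shared with) dense ones
    if (config$shared_fraction > 0 && length(sparse) > 0) {
      step <- max(1L, round(1 / config$shared_fraction))
      shared_idx <- seq(1L, length(sparse), by = step)
      sparse[shared_idx] <- dense[pmin(length(dense),
                                       vapply(sparse[shared_idx], function(x)
                                         which.min(abs(dense - x)), integer(1)))]
    }
    shared <- intersect(dense, sparse)
    chrom <- paste0("chr", cc)
    m <- rbind(
      data.frame(chrom = chrom, cM = setdiff(dense, shared), platform = "dense"),
      data.frame(chrom = chrom, cM = setdiff(sparse, shared), platform = "sparse"),
      if (length(shared)) data.frame(chrom = chrom, cM = shared,
                                     platform = "both"))
    m <- m[order(m$cM), , drop = FALSE]
    m$marker <- sprintf("%s_m%04d", chrom, seq_len(nrow(m)))
    m$bp <- as.integer(round(m$cM * 2e6))
    m[, c("marker", "chrom", "bp", "cM", "platform")]
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

#' Simulate a full genotyped cohort
#'
#' For each group in the configuration, simulates `n` offspring: per
#' chromosome, crossovers from the configured `(nu, p)`; a transmitted
#' haplotype origin (grandparent A = the maternal strain of the F1 sire,
#' grandparent B = the paternal strain) that starts at random and alternates
#' at every crossover; and marker genotypes on the group's platform, flipped
#' with probability `error_rate` and set missing with `missing_rate`. Calls
#' are coded as the transmitted paternal allele: 0 = reference (grandparent
#' A / first-listed founder), 2 = alternate (grandparent B). Fully
#' reproducible from the seed; each offspring has its own derived RNG
#' substream.
#'
#' @param config a [sim_config].
#' @return List of class `sim_cohort` with elements `config`, `map`,
#'   `founders`, `genotypes`, `meta`, `truth_segments`, `truth_xo` (an
#'   [xo_data] of true crossovers on the full chromosomes) and
#'   `truth_pathway`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$groups) == 0L) stop("empty group table")
  set.seed(config$seed)
  map <- build_marker_map(config)
  informative <- stats::runif(nrow(map)) >= config$noninformative_rate
  founders <- data.frame(marker = map$marker,
                         founder_a = 0L,
                         founder_b = ifelse(informative, 2L, 0L))
  chrom_labels <- paste0("chr", seq_along(config$chromosome_lengths))
  L_cM <- config$chromosome_lengths

  geno_cols <- list()
  meta <- list()
  seg_rows <- list()
  xo_rows <- list()
  path_rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    marker_sel <- map$platform %in% c(grp$platform, "both")
    msub <- map[marker_sel, , drop = FALSE]
    for (j in seq_len(grp$n)) {
      idx <- idx + 1L
      id <- sprintf("N2_%04d", idx)
      set.seed(offspring_seed(config$seed, g, j))
      calls <- rep(NA_integer_, nrow(map))
      for (cc in seq_along(L_cM)) {
        sim <- simulate_chrom_crossovers(L_cM[cc] / 100, grp$nu, grp$p)
        pos_cM <- sim$pos * 100
        start_origin <- if (stats::runif(1) < 0.5) 0L else 1L
        # segments: origin alternates at each crossover
        bounds <- c(0, pos_cM, L_cM[cc])
        origins <- (start_origin + seq_len(length(pos_cM) + 1L) - 1L) %% 2L
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          individual = id, chrom = chrom_labels[cc],
          start_cM = bounds[-length(bounds)], end_cM = bounds[-1],
          origin = ifelse(origins == 0L, "A", "B"))
        xo_rows[[length(xo_rows) + 1L]] <- data.frame(
          individual = id, chrom = chrom_labels[cc], L_cM = L_cM[cc],
          positions = I(list(pos_cM)))
        if (grp$p > 0 && length(pos_cM))
          path_rows[[length(path_rows) + 1L]] <- data.frame(
            individual = id, chrom = chrom_labels[cc], pos_cM = pos_cM,
            pathway = sim$pathway)
        # genotype the markers of this chromosome on the group's platform
        mi <- which(marker_sel & map$chrom == chrom_labels[cc])
        if (length(mi)) {
          n_before <- findInterval(map$cM[mi], pos_cM)
          origin <- (start_origin + n_before) %% 2L
          call <- ifelse(informative[mi], origin * 2L, 0L)
          flip <- stats::runif(length(mi)) < config$error_rate
          call[flip] <- 2L - call[flip]
          call[stats::runif(length(mi)) < config$missing_rate] <- NA_integer_
          calls[mi] <- call
        }
      }
      geno_cols[[id]] <- calls
      meta[[idx]] <- data.frame(individual = id, maternal_strain = grp$maternal,
                                paternal_strain = grp$paternal, age = grp$age,
                                platform = grp$platform)
    }
  }
  genotypes <- cbind(map[, c("marker", "chrom", "cM", "bp")],
                     as.data.frame(geno_cols, check.names = FALSE))
  truth_segments <- do.call(rbind, seg_rows)
  xo_df <- do.call(rbind, xo_rows)
  truth_xo <- xo_data(xo_df$individual, xo_df$chrom, xo_df$L_cM, xo_df$positions)
  structure(list(config = config, map = map, founders = founders,
                 genotypes = genotypes, meta = do.call(rbind, meta),
                 truth_segments = truth_segments, truth_xo = truth_xo,
                 truth_pathway = if (length(path_rows))
                   do.call(rbind, path_rows) else NULL),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("simulated cohort:", nrow(x$meta), "offspring,",
      length(x$config$chromosome_lengths), "chromosomes,",
      nrow(x$map), "markers;",
      sum(n_crossovers(x$truth_xo)), "true crossovers\n")
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Emits the genotype table (CSV: marker, chrom, cM, bp, one column per
#' individual), founder genotypes (CSV), marker map (TSV), metadata (CSV),
#' truth segments (BED-like TSV), truth crossovers (TSV) and the configuration
#' (YAML).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$genotypes, file.path(dir, "genotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$founders, file.path(dir, "founders.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$map, file.path(dir, "map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.table(cohort$truth_segments, file.path(dir, "truth_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_crossovers(cohort$truth_xo, file.path(dir, "truth_crossovers.tsv"))
  cfg <- cohort$config
  cfg$groups <- as.list(cfg$groups)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
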