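# Crossover-count statistics: chi-square tails, Poisson analysis of deviance,
# inter-crossover distance summaries, and the map-length bootstrap.

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution, computed through the
#' log-space regularized incomplete gamma function so that far-tail values
#' (p ~ 1e-13 and below) keep full relative accuracy.
#'
#' @param x test statistic (non-negative).
#' @param df degrees of freedom (positive integer).
#' @return Upper-tail probability.
#' @export
chisq_sf <- function(x, df) {
  stopifnot(is.finite(x), x >= 0, is.finite(df), df >= 1, df == as.integer(df))
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Build the crossover count table
#'
#' One row per offspring: total autosomal crossovers plus genotype and age
#' labels from the metadata.
#'
#' @param xo an [xo_data] object.
#' @param meta data frame with columns `individual`, `maternal_strain`,
#'   `paternal_strain`, `age` (and optionally `platform`).
#' @return Data frame of class `count_table` with columns `individual`,
#'   `count`, `genotype`, `age`.
#' @export
count_table <- function(xo, meta) {
  stopifnot(all(c("individual", "maternal_strain", "paternal_strain", "age")
                %in% names(meta)))
  counts <- n_crossovers(xo, by = "individual")
  m <- meta[match(names(counts), meta$individual), , drop = FALSE]
  if (anyNA(m$individual))
    stop("missing metadata for: ",
         paste(names(counts)[is.na(m$individual)], collapse = ", "))
  out <- data.frame(individual = names(counts), count = as.integer(counts),
                    genotype = paste(m$maternal_strain, "x", m$paternal_strain),
                    age = m$age, row.names = NULL)
  class(out) <- c("count_table", "data.frame")
  out
}

#' Sequential (Type-I) analysis of deviance for crossover counts
#'
#' Fits a generalized linear model with Poisson response and log link to the
#' per-meiosis crossover counts, with terms added in the order genotype, age,
#' genotype-by-age, and reports the sequential deviance decomposition with
#' chi-square (likelihood-ratio) p-values, plus the null-model residual row.
#'
#' @param counts a [count_table] (columns `count`, `genotype`, `age`).
#' @return Data frame of class `deviance_table` with columns `term`, `df`,
#'   `deviance`, `resid_df`, `resid_deviance`, `p`.
#' @export
poisson_glm_deviance <- function(counts) {
  stopifnot(all(c("count", "genotype", "age") %in% names(counts)))
  counts$genotype <- factor(counts$genotype)
  counts$age <- factor(counts$age)
  if (nlevels(counts$genotype) < 2) stop("need at least 2 genotypes")
  if (nlevels(counts$age) < 2) stop("need both age cohorts")
  fit <- stats::glm(count ~ genotype * age, family = stats::poisson(),
                    data = counts)
  an <- stats::anova(fit, test = "Chisq")
  terms <- rownames(an)[-1]
  out <- data.frame(term = c(sub(":", " x ", terms, fixed = TRUE), "residuals"),
                    df = c(an$Df[-1], NA),
                    deviance = c(an$Deviance[-1], NA),
                    resid_df = c(an$`Resid. Df`[-1], an$`Resid. Df`[1]),
                    resid_deviance = c(an$`Resid. Dev`[-1], an$`Resid. Dev`[1]),
                    p = c(an$`Pr(>Chi)`[-1], NA), row.names = NULL)
  class(out) <- c("deviance_table", "data.frame")
  out
}

#' Inter-crossover distance summaries by genotype
#'
#' Distances between successive crossovers on the genetic scale, restricted to
#' chromosomes carrying at least two crossovers, summarized per genotype
#' (mean, median and the 2.5/25/75/97.5 percentiles, in cM). Groups without a
#' multi-crossover chromosome get a row of `NA`.
#'
#' @inheritParams count_table
#' @return Data frame with one row per genotype and columns `genotype`, `n`,
#'   `mean`, `median`, `q2.5`, `q25`, `q75`, `q97.5`.
#' @export
distance_summaries <- function(xo, meta) {
  m <- meta[match(xo$individual, meta$individual), , drop = FALSE]
  genotype <- paste(m$maternal_strain, "x", m$paternal_strain)
  gaps <- lapply(xo$positions_cM, function(p) if (length(p) >= 2) diff(p)
                 else numeric(0))
  glab <- rep(genotype, vapply(gaps, length, integer(1)))
  d <- unlist(gaps, use.names = FALSE)
  out <- do.call(rbind, lapply(sort(unique(genotype)), function(g) {
    x <- d[glab == g]
    if (length(x) == 0L)
      return(data.frame(genotype = g, n = 0L, mean = NA_real_,
                        median = NA_real_, q2.5 = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, q97.5 = NA_real_))
    q <- stats::quantile(x, c(0.025, 0.25, 0.75, 0.975), names = FALSE)
    data.frame(genotype = g, n = length(x), mean = mean(x),
               median = stats::median(x), q2.5 = q[1], q25 = q[2], q75 = q[3],
               q97.5 = q[4])
  }))
  rownames(out) <- NULL
  out
}

#' Bootstrap estimate of autosomal map length by genotype
#'
#' The expected number of crossovers transmitted per gamete equals the map
#' length in Morgans, so map length is estimated as `100 x mean crossover
#' count` (cM), with individual-level bootstrap percentile intervals.
#'
#' @param counts a [count_table].
#' @param n_boot bootstrap replicates (warns below 100).
#' @param seed RNG seed.
#' @return Data frame with columns `genotype`, `n`, `map_length_cM`, `ci95_lo`,
#'   `ci95_hi`, `ci50_lo`, `ci50_hi`.
#' @export
map_length_bootstrap <- function(counts, n_boot = 1000, seed = NULL) {
  stopifnot(all(c("count", "genotype") %in% names(counts)))
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(sort(unique(counts$genotype)), function(g) {
    x <- counts$count[counts$genotype == g]
    if (length(x) < 2) stop("need >= 2 individuals per genotype (", g, ")")
    reps <- vapply(seq_len(n_boot),
                   function(b) 100 * mean(sample(x, replace = TRUE)),
                   numeric(1))
    q <- stats::quantile(reps, c(0.025, 0.975, 0.25, 0.75), names = FALSE)
    data.frame(genotype = g, n = length(x), map_length_cM = 100 * mean(x),
               ci95_lo = q[1], ci95_hi = q[2], ci50_lo = q[3], ci50_hi = q[4])
  }))
  rownames(out) <- NULL
  out
}
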