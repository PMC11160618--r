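test_that("chi-square tail matches closed forms to high precision", {
  expect_equal(chisq_sf(0, 3), 1)
  # df = 1: 2 * Phi(-sqrt(x))
  for (x in c(0.5, 3.23, 10, 40))
    expect_equal(chisq_sf(x, 1), 2 * pnorm(-sqrt(x)), tolerance = 1e-13)
  # even df: finite Poisson sum exp(-x/2) sum_{j<df/2} (x/2)^j / j!
  for (df in c(2, 6, 10)) for (x in c(1, 15, 70.7)) {
    j <- 0:(df / 2 - 1)
    expect_equal(chisq_sf(x, df), sum(exp(-x / 2 + j * log(x / 2) -
                                            lfactorial(j))),
                 tolerance = 1e-12)
  }
  expect_error(chisq_sf(1, 0), "df")
  expect_error(chisq_sf(-1, 2))
})

test_that("count table joins metadata and validates completeness", {
  xo <- xo_data(c("a", "a", "b"), c("c1", "c2", "c1"), c(90, 70, 90),
                list(c(30, 60), 40, numeric(0)))
  meta <- data.frame(individual = c("a", "b"),
                     maternal_strain = c("P", "W"),
                     paternal_strain = c("W", "P"),
                     age = c("young", "old"))
  ct <- count_table(xo, meta)
  expect_equal(ct$count[ct$individual == "a"], 3L)
  expect_equal(ct$count[ct$individual == "b"], 0L)
  expect_equal(ct$genotype, c("P x W", "W x P"))
  expect_error(count_table(xo, meta[1, ]), "missing metadata")
})

test_that("analysis of deviance matches a hand-rolled IRLS oracle", {
  counts <- data.frame(
    count = c(10L, 12L, 14L, 8L, 9L, 13L, 11L, 7L),
    genotype = rep(c("g1", "g2"), each = 4),
    age = rep(c("young", "young", "old", "old"), 2))
  # independent IRLS for a Poisson log-link fit
  irls <- function(X, y) {
    beta <- rep(0, ncol(X))
    for (it in 1:50) {
      mu <- exp(drop(X %*% beta))
      z <- drop(X %*% beta) + (y - mu) / mu
      beta <- solve(crossprod(X, mu * X), crossprod(X, mu * z))
    }
    exp(drop(X %*% beta))
  }
  dev <- function(y, mu) 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  y <- counts$count
  X0 <- matrix(1, length(y))
  Xg <- model.matrix(~genotype, counts)
  Xga <- model.matrix(~genotype + age, counts)
  Xfull <- model.matrix(~genotype * age, counts)
  d <- vapply(list(X0, Xg, Xga, Xfull), function(X) dev(y, irls(X, y)),
              numeric(1))
  tab <- poisson_glm_deviance(counts)
  expect_equal(tab$deviance[1:3], -diff(d), tolerance = 1e-8)
  expect_equal(tab$resid_deviance[1:3], d[2:4], tolerance = 1e-8)
  expect_equal(tab$resid_deviance[tab$term == "residuals"], d[1],
               tolerance = 1e-8)
  # term deviances sum to null minus final residual deviance
  expect_equal(sum(tab$deviance[1:3]), d[1] - d[4], tolerance = 1e-8)
  # residual deviance is non-increasing down the table
  expect_true(all(diff(tab$resid_deviance[1:3]) <= 1e-12))
  # p-values are the chi-square upper tails of the deviance drops
  expect_equal(tab$p[1], chisq_sf(tab$deviance[1], tab$df[1]),
               tolerance = 1e-12)
})

test_that("identical count distributions give zero genotype deviance", {
  counts <- data.frame(count = rep(c(5L, 9L, 12L, 14L), 2),
                       genotype = rep(c("g1", "g2"), each = 4),
                       age = rep(c("young", "old"), 4))
  tab <- poisson_glm_deviance(counts)
  expect_equal(tab$deviance[tab$term == "genotype"], 0, tolerance = 1e-10)
  expect_error(poisson_glm_deviance(counts[counts$genotype == "g1", ]),
               "2 genotypes")
  expect_error(poisson_glm_deviance(transform(counts, age = "young")),
               "age")
})

test_that("null-model p-values are approximately uniform", {
  set.seed(61)
  pvals <- vapply(seq_len(200), function(i) {
    counts <- data.frame(count = rpois(80, 12),
                         genotype = rep(c("g1", "g2"), 40),
                         age = rep(c("young", "old"), each = 40))
    poisson_glm_deviance(counts)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, punif))$p.value, 0.01)
})

test_that("inter-crossover distance summaries mirror their definitions", {
  xo <- xo_data(c("a", "a", "b"), c("c1", "c2", "c1"), c(90, 80, 100),
                list(c(20, 60), c(10), c(5, 15, 35, 65)))
  meta <- data.frame(individual = c("a", "b"),
                     maternal_strain = c("P", "W"),
                     paternal_strain = c("W", "P"), age = "young")
  ds <- distance_summaries(xo, meta)
  a <- ds[ds$genotype == "P x W", ]
  expect_equal(a$n, 1L)              # single multi-crossover chromosome
  expect_equal(unlist(a[c("mean", "median", "q2.5", "q25", "q75", "q97.5")]),
               rep(40, 6), ignore_attr = TRUE)
  b <- ds[ds$genotype == "W x P", ]  # distances 10, 20, 30
  expect_equal(b$mean, 20)
  expect_equal(b$median, 20)

  # group with no multi-crossover chromosome: row of NA
  xo1 <- xo_data("c", "c1", 90, list(numeric(0)))
  meta1 <- data.frame(individual = "c", maternal_strain = "C",
                      paternal_strain = "P", age = "old")
  expect_true(all(is.na(distance_summaries(xo1, meta1)[, -(1:2)])))
})

test_that("simulated distances match the length-censored renewal mean", {
  set.seed(62)
  xo <- sim_xo_group(40, default_chromosome_lengths(), 11.3)
  meta <- data.frame(individual = unique(xo$individual),
                     maternal_strain = "P", paternal_strain = "W",
                     age = "young")
  ds <- distance_summaries(xo, meta)
  # oracle: a gap of size y fits a window of length L at rate (L - y) f*(y),
  # so the observed mean is the (L - y)-weighted mean of f*, summed over
  # chromosomes; censoring pulls it below the unconditional 50 cM
  wnum <- wden <- 0
  for (L in default_chromosome_lengths() / 100) {
    wnum <- wnum + integrate(function(y)
      y * interarrival_density(y, 11.3) * (L - y), 0, L)$value
    wden <- wden + integrate(function(y)
      interarrival_density(y, 11.3) * (L - y), 0, L)$value
  }
  oracle_cM <- 100 * wnum / wden
  gaps <- unlist(lapply(xo$positions_cM, function(p)
    if (length(p) >= 2) diff(p) else numeric(0)))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(ds$mean - oracle_cM), 3 * se)
  expect_gt(ds$mean, 35)
  expect_lt(ds$mean, 60)
})

test_that("map length is 100 x mean crossover count with bootstrap intervals", {
  counts <- data.frame(count = rep(12L, 30), genotype = "g1", age = "young")
  ml <- map_length_bootstrap(counts, n_boot = 200, seed = 1)
  expect_equal(ml$map_length_cM, 1200)
  expect_equal(ml$ci95_lo, 1200)
  expect_equal(ml$ci95_hi, 1200)
  expect_warning(map_length_bootstrap(counts, n_boot = 50, seed = 1),
                 "100 bootstrap")

  set.seed(63)
  xo <- sim_xo_group(300, default_chromosome_lengths(), 11.3)
  cnt <- data.frame(count = as.integer(n_crossovers(xo, "individual")),
                    genotype = "g1", age = "young")
  ml2 <- map_length_bootstrap(cnt, n_boot = 200, seed = 2)
  expect_lt(abs(ml2$map_length_cM - 1230), 40)

  # intervals widen as individuals get scarcer
  widths <- vapply(c(200, 50, 10), function(n) {
    m <- map_length_bootstrap(cnt[seq_len(n), ], n_boot = 400, seed = 3)
    m$ci95_hi - m$ci95_lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
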