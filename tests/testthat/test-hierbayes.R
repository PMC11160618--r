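test_that("HPDI equals the brute-force shortest window", {
  brute_hpdi <- function(x, mass) {
    x <- sort(x)
    n <- length(x)
    m <- ceiling(mass * n)
    best <- c(-Inf, Inf)
    for (i in seq_len(n - m + 1))
      if (x[i + m - 1] - x[i] < diff(best)) best <- c(x[i], x[i + m - 1])
    best
  }
  expect_equal(hpdi(1:100, 0.95), brute_hpdi(1:100, 0.95))
  expect_equal(hpdi(1:100, 0.95), c(1, 95))
  set.seed(51)
  for (rep in 1:5) {
    x <- rlnorm(500, 0, sample(c(0.3, 1), 1))
    for (mass in c(0.5, 0.95))
      expect_equal(hpdi(x, mass), brute_hpdi(x, mass))
  }
  # right-skewed: HPDI upper bound below the equal-tailed upper bound
  x <- rlnorm(5000, 0, 1)
  expect_lt(hpdi(x, 0.95)[2], quantile(x, 0.975))
  # symmetric unimodal: close to equal-tailed
  z <- rnorm(20000)
  expect_equal(hpdi(z, 0.95), unname(quantile(z, c(0.025, 0.975))),
               tolerance = 0.05)
  expect_error(hpdi(1:200, 1.2), "mass")
  expect_error(hpdi(1:50, 0.9), "100")
})

test_that("Gelman-Rubin diagnostic separates mixed from unmixed chains", {
  set.seed(52)
  iid <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(gelman_rubin(iid), 1.02)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  # closed form: W ~ 1, B = n var(means) ~ n * 12.5 -> R ~ sqrt(13)
  expect_gt(gelman_rubin(apart), 3)
  expect_warning(r <- gelman_rubin(matrix(2, 100, 3)), "constant")
  expect_equal(r, 1)
  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("log posterior has the prior and identifiability structure", {
  spec <- hier_spec(k = 2, iterations = 100, burnin = 10, chains = 2)
  empty <- structure(list(groups = list(), genotypes = character(0)),
                     class = "hier_groups")
  th <- c(0.4, -0.2, 0.1, 0.3)
  lp <- log_posterior(th, empty)
  expect_equal(lp, sum(dnorm(th, c(1, 0, 0, 0), sqrt(0.5), log = TRUE)))
  expect_equal(log_posterior(c(th[1], Inf, th[3:4]), empty), -Inf)

  set.seed(53)
  xo <- sim_xo_group(10, c(90, 60), 8, prefix = "a")
  xo2 <- sim_xo_group(10, c(90, 60), 12, prefix = "b")
  both <- rbind(xo, xo2)
  class(both) <- c("xo_data", "data.frame")
  meta <- data.frame(individual = unique(both$individual),
                     maternal_strain = rep(c("P", "W"), each = 10),
                     paternal_strain = rep(c("W", "P"), each = 10),
                     age = "young")
  grp <- hier_groups(both, meta)
  # shifting beta0 by c and all genotype effects by -c changes the prior only
  th1 <- c(2.0, 0.3, -0.1, 0)
  th2 <- c(2.5, -0.2, -0.6, 0)
  prior_of <- function(t) sum(dnorm(t, c(1, 0, 0, 0), sqrt(0.5), log = TRUE))
  expect_equal(log_posterior(th1, grp) - prior_of(th1),
               log_posterior(th2, grp) - prior_of(th2), tolerance = 1e-10)
})

test_that("with one group the posterior mode shrinks the MLE toward the prior", {
  set.seed(54)
  xo <- sim_xo_group(60, c(90, 80, 70, 60, 50), 9)
  meta <- data.frame(individual = unique(xo$individual),
                     maternal_strain = "P", paternal_strain = "W",
                     age = "young")
  grp <- hier_groups(xo, meta)
  lmle <- log(fit_gamma(xo)$nu_hat)
  # profile the posterior over beta0 with the genotype effect at zero
  b0 <- seq(0.5, 3.5, by = 0.002)
  lp <- vapply(b0, function(b) log_posterior(c(b, 0, 0), grp), numeric(1))
  mode <- b0[which.max(lp)]
  expect_gt(lmle, 1)           # informative data, MLE above the prior mean
  expect_gt(mode, 1)
  expect_lt(mode, lmle)        # shrunk toward mu = 1, but not past it
  expect_lt(abs(mode - lmle), 0.25)
})

test_that("the sampler is deterministic given a seed and caches correctly", {
  set.seed(55)
  xo <- sim_xo_group(6, c(90, 60), 8, prefix = "a")
  xo2 <- sim_xo_group(6, c(90, 60), 11, prefix = "b")
  both <- rbind(xo, xo2)
  class(both) <- c("xo_data", "data.frame")
  meta <- data.frame(individual = unique(both$individual),
                     maternal_strain = rep(c("P", "W"), each = 6),
                     paternal_strain = rep(c("W", "P"), each = 6),
                     age = rep(c("young", "old"), 6))
  grp <- hier_groups(both, meta)
  spec <- hier_spec(k = 2, iterations = 1200, burnin = 200, chains = 2,
                    seed = 9)
  p1 <- suppressWarnings(run_mcmc(spec, grp, debug = TRUE))  # cache check on
  p2 <- suppressWarnings(run_mcmc(spec, grp))
  expect_identical(p1$draws, p2$draws)
  expect_equal(dim(p1$draws), c(1000, 4, 2))
  expect_true(all(p1$nu_draws > 0))
  expect_error(run_mcmc(hier_spec(k = 3, iterations = 100, burnin = 10), grp),
               "does not match")
})

test_that("a prior-only run recovers the Gaussian prior moments", {
  spec <- hier_spec(k = 1, iterations = 20000, burnin = 2000, chains = 4,
                    seed = 3)
  post <- run_mcmc(spec)
  b <- post$beta_draws
  # beta0 ~ N(1, 0.5), beta1 and alpha ~ N(0, 0.5); the tau2 = 0.005 random
  # walk has an integrated autocorrelation time of a few hundred iterations,
  # hence the long prior-only run
  expect_lt(abs(mean(b[, "beta0"]) - 1), 0.15)
  expect_lt(abs(var(b[, "beta0"]) - 0.5), 0.15)
  expect_lt(abs(mean(b[, "beta1"])), 0.15)
  expect_lt(abs(var(b[, "alpha"]) - 0.5), 0.15)
  expect_true(all(post$rhat < 1.05))
  # near-free moves: the tau2 = 0.005 walk accepts most prior-only proposals
  expect_true(all(post$accept > 0.5))
})

test_that("posterior spread shrinks as data grow", {
  sds <- vapply(c(4, 40, 400), function(n) {
    set.seed(56)
    xo <- sim_xo_group(n, 100, 10)
    meta <- data.frame(individual = unique(xo$individual),
                       maternal_strain = "P", paternal_strain = "W",
                       age = "young")
    spec <- hier_spec(k = 1, iterations = 2500, burnin = 500, chains = 2,
                      seed = 4)
    post <- suppressWarnings(run_mcmc(spec, hier_groups(xo, meta)))
    sd(log(post$nu_draws[, 1]))
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("contrasts are draw-wise ratios with exact trivial cases", {
  set.seed(57)
  xo <- sim_xo_group(8, c(90, 60), 9, prefix = "a")
  xo2 <- sim_xo_group(8, c(90, 60), 9, prefix = "b")
  both <- rbind(xo, xo2)
  class(both) <- c("xo_data", "data.frame")
  meta <- data.frame(individual = unique(both$individual),
                     maternal_strain = rep(c("P", "W"), each = 8),
                     paternal_strain = rep(c("W", "P"), each = 8),
                     age = rep(c("young", "old"), 8))
  spec <- hier_spec(k = 2, iterations = 800, burnin = 300, chains = 2, seed = 5)
  post <- suppressWarnings(run_mcmc(spec, hier_groups(both, meta)))
  glev <- post$genotypes
  same <- posterior_contrasts(post, pairs = list(c(glev[1], glev[1])),
                              age = FALSE)
  expect_equal(same$mean, 1)
  expect_equal(unname(c(same$hpdi95_lo, same$hpdi95_hi)), c(1, 1))
  cs <- posterior_contrasts(post)
  expect_true("young / old" %in% cs$contrast)
  expect_error(posterior_contrasts(post, pairs = list(c("nope", glev[1]))),
               "unknown")
})
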