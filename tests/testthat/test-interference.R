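test_that("inter-crossover density has the exponential closed form at nu = 1", {
  y <- c(0.01, 0.3, 1, 2.7)
  expect_equal(interarrival_density(y, 1), exp(-y), tolerance = 1e-12)
  expect_equal(interarrival_density(y, 1, "survival"), exp(-y),
               tolerance = 1e-12)
})

test_that("f* integrates to 1 with unit mean, and S*(0) = 1", {
  for (nu in c(1, 2.6, 11.3)) {
    expect_equal(integrate(function(y) interarrival_density(y, nu), 0, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    expect_equal(integrate(function(y) y * interarrival_density(y, nu), 0, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    expect_equal(interarrival_density(0, nu, "survival"), 1, tolerance = 1e-12)
  }
})

test_that("gamma log-likelihood reduces to the Poisson closed form at nu = 1", {
  set.seed(41)
  for (rep in 1:5) {
    n_chr <- sample(3:8, 1)
    L <- runif(n_chr, 40, 110)
    pos <- lapply(L, function(l) sort(runif(rpois(1, l / 100), 0.01 * l,
                                            0.99 * l)))
    xo <- xo_data(rep("i1", n_chr), paste0("c", 1:n_chr), L, pos)
    expect_equal(gamma_loglik(xo, 1), -sum(L) / 100, tolerance = 1e-10)
  }
  # single empty chromosome of 1 Morgan: log P = -1
  x0 <- xo_data("i", "c1", 100, list(numeric(0)))
  expect_equal(gamma_loglik(x0, 1), -1, tolerance = 1e-12)
})

test_that("likelihood components agree with direct simulation probabilities", {
  # dual route: P(no crossover) and P(exactly one crossover in a window)
  # computed from the renewal-theory formulas vs Monte-Carlo frequencies
  set.seed(42)
  n_sim <- 40000
  for (nu in c(2.6, 11.3)) {
    L <- 0.6
    sims <- lapply(seq_len(n_sim), function(i)
      xointer:::simulate_chrom_crossovers(L, nu, 0)$pos)
    n <- lengths(sims)

    p0_model <- exp(xointer:::g0_log(L, nu))
    p0_mc <- mean(n == 0)
    se0 <- sqrt(p0_mc * (1 - p0_mc) / n_sim)
    expect_lt(abs(p0_model - p0_mc), 3 * se0 + 1e-12)

    # one crossover with position in [0.2, 0.4]:
    # integral over the window of S*(x) S*(L - x) (stationary start, mu* = 1)
    p1_model <- integrate(function(x)
      interarrival_density(x, nu, "survival") *
        interarrival_density(L - x, nu, "survival"), 0.2, 0.4,
      rel.tol = 1e-9)$value
    hit <- vapply(sims, function(x)
      length(x) == 1 && x >= 0.2 && x <= 0.4, logical(1))
    p1_mc <- mean(hit)
    se1 <- sqrt(p1_mc * (1 - p1_mc) / n_sim)
    expect_lt(abs(p1_model - p1_mc), 3 * se1 + 1e-12)
  }
})

test_that("likelihood is invariant to row order and individual relabeling", {
  set.seed(43)
  xo <- sim_xo_group(8, c(90, 60, 50), 6)
  ll <- gamma_loglik(xo, 6)
  perm <- xo[sample(nrow(xo)), ]
  class(perm) <- c("xo_data", "data.frame")
  expect_equal(gamma_loglik(perm, 6), ll, tolerance = 1e-12)
  relab <- xo
  relab$individual <- paste0("z", as.integer(factor(xo$individual)))
  class(relab) <- c("xo_data", "data.frame")
  expect_equal(gamma_loglik(relab, 6), ll, tolerance = 1e-12)
  expect_equal(escape_loglik(perm, 6, 0.1), escape_loglik(xo, 6, 0.1),
               tolerance = 1e-10)
})

test_that("invalid crossover data are rejected with the offending chromosome", {
  expect_error(xo_data("i", "c7", 100, list(c(50, 30))), "c7")
  expect_error(xo_data("i", "c2", 80, list(c(10, 90))), "c2")
  expect_error(gamma_loglik(sim_xo_group(2, 50, 2), -1))
})

test_that("escape model nests the gamma model and has the Poisson limits", {
  set.seed(44)
  xo <- sim_xo_group(10, c(90, 70, 50), 10, p = 0.1)
  for (nu in c(2, 11.3))
    expect_equal(escape_loglik(xo, nu, 0), gamma_loglik(xo, nu),
                 tolerance = 1e-10)
  # p -> 1: pure Poisson process of unit rate, loglik -> -sum(L)
  expect_equal(escape_loglik(xo, 5, 1 - 1e-9), -sum(xo$L_cM) / 100,
               tolerance = 1e-6)
  # at nu = 1 both pathways are Poisson: loglik = -sum(L) for every p
  expect_equal(escape_loglik(xo, 1, 0.3), -sum(xo$L_cM) / 100,
               tolerance = 1e-10)

  # two-crossover chromosome: direct 4-term enumeration oracle
  x2 <- xo_data("i", "c1", 100, list(c(30, 75)))
  nu <- 8; p <- 0.15; lam <- 1 - p
  g <- function(x, L) xointer:::gamma_chrom_loglik(x, L, nu, lam)
  terms <- c(g(c(0.30, 0.75), 1),
             log(p) + g(0.75, 1),
             log(p) + g(0.30, 1),
             2 * log(p) + g(numeric(0), 1)) - p * 1
  expect_equal(escape_loglik(x2, nu, p), xointer:::logsumexp(terms),
               tolerance = 1e-10)

  # enumeration bound
  x13 <- xo_data("i", "c1", 1400, list(seq(100, 1300, by = 100)))
  expect_error(escape_loglik(x13, 5, 0.1), "12 crossovers")
})

test_that("maximum likelihood recovers the interference strength", {
  lengths <- default_chromosome_lengths()
  for (nu in c(2, 6, 11.3)) {
    rel_err <- vapply(1:3, function(s) {
      set.seed(100 + s)
      xo <- sim_xo_group(1000, lengths, nu)
      abs(fit_gamma(xo)$nu_hat - nu) / nu
    }, numeric(1))
    expect_lt(median(rel_err), 0.10, label = paste("nu =", nu))
  }
})

test_that("fits behave at the no-interference limit and under nesting", {
  set.seed(45)
  xo <- sim_xo_group(300, c(90, 70, 60, 50), 1)
  f1 <- fit_gamma(xo)
  expect_lt(abs(f1$nu_hat - 1), 0.15)
  expect_true(f1$interior)

  xo2 <- sim_xo_group(60, default_chromosome_lengths()[1:9], 12, p = 0.05)
  fg <- fit_gamma(xo2)
  fe <- fit_gamma_escape(xo2)
  expect_gte(fe$loglik, fg$loglik - 1e-6)
  expect_true(fe$p_hat >= 0 && fe$p_hat < 1)
})

test_that("the (nu, p) profile shows the positive ridge", {
  # when part of the crossovers genuinely escape interference, assigning a
  # larger share to the Poisson pathway leaves more regular residual spacing,
  # so the profiled interference strength rises with the fixed escape share
  # (on the rising limb below the jointly fitted share; past it, it declines)
  set.seed(46)
  xo <- sim_xo_group(80, default_chromosome_lengths()[1:9], 12, p = 0.1)
  prof <- vapply(c(0, 0.05, 0.1), function(p) {
    o <- optimize(function(lnu) -escape_loglik(xo, exp(lnu), p),
                  c(log(1), log(80)), tol = 1e-5)
    exp(o$minimum)
  }, numeric(1))
  expect_true(all(diff(prof) > 0))
})

test_that("bootstrap resamples individuals and reports failures", {
  # two identical individuals: every resample is the same dataset
  xo <- xo_data(c("a", "a", "b", "b"), c("c1", "c2", "c1", "c2"),
                c(90, 70, 90, 70), list(c(30, 70), 40, c(30, 70), 40))
  b <- suppressWarnings(
    bootstrap_ci(xo, function(x) c(nu = fit_gamma(x)$nu_hat),
                 n_boot = 20, seed = 1))
  expect_equal(unname(diff(b$ci95["nu", ])), 0)
  expect_equal(unname(diff(b$ci50["nu", ])), 0)

  # an all-empty resample is recorded as failed and excluded
  xo2 <- xo_data(c("a", "b"), c("c1", "c1"), c(100, 100),
                 list(c(50), numeric(0)))
  # single-crossover resamples sit on the optimizer bracket boundary and warn
  b2 <- suppressWarnings(
    bootstrap_ci(xo2, function(x) c(nu = fit_gamma(x)$nu_hat),
                 n_boot = 40, seed = 2))
  expect_gt(b2$n_failed, 0)
  expect_equal(nrow(b2$replicates), 40 - b2$n_failed)

  expect_error(bootstrap_ci(xo2[1, ], identity, 10), "2 individuals")
})

test_that("model comparison arithmetic matches its definitions", {
  fits <- list("gamma.null" = list(df = 1, loglik = -5514.8),
               "gamma.full" = list(df = 6, loglik = -5507.0),
               "gamma-escape.null" = list(df = 2, loglik = -5480.8),
               "gamma-escape.full" = list(df = 12, loglik = -5471.6))
  cmp <- compare_models(fits)
  expect_equal(cmp$models$AIC, 2 * cmp$models$df - 2 * cmp$models$loglik)
  expect_equal(cmp$models$AIC[1], 11031.6)
  g_vs_g <- cmp$lrt[cmp$lrt$null == "gamma.null" & cmp$lrt$full == "gamma.full", ]
  expect_equal(g_vs_g$statistic, 15.6, tolerance = 1e-10)
  expect_equal(g_vs_g$df, 5)
  # identical log-likelihoods in a nested pair: statistic 0, p = 1
  t0 <- lrt_test(-100, 1, -100, 6)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  # the non-nested pair is never tested by default and errors on request
  expect_false(any(cmp$lrt$null == "gamma.full" &
                     cmp$lrt$full == "gamma-escape.null"))
  expect_error(compare_models(fits, pairs = list(c("gamma.full",
                                                   "gamma-escape.null"))),
               "non-nested")
  expect_error(lrt_test(-10, 3, -9, 3), "not nested")
})
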