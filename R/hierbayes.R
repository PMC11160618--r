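# Hierarchical Bayesian model of group-wise interference strength.
#
# For group i (a paternal genotype x age-cohort cell),
#   log(nu_i) = beta0 + beta_g(i) + alpha * [old cohort],
# with priors beta0 ~ N(mu, sigma2), beta_g ~ N(0, sigma2) and, for old
# males, alpha ~ N(0, sigma2) (alpha is 0 for young males). No sum-to-zero
# constraint is imposed on the genotype effects: the prior alone regularizes
# the beta0/beta_g redundancy. Inference is by component-wise random-walk
# Metropolis in independent replicate chains.

#' Specification of the hierarchical interference model
#'
#' @param k number of genotypes.
#' @param mu prior mean of the intercept `beta0` (log scale; default 1).
#' @param sigma2 prior variance of `beta0`, the genotype effects and the age
#'   effect (default 0.5).
#' @param tau2 variance of the `N(0, tau2)` random-walk proposal
#'   (default 0.005).
#' @param iterations MCMC iterations per chain (default 25000).
#' @param burnin iterations discarded from the start of each chain
#'   (default 5000).
#' @param chains number of independently seeded replicate chains (default 4).
#' @param seed integer seed; chain `c` uses `seed + 1000 (c - 1)`.
#' @return List of class `hier_spec`.
#' @export
hier_spec <- function(k, mu = 1, sigma2 = 0.5, tau2 = 0.005,
                      iterations = 25000, burnin = 5000, chains = 4,
                      seed = 1L) {
  stopifnot(k >= 1, sigma2 > 0, tau2 > 0, burnin < iterations, chains >= 1)
  structure(list(k = as.integer(k), mu = mu, sigma2 = sigma2, tau2 = tau2,
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), chains = as.integer(chains),
                 seed = as.integer(seed)),
            class = "hier_spec")
}

#' Group crossover data by genotype and age cohort
#'
#' @param xo an [xo_data].
#' @param meta metadata with `individual`, `maternal_strain`,
#'   `paternal_strain`, `age` ("young"/"old").
#' @return List of class `hier_groups`: per group a list with `label`,
#'   `genotype` (label and index), `old` flag and precompiled likelihood data;
#'   plus the genotype level set.
#' @export
hier_groups <- function(xo, meta) {
  m <- meta[match(xo$individual, meta$individual), , drop = FALSE]
  if (anyNA(m$individual)) stop("individuals missing from metadata")
  genotype <- paste(m$maternal_strain, "x", m$paternal_strain)
  glev <- sort(unique(genotype))
  age <- m$age
  stopifnot(all(age %in% c("young", "old")))
  key <- paste(genotype, age, sep = "|")
  groups <- lapply(sort(unique(key)), function(kk) {
    rows <- key == kk
    sub <- xo[rows, , drop = FALSE]
    class(sub) <- c("xo_data", "data.frame")
    g <- genotype[rows][1]
    list(label = sub("\\|", " ", kk), genotype = g,
         gi = match(g, glev), old = age[rows][1] == "old",
         comp = xo_compile(sub))
  })
  structure(list(groups = groups, genotypes = glev), class = "hier_groups")
}

# theta = c(beta0, beta_1..k, alpha)
group_nu <- function(theta, grp, k) {
  exp(theta[1] + theta[1 + grp$gi] + theta[k + 2] * grp$old)
}

log_prior <- function(theta, k, mu, sigma2) {
  sd <- sqrt(sigma2)
  stats::dnorm(theta[1], mu, sd, log = TRUE) +
    sum(stats::dnorm(theta[2:(k + 1)], 0, sd, log = TRUE)) +
    stats::dnorm(theta[k + 2], 0, sd, log = TRUE)
}

#' Log posterior density of the hierarchical interference model
#'
#' Sum over groups of the gamma-model log-likelihood at that group's
#' `nu = exp(beta0 + beta_i + alpha [old])`, plus the log prior densities.
#' Non-finite parameter vectors score `-Inf`.
#'
#' @param theta numeric vector `c(beta0, beta_1, ..., beta_k, alpha)`.
#' @param groups a [hier_groups] (may contain zero groups, in which case the
#'   posterior is the prior).
#' @param mu,sigma2 prior mean and variance.
#' @return Scalar log posterior (up to a constant).
#' @export
log_posterior <- function(theta, groups, mu = 1, sigma2 = 0.5) {
  k <- length(groups$genotypes)
  if (length(groups$groups) == 0L) k <- max(k, length(theta) - 2L)
  stopifnot(length(theta) == k + 2L)
  if (any(!is.finite(theta))) return(-Inf)
  lp <- log_prior(theta, k, mu, sigma2)
  for (grp in groups$groups)
    lp <- lp + gamma_loglik(grp$comp, group_nu(theta, grp, k))
  lp
}

#' Run the random-walk Metropolis sampler
#'
#' Component-wise Metropolis: per iteration each parameter is updated in turn
#' with a `N(0, tau2)` proposal. Group log-likelihoods are cached so that a
#' genotype-effect proposal re-evaluates only that genotype's groups and an
#' age-effect proposal only the old-cohort groups (`beta0` touches all).
#' Chains are independently seeded and burn-in is discarded. Setting
#' `data = NULL` samples the prior.
#'
#' @param spec a [hier_spec].
#' @param data a [hier_groups] built by [hier_groups], or `NULL` for a
#'   prior-only run.
#' @param debug if `TRUE`, cached group likelihoods are checked against a full
#'   recomputation every 1000 iterations.
#' @return Object of class `hier_posterior`: `draws` (array kept-iterations x
#'   parameters x chains), `nu_draws` (matrix of per-group interference draws,
#'   chains stacked), `groups` (data frame of group labels), `nu_summary`
#'   (posterior mean and 95%/50% HPDIs per group, computed on the exponentiated
#'   draws), `rhat`, `accept` (per parameter x chain) and `spec`. A warning is
#'   attached when any R-hat exceeds 1.1.
#' @export
run_mcmc <- function(spec, data = NULL, debug = FALSE) {
  stopifnot(inherits(spec, "hier_spec"))
  k <- spec$k
  grps <- if (is.null(data)) list() else data$groups
  if (!is.null(data) && length(data$genotypes) != k)
    stop("spec$k (", k, ") does not match the data (",
         length(data$genotypes), " genotypes)")
  npar <- k + 2L
  pnames <- c("beta0", paste0("beta", seq_len(k)), "alpha")
  # which groups each parameter touches
  touches <- c(list(seq_along(grps)),
               lapply(seq_len(k), function(i)
                 which(vapply(grps, function(g) g$gi == i, logical(1)))),
               list(which(vapply(grps, function(g) g$old, logical(1)))))
  sdp <- sqrt(spec$tau2)
  sd0 <- sqrt(spec$sigma2)
  kept <- spec$iterations - spec$burnin
  draws <- array(NA_real_, c(kept, npar, spec$chains),
                 dimnames = list(NULL, pnames, NULL))
  accept <- matrix(0, npar, spec$chains, dimnames = list(pnames, NULL))

  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + 1000L * (ch - 1L))
    theta <- c(stats::rnorm(1, spec$mu, sd0), stats::rnorm(k + 1, 0, sd0))
    gll <- vapply(grps, function(g)
      gamma_loglik(g$comp, group_nu(theta, g, k)), numeric(1))
    lpri <- log_prior(theta, k, spec$mu, spec$sigma2)
    for (it in seq_len(spec$iterations)) {
      for (p in seq_len(npar)) {
        prop <- theta
        prop[p] <- prop[p] + stats::rnorm(1, 0, sdp)
        touched <- touches[[p]]
        gll_new <- vapply(grps[touched], function(g)
          gamma_loglik(g$comp, group_nu(prop, g, k)), numeric(1))
        lpri_new <- log_prior(prop, k, spec$mu, spec$sigma2)
        lr <- (lpri_new - lpri) + sum(gll_new) - sum(gll[touched])
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          theta <- prop
          if (length(touched)) gll[touched] <- gll_new
          lpri <- lpri_new
          if (it > spec$burnin) accept[p, ch] <- accept[p, ch] + 1
        }
      }
      if (debug && it %% 1000L == 0L && length(grps)) {
        full <- vapply(grps, function(g)
          gamma_loglik(g$comp, group_nu(theta, g, k)), numeric(1))
        stopifnot(isTRUE(all.equal(full, gll, tolerance = 1e-10)))
      }
      if (it > spec$burnin) draws[it - spec$burnin, , ch] <- theta
    }
  }
  accept <- accept / kept

  rhat <- if (spec$chains >= 2)
    vapply(seq_len(npar), function(p) gelman_rubin(draws[, p, ]), numeric(1))
  else rep(NA_real_, npar)
  names(rhat) <- pnames
  if (any(is.finite(rhat) & rhat > 1.1))
    warning("R-hat > 1.1 for: ",
            paste(pnames[is.finite(rhat) & rhat > 1.1], collapse = ", "),
            " (chains may not have converged)")

  flat <- do.call(rbind, lapply(seq_len(spec$chains),
                                function(ch) draws[, , ch, drop = TRUE]))
  post <- list(draws = draws, accept = accept, rhat = rhat, spec = spec)
  if (length(grps)) {
    labs <- vapply(grps, `[[`, character(1), "label")
    nu_draws <- vapply(grps, function(g)
      exp(flat[, 1] + flat[, 1 + g$gi] + flat[, k + 2] * g$old),
      numeric(nrow(flat)))
    colnames(nu_draws) <- labs
    post$groups <- data.frame(
      label = labs,
      genotype = vapply(grps, `[[`, character(1), "genotype"),
      old = vapply(grps, `[[`, logical(1), "old"))
    post$genotypes <- data$genotypes
    post$nu_draws <- nu_draws
    post$nu_summary <- do.call(rbind, lapply(labs, function(l) {
      d <- nu_draws[, l]
      h95 <- hpdi(d, 0.95); h50 <- hpdi(d, 0.50)
      data.frame(group = l, mean = mean(d), hpdi95_lo = h95[1],
                 hpdi95_hi = h95[2], hpdi50_lo = h50[1], hpdi50_hi = h50[2])
    }))
  }
  post$beta_draws <- flat
  structure(post, class = "hier_posterior")
}

#' @export
print.hier_posterior <- function(x, ...) {
  cat("hierarchical interference posterior:", dim(x$draws)[1], "kept draws x",
      dim(x$draws)[3], "chains\n")
  if (!is.null(x$nu_summary)) print(x$nu_summary, row.names = FALSE)
  cat("max R-hat:", format(suppressWarnings(max(x$rhat, na.rm = TRUE)),
                           digits = 4), "\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' computed on the sorted draws.
#'
#' @param draws numeric vector of at least 100 draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (!is.finite(mass) || mass <= 0 || mass >= 1) stop("mass must be in (0,1)")
  stopifnot(length(draws) >= 100)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  w <- x[m:n] - x[seq_len(n - m + 1)]
  i <- which.min(w)
  c(x[i], x[i + m - 1])
}

#' Posterior contrasts between groups
#'
#' Ratios of interference strength are computed on the log scale per draw and
#' exponentiated, so every summary is a summary of draws (never a transform of
#' interval endpoints). Genotype contrasts `exp(beta_a - beta_b)` do not
#' depend on age; the age contrast (young vs old, common to all genotypes) is
#' `exp(-alpha)`.
#'
#' @param posterior a `hier_posterior` fitted with data.
#' @param pairs list of `c(genotype_a, genotype_b)` label pairs; default all
#'   ordered pairs.
#' @param age include the young-vs-old contrast (default `TRUE`).
#' @return Data frame with `contrast`, posterior `mean` ratio and 95%/50%
#'   HPDIs.
#' @export
posterior_contrasts <- function(posterior, pairs = NULL, age = TRUE) {
  stopifnot(inherits(posterior, "hier_posterior"),
            !is.null(posterior$nu_draws))
  glev <- posterior$genotypes
  k <- length(glev)
  flat <- posterior$beta_draws
  if (is.null(pairs)) {
    pairs <- list()
    for (a in seq_len(k)) for (b in seq_len(k)) if (a < b)
      pairs[[length(pairs) + 1L]] <- c(glev[a], glev[b])
  }
  rows <- lapply(pairs, function(p) {
    ia <- match(p[1], glev); ib <- match(p[2], glev)
    if (anyNA(c(ia, ib))) stop("unknown genotype label: ",
                               paste(p[is.na(c(ia, ib))], collapse = ", "))
    ratio <- exp(flat[, 1 + ia] - flat[, 1 + ib])
    h95 <- hpdi(ratio, 0.95); h50 <- hpdi(ratio, 0.50)
    data.frame(contrast = paste(p[1], "/", p[2]), mean = mean(ratio),
               hpdi95_lo = h95[1], hpdi95_hi = h95[2],
               hpdi50_lo = h50[1], hpdi50_hi = h50[2])
  })
  if (age) {
    ratio <- exp(-flat[, k + 2])
    h95 <- hpdi(ratio, 0.95); h50 <- hpdi(ratio, 0.50)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = "young / old", mean = mean(ratio),
      hpdi95_lo = h95[1], hpdi95_hi = h95[2],
      hpdi50_lo = h50[1], hpdi50_hi = h50[2])
  }
  do.call(rbind, rows)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from between- and within-chain variances of
#' equal-length chains. Degenerate constant chains return 1 with a warning.
#'
#' @param chains matrix with one column per chain (>= 2 chains).
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("at least 2 chains are required")
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) {
    warning("constant chains: within-chain variance is zero; returning 1")
    return(1)
  }
  B <- n * stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}
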