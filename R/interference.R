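# Gamma and gamma-escape models of crossover interference.
#
# Chiasmata on the four-strand bundle are modelled as a stationary renewal
# process with gamma(shape nu, rate 2*nu per Morgan) inter-event distances;
# each chiasma is transmitted to a given gamete with probability 1/2, so the
# crossover process is itself a renewal process whose inter-event density is
# the geometric mixture
#   f*(y) = sum_{k>=1} 2^(-k) dgamma(y; k*nu, 2*nu),
# with survival S*(y) defined analogously and mean exactly 1 Morgan.

MAX_MIXTURE_TERMS <- 60L
MIXTURE_REL_TOL <- 1e-12

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# The three mixture sums below accumulate in linear space (all values of
# interest are far above the double-precision underflow threshold at the map
# scales involved) and exploit two facts about the series:
#   * density terms dgamma(y; k nu, 2 nu) are unimodal in k with peak near
#     k = 2y, so once k is past every peak and the largest weighted term is
#     below 1e-13 of every accumulated value the remainder is negligible;
#   * survival terms pgamma(y; k nu, 2 nu, lower = FALSE) tend to 1, so once
#     the complementary cdf max(1 - Q_k) drops below 1e-12 the remaining tail
#     equals the geometric tail sum_{j>k} 2^(-j) (= 2^(-k)) to that relative
#     accuracy and is added in closed form.

# f*(y): density of the inter-crossover distance, vectorized over y (Morgans)
fstar_lin <- function(y, nu) {
  stopifnot(all(is.finite(y)), all(y >= 0), is.finite(nu), nu > 0)
  if (length(y) == 0L) return(numeric(0))
  acc <- numeric(length(y))
  kmin <- 2 * max(y) + 2
  w <- 1
  for (k in seq_len(MAX_MIXTURE_TERMS)) {
    w <- w / 2
    term <- w * stats::dgamma(y, shape = k * nu, rate = 2 * nu)
    acc <- acc + term
    if (k >= kmin && all(term <= 1e-13 * acc)) break
  }
  acc
}

# S*(y): survival of the inter-crossover distance
sstar_lin <- function(y, nu) {
  stopifnot(all(is.finite(y)), all(y >= 0), is.finite(nu), nu > 0)
  if (length(y) == 0L) return(numeric(0))
  acc <- numeric(length(y))
  w <- 1
  for (k in seq_len(MAX_MIXTURE_TERMS)) {
    w <- w / 2
    q <- stats::pgamma(y, shape = k * nu, rate = 2 * nu, lower.tail = FALSE)
    acc <- acc + w * q
    if (max(1 - q) < MIXTURE_REL_TOL) {
      acc <- acc + w      # closed-form geometric tail, Q_j ~ 1 beyond here
      break
    }
  }
  acc
}

# P(no crossover on [0, L]) for the stationary process:
# integral_L^Inf S*(x) dx (mean inter-crossover distance is 1), using the
# termwise partial expectation
#   integral_L^Inf pgamma(x; a, r, lower = FALSE) dx
#     = (a/r) Q(L; a+1, r) - L Q(L; a, r)  = E[(X - L)^+];
# once Q ~ 1 the remaining tail is sum_{j>k} 2^(-j) (j/2 - L).
g0_lin <- function(L, nu) {
  stopifnot(all(is.finite(L)), all(L >= 0), is.finite(nu), nu > 0)
  if (length(L) == 0L) return(numeric(0))
  acc <- numeric(length(L))
  w <- 1
  for (k in seq_len(MAX_MIXTURE_TERMS)) {
    w <- w / 2
    q1 <- stats::pgamma(L, shape = k * nu + 1, rate = 2 * nu,
                        lower.tail = FALSE)
    q0 <- stats::pgamma(L, shape = k * nu, rate = 2 * nu, lower.tail = FALSE)
    acc <- acc + w * pmax(k / 2 * q1 - L * q0, 0)
    if (max(1 - q0) < MIXTURE_REL_TOL) {
      acc <- acc + w * (k / 2 + 1 - L)
      break
    }
  }
  acc
}

fstar_log <- function(y, nu) log(fstar_lin(y, nu))
sstar_log <- function(y, nu) log(sstar_lin(y, nu))
g0_log <- function(L, nu) log(g0_lin(L, nu))

#' Inter-crossover distance density and survival under the gamma model
#'
#' Density (and survival function) of the distance between successive
#' crossovers on a gamete when chiasmata follow a stationary gamma renewal
#' process with shape `nu` and rate `2 nu` per Morgan, thinned by 1/2. The
#' mixture series is truncated when its remaining mass is below `1e-12` of the
#' accumulated value (at most 60 terms). The mean of the density is exactly
#' 1 Morgan for every `nu`.
#'
#' @param y distances in Morgans (non-negative).
#' @param nu interference strength, a positive unitless shape parameter;
#'   `nu = 1` is no interference (exponential distances).
#' @param what `"density"` for f*, `"survival"` for S*.
#' @param log return on the log scale.
#' @return Numeric vector of density or survival values.
#' @export
interarrival_density <- function(y, nu, what = c("density", "survival"),
                                 log = FALSE) {
  what <- match.arg(what)
  v <- if (what == "density") fstar_log(y, nu) else sstar_log(y, nu)
  if (log) v else exp(v)
}

#' Precompute the likelihood arrays for a crossover dataset
#'
#' Flattens an [xo_data] into the quantities the gamma likelihood needs
#' (first-event, inter-event and censored distances, and lengths of
#' crossover-free chromosomes), all in Morgans. Fitting and MCMC call the
#' likelihood many times on fixed data, so this is done once.
#'
#' @param xo an [xo_data] object.
#' @return An object of class `xo_compiled`.
#' @export
xo_compile <- function(xo) {
  if (inherits(xo, "xo_compiled")) return(xo)
  validate_xo_data(xo)
  L <- xo$L_cM / 100
  pos <- lapply(xo$positions_cM, function(p) p / 100)
  n <- vapply(pos, length, integer(1))
  has <- n > 0L
  first <- vapply(pos[has], function(p) p[1], numeric(1))
  censor <- L[has] - vapply(pos[has], function(p) p[length(p)], numeric(1))
  gaps <- unlist(lapply(pos[has], diff), use.names = FALSE)
  if (is.null(gaps)) gaps <- numeric(0)
  # crossover-free chromosomes contribute only through their length: collapse
  # to unique lengths with multiplicities
  L0_tab <- table(L[!has])
  structure(list(first = first, censor = censor, gaps = gaps,
                 L0 = as.numeric(names(L0_tab)), L0_n = as.integer(L0_tab),
                 n_events = sum(n), total_L = sum(L),
                 n_chrom = nrow(xo),
                 individuals = unique(xo$individual),
                 chrom_pos = pos, chrom_L = L),
            class = "xo_compiled")
}

#' Log-likelihood of crossover data under the gamma interference model
#'
#' Each gamete chromosome with crossovers `x_1 < ... < x_n` on `[0, L]`
#' contributes `h(x_1) * prod f*(x_{i+1} - x_i) * S*(L - x_n)` where
#' `h(x) = S*(x) / mu*` is the stationary first-event density (`mu* = 1`
#' Morgan); a chromosome with no crossover contributes the stationary
#' void probability `integral_L^Inf S*(x) dx`. At `nu = 1` the total reduces
#' analytically to `-sum(L)` (a unit-rate Poisson process).
#'
#' @param xo an [xo_data] or [xo_compile] result.
#' @param nu interference strength (> 0).
#' @param intensity crossover intensity per Morgan (default 1, the value
#'   implied by using the same genetic map for observation and model).
#' @param include_zero include chromosomes without crossovers (default `TRUE`;
#'   the likelihood is over all transmitted segments, and dropping
#'   crossover-free chromosomes biases the fit).
#' @return Log-likelihood (scalar).
#' @export
gamma_loglik <- function(xo, nu, intensity = 1, include_zero = TRUE) {
  stopifnot(is.finite(nu), nu > 0, is.finite(intensity), intensity > 0)
  comp <- xo_compile(xo)
  lam <- intensity
  ll <- sum(sstar_log(lam * comp$first, nu)) +
    sum(sstar_log(lam * comp$censor, nu)) +
    comp$n_events * log(lam)
  if (length(comp$gaps)) ll <- ll + sum(fstar_log(lam * comp$gaps, nu))
  if (include_zero && length(comp$L0))
    ll <- ll + sum(comp$L0_n * g0_log(lam * comp$L0, nu))
  ll
}

# one-chromosome gamma-pathway log-likelihood at crossover intensity lambda;
# x and L in Morgans
gamma_chrom_loglik <- function(x, L, nu, lambda = 1) {
  if (length(x) == 0L) return(g0_log(lambda * L, nu))
  lx <- lambda * x
  ll <- sstar_log(lx[1], nu) + sstar_log(lambda * L - lx[length(lx)], nu) +
    length(x) * log(lambda)
  if (length(x) > 1L) ll <- ll + sum(fstar_log(diff(lx), nu))
  ll
}

#' Log-likelihood under the gamma-escape (Housworth-Stahl) model
#'
#' A proportion `p` of crossovers arise from a non-interfering Poisson pathway
#' with intensity `p` per Morgan; the remainder follow the gamma pathway with
#' chiasma rate `2 nu (1 - p)` (crossover intensity `1 - p`), keeping total
#' intensity at 1 per Morgan. The likelihood sums, per chromosome, over all
#' 2^n assignments of observed crossovers to the two pathways (log-sum-exp).
#' At `p = 0` it equals [gamma_loglik] exactly.
#'
#' @inheritParams gamma_loglik
#' @param p escape proportion in `[0, 1)`.
#' @return Log-likelihood (scalar).
#' @export
escape_loglik <- function(xo, nu, p) {
  stopifnot(is.finite(nu), nu > 0, is.finite(p), p >= 0, p < 1)
  comp <- xo_compile(xo)
  if (p == 0) return(gamma_loglik(comp, nu))
  lam <- 1 - p
  ns <- lengths(comp$chrom_pos)
  if (any(ns > 12L))
    stop("escape likelihood enumeration limited to 12 crossovers per ",
         "chromosome (got ", max(ns), ")")
  # batch every gamma-pathway component the 2^n subset sums can need:
  # stationary-start survivals S*(lam x_i), censoring survivals
  # S*(lam (L - x_i)), densities of all within-chromosome pairwise gaps,
  # and void probabilities at the (few distinct) chromosome lengths
  allx <- unlist(comp$chrom_pos, use.names = FALSE)
  if (is.null(allx)) allx <- numeric(0)
  Lrep <- rep(comp$chrom_L, ns)
  sf <- sstar_log(lam * allx, nu)
  sl <- sstar_log(lam * (Lrep - allx), nu)
  pair_i <- list(); pair_j <- list(); pair_chrom <- list()
  for (c_ in which(ns >= 2L)) {
    n <- ns[c_]
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pair_i[[length(pair_i) + 1L]] <- ij[, 1]
    pair_j[[length(pair_j) + 1L]] <- ij[, 2]
    pair_chrom[[length(pair_chrom) + 1L]] <- rep(c_, nrow(ij))
  }
  pi_ <- unlist(pair_i); pj_ <- unlist(pair_j); pc_ <- unlist(pair_chrom)
  off <- c(0L, cumsum(ns))[seq_along(ns)]   # offset of each chromosome in allx
  gx <- if (length(pi_)) allx[off[pc_] + pj_] - allx[off[pc_] + pi_]
        else numeric(0)
  gf <- fstar_log(lam * gx, nu)
  uL <- unique(comp$chrom_L)
  g0u <- g0_log(lam * uL, nu)
  llam <- log(lam)
  lp <- log(p)

  total <- 0
  gap_off <- c(0L, cumsum(choose(ns, 2)))
  for (c_ in seq_along(ns)) {
    n <- ns[c_]
    L <- comp$chrom_L[c_]
    g0c <- g0u[match(L, uL)]
    if (n == 0L) {
      total <- total - p * L + g0c
      next
    }
    o <- off[c_]
    # gap lookup for this chromosome: index of pair (i, j), i < j
    gidx <- function(i, j) gap_off[c_] + (j - 1) * (j - 2) / 2 + i
    terms <- numeric(2^n)
    for (s in 0:(2^n - 1L)) {
      keep <- which(bitwAnd(s, 2^(seq_len(n) - 1L)) == 0)   # gamma pathway
      m <- length(keep)
      lg <- if (m == 0L) g0c
      else {
        v <- sf[o + keep[1]] + sl[o + keep[m]] + m * llam
        if (m > 1L)
          v <- v + sum(gf[gidx(keep[-m], keep[-1])])
        v
      }
      terms[s + 1L] <- (n - m) * lp - p * L + lg
    }
    total <- total + logsumexp(terms)
  }
  total
}

#' Maximum-likelihood fit of the gamma interference model
#'
#' Maximizes [gamma_loglik] over `log(nu)` by one-dimensional golden-section /
#' parabolic search on a bounded bracket. Optionally attaches an
#' individual-level bootstrap (see [bootstrap_ci]).
#'
#' @inheritParams gamma_loglik
#' @param interval bracket for `nu` (default `c(0.1, 100)`).
#' @param tol convergence tolerance on `log(nu)`.
#' @param n_boot number of bootstrap replicates (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `gamma_fit`: list with `nu_hat`, `loglik`,
#'   `df` (= 1), `n_meioses`, `interior` (FALSE when the optimum sits on the
#'   bracket boundary) and, when requested, `boot` with replicate estimates
#'   and percentile 95%/50% intervals.
#' @export
fit_gamma <- function(xo, interval = c(0.1, 100), tol = 1e-6,
                      include_zero = TRUE, n_boot = 0, seed = NULL) {
  comp <- xo_compile(xo)
  stopifnot(comp$n_chrom >= 1)
  opt <- stats::optimize(function(lnu) -gamma_loglik(comp, exp(lnu),
                                                     include_zero = include_zero),
                         lower = log(interval[1]), upper = log(interval[2]),
                         tol = tol)
  nu_hat <- exp(opt$minimum)
  interior <- (opt$minimum - log(interval[1]) > 1e-3) &&
    (log(interval[2]) - opt$minimum > 1e-3)
  if (!interior) warning("gamma fit at bracket boundary; estimate flagged")
  fit <- structure(list(nu_hat = nu_hat, loglik = -opt$objective, df = 1L,
                        n_meioses = length(comp$individuals),
                        interior = interior, interval = interval),
                   class = "gamma_fit")
  if (n_boot > 0) {
    fit$boot <- bootstrap_ci(xo, function(x)
      c(nu = fit_gamma(x, interval = interval, tol = tol,
                       include_zero = include_zero)$nu_hat),
      n_boot = n_boot, seed = seed)
  }
  fit
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma interference fit: nu = %.3f (loglik %.2f, %d meioses)\n",
              x$nu_hat, x$loglik, x$n_meioses))
  if (!is.null(x$boot))
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] (%d replicates, %d failed)\n",
                x$boot$ci95["nu", 1], x$boot$ci95["nu", 2],
                nrow(x$boot$replicates), x$boot$n_failed))
  invisible(x)
}

#' Maximum-likelihood fit of the gamma-escape model
#'
#' Derivative-free (Nelder-Mead) search over `(log nu, logit p)`, restarted
#' from the best points of a coarse 4 x 4 grid; bootstrap refits restart from
#' a supplied `start` instead.
#'
#' @inheritParams fit_gamma
#' @param start optional `c(log_nu, logit_p)` starting point; when given, the
#'   grid search is skipped (used for bootstrap refits).
#' @param n_restarts number of grid points to polish (default 5).
#' @return An object of class `escape_fit`: list with `nu_hat`, `p_hat`,
#'   `loglik`, `df` (= 2), `n_meioses`, `interior`, and optional `boot` whose
#'   replicates carry the (nu, p) pairs.
#' @export
fit_gamma_escape <- function(xo, interval = c(0.1, 100), start = NULL,
                             n_restarts = 5, n_boot = 0, seed = NULL) {
  comp <- xo_compile(xo)
  neg <- function(par) {
    nu <- exp(par[1])
    if (nu < interval[1] || nu > interval[2]) return(1e10)
    -escape_loglik(comp, nu, stats::plogis(par[2]))
  }
  if (is.null(start)) {
    grid <- expand.grid(lnu = log(c(2, 5, 10, 20)),
                        lp = stats::qlogis(c(0.01, 0.05, 0.1, 0.2)))
    gval <- apply(grid, 1, neg)
    starts <- grid[order(gval)[seq_len(min(n_restarts, nrow(grid)))], ,
                   drop = FALSE]
  } else {
    starts <- data.frame(lnu = start[1], lp = start[2])
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), neg, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 1000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  nu_hat <- exp(best$par[1])
  p_hat <- stats::plogis(best$par[2])
  interior <- nu_hat > interval[1] * 1.001 && nu_hat < interval[2] * 0.999
  fit <- structure(list(nu_hat = nu_hat, p_hat = p_hat, loglik = -best$value,
                        df = 2L, n_meioses = length(comp$individuals),
                        interior = interior, interval = interval),
                   class = "escape_fit")
  if (n_boot > 0) {
    st <- c(log(nu_hat), stats::qlogis(min(max(p_hat, 1e-4), 1 - 1e-4)))
    fit$boot <- bootstrap_ci(xo, function(x) {
      f <- fit_gamma_escape(x, interval = interval, start = st)
      c(nu = f$nu_hat, p = f$p_hat)
    }, n_boot = n_boot, seed = seed)
  }
  fit
}

#' @export
print.escape_fit <- function(x, ...) {
  cat(sprintf(
    "gamma-escape fit: nu = %.3f, p = %.4f (loglik %.2f, %d meioses)\n",
    x$nu_hat, x$p_hat, x$loglik, x$n_meioses))
  invisible(x)
}

#' Individual-level bootstrap for interference fits
#'
#' Resamples individuals (all of their chromosomes together) with replacement
#' within the supplied dataset, refits, and reports percentile intervals.
#' Replicates whose resampled data contain no crossovers at all cannot be fit
#' and are recorded as failed (excluded, with a count).
#'
#' @param xo an [xo_data] object with at least two individuals.
#' @param fitter function taking an `xo_data` and returning a named numeric
#'   vector of estimates.
#' @param n_boot number of replicates (1000 is the conventional choice).
#' @param seed RNG seed.
#' @return List with `replicates` (matrix, one row per successful replicate),
#'   `ci95` and `ci50` (matrices, one row per estimate), and `n_failed`.
#' @export
bootstrap_ci <- function(xo, fitter, n_boot = 1000, seed = NULL) {
  validate_xo_data(xo)
  ids <- unique(xo$individual)
  if (length(ids) < 2L) stop("bootstrap requires at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    xb <- resample_individuals(xo, sample(ids, replace = TRUE))
    if (sum(n_crossovers(xb)) == 0L) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[b]] <- fitter(xb)
  }
  reps <- do.call(rbind, reps)
  qm <- function(prob) t(apply(reps, 2, stats::quantile, probs = prob,
                               na.rm = TRUE))
  list(replicates = reps, ci95 = qm(c(0.025, 0.975)), ci50 = qm(c(0.25, 0.75)),
       n_failed = n_failed)
}

#' Pool per-group fits into a single "full" model
#'
#' @param fits list of `gamma_fit` or `escape_fit` objects, one per group.
#' @return List with summed `df` and `loglik`.
#' @export
pool_fits <- function(fits) {
  list(df = sum(vapply(fits, function(f) as.integer(f$df), integer(1))),
       loglik = sum(vapply(fits, function(f) f$loglik, numeric(1))))
}

# canonical nesting among the four standard model variants
NESTED_PAIRS <- list(c("gamma.null", "gamma.full"),
                     c("gamma.null", "gamma-escape.null"),
                     c("gamma.null", "gamma-escape.full"),
                     c("gamma.full", "gamma-escape.full"),
                     c("gamma-escape.null", "gamma-escape.full"))

#' Likelihood-ratio test between nested models
#'
#' @param loglik_null,df_null log-likelihood and parameter count of the
#'   restricted model.
#' @param loglik_full,df_full log-likelihood and parameter count of the
#'   richer model.
#' @return List with `statistic`, `df` and `p` (chi-square upper tail).
#' @export
lrt_test <- function(loglik_null, df_null, loglik_full, df_full) {
  if (df_full <= df_null) stop("models are not nested (df_full <= df_null)")
  stat <- 2 * (loglik_full - loglik_null)
  list(statistic = stat, df = df_full - df_null,
       p = chisq_sf(max(stat, 0), df_full - df_null))
}

#' Compare interference models by AIC and likelihood-ratio tests
#'
#' @param fits named list of fits or `pool_fits` results; recognized names are
#'   `gamma.null`, `gamma.full`, `gamma-escape.null`, `gamma-escape.full`
#'   (the null variants share one parameter set across groups, the full
#'   variants have per-group parameters).
#' @param pairs optional list of `c(null, full)` name pairs to test; defaults
#'   to every nested pair present. Requesting a non-nested pair is an error.
#' @return List of class `model_comparison`: `models` data frame (model, df,
#'   loglik, AIC with AIC = 2 df - 2 loglik) and `lrt` data frame (null, full,
#'   statistic, df, p).
#' @export
compare_models <- function(fits, pairs = NULL) {
  stopifnot(!is.null(names(fits)), all(nzchar(names(fits))))
  models <- data.frame(model = names(fits),
                       df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
                       loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                       row.names = NULL)
  models$AIC <- 2 * models$df - 2 * models$loglik
  if (is.null(pairs)) {
    pairs <- Filter(function(p) all(p %in% names(fits)), NESTED_PAIRS)
  } else {
    known <- vapply(pairs, function(p)
      any(vapply(NESTED_PAIRS, function(q) identical(q, p), logical(1))),
      logical(1))
    if (!all(known))
      stop("non-nested model pair requested: ",
           paste(vapply(pairs[!known], paste, character(1), collapse = " vs "),
                 collapse = "; "))
  }
  lrt <- do.call(rbind, lapply(pairs, function(p) {
    f0 <- fits[[p[1]]]; f1 <- fits[[p[2]]]
    t <- lrt_test(f0$loglik, f0$df, f1$loglik, f1$df)
    data.frame(null = p[1], full = p[2], statistic = t$statistic, df = t$df,
               p = t$p)
  }))
  structure(list(models = models, lrt = lrt), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (AIC = 2 df - 2 LL):\n")
  print(x$models, row.names = FALSE)
  if (!is.null(x$lrt) && nrow(x$lrt)) {
    cat("likelihood-ratio tests:\n")
    print(x$lrt, row.names = FALSE)
  }
  invisible(x)
}
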