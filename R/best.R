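# Robust Bayesian two-group estimation ("BEST"-style model):
#   y_gi ~ StudentT(nu, mu_g, sigma_g),  g = 1, 2
# with the canonical broad priors
#   mu_g ~ Normal(pooled mean, (1000 * pooled SD)^2)
#   sigma_g ~ Uniform(pooled SD / 1000, 1000 * pooled SD)
#   nu ~ 1 + Exponential(mean 29), shared across groups.
#
# Sampling is data-augmentation Gibbs: the Student-t is expressed as a
# Gamma scale mixture of normals (latent per-observation precisions
# lambda_gi ~ Gamma(nu/2, nu/2)), giving conjugate updates for mu_g and
# sigma_g^2 (the latter as a truncated Gamma on the precision, the
# truncation carrying the uniform-on-sigma prior bounds), plus an adaptive
# random-walk Metropolis step on log(nu - 1).

#' Priors for the robust two-group model
#'
#' @param y1,y2 the two data vectors.
#' @return list with `mu_mean`, `mu_sd`, `sigma_lo`, `sigma_hi`, `nu_mean`.
#' @export
best_priors <- function(y1, y2) {
  pooled <- c(y1, y2)
  m <- mean(pooled); s <- sd(pooled)
  if (!is.finite(s) || s <= 0) s <- max(abs(m), 1) * 1e-3 + 1e-6
  list(mu_mean = m, mu_sd = 1000 * s, sigma_lo = s / 1000, sigma_hi = 1000 * s,
       nu_mean = 29)
}

# One-group conjugate updates given latent precisions lam (vector).
update_mu <- function(y, lam, sigma2, prior_mean, prior_sd) {
  p0 <- 1 / prior_sd^2
  pn <- sum(lam) / sigma2
  post_mean <- (p0 * prior_mean + sum(lam * y) / sigma2) / (p0 + pn)
  rnorm(1, post_mean, 1 / sqrt(p0 + pn))
}

update_sigma2 <- function(y, lam, mu, sigma_lo, sigma_hi) {
  n <- length(y)
  ss <- sum(lam * (y - mu)^2)
  shape <- (n - 1) / 2
  rate <- ss / 2
  lo_tau <- 1 / sigma_hi^2; hi_tau <- 1 / sigma_lo^2
  p_lo <- pgamma(lo_tau, shape, rate = rate)
  p_hi <- pgamma(hi_tau, shape, rate = rate)
  u <- runif(1, p_lo, p_hi)
  tau <- qgamma(min(max(u, 1e-12), 1 - 1e-12), shape, rate = rate)
  if (!is.finite(tau) || tau <= 0) tau <- shape / rate
  1 / tau
}

# Marginal log-posterior of nu (latent precisions integrated out):
# Student-t likelihood in both groups plus the shifted-exponential prior.
log_post_nu <- function(nu, z1, z2, nu_mean) {
  if (nu <= 1) return(-Inf)
  sum(dt(z1, df = nu, log = TRUE)) + sum(dt(z2, df = nu, log = TRUE)) -
    (nu - 1) / nu_mean
}

run_best_chain <- function(y1, y2, priors, warmup, draws, thin = 1L) {
  n1 <- length(y1); n2 <- length(y2)
  mu1 <- mean(y1) + rnorm(1, 0, sd(y1) / sqrt(n1) + 1e-9)
  mu2 <- mean(y2) + rnorm(1, 0, sd(y2) / sqrt(n2) + 1e-9)
  s1 <- max(sd(y1), priors$sigma_lo * 2); s2 <- max(sd(y2), priors$sigma_lo * 2)
  sigma21 <- s1^2 * exp(rnorm(1, 0, 0.2)); sigma22 <- s2^2 * exp(rnorm(1, 0, 0.2))
  nu <- 1 + rexp(1, 1 / 5)
  step <- 0.5; acc_target <- 0.44
  total <- warmup + draws * thin
  out <- matrix(NA_real_, draws, 5L,
                dimnames = list(NULL, c("mu1", "mu2", "sigma1", "sigma2", "nu")))
  k <- 0L
  for (it in seq_len(total)) {
    # nu first, on the collapsed (lambda-marginalized) target; lambda is then
    # regenerated from its full conditional, keeping the scheme valid.
    z1 <- (y1 - mu1) / sqrt(sigma21); z2 <- (y2 - mu2) / sqrt(sigma22)
    lp_cur <- log_post_nu(nu, z1, z2, priors$nu_mean)
    theta <- log(nu - 1)
    theta_new <- theta + rnorm(1, 0, step)
    nu_new <- 1 + exp(theta_new)
    log_r <- (log_post_nu(nu_new, z1, z2, priors$nu_mean) + theta_new) -
             (lp_cur + theta)
    acc <- is.finite(log_r) && log(runif(1)) < log_r
    if (acc) nu <- nu_new
    if (it <= warmup)
      step <- exp(log(step) + (as.numeric(acc) - acc_target) / sqrt(it))
    # latent precisions, then conjugate location/scale updates
    lam1 <- rgamma(n1, (nu + 1) / 2, rate = (nu + (y1 - mu1)^2 / sigma21) / 2)
    lam2 <- rgamma(n2, (nu + 1) / 2, rate = (nu + (y2 - mu2)^2 / sigma22) / 2)
    mu1 <- update_mu(y1, lam1, sigma21, priors$mu_mean, priors$mu_sd)
    mu2 <- update_mu(y2, lam2, sigma22, priors$mu_mean, priors$mu_sd)
    sigma21 <- update_sigma2(y1, lam1, mu1, priors$sigma_lo, priors$sigma_hi)
    sigma22 <- update_sigma2(y2, lam2, mu2, priors$sigma_lo, priors$sigma_hi)
    if (it > warmup && (it - warmup) %% thin == 0L) {
      k <- k + 1L
      out[k, ] <- c(mu1, mu2, sqrt(sigma21), sqrt(sigma22), nu)
    }
  }
  out
}

#' Fit the robust Bayesian two-group model
#'
#' @param y1,y2 numeric data vectors (each length >= 2, finite).
#' @param priors prior list from [best_priors()]; defaults to data-derived
#'   canonical priors.
#' @param chains number of MCMC chains (>= 2).
#' @param warmup,draws warmup iterations and retained draws per chain.
#' @param seed integer seed; the draw sequence is deterministic given seed
#'   and config.
#' @param check if `TRUE` (default), reject runs failing R-hat < 1.01 or
#'   effective sample size >= 200 for mu1 - mu2 with a diagnostics report.
#' @return object of class `best_posterior`: `draws` (data.frame `mu1`,
#'   `mu2`, `sigma1`, `sigma2`, `nu`, `mu_diff`, `effect_size` pooled over
#'   chains), `chains`/`warmup`/`draws_per_chain`/`seed`, `priors`,
#'   `rhat` and `ess` (named, incl. `mu_diff`).
#' @export
best_fit <- function(y1, y2, priors = NULL, chains = 4L, warmup = 2000L,
                     draws = 5000L, seed = 1L, check = TRUE) {
  if (length(y1) < 2L || length(y2) < 2L)
    data_error("each group needs at least 2 observations")
  if (!all(is.finite(y1)) || !all(is.finite(y2)))
    data_error("non-finite values in input")
  if (chains < 2L) config_error("need at least 2 chains")
  if (warmup <= 0L || draws <= 0L) config_error("warmup and draws must be > 0")
  priors <- priors %||% best_priors(y1, y2)
  sims <- with_seed(substream_seed(seed, "best"),
                    lapply(seq_len(chains), function(ch)
                      run_best_chain(y1, y2, priors, warmup, draws)))
  arr <- array(NA_real_, c(draws, chains, 5L),
               dimnames = list(NULL, NULL, colnames(sims[[1L]])))
  for (ch in seq_len(chains)) arr[, ch, ] <- sims[[ch]]
  diff_mat <- arr[, , "mu1"] - arr[, , "mu2"]
  es_mat <- diff_mat / sqrt((arr[, , "sigma1"]^2 + arr[, , "sigma2"]^2) / 2)
  par_mats <- c(lapply(dimnames(arr)[[3L]], function(p) arr[, , p]),
                list(diff_mat, es_mat))
  names(par_mats) <- c(dimnames(arr)[[3L]], "mu_diff", "effect_size")
  rh <- vapply(par_mats, split_rhat, 0)
  es <- vapply(par_mats, ess_mean, 0)
  pooled <- data.frame(lapply(par_mats, as.vector))
  post <- structure(list(draws = pooled, chains = chains, warmup = warmup,
                         draws_per_chain = draws, seed = seed, priors = priors,
                         rhat = rh, ess = es, n1 = length(y1), n2 = length(y2)),
                    class = "best_posterior")
  if (check && (any(rh[c("mu1", "mu2", "mu_diff")] >= 1.01) ||
                es[["mu_diff"]] < 200)) {
    stop(errorCondition(
      paste0("MCMC run rejected: max R-hat = ", round(max(rh), 4),
             ", ESS(mu_diff) = ", round(es[["mu_diff"]], 1),
             " (need R-hat < 1.01 and ESS >= 200); ",
             "increase warmup/draws or chains"),
      class = c("oxphos_convergence_error", "error"),
      diagnostics = list(rhat = rh, ess = es)))
  }
  post
}

#' @export
print.best_posterior <- function(x, ...) {
  h <- hdi(x$draws$mu_diff, 0.95)
  cat(sprintf("<best_posterior> mu1-mu2 mean = %.3f, 95%% HDI [%.3f, %.3f], effect size = %.3f\n",
              mean(x$draws$mu_diff), h[1], h[2], mean(x$draws$effect_size)))
  cat(sprintf("  chains = %d, draws/chain = %d, max R-hat = %.4f, ESS(mu_diff) = %.0f\n",
              x$chains, x$draws_per_chain, max(x$rhat), x$ess[["mu_diff"]]))
  invisible(x)
}

#' @export
summary.best_posterior <- function(object, mass = 0.95, ...) {
  h <- hdi(object$draws$mu_diff, mass)
  data.frame(mu_diff_mean = mean(object$draws$mu_diff),
             hdi_lower = h[1], hdi_upper = h[2],
             effect_size_mean = mean(object$draws$effect_size),
             nu_median = median(object$draws$nu),
             rhat_max = max(object$rhat), ess_mu_diff = object$ess[["mu_diff"]],
             n1 = object$n1, n2 = object$n2, seed = object$seed)
}

#' Highest density interval of MCMC draws
#'
#' The shortest interval whose endpoints are sorted draws `ceiling(mass * n)`
#' apart (the canonical HDIofMCMC convention, so the interval spans
#' `ceiling(mass * n) + 1` draws); among equal-width candidates the one with
#' the lowest lower bound is returned.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param mass credible mass in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  assert_scalar_number(mass, "mass", 0, 1, strict = TRUE)
  n <- length(draws)
  if (n < 100L) data_error("need at least 100 draws for an HDI")
  xs <- sort(draws)
  inc <- ceiling(mass * n)
  if (inc >= n) return(c(xs[1L], xs[n]))
  widths <- xs[(inc + 1L):n] - xs[seq_len(n - inc)]
  i <- which.min(widths)  # which.min takes the first (lowest lower bound) tie
  c(xs[i], xs[i + inc])
}

#' Effect-size draws and summary
#'
#' (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2), computed per posterior
#' draw and summarized by the mean.
#'
#' @param posterior a `best_posterior`.
#' @return list with `draws` (numeric vector) and `mean`.
#' @export
effect_size <- function(posterior) {
  stopifnot(inherits(posterior, "best_posterior"))
  d <- posterior$draws$effect_size
  list(draws = d, mean = mean(d))
}

# Split-chain R-hat (each chain halved; rank-free classic version).
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, var)
  b <- nn * var(means)
  w <- mean(vars)
  if (w <= 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# Effective sample size for the mean, Geyer initial-monotone truncation on
# chain-averaged autocorrelations (rstan-style, direct autocovariance).
ess_mean <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  max_lag <- min(n - 1L, 500L)
  acov <- matrix(0, max_lag + 1L, m)
  for (ch in seq_len(m)) {
    x <- mat[, ch] - mean(mat[, ch])
    for (lag in 0:max_lag)
      acov[lag + 1L, ch] <- sum(x[seq_len(n - lag)] * x[(lag + 1L):n]) / n
  }
  w <- mean(acov[1L, ] * n / (n - 1))
  var_plus <- mean(acov[1L, ]) * (n - 1) / n + var(colMeans(mat))
  if (var_plus <= 0) return(m * n)
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  rho[1L] <- 1
  # Geyer: sum consecutive pairs while positive and monotone
  tau <- 0; t <- 1L
  prev_pair <- Inf
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m))
  min(m * n / tau, m * n)
}
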