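# Classical statistics used alongside the Bayesian machinery: Spearman
# correlation, Mann-Whitney U, OLS with r^2, the 95% data ellipse, and
# per-group neuron-count summaries.

# Iteratively build the matrix of all permutations of 1..n (rows).
all_permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- ((pos - 1L) * m + 1L):(pos * m)
      out[rows, pos] <- k
      out[rows, -pos] <- P
    }
    P <- out
  }
  P
}

#' Spearman rank correlation
#'
#' Midrank-based rank correlation with a two-sided p-value: exact by full
#' permutation enumeration for n <= 9 without ties, t-approximation
#' otherwise.
#'
#' @param x,y numeric vectors (n >= 4).
#' @return list with `r`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) data_error("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    data_error("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    P <- all_permutations(n)
    # S = sum of squared rank differences against the fixed x ranking
    s_perm <- rowSums(sweep(P, 2L, rx)^2)
    r_perm <- 1 - 6 * s_perm / (n * (n^2 - 1))
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(r = r, p = p, n = n, method = method)
}

# Exact null distribution of the rank sum of the a-sample: subset-count DP
# (number of size-m subsets of ranks 1..N with each possible sum).
ranksum_distribution <- function(m, N) {
  max_sum <- sum((N - m + 1L):N)
  counts <- matrix(0, m + 1L, max_sum + 1L)  # [size+1, sum+1]
  counts[1L, 1L] <- 1
  for (rk in seq_len(N)) {
    for (sz in rev(seq_len(min(rk, m)))) {
      reach <- which(counts[sz, ] > 0)
      if (length(reach))
        counts[sz + 1L, reach + rk] <- counts[sz + 1L, reach + rk] + counts[sz, reach]
    }
  }
  counts[m + 1L, ]
}

#' Mann-Whitney U test
#'
#' U counts the pairs where an `a` value beats a `b` value (ties count
#' half). The p-value is exact - from the full null distribution of U over
#' all group assignments - when `length(a) * length(b) <= 400` and there are
#' no ties; otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param a,b numeric vectors (each n >= 1).
#' @param alternative only `"two.sided"` is implemented.
#' @return list with `U`, `p`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  stopifnot(alternative == "two.sided")
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) data_error("both groups need at least one value")
  N <- na + nb
  rk <- rank(c(a, b))
  ra <- sum(rk[seq_len(na)])
  U <- ra - na * (na + 1) / 2  # = #{a > b} + 0.5 * ties
  m <- na * nb
  ties <- anyDuplicated(c(a, b)) > 0L
  if (m <= 400 && !ties) {
    dist <- ranksum_distribution(na, N)
    total <- sum(dist)
    u_all <- (seq_along(dist) - 1) - na * (na + 1) / 2  # U for each rank sum
    lo <- min(U, m - U); hi <- max(U, m - U)
    p <- min(1, (sum(dist[u_all <= lo]) + sum(dist[u_all >= hi])) / total)
    method <- "exact"
  } else {
    mu <- m / 2
    tie_tab <- table(rk)
    sig2 <- (m / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- U - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)  # continuity correction
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = U, p = p, n_a = na, n_b = nb, method = method)
}

#' Simple linear regression with r-squared
#'
#' OLS of y on x; `r2 = 1 - SSE/SST`; two-sided p from the t statistic of
#' the slope (df = n - 2).
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
linreg_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) data_error("need at least 3 complete pairs")
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  if (sxx <= 0)
    stop(errorCondition("degenerate design: constant x",
                        class = c("oxphos_degenerate_error", "error")))
  b <- sum((x - xbar) * (y - mean(y))) / sxx
  a <- mean(y) - b * xbar
  sse <- sum((y - a - b * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  if (sse <= 0) {
    p <- 0
  } else {
    se_b <- sqrt(sse / (n - 2) / sxx)
    p <- 2 * pt(-abs(b / se_b), df = n - 2)
  }
  list(slope = b, intercept = a, r2 = r2, p = p, n = n)
}

#' Confidence (data) ellipse of a 2-D scatter
#'
#' Mean + covariance eigendecomposition; semi-axis lengths are
#' `sqrt(eigenvalue * q)` where `q` is the chi-square(2) quantile at `level`
#' (5.991 at 0.95) for the population ("data ellipse") form, or the
#' small-sample F form `2 (n-1)/(n-2) F(level; 2, n-2)` when
#' `form = "F"`.
#'
#' @param points two-column matrix/data.frame of (x, y).
#' @param level confidence level in (0, 1).
#' @param form `"chisq"` (default) or `"F"`.
#' @return object of class `ellipse_spec`: `center`, `semi_axes`,
#'   `angle` (radians, first principal axis vs x), `level`, `cov`.
#' @export
confidence_ellipse <- function(points, level = 0.95, form = c("chisq", "F")) {
  form <- match.arg(form)
  assert_scalar_number(level, "level", 0, 1, strict = TRUE)
  pts <- as.matrix(points)
  if (nrow(pts) < 3L) data_error("need at least 3 points")
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  if (det(S) <= 0)
    stop(errorCondition("singular covariance: degenerate scatter",
                        class = c("oxphos_degenerate_error", "error")))
  e <- eigen(S, symmetric = TRUE)
  n <- nrow(pts)
  q <- if (form == "chisq") stats::qchisq(level, 2) else
    2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  structure(list(center = ctr, semi_axes = sqrt(e$values * q),
                 angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                 level = level, cov = S, q = q),
            class = "ellipse_spec")
}

#' @rdname confidence_ellipse
#' @param spec an `ellipse_spec`.
#' @export
in_ellipse <- function(spec, points) {
  pts <- sweep(as.matrix(points), 2L, spec$center)
  d2 <- rowSums((pts %*% solve(spec$cov)) * pts)
  d2 <= spec$q
}

#' Per-group neuron-count summary
#'
#' Mean, sample SD (n-1 denominator) and total of per-case neuron counts by
#' group; rounding is left to report time (conventionally 1 decimal).
#'
#' @param counts data.frame with columns `group` and `n_neurons` (one row
#'   per case), or a named list of per-case count vectors.
#' @return data.frame `group`, `n_cases`, `mean`, `sd`, `total`.
#' @export
summarize_counts <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- data.frame(
      group = rep(names(counts), lengths(counts)),
      n_neurons = unlist(counts, use.names = FALSE))
  }
  stopifnot(all(c("group", "n_neurons") %in% names(counts)))
  rows <- lapply(split(counts$n_neurons, counts$group), function(v)
    data.frame(n_cases = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0, total = sum(v)))
  out <- do.call(rbind, rows)
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Per-case neuron counts of the original midbrain cohort
#'
#' The published per-case numbers of analysed neurons (9 PD, 4 POLG, 10
#' control cases), shipped as a plain-text fixture; these are inputs for the
#' count-summary worked example.
#'
#' @return data.frame with columns `group`, `case_id`, `n_neurons`.
#' @export
reference_neuron_counts <- function() {
  path <- system.file("extdata", "cohort_neuron_counts.csv",
                      package = "oxphosimc", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
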