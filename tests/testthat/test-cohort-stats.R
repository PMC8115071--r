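test_that("spearman correlation handles monotone data and midrank ties", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$r, 1)
  x <- 1:5; y <- c(5, 6, 7, 8, 7)
  sp <- spearman_cor(x, y)
  # midrank oracle: Pearson correlation of the rank vectors
  expect_equal(sp$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(sp$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "oxphos_data_error")
})

test_that("exact spearman p matches an independent enumeration at n = 5", {
  x <- c(2, 4, 1, 5, 3); y <- c(10, 40, 20, 50, 30)
  sp <- spearman_cor(x, y)
  expect_identical(sp$method, "exact permutation")
  # independent oracle: enumerate permutations via recursive index expansion
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  rx <- rank(x)
  r_all <- apply(perms, 1, function(p) cor(rx, p))
  expect_equal(sp$p, mean(abs(r_all) >= abs(sp$r) - 1e-12), tolerance = 1e-12)
})

test_that("shuffled data have null-centered spearman r", {
  set.seed(149)
  x <- rnorm(30)
  r_bar <- mean(replicate(500, spearman_cor(x, sample(x))$r))
  expect_lt(abs(r_bar), 0.05)
})

test_that("mann-whitney U convention and exact p match the enumeration example", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)  # U counts a-over-b wins
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  expect_identical(mw$method, "exact")
  # identical groups: exact p = 1 (ties force the approximate path; use
  # distinct interleaved values instead for the exact-path check)
  mw2 <- mann_whitney(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(mw2$p, 1, tolerance = 1e-12)
  # matches wilcox.test's W and exact p
  set.seed(151)
  for (rep in 1:10) {
    a <- sample(100, 6); b <- setdiff(sample(100, 13), a)[1:6]
    mw3 <- mann_whitney(a, b)
    wt <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mw3$U, unname(wt$statistic))
    expect_equal(mw3$p, wt$p.value, tolerance = 1e-12)
  }
})

test_that("mann-whitney approximation handles ties like the corrected normal test", {
  set.seed(157)
  a <- sample(1:8, 30, replace = TRUE)
  b <- sample(3:10, 30, replace = TRUE)
  mw <- mann_whitney(a, b)
  expect_identical(mw$method, "normal approximation")
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  # a == b (all tied): the corrected normal path still gives p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # large shifted samples are decisively separated
  expect_lt(mann_whitney(rnorm(80), rnorm(80, 2))$p, 0.001)
  # symmetry under group swap
  expect_equal(mann_whitney(b, a)$p, mw$p, tolerance = 1e-12)
})

test_that("linear regression r2 and p match the closed form and lm", {
  expect_equal(linreg_r2(1:10, 2 * (1:10) + 3)$r2, 1)
  fx <- five_point_controls()
  lr <- linreg_r2(fx$x, fx$y)
  lmfit <- summary(lm(fx$y ~ fx$x))
  expect_equal(lr$slope, unname(coef(lmfit)[2, 1]), tolerance = 1e-12)
  expect_equal(lr$r2, lmfit$r.squared, tolerance = 1e-12)
  expect_equal(lr$p, unname(coef(lmfit)[2, 4]), tolerance = 1e-12)
  set.seed(163)
  expect_lt(linreg_r2(rnorm(1000), rnorm(1000))$r2, 0.01)
  expect_error(linreg_r2(rep(1, 5), rnorm(5)), class = "oxphos_degenerate_error")
})

test_that("confidence ellipse axes follow the chi-square quantile", {
  set.seed(167)
  raw <- matrix(rnorm(400), ncol = 2)
  # whiten so the sample covariance is exactly the identity
  pts <- scale(raw, scale = FALSE) %*% solve(chol(cov(raw)))
  spec <- confidence_ellipse(pts)
  expect_equal(unname(spec$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-9)
  # rotation equivariance: axes unchanged, angle shifts by the rotation
  set.seed(173)
  base <- cbind(rnorm(300, sd = 3), rnorm(300, sd = 1))
  th <- 30 * pi / 180
  R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  s1 <- confidence_ellipse(base)
  s2 <- confidence_ellipse(base %*% t(R))
  expect_equal(s2$semi_axes, s1$semi_axes, tolerance = 1e-9)
  ang_diff <- (s2$angle - s1$angle - th) %% pi
  expect_lt(min(ang_diff, pi - ang_diff), 1e-9)
  # coverage oracle on a large standard-normal sample
  set.seed(179)
  big <- matrix(rnorm(10000), ncol = 2)
  spec2 <- confidence_ellipse(big)
  expect_lt(abs(mean(in_ellipse(spec2, big)) - 0.95), 0.02)
  # F form is wider than the chi-square form at small n
  small <- matrix(rnorm(20), ncol = 2)
  expect_gt(confidence_ellipse(small, form = "F")$semi_axes[1],
            confidence_ellipse(small, form = "chisq")$semi_axes[1])
})

test_that("count summaries use the sample SD and reproduce the bundled cohort", {
  cs <- summarize_counts(list(g = c(40, 40, 40)))
  expect_equal(cs$sd, 0)
  expect_equal(cs$total, 120)
  counts <- reference_neuron_counts()
  s <- summarize_counts(counts[, c("group", "n_neurons")])
  pd <- s[s$group == "PD", ]; polg <- s[s$group == "POLG", ]
  expect_equal(round(pd$mean, 1), 35.1)
  expect_equal(round(pd$sd, 1), 9.6)
  expect_equal(pd$total, 316)
  expect_equal(round(polg$mean, 1), 39)
  expect_equal(round(polg$sd, 1), 11.7)
  expect_equal(polg$total, 156)
  expect_equal(s[s$group == "control", "total"], 437)
  # permutation invariance
  shuf <- counts[sample(nrow(counts)), ]
  expect_equal(summarize_counts(shuf[, c("group", "n_neurons")]), s,
               ignore_attr = TRUE)
})
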