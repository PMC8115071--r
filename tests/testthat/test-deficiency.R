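test_that("the decreased call is the strict lower-PI rule", {
  fx <- five_point_controls()
  fit <- fit_control_regression(fx$tab, "NDUFB8")
  # on the line: not decreased
  expect_false(call_decreased(fit, fit$xbar, fit$a + fit$b * fit$xbar))
  # 10 residual SDs below the line at xbar: decreased
  expect_true(call_decreased(fit, fit$xbar,
                             fit$a + fit$b * fit$xbar - 10 * fit$s_resid))
  # exactly on the lower limit: tie is not decreased
  lo <- prediction_interval(fit, fit$xbar, 0.80)$lower
  expect_false(call_decreased(fit, fit$xbar, lo))
  expect_true(call_decreased(fit, fit$xbar, lo - 1e-9))
})

test_that("fresh control-like neurons are flagged at the one-sided 10% rate", {
  sim <- simulate_cohort(ctrl_config(seed = 31))
  fit <- fit_control_regression(sim$table, "NDUFB8")
  fresh <- simulate_cohort(cohort_config(
    groups = list(group_spec("control", 1, 2000, 0)),
    regression = within(default_regression(), s <- 0.25), seed = 32))$table
  flags <- call_decreased(fit, log(fresh$VDAC1), log(fresh$NDUFB8))
  expect_gte(mean(flags), 0.08)
  expect_lte(mean(flags), 0.12)
})

test_that("complex calls follow the representative-subunit rule", {
  flags <- c(NDUFB8 = TRUE, NDUFA13 = FALSE, SDHA = FALSE, UqCRC2 = FALSE,
             MTCO1 = FALSE, COX4 = TRUE, ATP5B = FALSE, OSCP = TRUE)
  cc <- complex_calls(flags)
  expect_false(cc[["CI"]])   # NDUFB8 alone does not drive complex I
  expect_false(cc[["CIV"]])  # COX4 alone does not drive complex IV
  expect_false(any(cc))
  all_on <- setNames(rep(TRUE, 8), names(flags))
  expect_true(all(complex_calls(all_on)))
  expect_identical(sum(complex_calls(all_on)), 5L)
  expect_error(complex_calls(flags[-2]), class = "oxphos_data_error")
})

test_that("case summaries match hand enumeration", {
  flags <- matrix(FALSE, 4, 5)
  flags[1, 1] <- TRUE                       # neuron 1: category 1 (CI)
  flags[4, ] <- TRUE                        # neuron 4: category 5
  prof <- toy_profiles(flags)
  cs <- summarize_case(prof)
  expect_identical(cs$n_neurons, 4L)
  expect_equal(cs$pct_NDUFA13, 50)          # neurons 1 and 4 flag CI's rep
  expect_equal(cs$pct_SDHA, 25)
  expect_equal(cs$pct_cat0, 50)
  expect_equal(cs$pct_cat1, 25)
  expect_equal(cs$pct_cat5, 25)
  expect_equal(cs$pct_cat2 + cs$pct_cat3 + cs$pct_cat4, 0)
  expect_equal(sum(unlist(cs[paste0("pct_cat", 0:5)])), 100, tolerance = 1e-9)
})

test_that("binomial-scale case percentages emerge from the generator", {
  cfg <- deficit_config(seed = 41, delta = 1.5, pi = 0.5, n_cases = 1, npc = 200)
  sim <- simulate_cohort(cfg)
  model <- fit_control_model(sim$table[sim$table$group == "control", ])
  prof <- profile_neurons(model, sim$table)
  cs <- summarize_case(prof)
  pd <- cs[cs$group == "PD", ]
  expect_gt(pd$pct_NDUFA13, 40)
  expect_lt(pd$pct_NDUFA13, 60)
})

test_that("conditional profiles match hand enumeration and independence", {
  # toy 6-neuron case: CI decreased in neurons 1-3; CIV decreased in 1,4
  flags <- matrix(FALSE, 6, 5)
  flags[1:3, 1] <- TRUE
  flags[c(1, 4), 4] <- TRUE
  prof <- toy_profiles(flags)
  cp <- conditional_profile(prof, "CI")
  dec <- cp[cp$stratum == "decreased", ]
  nor <- cp[cp$stratum == "normal", ]
  expect_identical(dec$n, 3L)
  expect_equal(dec$pct_CI, 100)
  expect_equal(dec$pct_CIV, 100 * 1 / 3)
  expect_identical(nor$n, 3L)
  expect_equal(nor$pct_CIV, 100 * 1 / 3)
  # no anchor-decreased neurons anywhere -> empty decreased stratum
  cp0 <- conditional_profile(toy_profiles(matrix(FALSE, 4, 5)), "CII")
  expect_identical(nrow(cp0[cp0$stratum == "decreased", ]), 0L)
  # independent complexes: conditional ~ marginal within binomial error
  cfg <- deficit_config(seed = 43, delta = 2, pi = 0.4, n_cases = 1, npc = 400)
  sim <- simulate_cohort(cfg)
  model <- fit_control_model(sim$table[sim$table$group == "control", ])
  prof2 <- profile_neurons(model, sim$table)
  prof_pd <- prof2[prof2$group == "PD", ]
  cp2 <- conditional_profile(prof_pd, "CI")
  marg <- 100 * mean(prof_pd$dec_CIV)
  for (st in c("decreased", "normal")) {
    row <- cp2[cp2$stratum == st, ]
    se <- 100 * sqrt(0.25 / row$n)
    expect_lt(abs(row$pct_CIV - marg), 4 * se)
  }
})

test_that("severity stacks match hand counts and POLG-like composition", {
  flags <- matrix(FALSE, 3, 5)
  flags[2, 1] <- TRUE; flags[3, ] <- TRUE
  st <- severity_stack(toy_profiles(flags))
  expect_equal(st$categories$pct_cat0, 100 / 3, tolerance = 1e-9)
  expect_equal(st$categories$pct_cat1, 100 / 3, tolerance = 1e-9)
  expect_equal(st$categories$pct_cat5, 100 / 3, tolerance = 1e-9)
  # all-normal group
  st0 <- severity_stack(toy_profiles(matrix(FALSE, 5, 5)))
  expect_equal(st0$categories$pct_cat0, 100)
  # high per-complex pi: category 5 beats category 4 (Bernoulli composition)
  cfg <- cohort_config(groups = list(group_spec("control", 10, 45, 0),
                                     group_spec("POLG", 2, 300, 0, pi = 0.85)),
                       deficits = c(CI = 2, CII = 2, CIII = 2, CIV = 2, CV = 2),
                       seed = 47)
  sim <- simulate_cohort(cfg)
  model <- fit_control_model(sim$table[sim$table$group == "control", ])
  prof <- profile_neurons(model, sim$table)
  stp <- severity_stack(prof)
  polg <- stp$categories[stp$categories$group == "POLG", ]
  expect_gt(polg$pct_cat5, polg$pct_cat4)
})

test_that("adding a flagged complex never decreases the category", {
  set.seed(53)
  for (rep in 1:20) {
    flags <- matrix(runif(5) < 0.4, 1, 5)
    base_cat <- toy_profiles(flags)$n_complexes_decreased
    off <- which(!flags)
    if (!length(off)) next
    flags2 <- flags; flags2[sample(off, 1)] <- TRUE
    expect_gte(toy_profiles(flags2)$n_complexes_decreased, base_cat)
  }
})

test_that("summaries are invariant under neuron reordering", {
  cfg <- deficit_config(seed = 59, n_cases = 2, npc = 40)
  sim <- simulate_cohort(cfg)
  model <- fit_control_model(sim$table[sim$table$group == "control", ])
  prof <- profile_neurons(model, sim$table)
  perm <- sample(nrow(prof))
  prof_p <- prof[perm, ]
  cs1 <- summarize_case(prof)
  cs2 <- summarize_case(prof_p)
  expect_equal(cs2, cs1, ignore_attr = TRUE)
  st1 <- severity_stack(prof)$categories
  st2 <- severity_stack(prof_p)$categories
  expect_equal(st2, st1, ignore_attr = TRUE)
})

test_that("deficiency calling recovers ground-truth labels at delta = 4 s", {
  sim <- simulate_cohort(deficit_config(seed = 61, delta = 1, pi = 0.5,
                                        n_cases = 3, npc = 110))
  model <- fit_control_model(sim$table[sim$table$group == "control", ])
  prof <- profile_neurons(model, sim$table)
  rec <- recovery_metrics(prof[prof$group == "PD", ],
                          sim$truth[sim$truth$group == "PD", ])
  expect_gte(sum(sim$truth$group == "PD"), 300)
  expect_true(all(rec$recall >= 0.90))
  expect_true(all(rec$false_flag_rate <= 0.15))
})
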