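# Synthetic cohort generator: per-neuron intensity tables with ground-truth
# deficiency labels, statistically shaped like the normative model the
# analysis assumes (ln-ln linear dependence of each subunit on VDAC1 with
# homoscedastic ln-scale scatter, per-case neuron counts as rounded
# truncated normals, multiplicative per-complex deficits in labelled
# neuron subsets).

#' Group specification for a synthetic cohort
#'
#' @param name group label; conventionally one of `"control"`, `"PD"`, `"POLG"`.
#' @param n_cases number of cases (individuals).
#' @param neurons_mean,neurons_sd mean and SD of the per-case neuron count,
#'   drawn as a rounded normal truncated below at 5.
#' @param age_mean,age_sd mean and SD of per-case ages (years), truncated to
#'   \[18, 95\]; ignored when `ages` is given.
#' @param ages optional explicit per-case ages (length `n_cases`).
#' @param pi per-complex affected fraction: named numeric over CI..CV in
#'   \[0,1\] (recycled from a scalar).
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, n_cases, neurons_mean, neurons_sd,
                       age_mean = 70, age_sd = 10, ages = NULL, pi = 0) {
  complexes <- names(complex_representatives())
  if (length(pi) == 1L && is.null(names(pi))) pi <- rep(pi, 5L)
  if (is.null(names(pi))) names(pi) <- complexes
  pi <- pi[complexes]
  if (anyNA(pi) || any(pi < 0 | pi > 1))
    config_error("affected fractions `pi` must lie in [0, 1] for CI..CV")
  if (neurons_sd < 0) config_error("neurons_sd must be >= 0")
  if (!is.null(ages) && length(ages) != n_cases)
    config_error("`ages` must have one entry per case")
  structure(list(name = name, n_cases = as.integer(n_cases),
                 neurons_mean = neurons_mean, neurons_sd = neurons_sd,
                 age_mean = age_mean, age_sd = age_sd, ages = ages, pi = pi),
            class = "group_spec")
}

#' Cohort configuration
#'
#' Bundles everything [simulate_cohort()] needs: the group structure, the
#' control-truth ln-ln regression for each subunit, the ln-VDAC1
#' distribution, per-complex deficits and the master seed.
#'
#' @param groups list of [group_spec()] objects.
#' @param regression data.frame with columns `subunit`, `a` (intercept), `b`
#'   (slope), `s` (residual SD), all in ln-intensity units; one row per
#'   assayed subunit.
#' @param vdac list with `mean` and `sd` of ln VDAC1 (control truth).
#' @param deficits named numeric over CI..CV: the ln-units deficit subtracted
#'   from every subunit of an affected complex (multiplicative on the raw
#'   scale).
#' @param rho correlation knob in \[0,1) linking per-complex deficiency labels
#'   within a neuron through a shared Gaussian factor; 0 = independent.
#' @param seed master integer seed; independent substreams derive from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(groups, regression = default_regression(),
                          vdac = list(mean = 5, sd = 0.5),
                          deficits = c(CI = 1, CII = 1, CIII = 1, CIV = 1, CV = 1),
                          rho = 0, seed) {
  if (missing(seed)) config_error("`seed` is required")
  complexes <- names(complex_representatives())
  need <- c("subunit", "a", "b", "s")
  if (!all(need %in% names(regression)))
    config_error("regression must have columns subunit, a, b, s")
  if (any(regression$s < 0)) config_error("residual SDs must be >= 0")
  if (vdac$sd <= 0) config_error("ln-VDAC1 SD must be > 0")
  subs <- oxphos_subunits()
  if (!setequal(regression$subunit, names(subs)))
    config_error("regression must cover exactly the 8 assayed subunits")
  if (length(deficits) == 1L && is.null(names(deficits)))
    deficits <- structure(rep(deficits, 5L), names = complexes)
  deficits <- deficits[complexes]
  if (anyNA(deficits)) config_error("deficits must be named over CI..CV")
  if (rho < 0 || rho >= 1) config_error("rho must lie in [0, 1)")
  groups <- lapply(groups, function(g) {
    if (!inherits(g, "group_spec")) do.call(group_spec, g) else g
  })
  structure(list(groups = groups, regression = regression, vdac = vdac,
                 deficits = deficits, rho = rho, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default control-truth regression parameters
#'
#' Identity-slope ln-ln dependence on VDAC1 with residual SD 0.25 for every
#' subunit; the scatter is a free simulation parameter, not an estimate of
#' tissue biology.
#'
#' @return data.frame with columns `subunit`, `a`, `b`, `s`.
#' @export
default_regression <- function() {
  subs <- names(oxphos_subunits())
  data.frame(subunit = subs, a = 0, b = 1, s = 0.25, stringsAsFactors = FALSE)
}

#' Default three-group cohort configuration
#'
#' Control, PD and POLG groups whose case numbers, per-case neuron count
#' distributions and age distributions follow the published cohort summaries
#' (9 PD cases, 35.1 +/- 9.6 neurons; 4 POLG, 39.0 +/- 11.7; 10 controls,
#' 43.6 +/- 4.7; group mean ages 79.8 / 45.8 / 67.9). Deficit size defaults
#' to 1 ln-unit (= 4 residual SDs at the default scatter of 0.25) with
#' affected fractions 0 (control), 0.25 (PD) and 0.5 (POLG) per complex.
#'
#' @param seed master seed.
#' @inheritParams cohort_config
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(seed, deficits = c(CI = 1, CII = 1, CIII = 1,
                                                     CIV = 1, CV = 1),
                                  rho = 0) {
  cohort_config(
    groups = list(
      group_spec("control", 10, 43.6, 4.7, age_mean = 67.9, age_sd = 28.0,
                 pi = 0),
      group_spec("PD", 9, 35.1, 9.6, age_mean = 79.8, age_sd = 6.8,
                 pi = 0.25),
      group_spec("POLG", 4, 39.0, 11.7, age_mean = 45.8, age_sd = 28.1,
                 pi = 0.5)
    ),
    deficits = deficits, rho = rho, seed = seed
  )
}

#' Simulate a per-neuron intensity table with ground truth
#'
#' For each neuron, ln VDAC1 is drawn Normal(`vdac$mean`, `vdac$sd`); each
#' subunit k then follows ln I_k = a_k + b_k ln V + eps, eps ~ Normal(0,
#' s_k), minus the complex deficit delta_c when the neuron carries a
#' deficiency label for complex c (Bernoulli pi_c, optionally correlated
#' across complexes through `rho`). Intensities are returned on the raw
#' scale exp(ln I) > 0. Deterministic given the config seed; counts, ages,
#' labels and noise use independent substreams.
#'
#' @param config a [cohort_config()].
#' @return list of class `imc_cohort` with elements `table` (data.frame:
#'   `neuron_id`, `case_id`, `group`, `age`, one raw-intensity column per
#'   target incl. `VDAC1` and `TH`) and `truth` (data.frame: `neuron_id`,
#'   `case_id`, `group`, logical `def_CI`..`def_CV`, numeric
#'   `delta_CI`..`delta_CV` actually applied).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subs <- oxphos_subunits()
  complexes <- names(complex_representatives())
  reg <- config$regression
  rownames(reg) <- reg$subunit

  cases <- list()
  for (g in config$groups) {
    ncase <- g$n_cases
    counts <- with_seed(substream_seed(config$seed, paste0("counts/", g$name)),
                        pmax(5L, as.integer(round(rnorm(ncase, g$neurons_mean,
                                                        g$neurons_sd)))))
    ages <- g$ages %||%
      with_seed(substream_seed(config$seed, paste0("ages/", g$name)),
                round(pmin(95, pmax(18, rnorm(ncase, g$age_mean, g$age_sd)))))
    for (i in seq_len(ncase)) {
      cases[[length(cases) + 1L]] <- list(
        case_id = sprintf("%s%02d", g$name, i), group = g$name,
        age = ages[i], n = counts[i], pi = g$pi)
    }
  }

  tab_rows <- list(); truth_rows <- list()
  for (cs in cases) {
    n <- cs$n
    ids <- sprintf("%s_n%03d", cs$case_id, seq_len(n))
    lnV <- with_seed(substream_seed(config$seed, paste0("vdac/", cs$case_id)),
                     rnorm(n, config$vdac$mean, config$vdac$sd))
    # Gaussian-copula deficiency labels: shared factor w per neuron.
    lab <- with_seed(substream_seed(config$seed, paste0("labels/", cs$case_id)), {
      w <- rnorm(n)
      e <- matrix(rnorm(n * 5L), n, 5L)
      u <- sqrt(config$rho) * w + sqrt(1 - config$rho) * e
      thr <- qnorm(cs$pi)  # pi = 0 -> -Inf -> never labelled
      sweep(u, 2L, thr, `<`)
    })
    colnames(lab) <- complexes
    eps <- with_seed(substream_seed(config$seed, paste0("noise/", cs$case_id)),
                     matrix(rnorm(n * length(subs)), n, length(subs)))
    colnames(eps) <- names(subs)
    lnTH <- with_seed(substream_seed(config$seed, paste0("th/", cs$case_id)),
                      rnorm(n, 4, 0.3))

    intens <- matrix(NA_real_, n, length(subs),
                     dimnames = list(NULL, names(subs)))
    delta_applied <- matrix(0, n, 5L, dimnames = list(NULL, complexes))
    for (k in names(subs)) {
      cx <- subs[[k]]
      lnI <- reg[k, "a"] + reg[k, "b"] * lnV + reg[k, "s"] * eps[, k]
      hit <- lab[, cx]
      lnI[hit] <- lnI[hit] - config$deficits[[cx]]
      delta_applied[hit, cx] <- config$deficits[[cx]]
      intens[, k] <- exp(lnI)
    }

    tab_rows[[length(tab_rows) + 1L]] <- data.frame(
      neuron_id = ids, case_id = cs$case_id, group = cs$group, age = cs$age,
      intens, VDAC1 = exp(lnV), TH = exp(lnTH),
      stringsAsFactors = FALSE)
    tr <- data.frame(neuron_id = ids, case_id = cs$case_id, group = cs$group,
                     stringsAsFactors = FALSE)
    for (cx in complexes) tr[[paste0("def_", cx)]] <- lab[, cx]
    for (cx in complexes) tr[[paste0("delta_", cx)]] <- delta_applied[, cx]
    truth_rows[[length(truth_rows) + 1L]] <- tr
  }

  out <- list(table = do.call(rbind, tab_rows),
              truth = do.call(rbind, truth_rows),
              config = config)
  rownames(out$table) <- NULL; rownames(out$truth) <- NULL
  class(out) <- "imc_cohort"
  out
}

#' @export
print.imc_cohort <- function(x, ...) {
  cat("<imc_cohort>", nrow(x$table), "neurons,",
      length(unique(x$table$case_id)), "cases,",
      length(unique(x$table$group)), "groups\n")
  invisible(x)
}

#' Read/write neuron tables and ground truth as CSV
#'
#' @param table,truth data.frames as produced by [simulate_cohort()] or
#'   [extract_neuron_table()].
#' @param path CSV file path.
#' @return the read data.frame, or (invisibly) `path` for writers.
#' @export
write_neuron_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neuron_table
#' @export
read_neuron_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "case_id", "group")
  if (!all(need %in% names(tab)))
    data_error("neuron table must have columns neuron_id, case_id, group")
  tab
}

#' @rdname write_neuron_table
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Write/read a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @return `read_cohort_config()` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$groups <- lapply(x$groups, function(g) {
    g <- unclass(g); g$pi <- as.list(g$pi); g
  })
  x$deficits <- as.list(x$deficits)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) config_error("cohort config YAML must carry a seed")
  x$groups <- lapply(x$groups, function(g) {
    g$pi <- unlist(g$pi); do.call(group_spec, g)
  })
  reg <- x$regression
  if (is.list(reg) && !is.data.frame(reg))
    reg <- as.data.frame(lapply(reg, unlist), stringsAsFactors = FALSE)
  cohort_config(groups = x$groups, regression = reg, vdac = x$vdac,
                deficits = unlist(x$deficits), rho = x$rho %||% 0,
                seed = x$seed)
}
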