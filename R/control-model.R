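# The normative machinery: pooled-control ln-ln regression of each OxPhos
# subunit on ln VDAC1, vertical prediction intervals for deficiency calls,
# perpendicular-distance z-scores, and the ln-VDAC1 mass reference.

#' Fit the pooled-control regression for one subunit
#'
#' Ordinary least squares of y = ln(subunit intensity) on x = ln(VDAC1
#' intensity) over all control neurons (pooled across control cases).
#' Neurons with non-positive intensity in either channel are dropped and
#' counted. Residual SD `s_resid` uses the n-2 denominator; `s_perp` is the
#' n-1 sample SD of the signed perpendicular distances
#' d_i = (y_i - a - b x_i) / sqrt(1 + b^2).
#'
#' @param controls neuron table restricted to control neurons (raw-scale
#'   intensities).
#' @param subunit subunit column name (e.g. `"NDUFB8"`).
#' @param mass mass-marker column name (default `"VDAC1"`).
#' @return object of class `imc_regfit` with fields `subunit`, `a`, `b`,
#'   `n`, `xbar`, `sxx`, `s_resid`, `s_perp`, `n_dropped`.
#' @export
fit_control_regression <- function(controls, subunit, mass = "VDAC1") {
  if (!subunit %in% names(controls)) data_error(paste0("missing column ", subunit))
  if (!mass %in% names(controls)) data_error(paste0("missing column ", mass))
  ok <- is.finite(controls[[subunit]]) & is.finite(controls[[mass]]) &
    controls[[subunit]] > 0 & controls[[mass]] > 0
  n_dropped <- sum(!ok)
  x <- log(controls[[mass]][ok]); y <- log(controls[[subunit]][ok])
  n <- length(x)
  if (n < 3L) data_error("need at least 3 control neurons with positive intensities")
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  if (sxx <= 0)
    stop(errorCondition("degenerate design: all ln-VDAC1 values identical",
                        class = c("oxphos_degenerate_error", "error")))
  b <- sum((x - xbar) * (y - mean(y))) / sxx
  a <- mean(y) - b * xbar
  resid <- y - a - b * x
  s_resid <- sqrt(sum(resid^2) / (n - 2))
  if (s_resid <= 0)
    stop(errorCondition("degenerate fit: zero residual SD (perfect collinearity)",
                        class = c("oxphos_degenerate_error", "error")))
  d_perp <- resid / sqrt(1 + b^2)
  s_perp <- sd(d_perp)
  structure(list(subunit = subunit, a = a, b = b, n = n, xbar = xbar,
                 sxx = sxx, s_resid = s_resid, s_perp = s_perp,
                 n_dropped = n_dropped),
            class = "imc_regfit")
}

#' @export
print.imc_regfit <- function(x, ...) {
  cat(sprintf("<imc_regfit> %s: ln(y) = %.4f + %.4f ln(V), n = %d, s_resid = %.4f, s_perp = %.4f\n",
              x$subunit, x$a, x$b, x$n, x$s_resid, x$s_perp))
  invisible(x)
}

#' Prediction interval of the control regression
#'
#' Classical vertical prediction interval for a new observation at `x0`:
#' yhat0 +/- t_{(1+level)/2, n-2} * s_resid * sqrt(1 + 1/n + (x0-xbar)^2/Sxx).
#' Its lower limit at level 0.80 is the deficiency threshold.
#'
#' @param fit an `imc_regfit`.
#' @param x0 ln-VDAC1 value(s).
#' @param level interval level in (0,1); default 0.80.
#' @return data.frame with columns `fit`, `lower`, `upper` (one row per `x0`).
#' @export
prediction_interval <- function(fit, x0, level = 0.80) {
  stopifnot(inherits(fit, "imc_regfit"))
  assert_scalar_number(level, "level", 0, 1, strict = TRUE)
  yhat <- fit$a + fit$b * x0
  tq <- qt((1 + level) / 2, df = fit$n - 2)
  half <- tq * fit$s_resid * sqrt(1 + 1 / fit$n + (x0 - fit$xbar)^2 / fit$sxx)
  data.frame(fit = yhat, lower = yhat - half, upper = yhat + half)
}

#' Perpendicular-distance z-score against the control regression
#'
#' z = \[(y0 - a - b x0) / sqrt(1 + b^2)\] / s_perp: the signed straight-line
#' (orthogonal) distance from the neuron's (ln VDAC1, ln subunit) point to
#' the control line, standardized by the SD of that distance over control
#' neurons. Positive above the line. `mode = "vertical"` instead divides the
#' vertical residual by `s_resid` (sensitivity switch).
#'
#' @param fit an `imc_regfit`.
#' @param x0,y0 ln-scale coordinates (vectorized).
#' @param mode `"perpendicular"` (default) or `"vertical"`.
#' @return numeric z-score vector.
#' @export
zscore_perpendicular <- function(fit, x0, y0,
                                 mode = c("perpendicular", "vertical")) {
  stopifnot(inherits(fit, "imc_regfit"))
  mode <- match.arg(mode)
  resid <- y0 - fit$a - fit$b * x0
  if (mode == "perpendicular") {
    if (fit$s_perp <= 0)
      stop(errorCondition("degenerate fit: zero perpendicular SD",
                          class = c("oxphos_degenerate_error", "error")))
    (resid / sqrt(1 + fit$b^2)) / fit$s_perp
  } else {
    resid / fit$s_resid
  }
}

#' Mass (VDAC1) reference and z-score
#'
#' The mitochondrial-mass z-score is referenced to the mean and n-1 SD of
#' ln VDAC1 over pooled control neurons: z = (ln v - m) / s.
#'
#' @param controls control neuron table.
#' @param mass mass-marker column name.
#' @return `fit_mass_reference()`: object of class `imc_massref` with `m`,
#'   `s`, `n`, `n_dropped`.
#' @export
fit_mass_reference <- function(controls, mass = "VDAC1") {
  if (!mass %in% names(controls)) data_error(paste0("missing column ", mass))
  ok <- is.finite(controls[[mass]]) & controls[[mass]] > 0
  v <- log(controls[[mass]][ok])
  if (length(v) < 3L) data_error("need at least 3 controls with positive VDAC1")
  s <- sd(v)
  if (s <= 0)
    stop(errorCondition("degenerate mass reference: zero SD",
                        class = c("oxphos_degenerate_error", "error")))
  structure(list(m = mean(v), s = s, n = length(v), n_dropped = sum(!ok)),
            class = "imc_massref")
}

#' @rdname fit_mass_reference
#' @param ref an `imc_massref`.
#' @param v raw-scale VDAC1 intensity (vectorized, must be > 0).
#' @export
mass_zscore <- function(ref, v) {
  stopifnot(inherits(ref, "imc_massref"))
  if (any(v <= 0)) data_error("VDAC1 intensity must be > 0 for a mass z-score")
  (log(v) - ref$m) / ref$s
}

#' Fit the full control model (all subunits + mass reference)
#'
#' @param controls control neuron table.
#' @param subunits subunit column names (default: the 8 assayed subunits).
#' @param mass mass-marker column name.
#' @return object of class `imc_control_model`: list of per-subunit
#'   `imc_regfit`s (`$fits`), the `imc_massref` (`$mass`), and metadata.
#' @export
fit_control_model <- function(controls, subunits = names(oxphos_subunits()),
                              mass = "VDAC1") {
  fits <- lapply(subunits, function(s) fit_control_regression(controls, s, mass))
  names(fits) <- subunits
  structure(list(fits = fits, mass = fit_mass_reference(controls, mass),
                 mass_target = mass, n_controls = nrow(controls)),
            class = "imc_control_model")
}

#' @export
print.imc_control_model <- function(x, ...) {
  cat("<imc_control_model>", length(x$fits), "subunit fits, mass ref m =",
      round(x$mass$m, 3), "s =", round(x$mass$s, 3), "\n")
  invisible(x)
}

#' Score neurons against a frozen control model
#'
#' Computes per-subunit z-scores (perpendicular by default) and the mass
#' z-score for every neuron with positive intensities in the needed
#' channels; neurons failing positivity for a channel get NA there and are
#' listed in the drop log.
#'
#' @param model an `imc_control_model`.
#' @param table neuron table (any group).
#' @param mode z-score mode, see [zscore_perpendicular()].
#' @return data.frame `neuron_id`, `case_id`, `group`, one `z_<subunit>`
#'   column per subunit and `z_mass`; attribute `dropped` lists NA reasons.
#' @export
score_neurons <- function(model, table, mode = c("perpendicular", "vertical")) {
  stopifnot(inherits(model, "imc_control_model"))
  mode <- match.arg(mode)
  mass <- model$mass_target
  out <- table[, intersect(c("neuron_id", "case_id", "group", "age"),
                           names(table)), drop = FALSE]
  log <- drop_log()
  v_ok <- is.finite(table[[mass]]) & table[[mass]] > 0
  lnv <- ifelse(v_ok, log(pmax(table[[mass]], .Machine$double.xmin)), NA_real_)
  for (s in names(model$fits)) {
    y_ok <- v_ok & is.finite(table[[s]]) & table[[s]] > 0
    z <- rep(NA_real_, nrow(table))
    z[y_ok] <- zscore_perpendicular(model$fits[[s]], lnv[y_ok],
                                    log(table[[s]][y_ok]), mode)
    out[[paste0("z_", s)]] <- z
    for (i in which(!y_ok))
      log <- log_drop(log, table$neuron_id[i], table$case_id[i],
                      paste0("non-positive ", s, " or ", mass))
  }
  out$z_mass <- ifelse(v_ok, (lnv - model$mass$m) / model$mass$s, NA_real_)
  attr(out, "dropped") <- unique(log)
  out
}

#' Serialize / restore a control model
#'
#' Writes every per-subunit fit (a, b, n, xbar, Sxx, s_resid, s_perp) and
#' the mass reference to YAML (or JSON by extension) so disease cohorts can
#' be scored against a frozen control fit.
#'
#' @param model an `imc_control_model`.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `read_control_model()` returns an `imc_control_model`.
#' @export
write_control_model <- function(model, path) {
  stopifnot(inherits(model, "imc_control_model"))
  x <- list(mass_target = model$mass_target, n_controls = model$n_controls,
            mass = unclass(model$mass),
            fits = lapply(model$fits, unclass))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  fits <- lapply(x$fits, function(f) structure(f, class = "imc_regfit"))
  structure(list(fits = fits, mass = structure(x$mass, class = "imc_massref"),
                 mass_target = x$mass_target, n_controls = x$n_controls),
            class = "imc_control_model")
}
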