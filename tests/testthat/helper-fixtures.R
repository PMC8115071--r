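# Shared fixtures and independent oracle helpers. Everything is generated in
# code; no binary fixtures.

# Control-only cohort config: a = 0, b = 1, s = 0.25, ln V ~ N(5, 0.5).
ctrl_config <- function(seed, n_cases = 10, npc = 45, npc_sd = 0, s = 0.25) {
  reg <- default_regression()
  reg$s <- s
  cohort_config(groups = list(group_spec("control", n_cases, npc, npc_sd)),
                regression = reg, seed = seed)
}

# Two-group config with per-complex deficits for recovery tests.
deficit_config <- function(seed, delta = 1, pi = 0.5, n_cases = 3, npc = 110) {
  cohort_config(
    groups = list(group_spec("control", 10, 45, 0),
                  group_spec("PD", n_cases, npc, 0, pi = pi)),
    deficits = c(CI = delta, CII = delta, CIII = delta, CIV = delta, CV = delta),
    seed = seed)
}

# The 5-point regression fixture (ln-scale x/y), embedded into a raw-scale
# control table for fit_control_regression.
five_point_controls <- function() {
  x <- c(0, 1, 2, 3, 4)
  y <- c(0.1, 0.9, 2.1, 2.9, 4.0)
  tab <- data.frame(neuron_id = paste0("n", 1:5), case_id = "c1",
                    group = "control", VDAC1 = exp(x), NDUFB8 = exp(y))
  list(tab = tab, x = x, y = y)
}

# Closed-form OLS via the normal equations (independent of the package path).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(a = beta[1], b = beta[2],
       s_resid = sqrt(sum(resid^2) / (length(x) - 2)))
}

# Hand-built regression fit object for geometry-only z-score checks.
manual_regfit <- function(a, b, s_perp, s_resid = s_perp, n = 100,
                          xbar = 0, sxx = 100) {
  structure(list(subunit = "toy", a = a, b = b, n = n, xbar = xbar,
                 sxx = sxx, s_resid = s_resid, s_perp = s_perp,
                 n_dropped = 0), class = "imc_regfit")
}

# Scalar per-pixel point-in-polygon oracle (crossing test coded
# independently of the vectorized implementation).
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      x_int <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (px < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

rasterize_oracle <- function(vertices, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2]))
    mask[r, c] <- pip_oracle(c - 1, r - 1, vertices[, 1], vertices[, 2])
  mask
}

# Minimal 4-channel panel for tiny pixel fixtures.
tiny_panel <- function() {
  data.frame(channel_index = 1:4,
             metal_tag = c("m1", "m2", "m3", "m4"),
             target = c("T1", "VDAC1", "HistoneH3", "Ir"),
             role = c("oxphos_subunit", "mass", "nuclear", "intercalator"),
             stringsAsFactors = FALSE)
}

# Hand-built profile table over the five complexes (representative subunits
# only), for summary-level enumeration oracles. `flags` is a logical matrix
# [neuron, complex CI..CV].
toy_profiles <- function(flags, case_id = "c1", group = "g1") {
  complexes <- names(complex_representatives())
  reps <- complex_representatives()
  stopifnot(ncol(flags) == 5L)
  colnames(flags) <- complexes
  out <- data.frame(neuron_id = sprintf("n%02d", seq_len(nrow(flags))),
                    case_id = case_id, group = group,
                    stringsAsFactors = FALSE)
  for (cx in complexes) out[[paste0("dec_", reps[[cx]])]] <- flags[, cx]
  for (cx in complexes) out[[paste0("dec_", cx)]] <- flags[, cx]
  out$n_complexes_decreased <- as.integer(rowSums(flags))
  out
}
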