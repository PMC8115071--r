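# End-to-end orchestration: acquire (simulate/load/extract) -> fit controls
# -> score -> call -> profile -> Bayesian contrasts -> classical statistics,
# with seeded determinism and CSV outputs for every reported number.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (simulate a cohort), `"table"` (read a neuron
#'   table CSV) or `"images"` (read TIFF + ROIs + panel + metadata and
#'   extract).
#' @param cohort a [cohort_config()] for synthetic mode (default:
#'   [default_cohort_config()] at `seed`).
#' @param table_path,image_path,roi_path,panel_path,metadata_path input
#'   paths for the non-synthetic modes.
#' @param control_group group label used as the normative reference.
#' @param pi_level prediction-interval level for deficiency calls.
#' @param z_mode `"perpendicular"` or `"vertical"`.
#' @param exclusion_targets,exclusion_threshold pixel-exclusion rule for
#'   image extraction.
#' @param representatives complex -> representative subunit map.
#' @param best list with `chains`, `warmup`, `draws` for the Bayesian
#'   contrasts (reduced defaults keep the many per-case contrasts cheap).
#' @param min_neurons_gate minimum neurons per stratum for per-case mass
#'   contrasts (>= 2; default 3).
#' @param group_contrasts,mass_contrasts switch the two Bayesian contrast
#'   families on/off.
#' @param seed master seed for every stochastic step.
#' @param outdir output directory for CSVs (NULL = in-memory report only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "table", "images"),
                            cohort = NULL, table_path = NULL,
                            image_path = NULL, roi_path = NULL,
                            panel_path = NULL, metadata_path = NULL,
                            control_group = "control", pi_level = 0.80,
                            z_mode = c("perpendicular", "vertical"),
                            exclusion_targets = c("HistoneH3", "Ir"),
                            exclusion_threshold = 5,
                            representatives = complex_representatives(),
                            best = list(chains = 2L, warmup = 500L,
                                        draws = 1500L),
                            min_neurons_gate = 3L,
                            group_contrasts = TRUE, mass_contrasts = TRUE,
                            seed = 1L, outdir = NULL) {
  mode <- match.arg(mode)
  z_mode <- match.arg(z_mode)
  assert_scalar_number(pi_level, "pi_level", 0, 1, strict = TRUE)
  if (min_neurons_gate < 2L) config_error("min_neurons_gate must be >= 2")
  structure(list(mode = mode, cohort = cohort, table_path = table_path,
                 image_path = image_path, roi_path = roi_path,
                 panel_path = panel_path, metadata_path = metadata_path,
                 control_group = control_group, pi_level = pi_level,
                 z_mode = z_mode, exclusion_targets = exclusion_targets,
                 exclusion_threshold = exclusion_threshold,
                 representatives = representatives, best = best,
                 min_neurons_gate = min_neurons_gate,
                 group_contrasts = group_contrasts,
                 mass_contrasts = mass_contrasts,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

acquire_table <- function(config) {
  if (config$mode == "synthetic") {
    cohort <- config$cohort %||% default_cohort_config(config$seed)
    sim <- simulate_cohort(cohort)
    list(table = sim$table, truth = sim$truth)
  } else if (config$mode == "table") {
    if (is.null(config$table_path)) config_error("table mode needs table_path")
    list(table = read_neuron_table(config$table_path), truth = NULL)
  } else {
    for (p in c("image_path", "roi_path", "panel_path", "metadata_path"))
      if (is.null(config[[p]])) config_error(paste0("images mode needs ", p))
    stack <- read_stack(config$image_path, config$panel_path)
    rois <- read_rois(config$roi_path)
    meta <- read.csv(config$metadata_path, stringsAsFactors = FALSE)
    tab <- extract_neuron_table(stack, rois, meta, config$exclusion_targets,
                                config$exclusion_threshold)
    list(table = tab, truth = NULL)
  }
}

best_summary_row <- function(contrast, fit) {
  s <- summary(fit)
  cbind(data.frame(contrast = contrast, stringsAsFactors = FALSE), s)
}

#' Run the full analysis pipeline
#'
#' Executes acquire -> fit control model -> score -> call -> profile ->
#' Bayesian contrasts (each disease group vs control per subunit and mass;
#' per-case decreased-vs-normal mass contrasts under the neurons-per-stratum
#' gate) -> classical statistics. Disease cohorts are always scored against
#' the frozen pooled-control fit. Re-running with the same config and seed
#' reproduces every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return list of class `imc_report` with the config echo, all tables and
#'   (for synthetic runs) ground-truth recovery metrics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  acq <- acquire_table(config)
  table <- acq$table
  controls <- table[table$group == config$control_group, , drop = FALSE]
  if (nrow(controls) < 3L)
    data_error(paste0("control group '", config$control_group,
                      "' has fewer than 3 neurons"))
  model <- fit_control_model(controls)
  profiles <- profile_neurons(model, table, level = config$pi_level,
                              representatives = config$representatives,
                              mode = config$z_mode)
  case_summaries <- summarize_case(profiles)
  severity <- severity_stack(profiles)
  cond <- do.call(rbind, lapply(names(config$representatives), function(cx) {
    cp <- conditional_profile(profiles, cx)
    if (nrow(cp)) cbind(anchor = cx, cp) else NULL
  }))

  disease_groups <- setdiff(unique(table$group), config$control_group)
  best_cfg <- config$best
  group_best <- NULL
  if (isTRUE(config$group_contrasts) && length(disease_groups)) {
    rows <- list()
    z_cols <- c(paste0("z_", names(model$fits)), "z_mass")
    for (g in disease_groups) for (zc in z_cols) {
      y1 <- profiles[[zc]][profiles$group == g]
      y2 <- profiles[[zc]][profiles$group == config$control_group]
      y1 <- y1[is.finite(y1)]; y2 <- y2[is.finite(y2)]
      if (length(y1) < 2L || length(y2) < 2L) next
      lab <- paste0(g, "_vs_", config$control_group, "/", sub("^z_", "", zc))
      fit <- best_fit(y1, y2, chains = best_cfg$chains,
                      warmup = best_cfg$warmup, draws = best_cfg$draws,
                      seed = substream_seed(config$seed, lab))
      rows[[length(rows) + 1L]] <- best_summary_row(lab, fit)
    }
    group_best <- do.call(rbind, rows)
  }

  mass_best <- NULL
  if (isTRUE(config$mass_contrasts)) {
    rows <- list()
    for (p in split(profiles, profiles$case_id)) {
      for (cx in names(config$representatives)) {
        fl <- p[[paste0("dec_", cx)]]
        ok <- !is.na(fl) & is.finite(p$z_mass)
        y1 <- p$z_mass[ok & fl]; y2 <- p$z_mass[ok & !fl]
        if (length(y1) < config$min_neurons_gate ||
            length(y2) < config$min_neurons_gate) next
        lab <- paste0(p$case_id[1L], "/mass|", cx, "_decreased_vs_normal")
        fit <- best_fit(y1, y2, chains = best_cfg$chains,
                        warmup = best_cfg$warmup, draws = best_cfg$draws,
                        seed = substream_seed(config$seed, lab))
        row <- best_summary_row(lab, fit)
        row$case_id <- p$case_id[1L]; row$group <- p$group[1L]; row$complex <- cx
        rows[[length(rows) + 1L]] <- row
      }
    }
    mass_best <- do.call(rbind, rows)
  }

  # classical statistics
  classical <- list()
  for (g in disease_groups) for (col in grep("^pct_(?!cat)", names(case_summaries),
                                             perl = TRUE, value = TRUE)) {
    a <- case_summaries[[col]][case_summaries$group == g]
    b <- case_summaries[[col]][case_summaries$group == config$control_group]
    if (!length(a) || !length(b)) next
    mw <- mann_whitney(a, b)
    classical[[length(classical) + 1L]] <- data.frame(
      test = "mann_whitney", contrast = paste0(g, "_vs_", config$control_group),
      variable = sub("^pct_", "", col), statistic = mw$U, p = mw$p,
      n1 = mw$n_a, n2 = mw$n_b, stringsAsFactors = FALSE)
  }
  ctrl_tab <- table[table$group == config$control_group, , drop = FALSE]
  for (s in names(model$fits)) {
    ok <- ctrl_tab[[s]] > 0 & ctrl_tab$VDAC1 > 0
    sp <- spearman_cor(log(ctrl_tab$VDAC1[ok]), log(ctrl_tab[[s]][ok]))
    classical[[length(classical) + 1L]] <- data.frame(
      test = "spearman", contrast = "control", variable = paste0(s, ":VDAC1"),
      statistic = sp$r, p = sp$p, n1 = sp$n, n2 = NA_integer_,
      stringsAsFactors = FALSE)
  }
  ctrl_prof <- profiles[profiles$group == config$control_group &
                          !is.na(profiles$n_complexes_decreased), , drop = FALSE]
  age_reg <- NULL
  if ("age" %in% names(ctrl_prof) && length(unique(ctrl_prof$age)) > 1L) {
    lr <- linreg_r2(ctrl_prof$age, ctrl_prof$n_complexes_decreased)
    age_reg <- data.frame(test = "linreg_severity_age", contrast = "control",
                          variable = "n_complexes_decreased~age",
                          statistic = lr$r2, p = lr$p, n1 = lr$n,
                          n2 = NA_integer_, stringsAsFactors = FALSE)
    classical[[length(classical) + 1L]] <- age_reg
  }
  classical <- do.call(rbind, classical)

  agg <- stats::aggregate(list(n_neurons = table$neuron_id),
                          by = list(case_id = table$case_id,
                                    group = table$group), FUN = length)
  counts <- summarize_counts(agg[, c("group", "n_neurons")])

  recovery <- if (!is.null(acq$truth))
    recovery_metrics(profiles, acq$truth) else NULL

  report <- structure(list(
    version = as.character(utils::packageVersion("oxphosimc")),
    config = config, table = table, truth = acq$truth, model = model,
    profiles = profiles, case_summaries = case_summaries,
    severity = severity, conditional = cond, group_best = group_best,
    mass_best = mass_best, classical = classical, counts = counts,
    recovery = recovery, dropped = dropped_neurons(profiles)),
    class = "imc_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Ground-truth recovery metrics
#'
#' Per complex: recall (fraction of truly deficient neurons called
#' decreased) and false-flag rate (fraction of truly normal neurons called
#' decreased), matching profiles to ground truth by `neuron_id`.
#'
#' @param profiles data.frame from [profile_neurons()].
#' @param truth ground-truth data.frame from [simulate_cohort()].
#' @return data.frame `complex`, `n_deficient`, `recall`, `false_flag_rate`.
#' @export
recovery_metrics <- function(profiles, truth) {
  idx <- match(profiles$neuron_id, truth$neuron_id)
  rows <- lapply(names(complex_representatives()), function(cx) {
    called <- profiles[[paste0("dec_", cx)]]
    actual <- truth[[paste0("def_", cx)]][idx]
    ok <- !is.na(called) & !is.na(actual)
    data.frame(complex = cx, n_deficient = sum(actual[ok]),
               recall = if (any(actual[ok])) mean(called[ok & actual]) else NA_real_,
               false_flag_rate = if (any(!actual[ok]))
                 mean(called[ok & !actual]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an `imc_report` to CSV/YAML files
#'
#' @param report an `imc_report` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(obj, name) {
    if (is.null(obj) || (is.data.frame(obj) && nrow(obj) == 0L)) return()
    p <- file.path(outdir, name)
    write.csv(obj, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  put(report$table, "neuron_table.csv")
  put(report$truth, "ground_truth.csv")
  put(report$profiles, "profiles.csv")
  put(report$case_summaries, "case_summaries.csv")
  put(report$severity$categories, "severity_categories.csv")
  put(report$severity$composition, "severity_composition.csv")
  put(report$conditional, "conditional_profiles.csv")
  put(report$group_best, "best_group_contrasts.csv")
  put(report$mass_best, "best_mass_contrasts.csv")
  put(report$classical, "classical_stats.csv")
  put(report$counts, "case_counts.csv")
  put(report$recovery, "recovery_metrics.csv")
  put(report$dropped, "dropped_neurons.csv")
  put(heatmap_table(report$case_summaries), "heatmap_long.csv")
  write_control_model(report$model, file.path(outdir, "control_model.yaml"))
  cfg <- report$config
  cfg$representatives <- as.list(cfg$representatives)
  cfg$cohort <- NULL  # cohort config serialized separately when present
  yaml::write_yaml(c(list(version = report$version), unclass(cfg)),
                   file.path(outdir, "config_echo.yaml"))
  invisible(c(paths, file.path(outdir, c("control_model.yaml",
                                         "config_echo.yaml"))))
}

#' @export
print.imc_report <- function(x, ...) {
  cat("<imc_report>", nrow(x$table), "neurons;",
      nrow(x$case_summaries), "cases;",
      if (!is.null(x$group_best)) nrow(x$group_best) else 0,
      "group contrasts;",
      if (!is.null(x$mass_best)) nrow(x$mass_best) else 0,
      "per-case mass contrasts\n")
  invisible(x)
}

#' Histogram binning at a fixed bin width
#'
#' Bins anchored at multiples of `width` (the figure convention: bin width
#' 0.1 for z-score histograms).
#'
#' @param x numeric vector.
#' @param width bin width.
#' @return list with `breaks` and `counts`.
#' @export
z_histogram <- function(x, width = 0.1) {
  x <- x[is.finite(x)]
  if (!length(x)) data_error("no finite values to bin")
  lo <- floor(min(x) / width) * width
  n_bins <- max(1L, ceiling((max(x) - lo) / width))
  breaks <- lo + width * (0:n_bins)
  if (max(x) == breaks[length(breaks)]) breaks <- c(breaks, max(x) + width)
  counts <- as.vector(table(cut(x, breaks, right = FALSE)))
  list(breaks = breaks, counts = counts)
}

#' Render figure files from a report
#'
#' Presentation-only: z-score histograms (bin width 0.1) with group density
#' curves and mean dash lines, a z-vs-z scatter with the 95% data ellipse,
#' the per-case percent-decreased heatmap, and the severity stacked bars.
#' Missing tables skip their figure with a warning. No numbers originate
#' here.
#'
#' @param report an `imc_report`.
#' @param outdir directory for PNG files.
#' @param width bin width for z histograms.
#' @return character vector of written files, invisibly.
#' @export
make_figures <- function(report, outdir, width = 0.1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  prof <- report$profiles
  groups <- unique(prof$group)
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(groups)),
                                                "Dark 3")[seq_along(groups)],
                          groups)
  z_cols <- grep("^z_", names(prof), value = TRUE)
  for (zc in z_cols) {
    f <- file.path(outdir, paste0("hist_", zc, ".png"))
    grDevices::png(f, 900, 600)
    vals <- prof[[zc]][is.finite(prof[[zc]])]
    hb <- z_histogram(vals, width)
    plot(NULL, xlim = range(hb$breaks), ylim = c(0, max(hb$counts) * 1.1),
         xlab = zc, ylab = "neurons", main = paste0(zc, " (bin width ", width, ")"))
    for (g in groups) {
      v <- prof[[zc]][prof$group == g]
      v <- v[is.finite(v)]
      if (!length(v)) next
      h <- graphics::hist(v, breaks = hb$breaks, plot = FALSE)
      graphics::lines(h$mids, h$counts, type = "s", col = cols[[g]])
      if (length(v) > 1L) {
        d <- stats::density(v)
        graphics::lines(d$x, d$y * length(v) * width, col = cols[[g]], lty = 3)
      }
      graphics::abline(v = mean(v), col = cols[[g]], lty = 2)
    }
    graphics::legend("topright", legend = groups, col = cols[groups], lty = 1)
    grDevices::dev.off()
    files <- c(files, f)
  }
  # z-vs-z scatter with ellipse per group
  if (all(c("z_NDUFB8", "z_MTCO1") %in% names(prof))) {
    f <- file.path(outdir, "scatter_zNDUFB8_zMTCO1.png")
    grDevices::png(f, 700, 700)
    ok <- is.finite(prof$z_NDUFB8) & is.finite(prof$z_MTCO1)
    plot(prof$z_NDUFB8[ok], prof$z_MTCO1[ok], col = cols[prof$group[ok]],
         pch = 16, cex = 0.6, xlab = "z_NDUFB8", ylab = "z_MTCO1")
    th <- seq(0, 2 * pi, length.out = 181)
    for (g in groups) {
      sel <- ok & prof$group == g
      if (sum(sel) < 3L) next
      sp <- try(confidence_ellipse(cbind(prof$z_NDUFB8[sel],
                                         prof$z_MTCO1[sel])), silent = TRUE)
      if (inherits(sp, "try-error")) next
      R <- cbind(c(cos(sp$angle), sin(sp$angle)),
                 c(-sin(sp$angle), cos(sp$angle)))
      pts <- t(R %*% rbind(sp$semi_axes[1] * cos(th), sp$semi_axes[2] * sin(th)))
      graphics::lines(pts[, 1] + sp$center[1], pts[, 2] + sp$center[2],
                      col = cols[[g]])
    }
    grDevices::dev.off()
    files <- c(files, f)
  } else warning("z columns missing; scatter skipped")
  # heatmap of per-case percent decreased
  hm <- heatmap_table(report$case_summaries)
  if (nrow(hm)) {
    f <- file.path(outdir, "heatmap_pct_decreased.png")
    grDevices::png(f, 900, 600)
    cases <- unique(hm$case_id); targets <- unique(hm$target)
    mat <- matrix(NA_real_, length(targets), length(cases),
                  dimnames = list(targets, cases))
    for (i in seq_len(nrow(hm))) mat[hm$target[i], hm$case_id[i]] <- hm$percent[i]
    graphics::image(seq_along(targets), seq_along(cases), mat,
                    col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "", zlim = c(0, 100))
    graphics::axis(1, seq_along(targets), targets, las = 2)
    graphics::axis(2, seq_along(cases), cases, las = 2, cex.axis = 0.6)
    grDevices::dev.off()
    files <- c(files, f)
  } else warning("case summary empty; heatmap skipped")
  # severity stacked bars
  sev <- report$severity$categories
  if (!is.null(sev) && nrow(sev)) {
    f <- file.path(outdir, "severity_stack.png")
    grDevices::png(f, 700, 600)
    mat <- t(as.matrix(sev[, paste0("pct_cat", 0:5)]))
    colnames(mat) <- sev$group
    graphics::barplot(mat, col = grDevices::hcl.colors(6, "Viridis"),
                      legend.text = paste0("cat ", 0:5),
                      ylab = "% of neurons")
    grDevices::dev.off()
    files <- c(files, f)
  } else warning("severity table empty; stacked bars skipped")
  invisible(files)
}
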