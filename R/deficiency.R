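# Deficiency profiling: per-subunit prediction-interval calls, per-complex
# calls through representative subunits, 0-5 severity categories, per-case
# percentage summaries, severity stacks and conditional co-deficiency tables.

#' Call decreased expression for one subunit
#'
#' A neuron is called decreased iff its ln intensity falls strictly below
#' the lower limit of the `level` (default 80%) prediction interval of the
#' control regression evaluated at its ln VDAC1. Ties (exactly on the limit)
#' are not decreased.
#'
#' @param fit an `imc_regfit`.
#' @param x0 ln VDAC1 value(s).
#' @param y0 ln subunit value(s).
#' @param level prediction-interval level.
#' @return logical vector.
#' @export
call_decreased <- function(fit, x0, y0, level = 0.80) {
  pi_ <- prediction_interval(fit, x0, level)
  y0 < pi_$lower
}

#' Per-complex calls from per-subunit flags
#'
#' Each complex's flag equals its representative subunit's flag (CI ->
#' NDUFA13, CII -> SDHA, CIII -> UqCRC2, CIV -> MTCO1, CV -> ATP5B by
#' default); non-representative subunits are still reported at subunit level
#' but do not drive complex categories.
#'
#' @param flags named logical vector (or 1-row data.frame slice) of
#'   per-subunit flags.
#' @param representatives named map complex -> representative subunit.
#' @return named logical vector over complexes.
#' @export
complex_calls <- function(flags, representatives = complex_representatives()) {
  missing_r <- setdiff(representatives, names(flags))
  if (length(missing_r))
    data_error(paste0("missing representative subunit flags: ",
                      paste(missing_r, collapse = ", ")))
  out <- vapply(representatives, function(s) as.logical(flags[[s]]), NA)
  names(out) <- names(representatives)
  out
}

#' Build per-neuron deficiency profiles
#'
#' Combines z-scores and prediction-interval calls into the central derived
#' object: per-subunit decreased flags, per-complex flags via representative
#' subunits, and the severity category (number of complexes decreased,
#' 0-5). Neurons missing any representative subunit measurement get an NA
#' category and are listed in the drop log.
#'
#' @param model an `imc_control_model`.
#' @param table neuron table (raw intensities).
#' @param level prediction-interval level (default 0.80).
#' @param representatives complex -> representative subunit map.
#' @param mode z-score mode.
#' @return data.frame with `neuron_id`, `case_id`, `group`, `age`,
#'   `dec_<subunit>` flags, `z_<subunit>` and `z_mass` scores, `dec_<complex>`
#'   flags and `n_complexes_decreased`; attribute `dropped`.
#' @export
profile_neurons <- function(model, table, level = 0.80,
                            representatives = complex_representatives(),
                            mode = c("perpendicular", "vertical")) {
  stopifnot(inherits(model, "imc_control_model"))
  mode <- match.arg(mode)
  mass <- model$mass_target
  scores <- score_neurons(model, table, mode)
  out <- scores
  v_ok <- is.finite(table[[mass]]) & table[[mass]] > 0
  lnv <- ifelse(v_ok, log(pmax(table[[mass]], .Machine$double.xmin)), NA_real_)
  for (s in names(model$fits)) {
    y_ok <- v_ok & is.finite(table[[s]]) & table[[s]] > 0
    fl <- rep(NA, nrow(table))
    fl[y_ok] <- call_decreased(model$fits[[s]], lnv[y_ok],
                               log(table[[s]][y_ok]), level)
    out[[paste0("dec_", s)]] <- fl
  }
  log <- dropped_neurons(scores)
  for (cx in names(representatives)) {
    rep_s <- representatives[[cx]]
    out[[paste0("dec_", cx)]] <- out[[paste0("dec_", rep_s)]]
  }
  cx_cols <- paste0("dec_", names(representatives))
  cx_mat <- as.matrix(out[, cx_cols])
  ncd <- rowSums(cx_mat)
  miss <- rowSums(is.na(cx_mat)) > 0
  ncd[miss] <- NA_integer_
  for (i in which(miss))
    log <- log_drop(log, out$neuron_id[i], out$case_id[i],
                    "missing representative subunit; no severity category")
  out$n_complexes_decreased <- as.integer(ncd)
  attr(out, "dropped") <- unique(log)
  attr(out, "level") <- level
  attr(out, "representatives") <- representatives
  out
}

subunit_flag_cols <- function(profiles) {
  cand <- paste0("dec_", names(oxphos_subunits()))
  cand[cand %in% names(profiles)]
}

complex_flag_cols <- function(profiles) {
  cand <- paste0("dec_", names(complex_representatives()))
  cand[cand %in% names(profiles)]
}

#' Summarize one or more cases
#'
#' Per case: neuron count, the percentage of neurons flagged decreased for
#' each subunit, and the percentage of neurons in each severity category
#' 0-5 (over neurons with a defined category). Percentages are plain
#' ratios * 100; rounding is left to report time.
#'
#' @param profiles data.frame from [profile_neurons()].
#' @return data.frame, one row per case, columns `case_id`, `group`,
#'   `n_neurons`, `pct_<subunit>`, `pct_cat0`..`pct_cat5`.
#' @export
summarize_case <- function(profiles) {
  if (nrow(profiles) == 0L) data_error("no profiles to summarize")
  split_p <- split(profiles, profiles$case_id)
  rows <- lapply(split_p, function(p) {
    row <- data.frame(case_id = p$case_id[1L], group = p$group[1L],
                      n_neurons = nrow(p), stringsAsFactors = FALSE)
    for (col in subunit_flag_cols(p)) {
      fl <- p[[col]]
      row[[sub("^dec_", "pct_", col)]] <-
        100 * sum(fl, na.rm = TRUE) / sum(!is.na(fl))
    }
    cat_ok <- !is.na(p$n_complexes_decreased)
    for (k in 0:5)
      row[[paste0("pct_cat", k)]] <- if (any(cat_ok))
        100 * sum(p$n_complexes_decreased[cat_ok] == k) / sum(cat_ok) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$case_id), , drop = FALSE]
}

#' Conditional co-deficiency profile around an anchor complex
#'
#' For each case, splits neurons by whether the anchor complex is decreased
#' and reports, in each stratum, the percentage of neurons decreased for
#' every complex. Cases with zero neurons in the decreased stratum are
#' excluded from that stratum's table (and symmetrically for the normal
#' stratum).
#'
#' @param profiles data.frame from [profile_neurons()].
#' @param anchor complex id in `"CI".."CV"`.
#' @return data.frame with columns `case_id`, `group`, `stratum`
#'   (`"decreased"`/`"normal"`), `n`, `pct_CI`..`pct_CV`.
#' @export
conditional_profile <- function(profiles, anchor) {
  complexes <- names(complex_representatives())
  if (!anchor %in% complexes) config_error("anchor must be one of CI..CV")
  acol <- paste0("dec_", anchor)
  rows <- list()
  for (p in split(profiles, profiles$case_id)) {
    p <- p[!is.na(p[[acol]]), , drop = FALSE]
    for (stratum in c("decreased", "normal")) {
      q <- p[if (stratum == "decreased") p[[acol]] else !p[[acol]], ,
             drop = FALSE]
      if (nrow(q) == 0L) next
      row <- data.frame(case_id = q$case_id[1L], group = q$group[1L],
                        stratum = stratum, n = nrow(q),
                        stringsAsFactors = FALSE)
      for (cx in complexes) {
        fl <- q[[paste0("dec_", cx)]]
        row[[paste0("pct_", cx)]] <-
          100 * sum(fl, na.rm = TRUE) / sum(!is.na(fl))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), group = character(),
               stratum = character(), n = integer())
  rownames(out) <- NULL
  out
}

#' Severity stack per group
#'
#' Per group: the percentage of neurons in each severity category 0-5, and
#' within each category the share of each complex among all flagged
#' complexes (the composition of the stacked bars).
#'
#' @param profiles data.frame from [profile_neurons()].
#' @return list with `categories` (data.frame group x `pct_cat0..5`) and
#'   `composition` (data.frame group, category, complex, share).
#' @export
severity_stack <- function(profiles) {
  complexes <- names(complex_representatives())
  groups <- split(profiles, profiles$group)
  cat_rows <- list(); comp_rows <- list()
  for (g in names(groups)) {
    p <- groups[[g]]
    ok <- !is.na(p$n_complexes_decreased)
    if (!any(ok)) data_error(paste0("group ", g, " has no categorizable neurons"))
    row <- data.frame(group = g, n_neurons = sum(ok), stringsAsFactors = FALSE)
    for (k in 0:5)
      row[[paste0("pct_cat", k)]] <-
        100 * sum(p$n_complexes_decreased[ok] == k) / sum(ok)
    cat_rows[[length(cat_rows) + 1L]] <- row
    for (k in 1:5) {
      q <- p[ok & p$n_complexes_decreased == k, , drop = FALSE]
      tot_flags <- sum(vapply(complexes,
                              function(cx) sum(q[[paste0("dec_", cx)]]), 0))
      for (cx in complexes) {
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          group = g, category = k, complex = cx,
          share = if (tot_flags > 0)
            sum(q[[paste0("dec_", cx)]]) / tot_flags else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(categories = do.call(rbind, cat_rows),
       composition = do.call(rbind, comp_rows))
}

#' Long-format heatmap table of per-case percent decreased
#'
#' @param summaries data.frame from [summarize_case()].
#' @return data.frame `case_id`, `group`, `target`, `percent` (one row per
#'   case x subunit), ready for heatmap plotting.
#' @export
heatmap_table <- function(summaries) {
  pct_cols <- grep("^pct_(?!cat)", names(summaries), perl = TRUE, value = TRUE)
  rows <- lapply(pct_cols, function(col)
    data.frame(case_id = summaries$case_id, group = summaries$group,
               target = sub("^pct_", "", col), percent = summaries[[col]],
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
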