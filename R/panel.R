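#' OxPhos subunit / complex dictionary
#'
#' The eight assayed OxPhos subunits and the respiratory-chain complex each
#' belongs to, plus the representative subunit that drives complex-level
#' deficiency calls when a complex has two assayed subunits.
#'
#' @return `oxphos_subunits()`: named character vector mapping subunit name to
#'   complex ("CI".."CV"). `complex_representatives()`: named character vector
#'   mapping complex to its representative subunit.
#' @export
oxphos_subunits <- function() {
  c(NDUFB8 = "CI", NDUFA13 = "CI", SDHA = "CII", UqCRC2 = "CIII",
    MTCO1 = "CIV", COX4 = "CIV", ATP5B = "CV", OSCP = "CV")
}

#' @rdname oxphos_subunits
#' @export
complex_representatives <- function() {
  c(CI = "NDUFA13", CII = "SDHA", CIII = "UqCRC2", CIV = "MTCO1", CV = "ATP5B")
}

#' Default IMC antibody panel
#'
#' One row per image channel: the eight OxPhos subunits, the VDAC1
#' mitochondrial mass marker, tyrosine hydroxylase (dopaminergic marker),
#' Histone H3 (nuclear) and the Ir DNA intercalator (also binds
#' neuromelanin). Roles mirror how channels are used downstream: `mass` is
#' the regression covariate; `nuclear` and `intercalator` channels drive
#' cytoplasmic pixel exclusion.
#'
#' @return data.frame with columns `channel_index`, `metal_tag`, `target`, `role`.
#' @export
default_panel <- function() {
  data.frame(
    channel_index = seq_len(12L),
    metal_tag = c("160Gd", "164Dy", "153Eu", "174Yb", "158Yb", "168Er",
                  "170Yb", "161Dy", "166Er", "176Yb", "171Yb", "193Ir"),
    target = c("NDUFB8", "NDUFA13", "SDHA", "UqCRC2", "MTCO1", "COX4",
               "ATP5B", "OSCP", "VDAC1", "TH", "HistoneH3", "Ir"),
    role = c(rep("oxphos_subunit", 8L), "mass", "neuronal", "nuclear",
             "intercalator"),
    stringsAsFactors = FALSE
  )
}

validate_panel <- function(panel) {
  need <- c("channel_index", "metal_tag", "target", "role")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(panel$target))
    stop("panel target names must be unique", call. = FALSE)
  if (sum(panel$role == "mass") != 1L)
    stop("panel must contain exactly one mass target", call. = FALSE)
  invisible(panel)
}

#' Read or write a panel sidecar CSV
#'
#' @param path file path of the CSV (columns `channel_index`, `metal_tag`,
#'   `target`, `role`).
#' @param panel a panel data.frame as returned by [default_panel()].
#' @return `read_panel()` returns the validated panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
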