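# ImageStack container and the quantification path: polygon rasterization,
# cytoplasmic pixel selection, per-neuron mean intensities; plus the
# synthesis counterpart that renders images from planned geometry.

#' Construct a multichannel image stack
#'
#' @param pixels numeric array `[channel, row, col]`, all values >= 0.
#' @param panel panel data.frame (one row per channel, see [default_panel()]).
#' @param pixel_size physical pixel edge in micrometres (IMC ablates ~1 um^2
#'   per pixel).
#' @return object of class `imc_stack`.
#' @export
imc_stack <- function(pixels, panel = default_panel(), pixel_size = 1) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(1L, dim(pixels)))
  stopifnot(length(dim(pixels)) == 3L)
  validate_panel(panel)
  if (dim(pixels)[1] != nrow(panel))
    data_error(sprintf("channel count (%d) does not match panel rows (%d)",
                       dim(pixels)[1], nrow(panel)))
  if (any(pixels < 0)) data_error("negative intensities are not a valid stack")
  if (any(dim(pixels)[2:3] < 1L)) data_error("image must be at least 1x1")
  structure(list(pixels = pixels, panel = panel, pixel_size = pixel_size),
            class = "imc_stack")
}

#' @export
print.imc_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<imc_stack> %d channels, %d x %d px (%g um/px)\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

channel_plane <- function(stack, target) {
  i <- match(target, stack$panel$target)
  if (is.na(i)) data_error(paste0("no channel for target ", target))
  stack$pixels[i, , ]
}

#' Read an image stack from a multi-page TIFF plus panel sidecar
#'
#' @param path TIFF path (one grayscale page per channel).
#' @param panel_path CSV sidecar mapping channels to targets.
#' @return an [imc_stack()].
#' @export
read_stack <- function(path, panel_path) {
  panel <- read_panel(panel_path)
  px <- read_imc_tiff(path)
  imc_stack(px, panel)
}

#' Write an image stack to TIFF (+ optional panel sidecar)
#'
#' @param stack an [imc_stack()].
#' @param path TIFF output path.
#' @param panel_path optional CSV sidecar path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, panel_path = NULL) {
  write_imc_tiff(stack$pixels, path)
  if (!is.null(panel_path)) write_panel(stack$panel, panel_path)
  invisible(path)
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon
#' (even-odd rule). Centers follow the package convention: pixel (r, c) of
#' the image matrix has center (x = c - 1, y = r - 1).
#'
#' @param roi ROI polygon (list with `vertices`, an (x, y) matrix) or a bare
#'   vertex matrix.
#' @param shape image shape `c(rows, cols)`.
#' @return logical matrix `rows x cols`.
#' @export
rasterize_roi <- function(roi, shape) {
  v <- if (is.matrix(roi)) roi else roi$vertices
  if (nrow(v) < 3L)
    stop(errorCondition("polygon needs at least 3 vertices",
                        class = c("oxphos_geometry_error", "error")))
  if (polygon_area(v[, 1], v[, 2]) <= 0)
    stop(errorCondition("degenerate polygon (zero area)",
                        class = c("oxphos_geometry_error", "error")))
  rows <- shape[1]; cols <- shape[2]
  # restrict the test to the bounding box
  cr <- max(1L, floor(min(v[, 2])) + 1L):min(rows, ceiling(max(v[, 2])) + 1L)
  cc <- max(1L, floor(min(v[, 1])) + 1L):min(cols, ceiling(max(v[, 1])) + 1L)
  mask <- matrix(FALSE, rows, cols)
  if (length(cr) == 0L || length(cc) == 0L) return(mask)
  grid <- expand.grid(r = cr, c = cc)
  inside <- point_in_polygon(grid$c - 1, grid$r - 1, v[, 1], v[, 2])
  mask[cbind(grid$r, grid$c)] <- inside
  mask
}

#' Mean cytoplasmic intensity per target within a mask
#'
#' Implements the published pixel-segmentation rule: within a neuron
#' outline, pixels with intensity strictly above `threshold` on any
#' exclusion channel (by default the nuclear Histone H3 channel and the Ir
#' intercalator channel, which marks nuclei and neuromelanin) are removed;
#' every target's arithmetic mean is taken over the remaining cytoplasmic
#' pixels.
#'
#' @param stack an [imc_stack()].
#' @param mask logical pixel mask (from [rasterize_roi()]).
#' @param exclusion_targets channels whose bright pixels are excluded.
#' @param threshold raw-count threshold; pixels are kept iff <= threshold on
#'   every exclusion channel.
#' @return list with `means` (named numeric per target), `n_pixels_total`,
#'   `n_pixels_cytoplasm`. Zero cytoplasmic pixels raise a condition of
#'   class `oxphos_empty_cytoplasm`.
#' @export
cytoplasmic_mean <- function(stack, mask,
                             exclusion_targets = c("HistoneH3", "Ir"),
                             threshold = 5) {
  stopifnot(inherits(stack, "imc_stack"))
  if (threshold < 0) config_error("threshold must be >= 0")
  missing_t <- setdiff(exclusion_targets, stack$panel$target)
  if (length(missing_t))
    data_error(paste0("exclusion targets not in panel: ",
                      paste(missing_t, collapse = ", ")))
  n_total <- sum(mask)
  if (n_total == 0L) data_error("mask is empty")
  keep <- mask
  for (t in exclusion_targets)
    keep <- keep & (channel_plane(stack, t) <= threshold)
  n_cyto <- sum(keep)
  if (n_cyto == 0L)
    stop(errorCondition("no cytoplasmic pixels after exclusion",
                        class = c("oxphos_empty_cytoplasm", "error")))
  means <- vapply(stack$panel$target,
                  function(t) mean(channel_plane(stack, t)[keep]), 0)
  list(means = means, n_pixels_total = n_total, n_pixels_cytoplasm = n_cyto)
}

#' Extract a per-neuron intensity table from an image stack
#'
#' One row per ROI with non-empty cytoplasm, in ROI order; ROIs whose pixels
#' are all excluded (or whose polygons rasterize to nothing) are dropped and
#' reported in the `dropped` attribute.
#'
#' @param stack an [imc_stack()].
#' @param rois list of ROI polygons.
#' @param metadata data.frame mapping `case_id` to `group` and `age`.
#' @inheritParams cytoplasmic_mean
#' @return data.frame (`neuron_id`, `case_id`, `group`, `age`, one column
#'   per panel target, `n_pixels_total`, `n_pixels_cytoplasm`) with
#'   attribute `dropped` (a drop log data.frame). Use [dropped_neurons()].
#' @export
extract_neuron_table <- function(stack, rois, metadata,
                                 exclusion_targets = c("HistoneH3", "Ir"),
                                 threshold = 5) {
  stopifnot(inherits(stack, "imc_stack"))
  shape <- dim(stack$pixels)[2:3]
  log <- drop_log()
  rows <- list()
  for (roi in rois) {
    if (!roi$case_id %in% metadata$case_id)
      data_error(paste0("case_id not in metadata: ", roi$case_id))
    meta <- metadata[match(roi$case_id, metadata$case_id), ]
    res <- tryCatch({
      mask <- rasterize_roi(roi, shape)
      if (!any(mask))
        stop(errorCondition("empty mask", class = c("oxphos_empty_cytoplasm",
                                                    "error")))
      cytoplasmic_mean(stack, mask, exclusion_targets, threshold)
    }, oxphos_empty_cytoplasm = function(e) e,
       oxphos_geometry_error = function(e) e)
    if (inherits(res, "condition")) {
      log <- log_drop(log, roi$neuron_id, roi$case_id, conditionMessage(res))
      next
    }
    row <- data.frame(neuron_id = roi$neuron_id, case_id = roi$case_id,
                      group = meta$group %||% NA_character_,
                      age = meta$age %||% NA_real_,
                      stringsAsFactors = FALSE)
    for (t in names(res$means)) row[[t]] <- res$means[[t]]
    row$n_pixels_total <- res$n_pixels_total
    row$n_pixels_cytoplasm <- res$n_pixels_cytoplasm
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = character(), case_id = character(),
               group = character(), age = numeric())
  rownames(out) <- NULL
  attr(out, "dropped") <- log
  out
}

#' Drop log accessor
#'
#' @param x an object carrying a `dropped` attribute (e.g. the result of
#'   [extract_neuron_table()]).
#' @return data.frame of dropped neurons with reasons.
#' @export
dropped_neurons <- function(x) attr(x, "dropped") %||% drop_log()

disc_mask <- function(shape, cx, cy, r) {
  rows <- shape[1]; cols <- shape[2]
  rr <- matrix(seq_len(rows) - 1, rows, cols)
  cc <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
  (cc - cx)^2 + (rr - cy)^2 <= r^2
}

#' Render a synthetic image stack from planned geometry
#'
#' The synthesis counterpart of [extract_neuron_table()]: cytoplasm pixels
#' of each cell get `max(0, Normal(mean, noise_frac * mean))` per target,
#' the nucleus disc gets a bright Histone H3 signal and the neuromelanin
#' blob a bright Ir signal (both above the exclusion threshold), background
#' stays at zero. With `noise_frac = 0` extraction inverts rendering
#' exactly.
#'
#' @param geometry an `imc_geometry` from [plan_geometry()].
#' @param table neuron table carrying one row per cell in `geometry` with
#'   per-target mean intensities.
#' @param noise_frac per-pixel Gaussian noise SD as a fraction of each
#'   cell-target mean.
#' @param seed integer seed.
#' @param panel panel data.frame.
#' @param marker_value intensity painted on nuclear/intercalator marker
#'   pixels (must exceed the exclusion threshold; default 50).
#' @return list with `stack` (an [imc_stack()]) and `rois` (ROI polygons).
#' @export
render_image <- function(geometry, table, noise_frac = 0, seed = 1L,
                         panel = default_panel(), marker_value = 50) {
  shape <- attr(geometry, "image_shape")
  stopifnot(!is.null(shape))
  targets <- panel$target
  px <- array(0, c(nrow(panel), shape[1], shape[2]))
  dimnames(px) <- list(targets, NULL, NULL)
  cells <- unclass(geometry)
  rng_seed <- substream_seed(seed, "render")
  with_seed(rng_seed, {
    for (cell in cells) {
      row <- table[match(cell$neuron_id, table$neuron_id), ]
      if (any(is.na(row$neuron_id)))
        data_error(paste0("no table row for cell ", cell$neuron_id))
      mask <- rasterize_roi(cell$polygon, shape)
      nuc <- disc_mask(shape, cell$nucleus$cx, cell$nucleus$cy, cell$nucleus$r) & mask
      mel <- matrix(FALSE, shape[1], shape[2])
      for (m in cell$melanin)
        mel <- mel | (disc_mask(shape, m$cx, m$cy, m$r) & mask)
      for (t in targets) {
        mu <- if (!is.null(row[[t]]) && !is.na(row[[t]])) row[[t]] else 0
        if (mu > 0) {
          vals <- if (noise_frac > 0)
            pmax(0, rnorm(sum(mask), mu, noise_frac * mu)) else rep(mu, sum(mask))
          plane <- px[t, , ]
          plane[mask] <- vals
          px[t, , ] <- plane
        }
      }
      hh <- px["HistoneH3", , ]; hh[nuc] <- marker_value; px["HistoneH3", , ] <- hh
      ir <- px["Ir", , ]; ir[mel] <- marker_value; px["Ir", , ] <- ir
    }
  })
  list(stack = imc_stack(px, panel), rois = roi_polygons(geometry))
}
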