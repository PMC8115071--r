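test_that("stack construction enforces the panel contract", {
  px <- array(1, c(12, 4, 4))
  expect_s3_class(imc_stack(px), "imc_stack")
  expect_error(imc_stack(array(1, c(11, 4, 4))), class = "oxphos_data_error")
  bad <- px; bad[1, 1, 1] <- -1
  expect_error(imc_stack(bad), class = "oxphos_data_error")
  # a panel without a mass channel is invalid
  expect_error(imc_stack(array(1, c(8, 4, 4)), default_panel()[1:8, ]))
})

test_that("TIFF + panel round trip preserves pixels and channel order", {
  set.seed(99)
  px <- array(round(runif(12 * 6 * 5) * 1000), c(12, 6, 5))
  stack <- imc_stack(px)
  tif <- withr::local_tempfile(fileext = ".tiff")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_stack(stack, tif, csv)
  back <- read_stack(tif, csv)
  expect_identical(back$pixels, px)
  expect_identical(back$panel$target, default_panel()$target)
})

test_that("our TIFF bytes are readable by an independent reader (tifffile)", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  px <- array(as.numeric(1:24), c(2, 3, 4))
  tif <- withr::local_tempfile(fileext = ".tiff")
  write_imc_tiff(px, tif)
  out <- system2(py, c("-c", shQuote(paste0(
    "import tifffile,sys; a=tifffile.imread('", tif, "'); ",
    "print(a.shape[0], a.shape[1], a.shape[2], float(a.sum()))"))),
    stdout = TRUE)
  got <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(got, c(2, 3, 4, sum(px)))
})

test_that("rasterization matches the per-pixel point-in-polygon oracle", {
  shape <- c(8, 8)
  polys <- list(
    square = cbind(x = c(0.5, 3.5, 3.5, 0.5), y = c(0.5, 0.5, 3.5, 3.5)),
    triangle = cbind(x = c(1.2, 6.8, 4.0), y = c(1.1, 1.3, 6.7)),
    lshape = cbind(x = c(0.5, 5.5, 5.5, 3.5, 3.5, 0.5),
                   y = c(0.5, 0.5, 2.5, 2.5, 5.5, 5.5))
  )
  for (nm in names(polys)) {
    mask <- rasterize_roi(polys[[nm]], shape)
    expect_identical(mask, rasterize_oracle(polys[[nm]], shape), label = nm)
  }
  # axis-aligned square: exactly rows 2-4 x cols 2-4 (1-based), 9 pixels
  sq <- rasterize_roi(polys$square, shape)
  expect_identical(sum(sq), 9L)
  expect_true(all(sq[2:4, 2:4]))
})

test_that("a polygon covering the image boundary +/- 0.5 masks all pixels", {
  shape <- c(5, 7)
  full <- cbind(x = c(-0.5, shape[2] - 0.5, shape[2] - 0.5, -0.5),
                y = c(-0.5, -0.5, shape[1] - 0.5, shape[1] - 0.5))
  expect_true(all(rasterize_roi(full, shape)))
})

test_that("degenerate polygons are refused", {
  line <- cbind(x = c(0, 1, 2), y = c(0, 1, 2))
  expect_error(rasterize_roi(line, c(4, 4)), class = "oxphos_geometry_error")
})

test_that("cytoplasmic means follow the exclusion rule exactly", {
  # 2x2 fixture: HistoneH3 = [[6,0],[0,0]] excludes top-left at threshold 5;
  # target T1 = [[100,2],[4,6]] -> mean over remaining three = 4
  px <- array(0, c(4, 2, 2))
  px[1, , ] <- matrix(c(100, 2, 4, 6), 2, 2, byrow = TRUE)
  px[3, , ] <- matrix(c(6, 0, 0, 0), 2, 2, byrow = TRUE)
  stack <- imc_stack(px, tiny_panel())
  mask <- matrix(TRUE, 2, 2)
  res <- cytoplasmic_mean(stack, mask)
  expect_equal(res$means[["T1"]], 4)
  expect_identical(res$n_pixels_total, 4L)
  expect_identical(res$n_pixels_cytoplasm, 3L)

  # constant image, no exclusions triggered
  px2 <- array(7, c(4, 3, 3)); px2[3, , ] <- 0; px2[4, , ] <- 0
  res2 <- cytoplasmic_mean(imc_stack(px2, tiny_panel()), matrix(TRUE, 3, 3))
  expect_equal(unname(res2$means["T1"]), 7)
  expect_identical(res2$n_pixels_cytoplasm, 9L)

  # threshold is strict: > excluded, <= kept
  px3 <- array(0, c(4, 1, 2))
  px3[1, , ] <- c(10, 20); px3[3, , ] <- c(5, 5.0001)
  res3 <- cytoplasmic_mean(imc_stack(px3, tiny_panel()), matrix(TRUE, 1, 2))
  expect_equal(res3$means[["T1"]], 10)

  # all pixels excluded -> empty-cytoplasm signal
  px4 <- array(9, c(4, 2, 2))
  expect_error(cytoplasmic_mean(imc_stack(px4, tiny_panel()), matrix(TRUE, 2, 2)),
               class = "oxphos_empty_cytoplasm")
})

test_that("extraction drops fully nuclear neurons and keeps ROI order", {
  geom <- plan_geometry(3, c(256, 256), seed = 8)
  tab <- data.frame(neuron_id = vapply(unclass(geom), `[[`, "", "neuron_id"),
                    case_id = "case01", group = "g", age = 60,
                    NDUFB8 = c(50, 60, 70), NDUFA13 = 50, SDHA = 50,
                    UqCRC2 = 50, MTCO1 = 50, COX4 = 50, ATP5B = 50, OSCP = 50,
                    VDAC1 = c(100, 110, 120), TH = 40)
  ri <- render_image(geom, tab, noise_frac = 0, seed = 8)
  # force ROI 2 to be "fully nuclear": paint HistoneH3 above threshold there
  mask2 <- rasterize_roi(ri$rois[[2]], dim(ri$stack$pixels)[2:3])
  hh <- ri$stack$pixels[match("HistoneH3", ri$stack$panel$target), , ]
  hh[mask2] <- 50
  ri$stack$pixels[match("HistoneH3", ri$stack$panel$target), , ] <- hh
  meta <- data.frame(case_id = "case01", group = "g", age = 60)
  ext <- extract_neuron_table(ri$stack, ri$rois, meta)
  expect_identical(nrow(ext), 2L)
  expect_identical(ext$neuron_id, tab$neuron_id[c(1, 3)])
  drops <- dropped_neurons(ext)
  expect_identical(nrow(drops), 1L)
  expect_identical(drops$neuron_id, tab$neuron_id[2])
  # unknown case_id is a metadata error
  expect_error(extract_neuron_table(ri$stack, ri$rois,
                                    data.frame(case_id = "other", group = "g",
                                               age = 1)),
               class = "oxphos_data_error")
})

test_that("extraction is equivariant under ROI permutation", {
  geom <- plan_geometry(4, c(256, 256), seed = 10)
  ids <- vapply(unclass(geom), `[[`, "", "neuron_id")
  tab <- data.frame(neuron_id = ids, case_id = "case01", group = "g", age = 1,
                    NDUFB8 = c(10, 20, 30, 40), NDUFA13 = 10, SDHA = 10,
                    UqCRC2 = 10, MTCO1 = 10, COX4 = 10, ATP5B = 10, OSCP = 10,
                    VDAC1 = c(90, 80, 70, 60), TH = 40)
  ri <- render_image(geom, tab, noise_frac = 0, seed = 10)
  meta <- data.frame(case_id = "case01", group = "g", age = 1)
  e1 <- extract_neuron_table(ri$stack, ri$rois, meta)
  perm <- c(3, 1, 4, 2)
  e2 <- extract_neuron_table(ri$stack, ri$rois[perm], meta)
  expect_identical(e2$neuron_id, e1$neuron_id[perm])
  expect_equal(e2$NDUFB8, e1$NDUFB8[perm], tolerance = 1e-12)
})

test_that("mask partition invariant: cytoplasm + excluded = mask", {
  geom <- plan_geometry(2, c(128, 128), seed = 12)
  ids <- vapply(unclass(geom), `[[`, "", "neuron_id")
  tab <- data.frame(neuron_id = ids, case_id = "case01", group = "g", age = 1,
                    NDUFB8 = 10, NDUFA13 = 10, SDHA = 10, UqCRC2 = 10,
                    MTCO1 = 10, COX4 = 10, ATP5B = 10, OSCP = 10,
                    VDAC1 = 100, TH = 40)
  ri <- render_image(geom, tab, noise_frac = 0, seed = 12)
  for (roi in ri$rois) {
    mask <- rasterize_roi(roi, dim(ri$stack$pixels)[2:3])
    res <- cytoplasmic_mean(ri$stack, mask)
    hh <- channel_plane(ri$stack, "HistoneH3") > 5
    ir <- channel_plane(ri$stack, "Ir") > 5
    n_excluded <- sum(mask & (hh | ir))
    expect_identical(res$n_pixels_cytoplasm + n_excluded, res$n_pixels_total)
  }
})

test_that("rendering is deterministic and invertible", {
  geom <- plan_geometry(3, c(128, 128), seed = 14)
  ids <- vapply(unclass(geom), `[[`, "", "neuron_id")
  tab <- data.frame(neuron_id = ids, case_id = "case01", group = "g", age = 1,
                    NDUFB8 = c(11, 22, 33), NDUFA13 = 15, SDHA = 15,
                    UqCRC2 = 15, MTCO1 = 15, COX4 = 15, ATP5B = 15, OSCP = 15,
                    VDAC1 = c(101, 102, 103), TH = 40)
  r1 <- render_image(geom, tab, noise_frac = 0.1, seed = 14)
  r2 <- render_image(geom, tab, noise_frac = 0.1, seed = 14)
  expect_identical(r1$stack$pixels, r2$stack$pixels)
  # zero-noise inversion
  r0 <- render_image(geom, tab, noise_frac = 0, seed = 14)
  meta <- data.frame(case_id = "case01", group = "g", age = 1)
  ext <- extract_neuron_table(r0$stack, r0$rois, meta)
  m <- match(ext$neuron_id, tab$neuron_id)
  expect_equal(ext$NDUFB8, tab$NDUFB8[m], tolerance = 1e-12)
  expect_equal(ext$VDAC1, tab$VDAC1[m], tolerance = 1e-12)
})
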