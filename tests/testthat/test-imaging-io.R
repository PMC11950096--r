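test_that("tiles round-trip through PNG and TIFF unchanged", {
  cs <- diploid_case()
  for (ext in c("tiff", "png")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_tile(cs$tile, path)
    back <- read_tile(path, cs$tile$pixel_size_um)
    expect_identical(back$pixels, cs$tile$pixels)
  }
})

test_that("channel-layout contracts are enforced on read", {
  # alpha channel is dropped with a warning
  rgba <- array(runif(32 * 32 * 4), dim = c(32, 32, 4))
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgba, p)
  expect_warning(tile <- read_tile(p, 1), "alpha")
  expect_equal(dim(tile$pixels)[3], 3)
  # grayscale is an error
  g <- matrix(runif(32 * 32), 32)
  pg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(g, pg)
  expect_error(read_tile(pg, 1), "3 channels", class = "ishquant_io_error")
  # missing pixel size from both sources
  rgb3 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  p3 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb3, p3)
  expect_error(read_tile(p3), "pixel size", class = "ishquant_io_error")
  expect_error(read_tile(withr::local_tempfile(fileext = ".png"), 1),
               class = "ishquant_io_error")
})

test_that("GeoJSON ROIs load, validate and measure correctly", {
  sq <- function(x0, y0, w) list(list(c(x0, y0), c(x0 + w, y0),
                                      c(x0 + w, y0 + w), c(x0, y0 + w),
                                      c(x0, y0)))
  gj <- list(type = "Polygon", coordinates = sq(0, 0, 1))
  p <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)
  roi <- read_roi(p)
  expect_s3_class(roi, "ish_roi")
  expect_equal(roi_area_um2(roi, 1), 1)            # unit square at 1 um/px
  gj2 <- list(type = "Feature", properties = list(name = "tumor"),
              geometry = list(type = "Polygon", coordinates = sq(0, 0, 100)))
  p2 <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj2, p2, auto_unbox = TRUE, digits = NA)
  expect_equal(roi_area_um2(read_roi(p2), 0.121), 146.41) # (100 * 0.121)^2
  expect_error(read_roi(withr::local_tempfile(fileext = ".geojson")),
               "not found", class = "ishquant_io_error")
  # self-intersecting bow-tie names the ring
  bow <- list(type = "Polygon",
              coordinates = list(list(c(0, 0), c(2, 2), c(2, 0), c(0, 2), c(0, 0))))
  p3 <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(bow, p3, auto_unbox = TRUE, digits = NA)
  expect_error(read_roi(p3), "ring 1", class = "ishquant_io_error")
})

test_that("point-in-ROI respects holes and multiple parts", {
  outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  hole <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
  roi <- ish_roi(list(list(outer, hole)))
  expect_true(points_in_roi(2, 2, roi))
  expect_false(points_in_roi(5, 5, roi))   # inside the hole
  expect_false(points_in_roi(12, 5, roi))  # outside
  expect_true(all(points_in_roi(c(1, 2), c(1, 2), NULL)))
})

test_that("the overlay writes outlines plus a parseable annotation sidecar", {
  H <- 120; W <- 120
  m <- disk_mask(H, W, 60, 60, 25)
  labels <- matrix(0L, H, W); labels[m] <- 1L
  px <- array(250, dim = c(H, W, 3))
  tile <- ish_tile(px, 0.5)
  nuc <- make_nuclei(4, 2)
  nuc$x <- 60; nuc$y <- 60
  path <- withr::local_tempfile(fileext = ".png")
  out <- write_overlay(tile, nuc, labels, path)
  side <- jsonlite::read_json(out[["sidecar"]], simplifyVector = FALSE)
  expect_length(side$nuclei, 1)
  expect_equal(side$nuclei[[1]]$text, "H:4 C:2")
  expect_true(side$nuclei[[1]]$included)
  # an excluded-by-size nucleus carries its reason code
  nuc2 <- nuc
  nuc2$included <- FALSE; nuc2$reason <- "AREA_SMALL"
  out2 <- write_overlay(tile, nuc2, labels, withr::local_tempfile(fileext = ".png"))
  side2 <- jsonlite::read_json(out2[["sidecar"]], simplifyVector = FALSE)
  expect_equal(side2$nuclei[[1]]$reason, "AREA_SMALL")
  # zero nuclei: overlay equals the input image
  empty <- make_nuclei(integer(), integer())
  out3 <- write_overlay(tile, empty, matrix(0L, H, W),
                        withr::local_tempfile(fileext = ".png"))
  back <- read_tile(out3[["overlay"]], 0.5)
  expect_identical(back$pixels, tile$pixels)
})

test_that("case outputs conserve counts and the summary round-trips", {
  res <- diploid_result()
  cs <- diploid_case()
  dir <- withr::local_tempdir()
  paths <- write_case_outputs(res$quant, res$nuclei, cs$tile, res$labels, dir)
  cells <- read.csv(paths[["cells"]])
  expect_equal(nrow(cells), nrow(res$nuclei))
  expect_equal(sum(cells$included), res$quant$n_cells)
  back <- read_case_summary(paths[["summary"]])
  for (f in c("n_cells", "mean_her2", "mean_cep17", "ratio", "me_her2",
              "me_ratio", "ish_group", "her2_status")) {
    expect_equal(back[[f]], res$quant[[f]], info = f)
  }
  # writers are pure: a second run writes identical files
  dir2 <- withr::local_tempdir()
  paths2 <- write_case_outputs(res$quant, res$nuclei, cs$tile, res$labels, dir2)
  expect_identical(readLines(paths[["summary"]]), readLines(paths2[["summary"]]))
  expect_identical(readLines(paths[["cells"]]), readLines(paths2[["cells"]]))
})
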