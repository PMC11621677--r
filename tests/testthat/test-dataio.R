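test_that("polygon rasterisation matches analytic pixel counts", {
  sq <- rasterizePolygon(c(0, 0, 9, 0, 9, 9, 0, 9), 20, 20)
  expect_equal(nrow(sq), 100)
  expect_true(all(sq >= 0 & sq <= 9))
  # axis-aligned rectangle partially off-image is cropped
  rect <- rasterizePolygon(c(-5, 0, 4, 0, 4, 2, -5, 2), 20, 20)
  expect_equal(nrow(rect), 5 * 3)
})

test_that("RLE and polygon encodings of the same region decode identically", {
  h <- 20L; w <- 20L
  poly_pix <- rasterizePolygon(c(3, 2, 12, 2, 12, 9, 3, 9), w, h)
  rle <- dietvision:::rleEncode(poly_pix, h, w)
  rle_pix <- dietvision:::rleDecode(rle$counts, h, w)
  expect_setequal(paste(poly_pix[, 1], poly_pix[, 2]),
                  paste(rle_pix[, 1], rle_pix[, 2]))
  # and a COCO JSON carrying both encodings yields identical pixel sets
  doc <- list(
    images = list(list(id = 1, file_name = "fr1.png", width = w,
                       height = h)),
    categories = list(list(id = 1, name = "yam")),
    annotations = list(
      list(id = 1, image_id = 1, category_id = 1,
           segmentation = list(list(c(3, 2, 12, 2, 12, 9, 3, 9)))),
      list(id = 2, image_id = 1, category_id = 1,
           segmentation = list(counts = as.list(rle$counts),
                               size = list(h, w)))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  frames <- readAnnotations(path)
  ms <- frames[["fr1"]]
  expect_length(ms, 2)
  expect_setequal(paste(maskPixels(ms[[1]])[, 1], maskPixels(ms[[1]])[, 2]),
                  paste(maskPixels(ms[[2]])[, 1], maskPixels(ms[[2]])[, 2]))
})

test_that("mask decode is idempotent through an encode round trip", {
  set.seed(3)
  pix <- unique(cbind(row = sample(0:19, 60, TRUE),
                      col = sample(0:19, 60, TRUE)))
  rle <- dietvision:::rleEncode(pix, 20L, 20L)
  dec <- dietvision:::rleDecode(rle$counts, 20L, 20L)
  rle2 <- dietvision:::rleEncode(dec, 20L, 20L)
  expect_identical(rle$counts, rle2$counts)
})

test_that("unknown categories are rejected naming the accepted labels", {
  doc <- list(
    images = list(list(id = 1, file_name = "fr1.png", width = 10,
                       height = 10)),
    categories = list(list(id = 1, name = "pizza")),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            segmentation = list(list(c(0, 0, 3, 0, 3, 3))))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(readAnnotations(path), "pizza")
  expect_error(readAnnotations(path), "ugali")  # lists accepted labels
})

test_that("annotations survive a write/read round trip", {
  frames <- list(fr1 = list(discMask(10, 8, 5, "fr1", "container"),
                            discMask(10, 8, 2, "fr1", "yam", "y1")))
  sizes <- list(fr1 = c(width = 24, height = 20))
  path <- withr::local_tempfile(fileext = ".json")
  writeAnnotations(frames, sizes, path)
  back <- readAnnotations(path)
  expect_length(back[["fr1"]], 2)
  cats <- vapply(back[["fr1"]], maskCategory, character(1))
  for (cat in c("container", "yam")) {
    a <- maskPixels(frames$fr1[[match(cat, c("container", "yam"))]])
    b <- maskPixels(back[["fr1"]][[match(cat, cats)]])
    expect_setequal(paste(a[, 1], a[, 2]), paste(b[, 1], b[, 2]))
  }
})

test_that("16-bit depth PNG round trip is lossless to the millimetre", {
  k <- tinyIntrinsics(32, 24)
  mm <- matrix(sample(0:4000, 32 * 24, replace = TRUE), 24, 32)
  mm[1, 1] <- 0  # invalid sentinel
  frame <- depthFrame("d1", mm / 1000, k)
  path <- withr::local_tempfile(fileext = ".png")
  writeDepth(frame, path)
  back <- readDepth(path, k, frame_id = "d1")
  expect_equal(depthMatrix(back), depthMatrix(frame), tolerance = 0)
  # stored value 1000 at scale 1 is exactly one metre
  expect_equal(depthMatrix(back)[2, 2], mm[2, 2] / 1000)
  # zero stays an invalid pixel and is excluded from re-projection
  pts <- reproject(back)
  expect_equal(nrow(pts), sum(mm > 0))
})

test_that("depth reading validates image size and scale", {
  k <- tinyIntrinsics(32, 24)
  frame <- depthFrame("d1", matrix(0.5, 24, 32), k)
  path <- withr::local_tempfile(fileext = ".png")
  writeDepth(frame, path)
  expect_error(readDepth(path, tinyIntrinsics(16, 12)), "does not match")
  # scale 0.5 mm per unit halves the metric depth
  half <- readDepth(path, k, scale_mm_per_unit = 0.5)
  expect_equal(depthMatrix(half)[1, 1], 0.25)
})

test_that("feature table round trips with the canonical 24-column order", {
  fv <- featureVector("yam", oneHot("yam"), frr = 0.25, vc = 400,
                      np = 30000, par = 1.2, awr = 3.5)
  df <- featureTable(list(yam = fv), episode_id = "ep1", frame_id = "fr1",
                     weights = c(yam = 120.5))
  expect_identical(names(df), dietvision:::featureTableColumns())
  expect_length(names(df), 24)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(df, path)
  back <- readFeatureTable(path)
  expect_equal(back$weight_g, 120.5)
  expect_equal(as.numeric(back[1, featureOrder()]),
               as.numeric(df[1, featureOrder()]), tolerance = 1e-9)
  # empty record list gives a header-only file
  writeFeatureTable(df[0, ], path)
  expect_equal(nrow(readFeatureTable(path)), 0)
  # a missing feature column is an error naming the column
  expect_error(writeFeatureTable(df[setdiff(names(df), "par")], path),
               "par")
})

test_that("AWR table and weights CSV round trip", {
  tab <- c("beef stew" = 2.3, "yam" = 3.5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeAwrTable(tab, path)
  expect_equal(readAwrTable(path), tab)
  w <- data.frame(episode_id = "ep1", category = "Yam", weight_g = 80)
  writeWeights(w, path)
  expect_equal(readWeights(path)$category, "yam")
})

test_that("manifest round trips and validates its frame references", {
  m <- episodeManifest("ep1", c("f1", "f2", "f3"), "f1", "f3",
                       device_tag = "cam", ground_truth = c(yam = 50))
  path <- withr::local_tempfile(fileext = ".json")
  writeManifest(m, path)
  back <- readManifest(path)
  expect_equal(back@startFrameId, "f1")
  expect_equal(back@groundTruth, c(yam = 50))
  expect_error(episodeManifest("e", c("f1"), "f1", "f9"), "end frame")
  expect_error(episodeManifest("e", "f1", "f1", "f1",
                               ground_truth = c(yam = -2)), ">= 0")
})

test_that("instance masks from a PNG directory match the label sheet", {
  dir <- withr::local_tempdir()
  img <- matrix(0, 10, 12)
  img[3:5, 4:7] <- 1
  png::writePNG(img, file.path(dir, "m1.png"))
  write.csv(data.frame(file = "m1.png", frame_id = "fr9",
                       category = "Ugali", instance_id = "a"),
            file.path(dir, "labels.csv"), row.names = FALSE)
  frames <- readAnnotations(dir)
  m <- frames[["fr9"]][[1]]
  expect_equal(maskCategory(m), "ugali")
  expect_equal(nrow(maskPixels(m)), 12)
})
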