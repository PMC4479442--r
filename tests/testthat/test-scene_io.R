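test_that("scene write/read round-trip recovers arrays and georeference", {
    orch <- tinyOrchard(seed = 21, n = 1L, gsd = 0.1)
    scene <- orch$scene
    d <- withr::local_tempdir()
    op <- file.path(d, "ortho.tif"); dp <- file.path(d, "dsm.tif")
    writeScene(scene, op, dp)
    back <- loadScene(op, dp, sensor_kind = "visible")
    expect_identical(bands(back)$G, bands(scene)$G)     # integer DN exact
    expect_identical(bands(back)$R, bands(scene)$R)
    expect_lt(max(abs(dsm(back) - dsm(scene))), 1e-6)   # float layer
    expect_equal(sceneTransform(back), sceneTransform(scene), tolerance = 1e-9)
    expect_identical(sensorKind(back), "visible")
    expect_identical(back@crs_id, scene@crs_id)
})

test_that("combined multi-layer file carries the DSM as a band", {
    orch <- tinyOrchard(seed = 22, n = 1L, gsd = 0.1)
    d <- withr::local_tempdir()
    op <- file.path(d, "stack.tif")
    writeScene(orch$scene, op, combined = TRUE)
    back <- loadScene(op, sensor_kind = "visible")
    expect_lt(max(abs(dsm(back) - dsm(orch$scene))), 1e-6)
    expect_setequal(names(bands(back)), names(bands(orch$scene)))
})

test_that("shape and schema violations fail loudly", {
    orch <- tinyOrchard(seed = 23, n = 1L, gsd = 0.1)
    scene <- orch$scene
    d <- withr::local_tempdir()
    op <- file.path(d, "o.tif"); dp <- file.path(d, "d.tif")
    writeScene(scene, op, dp)
    # DSM with one column chopped off -> alignment error
    cropped <- scene
    cropped@bands <- lapply(cropped@bands, function(m) m[, -1])
    cropped@dsm <- cropped@dsm[, -1]
    cropped@nodata_mask <- cropped@nodata_mask[, -1]
    dp2 <- file.path(d, "d2.tif")
    .w <- getFromNamespace(".writeRaster", "canopyOBIA")
    .w(dp2, list(DSM = cropped@dsm), scene@transform, scene@crs_id, NULL,
       dtypes = "float")
    expect_error(loadScene(op, dp2, sensor_kind = "visible"),
                 class = "alignment_error")
    # multispectral without NIR -> schema error
    expect_error(loadScene(op, dp, sensor_kind = "multispectral"),
                 class = "schema_error")
})

test_that("a geographic CRS is rejected with a unit error", {
    orch <- tinyOrchard(seed = 24, n = 1L, gsd = 0.1)
    scene <- orch$scene
    scene@crs_id <- "EPSG:4326"
    d <- withr::local_tempdir()
    op <- file.path(d, "o.tif"); dp <- file.path(d, "d.tif")
    writeScene(scene, op, dp)
    expect_error(loadScene(op, dp, sensor_kind = "visible"),
                 class = "unit_error")
})

test_that("nodata propagates as the union of per-layer nodata", {
    orch <- tinyOrchard(seed = 25, n = 1L, gsd = 0.1)
    scene <- orch$scene
    mask <- matrix(FALSE, nrow(dsm(scene)), ncol(dsm(scene)))
    mask[1:5, 1:5] <- TRUE            # hole in the ortho
    dmask <- matrix(FALSE, nrow(mask), ncol(mask))
    dmask[10:12, 3:9] <- TRUE         # different hole in the DSM
    d <- withr::local_tempdir()
    op <- file.path(d, "o.tif"); dp <- file.path(d, "d.tif")
    .w <- getFromNamespace(".writeRaster", "canopyOBIA")
    .w(op, bands(scene), scene@transform, scene@crs_id, !mask)
    .w(dp, list(DSM = dsm(scene)), scene@transform, scene@crs_id, !dmask,
       dtypes = "float")
    back <- loadScene(op, dp, sensor_kind = "visible")
    expect_true(all(nodataMask(back)[mask | dmask]))
    expect_false(any(nodataMask(back)[!(mask | dmask)]))
})

test_that("entity export writes matching GeoJSON and CSV and round-trips", {
    rec <- data.frame(tree_id = 1:3, x = c(10, 20, 30), y = c(5, 6, 7),
                      length_axis = c(4.1, 3.2, 2.5),
                      width_axis = c(3.9, 3.0, 1.6),
                      projected_area = c(13.2, 8.1, 2.6),
                      height = c(3.85, 2.1, 3.25),
                      volume = c(21.84, 9.3, 5.47))
    sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
    polys <- list("1" = sq + 10, "2" = sq + 20)
    d <- withr::local_tempdir()
    vp <- file.path(d, "ents.geojson"); tp <- file.path(d, "ents.csv")
    writeEntities(rec, polys, vp, tp)
    gj <- jsonlite::read_json(vp)
    expect_length(gj$features, 3L)
    tab <- read.csv(tp)
    expect_equal(nrow(tab), 3L)
    expect_named(tab, c("tree_id", "x", "y", "length_axis", "width_axis",
                        "projected_area", "height", "volume"))
    back <- readEntities(vp)
    expect_equal(back$records$volume, rec$volume, tolerance = 1e-9)
    expect_equal(back$records$height, rec$height, tolerance = 1e-9)
    # polygons round-trip closed rings
    expect_equal(back$polygons[["1"]][1:4, ], unname(sq + 10))
})

test_that("empty record sets export as valid empty artefacts", {
    rec <- data.frame(tree_id = integer(0), x = numeric(0), y = numeric(0),
                      length_axis = numeric(0), width_axis = numeric(0),
                      projected_area = numeric(0), height = numeric(0),
                      volume = numeric(0))
    d <- withr::local_tempdir()
    vp <- file.path(d, "e.geojson"); tp <- file.path(d, "e.csv")
    writeEntities(rec, list(), vp, tp)
    gj <- jsonlite::read_json(vp)
    expect_length(gj$features, 0L)
    tab <- read.csv(tp)
    expect_equal(nrow(tab), 0L)
    expect_equal(ncol(tab), 8L)
    expect_error(writeEntities(rec, list(), file.path(d, "nope", "x.geojson"),
                               tp), class = "io_error")
})
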