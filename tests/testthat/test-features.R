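# shared pipeline run for the feature tests
.featOrch <- NULL
.featAn <- NULL
featureFixture <- function() {
    if (is.null(.featAn)) {
        .featOrch <<- tinyOrchard(seed = 51, n = 2L)
        .featAn <<- runPipeline(.featOrch$scene)
    }
    list(orch = .featOrch, an = .featAn)
}

test_that("isolated crowns merge into one entity each, rows into one per row", {
    fx <- featureFixture()
    expect_equal(nrow(treeRecords(fx$an)), 4L)   # 2 x 2 single trees
    rows <- generateOrchard(orchardConfig(
        pattern = "tree_row", spacing = c(4, 1.2), n_rows = 3L, n_cols = 5L,
        rx_range = c(0.9, 1.3), ry_range = c(0.8, 1.1),
        height_range = c(1.5, 2.5), gsd = 0.03, sensor_kind = "visible",
        margin = 1.5, seed = 52))
    an_rows <- runPipeline(rows$scene)
    expect_equal(nrow(treeRecords(an_rows)), 3L)
})

test_that("single-pixel integration follows the pixel-volume arithmetic", {
    lab <- matrix(0L, 5, 5)
    lab[3, 3] <- 1L
    ph <- matrix(NA_real_, 5, 5)
    ph[3, 3] <- 2
    lv <- new("SegmentLevel", labels = lab,
              objects = getFromNamespace(".objectTable", "canopyOBIA")(
                  lab, list()),
              edges = matrix(integer(0), 0, 2),
              transform = c(0, 0.5, 0.1, 0.1), gsd = 0.1)
    lv@objects$tree_entity <- TRUE
    cm <- new("ClassMap", object_class = c("1" = "tree"),
              object_height = c("1" = 2), pixel_height = ph,
              baseline_elev = c("1" = 0), baseline_failed = integer(0))
    rec <- entityMetrics(lv, cm, ids = 1L)
    expect_equal(rec$projected_area, 0.01)
    expect_equal(rec$volume, 0.02)
    expect_equal(rec$height, 2)
    expect_equal(rec$length_axis, 0.1)
    expect_equal(rec$width_axis, 0.1)
    # centroid at the pixel centre in map coordinates
    expect_equal(rec$x, 0.25)
    expect_equal(rec$y, 0.25)
})

test_that("records carry the per-tree output schema and axis ordering", {
    fx <- featureFixture()
    rec <- treeRecords(fx$an)
    expect_named(rec, c("tree_id", "x", "y", "length_axis", "width_axis",
                        "projected_area", "height", "volume"))
    expect_true(all(rec$length_axis >= rec$width_axis))
    expect_true(all(rec$width_axis > 0))
    expect_true(all(rec$projected_area > 0))
    expect_true(all(rec$height >= 0))
})

test_that("volume is additive and bounded by area times height", {
    fx <- featureFixture()
    an <- fx$an
    rec <- treeRecords(an)
    expect_true(all(rec$volume <= rec$projected_area * rec$height + 1e-9))
    # split each entity's pixels into arbitrary groups: volumes add exactly
    ents <- entityLevel(an)
    lab <- segLabels(ents)
    ph <- pixelHeight(an@classes)
    g <- gsd(ents)
    set.seed(7)
    for (id in rec$tree_id) {
        idx <- which(lab == id)
        grp <- sample(1:3, length(idx), replace = TRUE)
        parts <- vapply(1:3, function(k) {
            v <- ph[idx[grp == k]]
            sum(v[is.finite(v)]) * g^2
        }, numeric(1))
        expect_equal(sum(parts), rec$volume[rec$tree_id == id],
                     tolerance = 1e-12)
    }
})

test_that("footprint polygons enclose their entity and export round-trips", {
    fx <- featureFixture()
    an <- fx$an
    rec <- treeRecords(an)
    for (id in rec$tree_id) {
        fp <- an@polygons[[as.character(id)]]
        expect_false(is.null(fp))
        # ring spans roughly the bounding box of the entity footprint
        expect_gt(nrow(fp), 8)
    }
    d <- withr::local_tempdir()
    paths <- writeAnalysis(an, d)
    expect_true(all(file.exists(paths)))
    back <- readEntities(paths[["vector"]])
    expect_equal(nrow(back$records), nrow(rec))
})

test_that("field summary reports counts, moments and spacing", {
    rec <- data.frame(tree_id = 1:3, x = c(0, 7, 14), y = c(0, 0, 0),
                      length_axis = 4, width_axis = 4,
                      projected_area = c(10, 12, 14),
                      height = c(2, 3, 4), volume = c(10, 20, 30))
    fs <- summarizeField(rec)
    expect_equal(fs$n_trees, 3L)
    expect_equal(fs$height_mean, 3)
    expect_equal(fs$mean_nn_spacing, 7)
    one <- summarizeField(rec[1, ])
    expect_equal(one$height_sd, 0)
    expect_true(one$single_sample)
    expect_error(summarizeField(rec[0, ]), class = "empty_summary_error")
})

test_that("a regular planting grid yields the expected mean spacing", {
    orch <- generateOrchard(orchardConfig(
        n_rows = 3L, n_cols = 3L, spacing = c(7, 7), gsd = 0.05,
        rx_range = c(1.5, 2.2), ry_range = c(1.5, 2.2),
        sensor_kind = "visible", margin = 2, seed = 53))
    an <- runPipeline(orch$scene)
    fs <- fieldSummary(an)
    expect_equal(fs$n_trees, 9L)
    expect_equal(fs$mean_nn_spacing, 7, tolerance = 0.02)
})
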