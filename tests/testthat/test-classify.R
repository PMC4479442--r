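test_that("Otsu separates two weighted clusters and rejects constants", {
    thr <- otsuThreshold(c(0.1, 0.9), c(50, 50))
    expect_gt(thr, 0.1)
    expect_lte(thr, 0.9)
    expect_error(otsuThreshold(rep(0.5, 10), rep(1, 10)),
                 class = "degenerate_distribution_error")
    expect_error(otsuThreshold(0.3, 1), class = "degenerate_distribution_error")
})

test_that("Otsu equals the exhaustive between-class-variance maximiser", {
    set.seed(99)
    for (rep in 1:25) {
        n <- 200L
        values <- c(rnorm(n / 2, 0.15, 0.05), rnorm(n / 2, 0.7, 0.08))
        weights <- sample(1:500, n, replace = TRUE)
        expect_equal(otsuThreshold(values, weights),
                     bruteForceOtsu(values, weights), tolerance = 1e-12)
    }
})

test_that("vegetation isolation recovers the true classes on a clean scene", {
    orch <- tinyOrchard(seed = 41, n = 2L, noise_sd = 0, grass_fraction = 0)
    lv <- multiresolutionSegment(orch$scene, segmentationParams())
    cm <- classifyVegetation(lv, vegetationIndex(orch$scene))
    lab <- segLabels(lv)
    veg_ids <- as.integer(names(objectClass(cm))[objectClass(cm) != "bare_soil"])
    pred_veg <- matrix(lab %in% veg_ids, nrow(lab))
    truth_crown <- classMask(orch$truth) == 2L
    truth_soil <- classMask(orch$truth) == 0L
    expect_gt(sum(pred_veg & truth_crown) / sum(truth_crown), 0.99)
    expect_gt(sum(!pred_veg & truth_soil) / sum(truth_soil), 0.99)
})

test_that("an all-soil scene surfaces the degenerate distribution", {
    m <- matrix(120, 40, 40)
    sc <- SceneStack(bands = list(R = m, G = m, B = m), dsm = matrix(80, 40, 40),
                     transform = c(0, 4, 0.1, 0.1), sensor_kind = "visible")
    lv <- multiresolutionSegment(sc, segmentationParams(scale = 50))
    expect_error(classifyVegetation(lv, excessGreen(sc)),
                 class = "degenerate_distribution_error")
})

test_that("thresholding acts on object means, not pixels", {
    # one object half-bright/half-dark in the index, two pure objects:
    # the mixed object must be classified once, as a unit
    v <- rbind(matrix(0.0, 4, 12),
               cbind(matrix(0.2, 4, 6), matrix(0.8, 4, 6)),
               matrix(1.0, 4, 12))
    idx <- new("IndexLayer", values = v, index_kind = "NDVI",
               nodata_mask = matrix(FALSE, 12, 12))
    lab <- rbind(matrix(1L, 4, 12), matrix(2L, 4, 12), matrix(3L, 4, 12))
    lv <- new("SegmentLevel", labels = lab,
              objects = getFromNamespace(".objectTable", "canopyOBIA")(
                  lab, list(idx = v)),
              edges = cbind(c(1L, 2L), c(2L, 3L)),
              transform = c(0, 1.2, 0.1, 0.1), gsd = 0.1)
    cm <- classifyVegetation(lv, idx)
    cls <- objectClass(cm)
    expect_identical(unname(cls[c("1", "3")]), c("bare_soil", "tree"))
    expect_length(unique(cls["2"]), 1L)  # single label for the mixed object
})

test_that("object heights use the local bare-soil baseline", {
    # flat terrain at 100 m, crown DSM at 103 m -> height 3.0
    sc <- squareCrownScene(height = 3, base = 100)
    lv <- multiresolutionSegment(sc, segmentationParams(scale = 15))
    cm <- classifyVegetation(lv, excessGreen(sc))
    cm <- objectHeight(lv, dsm(sc), cm, ring_px = 5L)
    cm <- removeHerbaceous(cm)
    h <- objectHeights(cm)[objectClass(cm) == "tree"]
    expect_equal(unname(max(h)), 3, tolerance = 1e-9)
    # translation invariance: DSM + 57 m changes nothing
    cm2 <- classifyVegetation(lv, excessGreen(sc))
    cm2 <- objectHeight(lv, dsm(sc) + 57, cm2, ring_px = 5L)
    cm2 <- removeHerbaceous(cm2)
    expect_equal(objectHeights(cm2), objectHeights(cm), tolerance = 1e-9)
    expect_identical(objectClass(cm2), objectClass(cm))
    ph1 <- pixelHeight(cm); ph2 <- pixelHeight(cm2)
    expect_equal(ph1[is.finite(ph1)], ph2[is.finite(ph2)], tolerance = 1e-9)
})

test_that("the local baseline removes terrain slope", {
    # a crown with a unique apex: its height reading must not change when
    # the whole terrain is tilted by 10 %
    flat <- halfEllipsoidScene(rx = 1.5, ry = 1.5, h = 3, gsd = 0.05,
                               slope = 0, extent = 6)
    tilt <- halfEllipsoidScene(rx = 1.5, ry = 1.5, h = 3, gsd = 0.05,
                               slope = 0.10, extent = 6)
    get_h <- function(orch) {
        sc <- orch$scene
        lv <- multiresolutionSegment(sc, segmentationParams())
        cm <- classifyVegetation(lv, excessGreen(sc))
        cm <- objectHeight(lv, dsm(sc), cm, ring_px = 5L)
        cm <- removeHerbaceous(cm)
        unname(max(objectHeights(cm)[objectClass(cm) == "tree"]))
    }
    tol <- 5 * 0.05 * 0.10  # ring_px * gsd * slope
    expect_lt(abs(get_h(tilt) - get_h(flat)), tol)
})

test_that("low vegetation is relabelled herbaceous, tall stays tree", {
    orch <- tinyOrchard(seed = 42, grass_fraction = 0.08)
    lv <- multiresolutionSegment(orch$scene, segmentationParams())
    cm <- classifyVegetation(lv, vegetationIndex(orch$scene))
    cm <- objectHeight(lv, dsm(orch$scene), cm, ring_px = 5L)
    cm <- removeHerbaceous(cm, min_tree_height = 0.5)
    lab <- segLabels(lv)
    cls <- objectClass(cm)
    truth <- classMask(orch$truth)
    herb_ids <- as.integer(names(cls)[cls == "herbaceous"])
    tree_ids <- as.integer(names(cls)[cls == "tree"])
    # grass-truth pixels never end up in tree objects, crowns never herbaceous
    grass_px <- truth == 1L
    crown_px <- truth == 2L
    in_tree <- matrix(lab %in% tree_ids, nrow(lab))
    expect_lt(sum(in_tree & grass_px) / max(sum(grass_px), 1), 0.01)
    expect_gt(sum(in_tree & crown_px) / sum(crown_px), 0.98)
    expect_gt(length(herb_ids), 0L)
    # explicit cuts
    cm2 <- cm
    cm2@object_class[] <- "tree"
    cm2@object_class[1] <- "bare_soil"
    cm2@object_height[] <- 3
    cm2@object_height[2] <- 0.2
    out <- removeHerbaceous(cm2, min_tree_height = 0.5)
    expect_identical(unname(objectClass(out)[2]), "herbaceous")
    expect_identical(unname(objectClass(out)[3]), "tree")
})
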