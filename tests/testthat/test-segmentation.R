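test_that("default layer weights pick DSM plus Green or NIR", {
    vis <- tinyOrchard(seed = 31, n = 1L, gsd = 0.1, sensor = "visible")$scene
    w <- defaultLayerWeights(vis)
    expect_equal(w[["DSM"]], 1)
    expect_equal(w[["G"]], 1)
    expect_true(all(w[setdiff(names(w), c("DSM", "G"))] == 0))
    ms <- tinyOrchard(seed = 31, n = 1L, gsd = 0.1,
                      sensor = "multispectral")$scene
    wm <- defaultLayerWeights(ms)
    expect_equal(wm[["DSM"]], 1)
    expect_equal(wm[["NIR"]], 1)
    expect_true(all(wm[setdiff(names(wm), c("DSM", "NIR"))] == 0))
    ov <- c(R = 0.5, DSM = 2)
    expect_identical(defaultLayerWeights(vis, override = ov), ov)
})

test_that("segmentation parameter constraints are enforced", {
    expect_error(segmentationParams(scale = -1), class = "parameter_error")
    expect_error(segmentationParams(color_weight = 0.7, shape_weight = 0.4),
                 class = "parameter_error")
    p <- segmentationParams()
    expect_equal(p@color_weight, 0.6)
    expect_equal(p@shape_weight, 0.4)
    expect_equal(p@smoothness_weight, 0.5)
    expect_equal(p@compactness_weight, 0.05)
})

test_that("degenerate scenes segment as expected", {
    m <- matrix(100, 50, 50)
    sc <- SceneStack(bands = list(R = m, G = m, B = m),
                     dsm = matrix(50, 50, 50),
                     transform = c(0, 5, 0.1, 0.1), sensor_kind = "visible")
    lv <- multiresolutionSegment(sc, segmentationParams(scale = 30))
    expect_equal(nObjects(lv), 1L)          # zero heterogeneity merges freely
    expect_true(all(segLabels(lv) == 1L))
    # two homogeneous halves with contrast far above scale stay separate
    g2 <- cbind(matrix(0, 40, 20), matrix(200, 40, 20))
    sc2 <- SceneStack(bands = list(R = g2 * 0, G = g2, B = g2 * 0),
                      dsm = matrix(0, 40, 40),
                      transform = c(0, 4, 0.1, 0.1), sensor_kind = "visible")
    lv2 <- multiresolutionSegment(sc2, segmentationParams(scale = 30))
    expect_equal(nObjects(lv2), 2L)
    expect_equal(sort(unique(as.vector(segLabels(lv2)[, 1:20]))), 1L)
    # empty valid area -> empty level
    sc3 <- sc
    sc3@nodata_mask <- matrix(TRUE, 50, 50)
    lv3 <- multiresolutionSegment(sc3, segmentationParams())
    expect_equal(nObjects(lv3), 0L)
})

test_that("labels partition the valid pixels and stats are recomputable", {
    orch <- tinyOrchard(seed = 32)
    lv <- multiresolutionSegment(orch$scene, segmentationParams())
    lab <- segLabels(lv)
    valid <- !nodataMask(orch$scene)
    expect_identical(lab > 0L, valid)
    obj <- segObjects(lv)
    expect_equal(sum(obj$pixel_count), sum(valid))
    expect_equal(obj$pixel_count,
                 as.integer(tabulate(lab[lab > 0L], nbins = max(obj$id))))
    # per-object DSM means recomputed independently agree
    sp <- split(dsm(orch$scene)[lab > 0L], lab[lab > 0L])
    expect_equal(unname(vapply(sp, mean, numeric(1))), obj$mean.DSM,
                 tolerance = 1e-9)
    # neighbour relation is symmetric and irreflexive by construction
    e <- segEdges(lv)
    expect_true(all(e[, 1] < e[, 2]))
    expect_true(all(e %in% obj$id))
})

test_that("a larger scale never yields more objects", {
    orch <- tinyOrchard(seed = 33)
    counts <- vapply(c(5, 10, 20, 40, 80), function(s) {
        nObjects(multiresolutionSegment(orch$scene,
                                        segmentationParams(scale = s)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("a zero-weight layer never influences the labels", {
    orch <- tinyOrchard(seed = 34)
    lw <- defaultLayerWeights(orch$scene)
    lv1 <- multiresolutionSegment(orch$scene,
                                  segmentationParams(layer_weights = lw))
    noisy <- orch$scene
    set.seed(1)
    noisy@bands$R <- matrix(runif(length(noisy@bands$R), 0, 255),
                            nrow(noisy@bands$R))
    lv2 <- multiresolutionSegment(noisy,
                                  segmentationParams(layer_weights = lw))
    expect_identical(segLabels(lv1), segLabels(lv2))
})

test_that("segmentation is deterministic across repeated runs", {
    orch <- tinyOrchard(seed = 35)
    lv1 <- multiresolutionSegment(orch$scene, segmentationParams())
    lv2 <- multiresolutionSegment(orch$scene, segmentationParams())
    expect_identical(segLabels(lv1), segLabels(lv2))
    expect_identical(segObjects(lv1), segObjects(lv2))
})

test_that("hierarchy building merges, refines and keeps the partition", {
    set.seed(5)
    g <- matrix(round(runif(400, 0, 255)), 20, 20)
    sc <- SceneStack(bands = list(R = g, G = g, B = g), dsm = matrix(0, 20, 20),
                     transform = c(0, 2, 0.1, 0.1), sensor_kind = "visible")
    base <- multiresolutionSegment(sc, segmentationParams(scale = 6))
    ids <- segObjects(base)$id
    expect_gt(length(ids), 3L)
    # full merge -> one upper object covering everything
    all_one <- stats::setNames(rep(1L, length(ids)), ids)
    up <- buildHierarchyLevel(base, all_one)
    expect_equal(nObjects(up), 1L)
    expect_equal(segObjects(up)$pixel_count, sum(segObjects(base)$pixel_count))
    # identity grouping -> same partition as the base
    ident <- stats::setNames(seq_along(ids), ids)
    up2 <- buildHierarchyLevel(base, ident)
    expect_equal(nObjects(up2), nObjects(base))
    expect_equal(sort(segObjects(up2)$pixel_count),
                 sort(segObjects(base)$pixel_count))
    # two groups: upper pixel counts are the group sums
    half <- ids[seq_len(floor(length(ids) / 2))]
    groups <- stats::setNames(ifelse(ids %in% half, 1L, 2L), ids)
    up3 <- buildHierarchyLevel(base, groups)
    expect_equal(nObjects(up3), 2L)
    cnt <- segObjects(base)$pixel_count
    expect_equal(sort(segObjects(up3)$pixel_count),
                 sort(c(sum(cnt[ids %in% half]), sum(cnt[!ids %in% half]))))
    # refinement: every base object lies wholly inside its parent
    based <- assignParents(base, groups)
    par <- segObjects(based)$parent_id
    lab_b <- segLabels(based); lab_u <- segLabels(up3)
    for (i in seq_along(ids)) {
        sel <- lab_b == ids[i]
        expect_equal(unique(lab_u[sel]), par[i])
    }
    # unknown base id -> key error
    expect_error(buildHierarchyLevel(base, stats::setNames(1L, max(ids) + 5L)),
                 class = "key_error")
    expect_error(buildHierarchyLevel(base, stats::setNames(c(1L, 2L),
                                                           c(ids[1], ids[1]))),
                 class = "key_error")
})
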