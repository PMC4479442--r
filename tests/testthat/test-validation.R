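test_that("overall accuracy counts pixel-wise agreement", {
    a <- matrix(c(TRUE, FALSE), 10, 10)
    expect_equal(overallAccuracy(a, a), 100)
    b <- a
    b[1:10] <- !b[1:10]
    expect_equal(overallAccuracy(b, a), 90)
    expect_equal(overallAccuracy(!a, a), 0)
    expect_equal(overallAccuracy(a, !a), overallAccuracy(!a, a))  # symmetry
    expect_error(overallAccuracy(a, a[, 1:5]), class = "alignment_error")
})

test_that("ellipsoid crown volume matches the field formula", {
    # mean-diameter ellipsoid: pi/6 * ((L + W)/2)^2 * H
    expect_equal(ellipsoidVolume(4.78, 4.00, 3.85),
                 pi / 6 * ((4.78 + 4.00) / 2)^2 * 3.85)
    expect_equal(ellipsoidVolume(4.78, 4.00, 3.85), 38.85, tolerance = 1e-3)
    expect_equal(ellipsoidVolume(3, 5, 0), 0)
    expect_equal(ellipsoidVolume(2, 2, 2), 4 * pi / 3)  # sphere, diameter 2
    expect_error(ellipsoidVolume(-1, 2, 2), class = "domain_error")
})

test_that("ellipsoid volume is monotone in every argument", {
    base <- ellipsoidVolume(4, 3, 2)
    expect_gt(ellipsoidVolume(4.5, 3, 2), base)
    expect_gt(ellipsoidVolume(4, 3.5, 2), base)
    expect_gt(ellipsoidVolume(4, 3, 2.5), base)
})

test_that("average feature error follows the paired-difference arithmetic", {
    expect_equal(averageFeatureError(c(1, 2, 3), c(1, 2, 3))$mean_abs_error, 0)
    afe <- averageFeatureError(c(3.8, 2.9), c(4.0, 3.0))
    expect_equal(afe$mean_abs_error, 0.15)
    expect_equal(afe$pct_of_mean, 100 * 0.15 / 3.5)
    one <- averageFeatureError(5, 4)
    expect_equal(one$mean_abs_error, 1)
    expect_true(is.na(one$sd_abs_error))
    expect_true(one$single_sample)
    # invariant to pair ordering, never negative
    set.seed(3)
    e <- runif(10); o <- runif(10)
    p <- sample(10)
    expect_equal(averageFeatureError(e, o)$mean_abs_error,
                 averageFeatureError(e[p], o[p])$mean_abs_error)
    expect_gte(averageFeatureError(e, o)$mean_abs_error, 0)
    expect_error(averageFeatureError(1:3, 1:2), class = "pairing_error")
})

test_that("regression fit recovers exact and noisy linear relations", {
    x <- c(1, 2, 3, 4, 5)
    f <- regressionFit(x, x)
    expect_equal(f$slope, 1)
    expect_equal(f$intercept, 0)
    expect_equal(f$r_squared, 1)
    expect_equal(f$rmse, 0)
    f2 <- regressionFit(2 * x + 1, x)
    expect_equal(f2$slope, 2)
    expect_equal(f2$intercept, 1)
    expect_equal(f2$r_squared, 1)
    # seeded Monte Carlo: recovered slope within 3 standard errors
    set.seed(123)
    obs <- runif(60, 1, 5)
    est <- 1.5 * obs + 0.3 + rnorm(60, 0, 0.2)
    f3 <- regressionFit(est, obs)
    se <- 0.2 / sqrt(sum((obs - mean(obs))^2))
    expect_lt(abs(f3$slope - 1.5), 3 * se)
    expect_error(regressionFit(1:4, rep(2, 4)), class = "singular_fit_error")
    expect_error(regressionFit(1:2, 1:2), class = "pairing_error")
})

test_that("validation against truth assembles a coherent report", {
    orch <- tinyOrchard(seed = 61, n = 2L)
    an <- runPipeline(orch$scene)
    rep <- validateAgainstTruth(an, orch$truth)
    expect_s4_class(rep, "ValidationReport")
    expect_gte(rep@overall_accuracy, 0)
    expect_lte(rep@overall_accuracy, 100)
    expect_equal(rep@n, 4L)
    expect_setequal(rep@features$feature,
                    c("height", "projected_area", "volume"))
    expect_true(all(rep@features$avg_error >= 0))
    expect_true(all(rep@features$r_squared >= 0 & rep@features$r_squared <= 1))
})
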