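#' @include features.R
NULL

#' Overall classification accuracy
#'
#' Percentage of the area correctly classified: pixel-wise agreement of a
#' predicted boolean mask with a reference mask over all valid (non-NA)
#' pixels. Symmetric in its two arguments.
#'
#' @param predicted_mask,reference_mask logical matrices of equal shape.
#' @return accuracy in percent (0-100).
#' @export
overallAccuracy <- function(predicted_mask, reference_mask) {
    if (!identical(dim(predicted_mask), dim(reference_mask)))
        .canopyError("alignment_error", "mask shapes differ")
    ok <- !is.na(predicted_mask) & !is.na(reference_mask)
    if (!any(ok)) .canopyError("alignment_error", "no valid pixels to compare")
    100 * sum(predicted_mask[ok] == reference_mask[ok]) / sum(ok)
}

#' Ellipsoid crown volume from field measurements
#'
#' The conventional field estimate that treats a crown as an ellipsoid:
#' `pi/6 * ((length + width) / 2)^2 * height`, with the mean of the two
#' canopy axes as diameter. This is the on-ground comparator for the
#' pixel-integrated volumes; the two intentionally differ for irregular
#' crowns.
#'
#' @param length_axis,width_axis canopy axes (m).
#' @param height tree height (m).
#' @return volume in m^3.
#' @export
ellipsoidVolume <- function(length_axis, width_axis, height) {
    if (any(c(length_axis, width_axis, height) < 0))
        .canopyError("domain_error", "axes and height must be non-negative")
    pi / 6 * ((length_axis + width_axis) / 2)^2 * height
}

#' Average feature error between estimated and observed values
#'
#' Mean absolute difference over paired entities, its sample standard
#' deviation, and the mean error expressed as a percentage of the mean
#' observed value.
#'
#' @param estimated,observed numeric vectors of equal length (>= 1).
#' @return list with `mean_abs_error`, `sd_abs_error` (NA with
#'   `single_sample = TRUE` when n = 1) and `pct_of_mean`.
#' @export
averageFeatureError <- function(estimated, observed) {
    if (length(estimated) != length(observed))
        .canopyError("pairing_error", "estimated and observed lengths differ")
    if (length(estimated) < 1L)
        .canopyError("pairing_error", "at least one pair is required")
    ae <- abs(estimated - observed)
    list(mean_abs_error = mean(ae),
         sd_abs_error = if (length(ae) > 1L) stats::sd(ae) else NA_real_,
         pct_of_mean = 100 * mean(ae) / mean(observed),
         single_sample = length(ae) == 1L)
}

#' Ordinary least squares fit of estimated on observed values
#'
#' @param estimated,observed numeric vectors (n >= 3).
#' @return list with `slope`, `intercept`, `r_squared` and `rmse` of the
#'   residuals.
#' @export
regressionFit <- function(estimated, observed) {
    if (length(estimated) != length(observed))
        .canopyError("pairing_error", "estimated and observed lengths differ")
    if (length(estimated) < 3L)
        .canopyError("pairing_error", "regression needs at least 3 pairs")
    if (stats::var(observed) == 0)
        .canopyError("singular_fit_error", "observed values have zero variance")
    fit <- stats::lm(estimated ~ observed)
    res <- stats::residuals(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         rmse = sqrt(mean(res^2)))
}

# Greedy one-to-one nearest-centroid matching within max_dist.
.matchRecords <- function(est, obs, max_dist) {
    if (nrow(est) == 0L || nrow(obs) == 0L)
        return(data.frame(est = integer(0), obs = integer(0)))
    d <- outer(seq_len(nrow(est)), seq_len(nrow(obs)),
               function(i, j) sqrt((est$x[i] - obs$x[j])^2 +
                                   (est$y[i] - obs$y[j])^2))
    pairs <- list()
    repeat {
        m <- which.min(d)
        if (!length(m) || d[m] > max_dist) break
        i <- (m - 1) %% nrow(d) + 1
        j <- (m - 1) %/% nrow(d) + 1
        pairs[[length(pairs) + 1L]] <- c(i, j)
        d[i, ] <- Inf
        d[, j] <- Inf
    }
    if (!length(pairs))
        return(data.frame(est = integer(0), obs = integer(0)))
    p <- do.call(rbind, pairs)
    data.frame(est = p[, 1], obs = p[, 2])
}

#' Validate a pipeline result against synthetic ground truth
#'
#' Computes the overall classification accuracy of the predicted tree mask
#' against the reference mask, and — after one-to-one nearest-centroid
#' matching of detected entities to reference trees — the average feature
#' error and regression fit for height, projected area and crown volume.
#' For tree-row patterns entity centroids do not correspond to single trees,
#' so only per-tree heights are compared, each reference tree being read at
#' its footprint through the pixel-height layer.
#'
#' @param analysis an [OrchardAnalysis-class].
#' @param truth a [GroundTruth-class] for the same scene.
#' @param max_match_dist maximum centroid distance for a match (m); default
#'   half the smaller truth spacing, estimated from the truth table.
#' @return a [ValidationReport-class].
#' @export
validateAgainstTruth <- function(analysis, truth, max_match_dist = NULL) {
    ents <- entityLevel(analysis)
    labels <- segLabels(ents)
    obj <- segObjects(ents)
    tree_ids <- obj$id[obj$tree_entity %in% TRUE]
    K <- if (nrow(obj)) max(obj$id) else 0L
    lut <- rep(FALSE, K + 1L)
    lut[tree_ids + 1L] <- TRUE
    pred_mask <- matrix(lut[labels + 1L], nrow(labels))
    ref_mask <- classMask(truth) == 2L
    oa <- overallAccuracy(pred_mask, ref_mask)

    rec <- treeRecords(analysis)
    tt <- truthTrees(truth)
    ref <- data.frame(x = tt$x, y = tt$y, height = tt$h,
                      projected_area = tt$true_area, volume = tt$true_volume)
    if (is.null(max_match_dist)) {
        nn <- if (nrow(tt) > 1) {
            dm <- as.matrix(stats::dist(tt[, c("x", "y")]))
            diag(dm) <- Inf
            min(dm)
        } else Inf
        max_match_dist <- nn / 2
    }
    feats <- data.frame(feature = character(0), avg_error = numeric(0),
                        sd_error = numeric(0), pct_of_mean = numeric(0),
                        rmse = numeric(0), r_squared = numeric(0),
                        slope = numeric(0), intercept = numeric(0),
                        n = integer(0))
    mt <- .matchRecords(rec, ref, max_match_dist)
    n_cmp <- nrow(mt)
    for (f in c("height", "projected_area", "volume")) {
        if (n_cmp < 3L) next
        est <- rec[[f]][mt$est]
        obs <- ref[[f]][mt$obs]
        afe <- averageFeatureError(est, obs)
        rf <- tryCatch(regressionFit(est, obs), canopyOBIA_error = function(e) NULL)
        feats <- rbind(feats, data.frame(
            feature = f, avg_error = afe$mean_abs_error,
            sd_error = afe$sd_abs_error, pct_of_mean = afe$pct_of_mean,
            rmse = if (is.null(rf)) NA_real_ else rf$rmse,
            r_squared = if (is.null(rf)) NA_real_ else rf$r_squared,
            slope = if (is.null(rf)) NA_real_ else rf$slope,
            intercept = if (is.null(rf)) NA_real_ else rf$intercept,
            n = n_cmp))
    }
    new("ValidationReport", overall_accuracy = oa, features = feats,
        n = as.integer(max(n_cmp, 0L)))
}

#' Per-tree apex heights read through the pixel-height layer
#'
#' For every reference tree, the estimated height is the maximum pipeline
#' pixel height inside the tree's true crown footprint. Works for both
#' single-tree and row patterns (where entity-level heights describe whole
#' rows).
#'
#' @param analysis an [OrchardAnalysis-class].
#' @param truth a [GroundTruth-class].
#' @return data.frame with `tree_id`, `est_height`, `true_height`.
#' @export
treeApexHeights <- function(analysis, truth) {
    ph <- pixelHeight(analysis@classes)
    tr <- sceneTransform(truth)
    g <- gsd(truth)
    tt <- truthTrees(truth)
    nr <- nrow(ph); nc <- ncol(ph)
    est <- rep(NA_real_, nrow(tt))
    for (i in seq_len(nrow(tt))) {
        c0 <- max(1L, floor((tt$x[i] - tt$rx[i] - tr[1]) / tr[3]) + 1L)
        c1 <- min(nc, ceiling((tt$x[i] + tt$rx[i] - tr[1]) / tr[3]))
        r0 <- max(1L, floor((tr[2] - tt$y[i] - tt$ry[i]) / tr[4]) + 1L)
        r1 <- min(nr, ceiling((tr[2] - tt$y[i] + tt$ry[i]) / tr[4]))
        if (c1 < c0 || r1 < r0) next
        v <- ph[r0:r1, c0:c1]
        v <- v[is.finite(v)]
        if (length(v)) est[i] <- max(v)
    }
    data.frame(tree_id = tt$tree_id, est_height = est, true_height = tt$h)
}
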