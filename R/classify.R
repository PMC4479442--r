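#' @include segmentation.R
NULL

#' Object-level Otsu threshold
#'
#' Otsu's automatic threshold adapted to the object-based framework: the
#' histogram is built over per-object mean index values, each object
#' weighted by its pixel count, on 256 equal-width bins spanning the value
#' range. The returned threshold is the upper edge of the bin that maximises
#' the between-class variance (ties towards the lowest such edge).
#'
#' @param values numeric vector of object means.
#' @param weights non-negative weights (object pixel counts); default 1.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, in index units.
#' @export
otsuThreshold <- function(values, weights = NULL, n_bins = 256L) {
    keep <- is.finite(values)
    values <- as.numeric(values[keep])
    if (is.null(weights)) weights <- rep(1, length(values))
    else weights <- as.numeric(weights[keep])
    if (length(values) < 2L || diff(range(values)) == 0)
        .canopyError("degenerate_distribution_error",
                     "Otsu thresholding needs at least two distinct values")
    rng <- range(values)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(values, breaks, rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
    w_k <- as.vector(tapply(weights, factor(bin, levels = seq_len(n_bins)), sum))
    w_k[is.na(w_k)] <- 0
    s_k <- as.vector(tapply(weights * values,
                            factor(bin, levels = seq_len(n_bins)), sum))
    s_k[is.na(s_k)] <- 0
    w0 <- cumsum(w_k); s0 <- cumsum(s_k)
    wt <- w0[n_bins]; st <- s0[n_bins]
    # candidate split after bin k = 1..n_bins-1
    k <- seq_len(n_bins - 1L)
    w1 <- wt - w0[k]
    ok <- w0[k] > 0 & w1 > 0
    sigma_b <- rep(-Inf, n_bins - 1L)
    mu0 <- s0[k][ok] / w0[k][ok]
    mu1 <- (st - s0[k][ok]) / w1[ok]
    sigma_b[ok] <- w0[k][ok] * w1[ok] * (mu0 - mu1)^2
    best <- which.max(sigma_b)
    breaks[best + 1L]
}

#' Isolate vegetation objects from bare soil
#'
#' Computes the mean vegetation index of every object and applies the
#' object-level Otsu threshold: objects whose mean lies above the threshold
#' are vegetation (provisionally labelled "tree" until heights are known),
#' the rest bare soil. Thresholding acts on object means, never on single
#' pixels, so a half-bright object is classified once as a unit.
#'
#' @param level a [SegmentLevel-class].
#' @param index an [IndexLayer-class] on the same grid.
#' @return a [ClassMap-class] with classes assigned and heights still NA.
#' @export
classifyVegetation <- function(level, index) {
    labels <- segLabels(level)
    vals <- indexValues(index)
    if (!identical(dim(labels), dim(vals)))
        .canopyError("alignment_error", "index grid does not match the segmentation")
    vals[nodataMask(index)] <- NA_real_
    obj <- segObjects(level)
    K <- nrow(obj)
    if (K == 0L)
        return(new("ClassMap", object_class = character(0),
                   object_height = numeric(0),
                   pixel_height = matrix(NA_real_, nrow(labels), ncol(labels)),
                   baseline_elev = numeric(0), baseline_failed = integer(0)))
    zs <- cpp_zonal_stats(labels, vals, max(obj$id))
    mu <- ifelse(zs$count > 0, zs$sum / zs$count, NA_real_)[obj$id]
    thr <- otsuThreshold(mu, obj$pixel_count)
    cls <- ifelse(!is.na(mu) & mu > thr, "tree", "bare_soil")
    names(cls) <- obj$id
    h <- rep(NA_real_, K); names(h) <- obj$id
    new("ClassMap", object_class = cls, object_height = h,
        pixel_height = matrix(NA_real_, nrow(labels), ncol(labels)),
        baseline_elev = stats::setNames(numeric(0), character(0)),
        baseline_failed = integer(0))
}

#' Height of vegetation objects above the local bare-soil baseline
#'
#' For every vegetation object the baseline is the median DSM elevation of
#' the bare-soil pixels inside a ring of `ring_px` pixels around the object;
#' an empty ring is widened to 2 x and then 4 x `ring_px`. Selecting soil
#' immediately around each object removes the terrain trend, so heights are
#' insensitive to slope. Per-pixel heights are `DSM - baseline`, clamped at
#' 0 (a vegetation pixel below its baseline is measurement noise, not
#' negative canopy); the object height is the maximum pixel height, i.e.
#' the crown apex.
#'
#' @param level a [SegmentLevel-class].
#' @param dsm numeric DSM matrix (m) on the same grid.
#' @param classes a [ClassMap-class] with vegetation/bare-soil classes.
#' @param ring_px ring width in pixels (default 5).
#' @param statistic "max" (default, the apex) or "p99" for noisy DSMs.
#' @return the updated [ClassMap-class] with `pixel_height`,
#'   `object_height`, `baseline_elev` and `baseline_failed` filled.
#' @export
objectHeight <- function(level, dsm, classes, ring_px = 5L,
                         statistic = c("max", "p99")) {
    statistic <- match.arg(statistic)
    labels <- segLabels(level)
    if (!identical(dim(labels), dim(dsm)))
        .canopyError("alignment_error", "DSM grid does not match the segmentation")
    cls <- objectClass(classes)
    ids <- as.integer(names(cls))
    veg_ids <- ids[cls != "bare_soil"]
    soil_ids <- ids[cls == "bare_soil"]
    K <- if (length(ids)) max(ids) else 0L
    soil_lut <- rep(FALSE, K + 1L)
    soil_lut[soil_ids + 1L] <- TRUE
    soil_mask <- matrix(soil_lut[labels + 1L], nrow(labels))
    baseline <- cpp_ring_baseline(labels, veg_ids, soil_mask, dsm,
                                  as.integer(ring_px))
    names(baseline) <- veg_ids
    # objects buried inside a large canopy have no soil within even the
    # widened ring; they inherit the baseline of their whole connected
    # vegetation region (whose ring does touch the surrounding soil)
    failed <- veg_ids[is.na(baseline)]
    if (length(failed)) {
        veg_lut <- rep(FALSE, K + 1L)
        veg_lut[veg_ids + 1L] <- TRUE
        comp <- cpp_cc_label(matrix(veg_lut[labels + 1L], nrow(labels)), 8L)
        comp_of <- comp[match(failed, as.vector(labels))]
        need <- unique(comp_of)
        comp_bl <- cpp_ring_baseline(comp, need, soil_mask, dsm,
                                     as.integer(ring_px))
        baseline[as.character(failed)] <- comp_bl[match(comp_of, need)]
    }
    bl_lut <- rep(NA_real_, K + 1L)
    bl_lut[veg_ids + 1L] <- baseline
    ph <- dsm - matrix(bl_lut[labels + 1L], nrow(labels))
    ph[ph < 0] <- 0
    oh <- classes@object_height
    if (statistic == "max") {
        mx <- cpp_zonal_max(labels, ph, K)
        oh[as.character(veg_ids)] <- mx[veg_ids]
    } else {
        for (id in veg_ids) {
            v <- ph[labels == id]
            oh[as.character(id)] <- if (any(is.finite(v)))
                stats::quantile(v, 0.99, na.rm = TRUE, names = FALSE) else NA_real_
        }
    }
    classes@pixel_height <- ph
    classes@object_height <- oh
    classes@baseline_elev <- baseline
    classes@baseline_failed <- veg_ids[is.na(baseline)]
    classes
}

#' Relabel low vegetation as herbaceous
#'
#' Vegetation objects lower than `min_tree_height` above their local
#' baseline become "herbaceous"; the rest remain "tree". Objects whose
#' baseline could not be determined are conservatively relabelled
#' herbaceous as well.
#'
#' @param classes a [ClassMap-class] with heights computed.
#' @param min_tree_height height cut in metres (default 0.5).
#' @return the updated [ClassMap-class].
#' @export
removeHerbaceous <- function(classes, min_tree_height = 0.5) {
    cls <- classes@object_class
    h <- classes@object_height[names(cls)]
    veg <- cls != "bare_soil"
    low <- veg & !is.na(h) & h < min_tree_height
    failed <- veg & names(cls) %in% as.character(classes@baseline_failed)
    cls[low | failed] <- "herbaceous"
    cls[veg & !(low | failed)] <- "tree"
    classes@object_class <- cls
    classes
}
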