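#' @include spectral.R
NULL

#' Construct multiresolution segmentation parameters
#'
#' @param scale positive scale parameter; merges are accepted while the
#'   weighted heterogeneity increase stays below `scale^2`. The default of
#'   20 (weighted-layer digital-number units) suits orchard scenes around
#'   2-4 cm GSD.
#' @param color_weight,shape_weight colour/shape mix (must sum to 1).
#' @param smoothness_weight,compactness_weight relative weights of the two
#'   shape heterogeneity terms, used exactly as given.
#' @param layer_weights named numeric weights per layer ("DSM" plus band
#'   names); leave empty to apply [defaultLayerWeights()] at run time.
#' @return a [SegmentationParams-class].
#' @export
segmentationParams <- function(scale = 20, color_weight = 0.6,
                               shape_weight = 0.4, smoothness_weight = 0.5,
                               compactness_weight = 0.05,
                               layer_weights = numeric(0)) {
    tryCatch(
        new("SegmentationParams", scale = scale, color_weight = color_weight,
            shape_weight = shape_weight,
            smoothness_weight = smoothness_weight,
            compactness_weight = compactness_weight,
            layer_weights = layer_weights),
        error = function(e) .canopyError("parameter_error", conditionMessage(e)))
}

#' Default segmentation layer weights for a scene
#'
#' The layers in which tree crowns are most prominent get weight 1 — the DSM
#' together with the Green band for visible-light scenes or the NIR band for
#' multispectral scenes — and all remaining layers weight 0.
#'
#' @param stack a [SceneStack-class].
#' @param override optional named weights that pass through unchanged.
#' @return named numeric vector over "DSM" and the band names.
#' @export
defaultLayerWeights <- function(stack, override = NULL) {
    if (!is.null(override)) return(override)
    w <- stats::setNames(rep(0, length(bands(stack)) + 1L),
                         c(names(bands(stack)), "DSM"))
    w["DSM"] <- 1
    spectral <- if (identical(sensorKind(stack), "visible")) "G" else "NIR"
    w[spectral] <- 1
    w
}

# Build the full object table for a label raster: per-object pixel counts,
# perimeter, bbox and mean/sd for each statistics layer.
.objectTable <- function(labels, stat_layers, pixel_count = NULL,
                         perimeter = NULL, bbox = NULL) {
    K <- max(0L, max(labels))
    if (K == 0L) {
        df <- data.frame(id = integer(0), pixel_count = integer(0),
                         perimeter = integer(0), rmin = integer(0),
                         rmax = integer(0), cmin = integer(0),
                         cmax = integer(0), parent_id = integer(0))
        for (nm in names(stat_layers)) {
            df[[paste0("mean.", nm)]] <- numeric(0)
            df[[paste0("sd.", nm)]] <- numeric(0)
        }
        return(df)
    }
    if (is.null(pixel_count))
        pixel_count <- tabulate(labels[labels > 0L], nbins = K)
    if (is.null(perimeter)) perimeter <- .perimeterPerObject(labels, K)
    if (is.null(bbox)) bbox <- .bboxPerObject(labels, K)
    df <- data.frame(id = seq_len(K), pixel_count = pixel_count,
                     perimeter = perimeter, rmin = bbox[, 1], rmax = bbox[, 2],
                     cmin = bbox[, 3], cmax = bbox[, 4],
                     parent_id = NA_integer_)
    for (nm in names(stat_layers)) {
        zs <- cpp_zonal_stats(labels, stat_layers[[nm]], K)
        mu <- ifelse(zs$count > 0, zs$sum / zs$count, NA_real_)
        va <- ifelse(zs$count > 0, pmax(zs$sumsq / zs$count - mu^2, 0), NA_real_)
        df[[paste0("mean.", nm)]] <- mu
        df[[paste0("sd.", nm)]] <- sqrt(va)
    }
    df
}

# 4-neighbour boundary edge count per object (image border and nodata count
# as boundary), vectorised over the raster.
.perimeterPerObject <- function(labels, K) {
    nr <- nrow(labels); nc <- ncol(labels)
    p <- numeric(K)
    add <- function(v) {
        if (length(v)) {
            t <- tabulate(v, nbins = K)
            p <<- p + t
        }
    }
    a <- labels[, -nc, drop = FALSE]; b <- labels[, -1, drop = FALSE]
    d <- a != b
    add(a[d & a > 0L]); add(b[d & b > 0L])
    a <- labels[-nr, , drop = FALSE]; b <- labels[-1, , drop = FALSE]
    d <- a != b
    add(a[d & a > 0L]); add(b[d & b > 0L])
    add(labels[1, ][labels[1, ] > 0L]); add(labels[nr, ][labels[nr, ] > 0L])
    add(labels[, 1][labels[, 1] > 0L]); add(labels[, nc][labels[, nc] > 0L])
    as.integer(p)
}

.bboxPerObject <- function(labels, K) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    nr <- nrow(labels)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    cbind(rmin = tapplyMin(rr, lab, K), rmax = tapplyMax(rr, lab, K),
          cmin = tapplyMin(cc, lab, K), cmax = tapplyMax(cc, lab, K))
}

tapplyMin <- function(v, g, K) {
    out <- rep(NA_integer_, K)
    o <- order(g, v)
    first <- !duplicated(g[o])
    out[g[o][first]] <- v[o][first]
    out
}

tapplyMax <- function(v, g, K) {
    out <- rep(NA_integer_, K)
    o <- order(g, -v)
    first <- !duplicated(g[o])
    out[g[o][first]] <- v[o][first]
    out
}

#' Multiresolution segmentation by pairwise region merging
#'
#' Bottom-up region merging from single-pixel seeds. A merge of regions 1
#' and 2 costs `f = color_weight * dh_color + shape_weight * dh_shape` where
#' `dh_color = sum_l w_l * (n_m * sd_m - n_1 * sd_1 - n_2 * sd_2)` (population
#' standard deviations per weighted layer) and `dh_shape` combines the
#' compactness deviation (`perimeter / sqrt(area)`) and smoothness deviation
#' (`perimeter / bounding-box perimeter`), each multiplied by object size and
#' weighted by the smoothness/compactness weights. Candidate pairs are
#' selected by local mutual best fitting (each merges only with its cheapest
#' neighbour when the choice is reciprocal, ties towards the smaller id) and
#' merges are accepted while `f < scale^2`. The neighbourhood is
#' 4-connected. The result is deterministic for identical inputs.
#'
#' @param stack a [SceneStack-class].
#' @param params a [SegmentationParams-class]; empty `layer_weights` apply
#'   [defaultLayerWeights()].
#' @return a [SegmentLevel-class]; its object table carries mean/sd for every
#'   band and the DSM.
#' @export
multiresolutionSegment <- function(stack, params = segmentationParams()) {
    ok <- validObject(params, test = TRUE)
    if (!isTRUE(ok)) .canopyError("parameter_error", paste(ok, collapse = "; "))
    all_layers <- c(bands(stack), list(DSM = dsm(stack)))
    w <- params@layer_weights
    if (!length(w)) w <- defaultLayerWeights(stack)
    unknown <- setdiff(names(w), names(all_layers))
    if (length(unknown))
        .canopyError("parameter_error", sprintf(
            "layer_weights reference unknown layer(s): %s",
            paste(unknown, collapse = ", ")))
    w <- w[w > 0]
    if (!length(w))
        .canopyError("parameter_error", "at least one layer weight must be positive")
    valid <- !nodataMask(stack)
    res <- cpp_mrs_segment(unname(all_layers[names(w)]), unname(w),
                           params@scale, params@color_weight,
                           params@shape_weight, params@smoothness_weight,
                           params@compactness_weight, valid, 0L)
    K <- length(res$pixel_count)
    objects <- .objectTable(res$labels, all_layers,
                            pixel_count = res$pixel_count,
                            perimeter = res$perimeter, bbox = res$bbox)
    new("SegmentLevel", labels = res$labels, objects = objects,
        edges = res$edges, transform = sceneTransform(stack),
        gsd = gsd(stack))
}

#' Build an upper hierarchy level by grouping base objects
#'
#' Creates a level whose objects are unions of base objects. Base objects
#' appearing in `merge_groups` are fused per group; unassigned base objects
#' carry over as their own upper objects, so the upper level partitions
#' exactly the same pixels as the base level. Upper ids 1..G follow
#' ascending group id, then the carried-over objects in ascending base id.
#' Upper statistics are recomputed from the pixels.
#'
#' @param base a [SegmentLevel-class].
#' @param merge_groups named integer vector: `names` are base object ids,
#'   values the group each belongs to (at most one group per base object).
#' @param stat_layers optional named list of layers for upper-level mean/sd.
#' @return the upper [SegmentLevel-class]; the grouping is recorded in its
#'   `@objects$group_id` column, and [assignParents()] stamps the matching
#'   `parent_id` onto the base level.
#' @export
buildHierarchyLevel <- function(base, merge_groups, stat_layers = list()) {
    ids <- base@objects$id
    gnames <- as.integer(names(merge_groups))
    if (length(merge_groups) && (anyNA(gnames) || !all(gnames %in% ids)))
        .canopyError("key_error", "merge_groups reference unknown base object ids")
    if (anyDuplicated(gnames))
        .canopyError("key_error", "a base object is assigned to more than one group")
    K <- if (length(ids)) max(ids) else 0L
    upper_of_base <- rep(NA_integer_, K)
    groups <- sort(unique(as.integer(merge_groups)))
    upper_of_base[gnames] <- match(as.integer(merge_groups), groups)
    G <- length(groups)
    loose <- setdiff(ids, gnames)
    upper_of_base[loose] <- G + seq_along(loose)
    lut <- c(0L, upper_of_base)  # index by label + 1
    upper_labels <- matrix(lut[base@labels + 1L], nrow(base@labels))
    objects <- .objectTable(upper_labels, stat_layers)
    objects$group_id <- c(groups, rep(NA_integer_, length(loose)))
    new("SegmentLevel", labels = upper_labels, objects = objects,
        edges = .upperEdges(base@edges, upper_of_base),
        transform = base@transform, gsd = base@gsd)
}

.upperEdges <- function(base_edges, upper_of_base) {
    if (!nrow(base_edges)) return(matrix(integer(0), 0, 2))
    a <- upper_of_base[base_edges[, 1]]
    b <- upper_of_base[base_edges[, 2]]
    keep <- !is.na(a) & !is.na(b) & a != b
    e <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
    unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

#' Stamp parent links of an upper level onto its base level
#'
#' @param base the base [SegmentLevel-class].
#' @param merge_groups the grouping passed to [buildHierarchyLevel()].
#' @return `base` with `@objects$parent_id` filled with upper-level ids.
#' @export
assignParents <- function(base, merge_groups) {
    gnames <- as.integer(names(merge_groups))
    groups <- sort(unique(as.integer(merge_groups)))
    G <- length(groups)
    ids <- base@objects$id
    parent <- rep(NA_integer_, length(ids))
    parent[match(gnames, ids)] <- match(as.integer(merge_groups), groups)
    loose <- which(is.na(parent))
    parent[loose] <- G + seq_along(loose)
    base@objects$parent_id <- parent
    base
}
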