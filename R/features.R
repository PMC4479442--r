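#' @include classify.R
NULL

#' Merge tree objects into individual trees or tree-rows
#'
#' Tree-class objects are grouped by spatial connectivity of their pixels
#' (8-connected, so diagonally touching crown pixels belong together) into
#' entities: one upper-level object per isolated tree or per tree-row.
#' Non-tree objects carry over unchanged, so the upper level still
#' partitions all valid pixels. Entities get upper ids 1..n (flagged by the
#' `tree_entity` column); the grouping is also stamped onto a copy of the
#' base level available via [assignParents()].
#'
#' @param level the base [SegmentLevel-class].
#' @param classes the final [ClassMap-class].
#' @return the upper [SegmentLevel-class] with a logical
#'   `tree_entity` column in its object table.
#' @export
mergeTreeEntities <- function(level, classes) {
    labels <- segLabels(level)
    cls <- objectClass(classes)
    ids <- as.integer(names(cls))
    tree_ids <- ids[cls == "tree"]
    obj <- segObjects(level)
    if (!length(tree_ids)) {
        upper <- buildHierarchyLevel(level, stats::setNames(integer(0), character(0)))
        upper@objects$tree_entity <- rep(FALSE, nrow(upper@objects))
        return(upper)
    }
    K <- max(ids)
    tree_lut <- rep(FALSE, K + 1L)
    tree_lut[tree_ids + 1L] <- TRUE
    mask <- matrix(tree_lut[labels + 1L], nrow(labels))
    comp <- cpp_cc_label(mask, 8L)
    # each (4-connected) base object lies inside exactly one 8-connected
    # component; read the component at its first pixel
    first_idx <- match(tree_ids, as.vector(labels))
    groups <- stats::setNames(comp[first_idx], tree_ids)
    upper <- buildHierarchyLevel(level, groups)
    n_ent <- length(unique(as.integer(groups)))
    upper@objects$tree_entity <- seq_len(nrow(upper@objects)) <= n_ent
    upper
}

# Minimum-area oriented bounding rectangle via rotating calipers over the
# convex hull; pts are pixel centres, expanded to pixel corners so a single
# pixel yields a gsd x gsd rectangle.
.minAreaRect <- function(pts, gsd) {
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    g2 <- gsd / 2
    corners <- rbind(
        cbind(hp[, 1] - g2, hp[, 2] - g2), cbind(hp[, 1] - g2, hp[, 2] + g2),
        cbind(hp[, 1] + g2, hp[, 2] - g2), cbind(hp[, 1] + g2, hp[, 2] + g2))
    h2 <- grDevices::chull(corners)
    hp <- corners[h2, , drop = FALSE]
    m <- nrow(hp)
    if (m <= 2) {
        d <- if (m == 2) sqrt(sum((hp[1, ] - hp[2, ])^2)) else 0
        return(c(length = max(d, gsd), width = gsd))
    }
    best <- c(Inf, NA, NA)
    for (i in seq_len(m)) {
        j <- if (i == m) 1L else i + 1L
        e <- hp[j, ] - hp[i, ]
        len <- sqrt(sum(e^2))
        if (len == 0) next
        u <- e / len
        v <- c(-u[2], u[1])
        pu <- hp %*% u
        pv <- hp %*% v
        w1 <- diff(range(pu)); w2 <- diff(range(pv))
        if (w1 * w2 < best[1]) best <- c(w1 * w2, w1, w2)
    }
    c(length = max(best[2], best[3]), width = min(best[2], best[3]))
}

# Best-fit-ellipse axes from the second moments of the pixel centres
# (full axis lengths of the ellipse with equal moments).
.ellipseAxes <- function(pts, gsd) {
    n <- nrow(pts)
    cxx <- stats::var(pts[, 1]) * (n - 1) / n + gsd^2 / 12
    cyy <- stats::var(pts[, 2]) * (n - 1) / n + gsd^2 / 12
    cxy <- if (n > 1) stats::cov(pts[, 1], pts[, 2]) * (n - 1) / n else 0
    tr <- cxx + cyy
    det <- cxx * cyy - cxy^2
    ev <- tr / 2 + c(1, -1) * sqrt(max(tr^2 / 4 - det, 0))
    c(length = 4 * sqrt(max(ev[1], 0)), width = 4 * sqrt(max(ev[2], 0)))
}

#' Geometric features of tree entities
#'
#' For every tree entity: projected area `n_pixels * gsd^2`; height = the
#' maximum pixel height over the entity (crown apex); crown volume = the sum
#' over its pixels of pixel height x pixel area (pixel-integrated, heights
#' above the local bare-soil baseline); position = area centroid in map
#' coordinates; length/width axes = side lengths of the minimum-area
#' oriented bounding rectangle of the footprint (length >= width; best-fit
#' ellipse axes available as an option).
#'
#' @param entities upper [SegmentLevel-class] from [mergeTreeEntities()].
#' @param classes the [ClassMap-class] carrying `pixel_height`.
#' @param ids entity ids to measure; defaults to all `tree_entity` objects.
#' @param axes "rectangle" (default) or "ellipse".
#' @return data.frame with columns `tree_id`, `x`, `y`, `length_axis`,
#'   `width_axis`, `projected_area`, `height`, `volume` (the per-tree output
#'   schema of the pipeline).
#' @export
entityMetrics <- function(entities, classes, ids = NULL,
                          axes = c("rectangle", "ellipse")) {
    axes <- match.arg(axes)
    obj <- segObjects(entities)
    if (is.null(ids)) {
        if (is.null(obj$tree_entity))
            .canopyError("feature_error", "no tree_entity flags; supply ids")
        ids <- obj$id[obj$tree_entity]
    }
    labels <- segLabels(entities)
    ph <- pixelHeight(classes)
    g <- gsd(entities)
    tr <- sceneTransform(entities)
    nr <- nrow(labels)
    rows <- vector("list", length(ids))
    for (k in seq_along(ids)) {
        id <- ids[k]
        o <- obj[obj$id == id, ]
        if (nrow(o) != 1L)
            .canopyError("key_error", sprintf("unknown entity id %s", id))
        win_r <- o$rmin:o$rmax; win_c <- o$cmin:o$cmax
        sub <- labels[win_r, win_c, drop = FALSE]
        idx <- which(sub == id)
        rr <- (idx - 1L) %% length(win_r) + o$rmin
        cc <- (idx - 1L) %/% length(win_r) + o$cmin
        hsub <- ph[win_r, win_c, drop = FALSE][idx]
        if (!any(is.finite(hsub)))
            .canopyError("feature_error",
                         sprintf("entity %d has no pixel height data", id))
        hsub[!is.finite(hsub)] <- 0
        x <- tr[1] + (cc - 0.5) * tr[3]
        y <- tr[2] - (rr - 0.5) * tr[4]
        ax <- if (axes == "rectangle") .minAreaRect(cbind(x, y), g)
              else .ellipseAxes(cbind(x, y), g)
        rows[[k]] <- data.frame(
            tree_id = id, x = mean(x), y = mean(y),
            length_axis = ax[["length"]], width_axis = ax[["width"]],
            projected_area = length(idx) * g^2,
            height = max(hsub), volume = sum(hsub) * g^2)
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(tree_id = integer(0), x = numeric(0), y = numeric(0),
                          length_axis = numeric(0), width_axis = numeric(0),
                          projected_area = numeric(0), height = numeric(0),
                          volume = numeric(0))
    out
}

#' Trace the footprint polygon of an entity
#'
#' Marching-squares contour of the entity mask at level 0.5, in map
#' coordinates; the longest ring is returned.
#'
#' @param entities upper [SegmentLevel-class].
#' @param id entity id.
#' @return 2-column matrix of map x, y (open ring), or NULL for degenerate
#'   footprints.
#' @export
entityFootprint <- function(entities, id) {
    obj <- segObjects(entities)
    o <- obj[obj$id == id, ]
    if (nrow(o) != 1L)
        .canopyError("key_error", sprintf("unknown entity id %s", id))
    labels <- segLabels(entities)
    tr <- sceneTransform(entities)
    win_r <- max(1L, o$rmin - 1L):min(nrow(labels), o$rmax + 1L)
    win_c <- max(1L, o$cmin - 1L):min(ncol(labels), o$cmax + 1L)
    m <- (labels[win_r, win_c, drop = FALSE] == id) * 1
    # contourLines wants increasing axes; flip rows so y increases
    ys <- tr[2] - (rev(win_r) - 0.5) * tr[4]
    xs <- tr[1] + (win_c - 0.5) * tr[3]
    z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])  # z[ix, iy]
    cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
    if (!length(cl)) return(NULL)
    lens <- vapply(cl, function(r) length(r$x), numeric(1))
    ring <- cl[[which.max(lens)]]
    cbind(x = ring$x, y = ring$y)
}

#' Field-level summary of tree records
#'
#' @param records data.frame from [entityMetrics()].
#' @param spacing_hint optional expected planting spacing (m), echoed into
#'   the summary.
#' @return list with `n_trees`, mean/sd of heights, volumes and areas, the
#'   mean nearest-neighbour centroid distance and a `single_sample` flag
#'   (sd reported as 0 when n = 1).
#' @export
summarizeField <- function(records, spacing_hint = NULL) {
    if (is.null(records) || nrow(records) == 0L)
        .canopyError("empty_summary_error", "no tree records to summarise")
    n <- nrow(records)
    sd0 <- function(v) if (n > 1L) stats::sd(v) else 0
    nn <- NA_real_
    if (n > 1L) {
        d <- as.matrix(stats::dist(records[, c("x", "y")]))
        diag(d) <- Inf
        nn <- mean(apply(d, 1, min))
    }
    list(n_trees = n,
         height_mean = mean(records$height), height_sd = sd0(records$height),
         volume_mean = mean(records$volume), volume_sd = sd0(records$volume),
         area_mean = mean(records$projected_area),
         area_sd = sd0(records$projected_area),
         mean_nn_spacing = nn,
         spacing_hint = spacing_hint,
         single_sample = n == 1L)
}
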