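#' @include validation.R
NULL

.DEFAULT_SPECTRA <- list(
    visible = list(
        soil = c(R = 150, G = 130, B = 105),
        canopy = c(R = 70, G = 110, B = 60),
        grass = c(R = 95, G = 135, B = 70)),
    multispectral = list(
        soil = c(R = 150, G = 130, B = 105, NIR = 120),
        canopy = c(R = 60, G = 90, B = 50, NIR = 200),
        grass = c(R = 90, G = 120, B = 65, NIR = 170)))

#' Configure a synthetic orchard scene
#'
#' See [OrchardConfig-class] for the slot meanings. Defaults describe a
#' gently sloping olive-like plantation: 2 % terrain slope, 0.15 m smooth
#' undulation, crowns of 1.5-2.5 m semi-axes and 2-4 m height, 5 % grass
#' cover up to 0.3 m tall, 8-bit spectra with 5 DN additive Gaussian noise.
#'
#' @param pattern "single_tree" or "tree_row".
#' @param spacing numeric(2) metres; for rows: (between-row, in-row).
#' @param n_rows,n_cols tree-grid dimensions.
#' @param gsd ground sample distance (m).
#' @param sensor_kind "visible" or "multispectral".
#' @param rx_range,ry_range,height_range crown geometry ranges (m).
#' @param gap_fraction fraction of crown pixels removed as random gaps.
#' @param slope,undulation_amp,undulation_wavelength terrain shape.
#' @param grass_fraction,grass_height herbaceous cover parameters.
#' @param soil_mean,canopy_mean,grass_mean named per-band mean DN; defaults
#'   depend on `sensor_kind`.
#' @param noise_sd additive sensor noise sigma (DN).
#' @param margin scene margin around the grid (m).
#' @param origin map coordinates of the lower-left corner.
#' @param crs_id CRS identifier stamped on outputs.
#' @param seed integer seed (mandatory for reproducibility).
#' @return an [OrchardConfig-class].
#' @export
orchardConfig <- function(pattern = "single_tree", spacing = c(7, 7),
                          n_rows = 5L, n_cols = 5L, gsd = 0.0271,
                          sensor_kind = "multispectral",
                          rx_range = c(1.5, 2.5), ry_range = c(1.5, 2.5),
                          height_range = c(2, 4), gap_fraction = 0,
                          slope = 0.02, undulation_amp = 0.15,
                          undulation_wavelength = 40,
                          grass_fraction = 0.05, grass_height = 0.3,
                          soil_mean = NULL, canopy_mean = NULL,
                          grass_mean = NULL, noise_sd = 5, margin = 2.5,
                          origin = c(367000, 4205000),
                          crs_id = "EPSG:32630", seed = 1L) {
    sp <- .DEFAULT_SPECTRA[[sensor_kind]]
    if (is.null(soil_mean)) soil_mean <- sp$soil
    if (is.null(canopy_mean)) canopy_mean <- sp$canopy
    if (is.null(grass_mean)) grass_mean <- sp$grass
    cfg <- tryCatch(
        new("OrchardConfig", pattern = pattern, spacing = spacing,
               n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               rx_range = rx_range, ry_range = ry_range,
               height_range = height_range, gap_fraction = gap_fraction,
               slope = slope, undulation_amp = undulation_amp,
               undulation_wavelength = undulation_wavelength,
               grass_fraction = grass_fraction, grass_height = grass_height,
               sensor_kind = sensor_kind, gsd = gsd, soil_mean = soil_mean,
               canopy_mean = canopy_mean, grass_mean = grass_mean,
            noise_sd = noise_sd, margin = margin, origin = origin,
            crs_id = crs_id, seed = as.integer(seed)),
        error = function(e) .canopyError("config_error", conditionMessage(e)))
    cfg
}

#' Preset orchard scenes
#'
#' Four presets mirroring common plantation layouts and flight setups:
#' \describe{
#'   \item{fieldA}{single trees at 7 x 7 m, visible-light sensor,
#'     gsd 0.0153 m, 5 x 5 grid.}
#'   \item{fieldB}{single trees at 8 x 8 m, multispectral sensor,
#'     gsd 0.0271 m, 10 x 10 grid.}
#'   \item{fieldC}{tree-rows at 3.75 x 1.3 m (crowns touch along the row),
#'     visible-light, gsd 0.0153 m, 5 rows of 10.}
#'   \item{fieldD}{tree-rows at 8 x 4 m, visible-light, gsd 0.0306 m,
#'     5 rows of 8.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [orchardConfig()].
#' @return an [OrchardConfig-class].
#' @export
orchardPreset <- function(name = c("fieldA", "fieldB", "fieldC", "fieldD"),
                          seed = 1L, ...) {
    name <- match.arg(name)
    args <- switch(name,
        fieldA = list(pattern = "single_tree", spacing = c(7, 7),
                      n_rows = 5L, n_cols = 5L, gsd = 0.0153,
                      sensor_kind = "visible"),
        fieldB = list(pattern = "single_tree", spacing = c(8, 8),
                      n_rows = 10L, n_cols = 10L, gsd = 0.0271,
                      sensor_kind = "multispectral"),
        fieldC = list(pattern = "tree_row", spacing = c(3.75, 1.3),
                      n_rows = 5L, n_cols = 10L, gsd = 0.0153,
                      sensor_kind = "visible",
                      rx_range = c(1.0, 1.5), ry_range = c(0.8, 1.2),
                      height_range = c(1.5, 3)),
        fieldD = list(pattern = "tree_row", spacing = c(8, 4),
                      n_rows = 5L, n_cols = 8L, gsd = 0.0306,
                      sensor_kind = "visible",
                      rx_range = c(1.5, 2.5), ry_range = c(1.8, 2.4),
                      height_range = c(2, 4)))
    over <- list(...)
    args[names(over)] <- over
    args$seed <- seed
    do.call(orchardConfig, args)
}

#' Generate a synthetic orchard scene with analytic ground truth
#'
#' Builds a georeferenced scene the pipeline can consume end to end:
#' terrain as a plane plus smooth sinusoidal undulation; each tree a
#' half-ellipsoid crown resting on the terrain
#' (`DSM = terrain + h * sqrt(1 - (dx/rx)^2 - (dy/ry)^2)` inside the
#' footprint, optionally with random crown gaps); low grass patches with
#' vegetation-like spectra; per-band class means with additive Gaussian
#' sensor noise, quantised to 8-bit digital numbers. The same config and
#' seed give bit-identical outputs; the RNG state of the caller is
#' preserved.
#'
#' @param config an [OrchardConfig-class].
#' @return list with `scene` (a [SceneStack-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
generateOrchard <- function(config) {
    ok <- validObject(config, test = TRUE)
    if (!isTRUE(ok)) .canopyError("config_error", paste(ok, collapse = "; "))
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(config@seed)

    g <- config@gsd
    sx <- config@spacing[1]; sy <- config@spacing[2]
    W <- 2 * config@margin + config@n_cols * sx
    H <- 2 * config@margin + config@n_rows * sy
    if (identical(config@pattern, "tree_row")) {
        W <- 2 * config@margin + config@n_rows * sx
        H <- 2 * config@margin + config@n_cols * sy
    }
    nc <- as.integer(ceiling(W / g)); nr <- as.integer(ceiling(H / g))
    xmin <- config@origin[1]; ymin <- config@origin[2]
    ymax <- ymin + nr * g
    transform <- c(xmin, ymax, g, g)
    xs <- xmin + (seq_len(nc) - 0.5) * g          # by column
    ys <- ymax - (seq_len(nr) - 0.5) * g          # by row (north-down)

    # tree centres
    if (identical(config@pattern, "single_tree")) {
        cx <- xmin + config@margin + (seq_len(config@n_cols) - 0.5) * sx
        cy <- ymin + config@margin + (seq_len(config@n_rows) - 0.5) * sy
        centres <- expand.grid(x = cx, y = cy)
        row_id <- rep(seq_len(config@n_rows), each = config@n_cols)
    } else {
        cx <- xmin + config@margin + (seq_len(config@n_rows) - 0.5) * sx
        cy <- ymin + config@margin + (seq_len(config@n_cols) - 0.5) * sy
        centres <- expand.grid(y = cy, x = cx)[, c("x", "y")]
        row_id <- rep(seq_len(config@n_rows), each = config@n_cols)
    }
    nt <- nrow(centres)
    trees <- data.frame(
        tree_id = seq_len(nt), x = centres$x, y = centres$y,
        rx = stats::runif(nt, config@rx_range[1], config@rx_range[2]),
        ry = stats::runif(nt, config@ry_range[1], config@ry_range[2]),
        h = stats::runif(nt, config@height_range[1], config@height_range[2]),
        row_id = row_id)
    trees$true_area <- pi * trees$rx * trees$ry
    trees$true_volume <- 2 / 3 * pi * trees$rx * trees$ry * trees$h

    # terrain: plane + smooth low-frequency undulation
    lam <- config@undulation_wavelength
    base_elev <- 100
    terrain <- outer(ys, xs, function(y, x)
        base_elev + config@slope * (x - xmin) +
            config@undulation_amp * sin(2 * pi * (x - xmin) / lam) *
            sin(2 * pi * (y - ymin) / lam))

    crown <- matrix(0, nr, nc)        # crown height above terrain
    class_mask <- matrix(0L, nr, nc)  # 0 soil, 1 grass, 2 tree
    for (i in seq_len(nt)) {
        rx <- trees$rx[i]; ry <- trees$ry[i]
        c0 <- max(1L, floor((trees$x[i] - rx - xmin) / g) + 1L)
        c1 <- min(nc, ceiling((trees$x[i] + rx - xmin) / g))
        r0 <- max(1L, floor((ymax - trees$y[i] - ry) / g) + 1L)
        r1 <- min(nr, ceiling((ymax - trees$y[i] + ry) / g))
        if (c1 < c0 || r1 < r0) next
        dx <- (xs[c0:c1] - trees$x[i]) / rx
        dy <- (ys[r0:r1] - trees$y[i]) / ry
        s <- 1 - outer(dy^2, dx^2, `+`)
        inside <- s > 0
        if (config@gap_fraction > 0) {
            gaps <- matrix(stats::runif(length(s)) < config@gap_fraction,
                           nrow(s))
            inside <- inside & !gaps
        }
        ch <- matrix(0, nrow(s), ncol(s))
        ch[inside] <- trees$h[i] * sqrt(s[inside])
        win <- crown[r0:r1, c0:c1]
        crown[r0:r1, c0:c1] <- pmax(win, ch)
        cm <- class_mask[r0:r1, c0:c1]
        cm[inside] <- 2L
        class_mask[r0:r1, c0:c1] <- cm
    }

    # grass patches on soil
    if (config@grass_fraction > 0) {
        patch_r <- c(0.5, 1.5)
        mean_area <- pi * mean(patch_r)^2
        n_patch <- max(0L, round(config@grass_fraction * W * H / mean_area))
        for (p in seq_len(n_patch)) {
            px <- stats::runif(1, xmin, xmin + W)
            py <- stats::runif(1, ymin, ymin + H)
            pr <- stats::runif(1, patch_r[1], patch_r[2])
            # keep grass off the crowns so classes stay unambiguous
            dmin <- min(sqrt((trees$x - px)^2 + (trees$y - py)^2) -
                        pmax(trees$rx, trees$ry))
            if (is.finite(dmin) && dmin < pr) next
            c0 <- max(1L, floor((px - pr - xmin) / g) + 1L)
            c1 <- min(nc, ceiling((px + pr - xmin) / g))
            r0 <- max(1L, floor((ymax - py - pr) / g) + 1L)
            r1 <- min(nr, ceiling((ymax - py + pr) / g))
            if (c1 < c0 || r1 < r0) next
            dx <- xs[c0:c1] - px
            dy <- ys[r0:r1] - py
            s <- 1 - outer(dy^2, dx^2, `+`) / pr^2
            inside <- s > 0
            gh <- matrix(0, nrow(s), ncol(s))
            gh[inside] <- config@grass_height * sqrt(s[inside])
            win <- crown[r0:r1, c0:c1]
            upd <- inside & win == 0
            win[upd] <- gh[upd]
            crown[r0:r1, c0:c1] <- win
            cm <- class_mask[r0:r1, c0:c1]
            cm[upd] <- 1L
            class_mask[r0:r1, c0:c1] <- cm
        }
    }

    dsm_m <- terrain + crown

    band_names <- names(config@canopy_mean)
    bands <- vector("list", length(band_names))
    names(bands) <- band_names
    for (b in band_names) {
        mu <- matrix(config@soil_mean[[b]], nr, nc)
        mu[class_mask == 1L] <- config@grass_mean[[b]]
        mu[class_mask == 2L] <- config@canopy_mean[[b]]
        v <- mu + stats::rnorm(nr * nc, 0, config@noise_sd)
        bands[[b]] <- matrix(pmin(pmax(round(v), 0), 255), nr, nc)
    }

    scene <- SceneStack(bands = bands, dsm = dsm_m, transform = transform,
                        sensor_kind = config@sensor_kind,
                        crs_id = config@crs_id,
                        nodata_mask = matrix(FALSE, nr, nc))
    truth <- new("GroundTruth", trees = trees, class_mask = class_mask,
                 terrain = terrain, transform = transform, gsd = g,
                 crs_id = config@crs_id)
    list(scene = scene, truth = truth)
}

#' Rasterize ground truth into reference masks and a reference table
#'
#' Stands in for a manual delineation of every crown: a boolean tree mask on
#' the scene grid plus per-tree reference records built from the analytic
#' crown parameters (`length_axis = 2 * max(rx, ry)`,
#' `width_axis = 2 * min(rx, ry)`, `projected_area = pi * rx * ry`,
#' `volume = (2/3) * pi * rx * ry * h`).
#'
#' @param truth a [GroundTruth-class].
#' @return list with `tree_mask` (logical matrix) and `records`
#'   (data.frame in the per-tree output schema).
#' @export
rasterizeTruth <- function(truth) {
    tt <- truthTrees(truth)
    records <- data.frame(
        tree_id = tt$tree_id, x = tt$x, y = tt$y,
        length_axis = 2 * pmax(tt$rx, tt$ry),
        width_axis = 2 * pmin(tt$rx, tt$ry),
        projected_area = tt$true_area, height = tt$h,
        volume = tt$true_volume)
    list(tree_mask = classMask(truth) == 2L, records = records)
}

#' Write a generated scene and its truth artefacts to disk
#'
#' Writes the orthomosaic and DSM rasters, the truth class-mask raster, the
#' reference tree table (CSV) and the truth footprints (GeoJSON, analytic
#' ellipse rings).
#'
#' @param orchard list from [generateOrchard()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
writeOrchard <- function(orchard, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    scene <- orchard$scene; truth <- orchard$truth
    paths <- c(ortho = file.path(out_dir, "ortho.tif"),
               dsm = file.path(out_dir, "dsm.tif"),
               mask = file.path(out_dir, "truth_mask.tif"),
               table = file.path(out_dir, "truth_trees.csv"),
               footprints = file.path(out_dir, "truth_footprints.geojson"))
    writeScene(scene, paths[["ortho"]], paths[["dsm"]])
    rt <- rasterizeTruth(truth)
    .writeRaster(paths[["mask"]], list(tree_mask = rt$tree_mask * 1),
                 sceneTransform(truth), truth@crs_id, NULL, dtypes = "uint8")
    utils::write.csv(rt$records, paths[["table"]], row.names = FALSE)
    tt <- truthTrees(truth)
    polys <- lapply(seq_len(nrow(tt)), function(i) {
        a <- seq(0, 2 * pi, length.out = 33)[-33]
        cbind(tt$x[i] + tt$rx[i] * cos(a), tt$y[i] + tt$ry[i] * sin(a))
    })
    names(polys) <- tt$tree_id
    writeEntities(rt$records, polys, paths[["footprints"]],
                  file.path(out_dir, "truth_trees_attrs.csv"),
                  crs_id = truth@crs_id)
    paths
}
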