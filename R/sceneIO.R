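#' @include AllGenerics.R
NULL

# Structured error conditions so callers/tests can match on failure kind.
.canopyError <- function(subclass, msg) {
    stop(errorCondition(msg, class = c(subclass, "canopyOBIA_error", "error")))
}

# --- raster container on disk -------------------------------------------
#
# Rasters are stored as TIFF pixel data plus two plain-text sidecars:
#  * an ESRI world file (.tfw) carrying the affine georeference, and
#  * a JSON sidecar (<path>.aux.json) carrying CRS id, layer names, per-layer
#    dtype ("uint8" or "float") and encoding range.
# All samples are written as 32-bit scaled values in [0, 1]; a trailing
# validity band marks nodata pixels. Per-layer min/max in the sidecar map
# the [0.05, 1] sample range back to physical units, which keeps float
# round-trip error far below 1e-6 for any realistic elevation range, and
# "uint8" layers are rounded back to exact digital numbers on read.

.worldFilePath <- function(path) {
    sub("\\.[^.]+$", ".tfw", path)
}

.writeWorldFile <- function(path, transform) {
    xres <- transform[3]; yres <- transform[4]
    lines <- formatC(c(xres, 0, 0, -yres,
                       transform[1] + 0.5 * xres,
                       transform[2] - 0.5 * yres),
                     format = "f", digits = 10)
    writeLines(lines, .worldFilePath(path))
}

.readWorldFile <- function(path, nr, nc) {
    wf <- .worldFilePath(path)
    if (!file.exists(wf)) return(NULL)
    v <- as.numeric(readLines(wf, n = 6))
    xres <- v[1]; yres <- -v[4]
    c(xmin = v[5] - 0.5 * xres, ymax = v[6] + 0.5 * yres,
      xres = xres, yres = yres)
}

.ENC_LO <- 0.05  # encoded value of the per-layer minimum; 0 is reserved

.writeRaster <- function(path, layers, transform, crs_id, valid,
                         dtypes = NULL) {
    nms <- names(layers)
    if (is.null(nms) || any(!nzchar(nms)))
        .canopyError("schema_error", "raster layers must be named")
    nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
    if (is.null(valid)) valid <- matrix(TRUE, nr, nc)
    if (is.null(dtypes)) {
        dtypes <- vapply(layers, function(m) {
            v <- m[valid]
            if (length(v) && all(is.finite(v)) && all(v >= 0 & v <= 255) &&
                all(v == round(v))) "uint8" else "float"
        }, character(1))
    }
    L <- length(layers)
    # one TIFF directory (grayscale plane) per layer, plus a validity plane
    planes <- vector("list", L + 1L)
    meta <- vector("list", L)
    for (l in seq_len(L)) {
        m <- layers[[l]]
        v <- m[valid]
        if (identical(dtypes[[l]], "uint8")) {
            lo <- 0; hi <- 255
        } else {
            lo <- if (length(v)) min(v) else 0
            hi <- if (length(v)) max(v) else 1
            if (hi <= lo) hi <- lo + 1
        }
        enc <- .ENC_LO + (1 - .ENC_LO) * (m - lo) / (hi - lo)
        enc[!valid | !is.finite(enc)] <- 0
        planes[[l]] <- enc
        meta[[l]] <- list(name = nms[l], dtype = dtypes[[l]],
                          min = lo, max = hi)
    }
    planes[[L + 1L]] <- valid * 1
    tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
    .writeWorldFile(path, transform)
    jsonlite::write_json(
        list(format = "canopyOBIA-raster-1", crs = crs_id,
             valid_band = TRUE, layers = meta),
        paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

.readRaster <- function(path, band_names = NULL) {
    if (!file.exists(path))
        .canopyError("io_error", sprintf("raster not found: %s", path))
    planes <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(planes)) planes <- list(planes)
    # single-directory multi-plane files from elsewhere: split the planes
    if (length(planes) == 1L && length(dim(planes[[1]])) == 3L) {
        a <- planes[[1]]
        planes <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    }
    planes <- lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    nr <- nrow(planes[[1]]); nc <- ncol(planes[[1]]); nb <- length(planes)
    aux_path <- paste0(path, ".aux.json")
    crs <- "LOCAL"
    layers <- list()
    valid <- matrix(TRUE, nr, nc)
    if (file.exists(aux_path)) {
        aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
        crs <- aux$crs
        meta <- aux$layers
        if (isTRUE(aux$valid_band)) {
            valid <- planes[[nb]] > 0.5
            nb <- nb - 1L
        }
        if (nrow(meta) != nb)
            .canopyError("schema_error", sprintf(
                "sidecar describes %d layers but %s has %d", nrow(meta), path, nb))
        for (l in seq_len(nb)) {
            lo <- meta$min[l]; hi <- meta$max[l]
            m <- lo + (planes[[l]] - .ENC_LO) / (1 - .ENC_LO) * (hi - lo)
            if (identical(meta$dtype[l], "uint8")) m <- round(m)
            m[!valid] <- NA_real_
            layers[[meta$name[l]]] <- m
        }
    } else {
        # plain TIFF from elsewhere: values as normalised by the reader
        if (is.null(band_names)) band_names <- paste0("band", seq_len(nb))
        if (length(band_names) != nb)
            .canopyError("schema_error", sprintf(
                "%d band names supplied for %d bands in %s",
                length(band_names), nb, path))
        for (l in seq_len(nb)) layers[[band_names[l]]] <- planes[[l]]
    }
    tr <- .readWorldFile(path, nr, nc)
    if (is.null(tr)) tr <- c(xmin = 0, ymax = nr, xres = 1, yres = 1)
    list(layers = layers, transform = unname(tr), crs = crs, valid = valid)
}

.isGeographicCRS <- function(crs_id) {
    grepl("4326|4269|4258|longlat|latlong|degree|CRS84", crs_id,
          ignore.case = TRUE)
}

# --- public API ----------------------------------------------------------

#' Construct a SceneStack in memory
#'
#' @param bands named list of numeric band matrices.
#' @param dsm numeric matrix of surface elevation (m).
#' @param transform numeric(4) `c(xmin, ymax, xres, yres)` in map metres.
#' @param sensor_kind "visible" or "multispectral".
#' @param crs_id planar CRS identifier.
#' @param nodata_mask logical matrix (TRUE = nodata); defaults to pixels
#'   where any layer is non-finite.
#' @return a [SceneStack-class].
#' @export
SceneStack <- function(bands, dsm, transform, sensor_kind,
                       crs_id = "LOCAL", nodata_mask = NULL) {
    if (is.null(nodata_mask)) {
        nodata_mask <- !is.finite(dsm)
        for (b in bands) nodata_mask <- nodata_mask | !is.finite(b)
    }
    xres <- transform[3]; yres <- transform[4]
    if (abs(xres - yres) > 1e-6 * xres)
        .canopyError("alignment_error", "non-square pixels are not supported")
    new("SceneStack", bands = bands, dsm = dsm,
        transform = as.numeric(transform), crs_id = crs_id,
        gsd = as.numeric(xres), nodata_mask = nodata_mask,
        sensor_kind = sensor_kind)
}

#' Load an orthomosaic + DSM raster pair into a SceneStack
#'
#' Reads the orthomosaic and the DSM (either a separate raster or a named
#' band of a combined multi-layer file), verifies that they share one grid
#' within half a pixel, and propagates nodata as the union of the per-layer
#' nodata. Georeferencing comes from world files / sidecars written by
#' [writeScene()] (or any ESRI world file).
#'
#' @param ortho_path path to the orthomosaic raster.
#' @param dsm_path path to the DSM raster; omit when the DSM travels as a
#'   band of `ortho_path`.
#' @param sensor_kind "visible" (needs R, G, B) or "multispectral" (needs at
#'   least R and NIR).
#' @param band_names ordered band names, required for rasters without a
#'   sidecar.
#' @param dsm_band name of the DSM layer inside `ortho_path` (default "DSM")
#'   when `dsm_path` is not given.
#' @return a [SceneStack-class].
#' @export
loadScene <- function(ortho_path, dsm_path = NULL, sensor_kind,
                      band_names = NULL, dsm_band = "DSM") {
    ortho <- .readRaster(ortho_path, band_names)
    if (!is.null(dsm_path)) {
        dsmr <- .readRaster(dsm_path, "DSM")
        dims_o <- dim(ortho$layers[[1]])
        dims_d <- dim(dsmr$layers[[1]])
        if (!identical(dims_o, dims_d))
            .canopyError("alignment_error", sprintf(
                "orthomosaic is %d x %d px but DSM is %d x %d px",
                dims_o[1], dims_o[2], dims_d[1], dims_d[2]))
        to <- ortho$transform; td <- dsmr$transform
        half_px <- 0.5 * to[3]
        if (any(abs(to[1:2] - td[1:2]) > half_px) ||
            any(abs(to[3:4] - td[3:4]) > 1e-6 * to[3]))
            .canopyError("alignment_error",
                         "orthomosaic and DSM transforms disagree beyond half a pixel")
        dsm_m <- dsmr$layers[[1]]
        valid <- ortho$valid & dsmr$valid
        band_layers <- ortho$layers
    } else {
        if (!dsm_band %in% names(ortho$layers))
            .canopyError("schema_error", sprintf(
                "no '%s' layer in the combined multi-layer file", dsm_band))
        dsm_m <- ortho$layers[[dsm_band]]
        band_layers <- ortho$layers[setdiff(names(ortho$layers), dsm_band)]
        valid <- ortho$valid
    }
    if (.isGeographicCRS(ortho$crs))
        .canopyError("unit_error", sprintf(
            "CRS '%s' appears geographic (degrees); a planar CRS in metres is required",
            ortho$crs))
    need <- if (identical(sensor_kind, "visible")) c("R", "G", "B") else c("R", "NIR")
    miss <- setdiff(need, names(band_layers))
    if (length(miss))
        .canopyError("schema_error", sprintf(
            "sensor_kind '%s' requires band(s) %s; have: %s", sensor_kind,
            paste(miss, collapse = ", "), paste(names(band_layers), collapse = ", ")))
    for (nm in names(band_layers)) {
        valid <- valid & is.finite(band_layers[[nm]])
        band_layers[[nm]][!valid] <- NA_real_
    }
    valid <- valid & is.finite(dsm_m)
    dsm_m[!valid] <- NA_real_
    # DSM must be finite where valid; fill nodata with 0 for slot validity
    dsm_fill <- dsm_m
    dsm_fill[!valid] <- 0
    SceneStack(bands = band_layers, dsm = dsm_fill,
               transform = ortho$transform, sensor_kind = sensor_kind,
               crs_id = ortho$crs, nodata_mask = !valid)
}

#' Write a SceneStack to an orthomosaic + DSM raster pair
#'
#' @param scene a [SceneStack-class].
#' @param ortho_path,dsm_path output raster paths (TIFF; world file and JSON
#'   sidecar are written next to each).
#' @param combined when TRUE, write a single multi-layer file at
#'   `ortho_path` with the DSM as an extra "DSM" layer.
#' @return the paths written, invisibly.
#' @export
writeScene <- function(scene, ortho_path, dsm_path = NULL, combined = FALSE) {
    valid <- !scene@nodata_mask
    if (combined) {
        layers <- c(scene@bands, list(DSM = scene@dsm))
        .writeRaster(ortho_path, layers, scene@transform, scene@crs_id, valid)
        return(invisible(ortho_path))
    }
    if (is.null(dsm_path))
        .canopyError("io_error", "dsm_path is required unless combined = TRUE")
    .writeRaster(ortho_path, scene@bands, scene@transform, scene@crs_id, valid)
    .writeRaster(dsm_path, list(DSM = scene@dsm), scene@transform,
                 scene@crs_id, valid, dtypes = "float")
    invisible(c(ortho_path, dsm_path))
}

#' Export a single-layer raster (index, labels or pixel heights)
#'
#' @param values numeric or integer matrix.
#' @param path output TIFF path.
#' @param transform,crs_id georeference.
#' @param name layer name recorded in the sidecar.
#' @export
writeLayer <- function(values, path, transform, crs_id = "LOCAL",
                       name = "layer") {
    storage.mode(values) <- "double"
    l <- stats::setNames(list(values), name)
    .writeRaster(path, l, transform, crs_id, is.finite(values),
                 dtypes = "float")
    invisible(path)
}

# Table 5 style column set of the per-entity output table.
.RECORD_COLS <- c("tree_id", "x", "y", "length_axis", "width_axis",
                  "projected_area", "height", "volume")

#' Export tree entities as a GeoJSON vector plus a CSV table
#'
#' Writes one GeoJSON feature per entity carrying all record attributes and
#' its footprint polygon, and a CSV with the per-tree output schema
#' (id, position, canopy axes, projected area, height, volume).
#'
#' @param records data.frame of tree records (see [entityMetrics()]).
#' @param polygons named list (by `tree_id`) of footprint rings: 2-column
#'   matrices of map x, y. Entities without a polygon get a point footprint
#'   at their centroid.
#' @param vector_path GeoJSON output path.
#' @param table_path CSV output path.
#' @param crs_id CRS identifier recorded in the GeoJSON.
#' @return invisibly, the paths written.
#' @export
writeEntities <- function(records, polygons = list(), vector_path,
                          table_path, crs_id = "LOCAL") {
    if (is.null(records) || !is.data.frame(records))
        .canopyError("schema_error", "records must be a data.frame")
    miss <- setdiff(.RECORD_COLS, names(records))
    if (length(miss))
        .canopyError("schema_error", sprintf("records lack column(s): %s",
                                             paste(miss, collapse = ", ")))
    feats <- lapply(seq_len(nrow(records)), function(i) {
        rec <- records[i, .RECORD_COLS]
        id <- rec$tree_id
        ring <- polygons[[as.character(id)]]
        geom <- if (!is.null(ring) && nrow(ring) >= 3) {
            ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
            list(type = "Polygon",
                 coordinates = list(lapply(seq_len(nrow(ring)), function(k)
                     c(ring[k, 1], ring[k, 2]))))
        } else {
            list(type = "Point", coordinates = c(rec$x, rec$y))
        }
        list(type = "Feature", id = id,
             properties = as.list(rec), geometry = geom)
    })
    gj <- list(type = "FeatureCollection",
               crs = list(type = "name",
                          properties = list(name = crs_id)),
               features = feats)
    ok <- tryCatch(suppressWarnings({
        jsonlite::write_json(gj, vector_path, auto_unbox = TRUE, digits = NA)
        utils::write.csv(records[, .RECORD_COLS, drop = FALSE], table_path,
                         row.names = FALSE)
        TRUE
    }), error = function(e) e)
    if (!isTRUE(ok))
        .canopyError("io_error", sprintf("failed to write entities: %s",
                                         conditionMessage(ok)))
    invisible(c(vector_path, table_path))
}

#' Read back an entity GeoJSON written by [writeEntities()]
#'
#' @param vector_path GeoJSON path.
#' @return list with `records` (data.frame) and `polygons` (named list).
#' @export
readEntities <- function(vector_path) {
    gj <- jsonlite::read_json(vector_path)
    feats <- gj$features
    if (length(feats) == 0L) {
        rec <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                                 length(.RECORD_COLS)),
                                             .RECORD_COLS))
        return(list(records = rec, polygons = list()))
    }
    rows <- lapply(feats, function(f) as.data.frame(f$properties))
    records <- do.call(rbind, rows)
    polygons <- list()
    for (f in feats) {
        if (identical(f$geometry$type, "Polygon")) {
            ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                          function(p) c(p[[1]], p[[2]])))
            polygons[[as.character(f$id)]] <- ring
        }
    }
    list(records = records, polygons = polygons)
}
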