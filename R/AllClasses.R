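#' @useDynLib canopyOBIA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' SceneStack: co-registered UAV orthomosaic bands plus a surface model
#'
#' Container for the raster inputs of the delineation pipeline: the named
#' spectral bands of the orthomosaic, the digital surface model (DSM, metres),
#' a shared axis-aligned georeference and a union nodata mask. The transform
#' is `c(xmin, ymax, xres, yres)` in map metres: pixel (row, col) has its
#' centre at `x = xmin + (col - 0.5) * xres`, `y = ymax - (row - 0.5) * yres`.
#'
#' @slot bands named list of numeric matrices (digital numbers 0-255 or
#'   reflectance 0-1), all with identical dimensions.
#' @slot dsm numeric matrix of surface elevation in metres.
#' @slot transform numeric(4): xmin, ymax, xres, yres (map metres).
#' @slot crs_id character, planar CRS identifier (e.g. "EPSG:32630").
#' @slot gsd numeric, ground sample distance in m/pixel.
#' @slot nodata_mask logical matrix, TRUE where any layer has no data.
#' @slot sensor_kind "visible" (requires R, G, B) or "multispectral"
#'   (requires at least R and NIR).
#' @export
setClass("SceneStack",
    representation(bands = "list", dsm = "matrix", transform = "numeric",
                   crs_id = "character", gsd = "numeric",
                   nodata_mask = "matrix", sensor_kind = "character"))

setValidity("SceneStack", function(object) {
    msgs <- character()
    d <- dim(object@dsm)
    if (length(object@bands) == 0L)
        msgs <- c(msgs, "at least one band is required")
    if (is.null(names(object@bands)) || any(!nzchar(names(object@bands))))
        msgs <- c(msgs, "bands must be named")
    for (nm in names(object@bands))
        if (!identical(dim(object@bands[[nm]]), d))
            msgs <- c(msgs, sprintf("band '%s' dimensions differ from DSM", nm))
    if (!identical(dim(object@nodata_mask), d))
        msgs <- c(msgs, "nodata_mask dimensions differ from DSM")
    if (length(object@gsd) != 1L || !is.finite(object@gsd) || object@gsd <= 0)
        msgs <- c(msgs, "gsd must be a single positive number")
    if (length(object@transform) != 4L || any(!is.finite(object@transform)) ||
        object@transform[3] <= 0 || object@transform[4] <= 0)
        msgs <- c(msgs, "transform must be c(xmin, ymax, xres, yres) with positive resolutions")
    if (!object@sensor_kind %in% c("visible", "multispectral"))
        msgs <- c(msgs, "sensor_kind must be 'visible' or 'multispectral'")
    need <- if (identical(object@sensor_kind, "visible")) c("R", "G", "B") else c("R", "NIR")
    miss <- setdiff(need, names(object@bands))
    if (length(miss))
        msgs <- c(msgs, sprintf("sensor_kind '%s' requires band(s): %s",
                                object@sensor_kind, paste(miss, collapse = ", ")))
    if (any(!is.finite(object@dsm[!object@nodata_mask])))
        msgs <- c(msgs, "dsm must be finite wherever nodata_mask is FALSE")
    if (length(msgs)) msgs else TRUE
})

#' IndexLayer: a per-pixel vegetation index
#'
#' @slot values numeric matrix of index values.
#' @slot index_kind "ExG" or "NDVI".
#' @slot nodata_mask logical matrix, TRUE where the index is undefined.
#' @export
setClass("IndexLayer",
    representation(values = "matrix", index_kind = "character",
                   nodata_mask = "matrix"))

setValidity("IndexLayer", function(object) {
    msgs <- character()
    if (!object@index_kind %in% c("ExG", "NDVI"))
        msgs <- c(msgs, "index_kind must be 'ExG' or 'NDVI'")
    if (!identical(dim(object@values), dim(object@nodata_mask)))
        msgs <- c(msgs, "values and nodata_mask dimensions differ")
    v <- object@values[!object@nodata_mask]
    v <- v[is.finite(v)]
    lo <- if (identical(object@index_kind, "NDVI")) -1 else -1
    hi <- if (identical(object@index_kind, "NDVI")) 1 else 2
    if (length(v) && (min(v) < lo - 1e-9 || max(v) > hi + 1e-9))
        msgs <- c(msgs, sprintf("%s values outside [%g, %g]", object@index_kind, lo, hi))
    if (length(msgs)) msgs else TRUE
})

#' SegmentationParams: multiresolution segmentation parameters
#'
#' Defaults follow common practice for orchard scenes at 2-4 cm GSD:
#' colour/shape 0.6/0.4, smoothness 0.5, compactness 0.05, scale 20 in
#' weighted-layer digital-number units. `layer_weights` may be empty, in
#' which case [defaultLayerWeights()] is applied at segmentation time
#' (DSM and Green for visible sensors, DSM and NIR for multispectral).
#'
#' @slot scale positive merge-threshold scale parameter.
#' @slot color_weight,shape_weight colour/shape mixing, must sum to 1.
#' @slot smoothness_weight,compactness_weight relative weights of the two
#'   shape terms (used exactly as given, not renormalised).
#' @slot layer_weights named numeric, weight per layer ("DSM" plus band names).
#' @export
setClass("SegmentationParams",
    representation(scale = "numeric", color_weight = "numeric",
                   shape_weight = "numeric", smoothness_weight = "numeric",
                   compactness_weight = "numeric", layer_weights = "numeric"),
    prototype(scale = 20, color_weight = 0.6, shape_weight = 0.4,
              smoothness_weight = 0.5, compactness_weight = 0.05,
              layer_weights = numeric(0)))

setValidity("SegmentationParams", function(object) {
    msgs <- character()
    if (object@scale <= 0) msgs <- c(msgs, "scale must be positive")
    if (abs(object@color_weight + object@shape_weight - 1) > 1e-9)
        msgs <- c(msgs, "color_weight + shape_weight must equal 1")
    w <- c(object@color_weight, object@shape_weight,
           object@smoothness_weight, object@compactness_weight)
    if (any(w < 0)) msgs <- c(msgs, "weights must be non-negative")
    if (length(object@layer_weights)) {
        if (is.null(names(object@layer_weights)))
            msgs <- c(msgs, "layer_weights must be named")
        if (any(object@layer_weights < 0))
            msgs <- c(msgs, "layer_weights must be non-negative")
        if (max(object@layer_weights) <= 0)
            msgs <- c(msgs, "at least one layer weight must be positive")
    }
    if (length(msgs)) msgs else TRUE
})

#' SegmentLevel: a label raster plus its object table
#'
#' One level of the segmentation hierarchy. Nonzero labels partition the
#' valid pixels; the object table holds per-object statistics and (for upper
#' levels built by [buildHierarchyLevel()]) the parent links of the level
#' below are set in that level's table.
#'
#' @slot labels integer matrix, object id per pixel, 0 = nodata.
#' @slot objects data.frame with columns `id`, `pixel_count`, `perimeter`
#'   (pixel edges), `rmin`,`rmax`,`cmin`,`cmax` (1-based bounding box),
#'   `parent_id` (NA until a hierarchy is built) and `mean.<layer>` /
#'   `sd.<layer>` columns for each statistics layer.
#' @slot edges 2-column integer matrix of symmetric neighbour pairs (a < b).
#' @slot transform,gsd georeference inherited from the scene.
#' @export
setClass("SegmentLevel",
    representation(labels = "matrix", objects = "data.frame",
                   edges = "matrix", transform = "numeric", gsd = "numeric"))

setValidity("SegmentLevel", function(object) {
    msgs <- character()
    need <- c("id", "pixel_count", "perimeter", "rmin", "rmax", "cmin", "cmax",
              "parent_id")
    miss <- setdiff(need, names(object@objects))
    if (length(miss))
        msgs <- c(msgs, sprintf("objects table lacks column(s): %s",
                                paste(miss, collapse = ", ")))
    if (nrow(object@objects) && !length(msgs)) {
        if (anyDuplicated(object@objects$id))
            msgs <- c(msgs, "duplicated object ids")
        if (sum(object@objects$pixel_count) != sum(object@labels > 0L))
            msgs <- c(msgs, "object pixel counts do not sum to the labelled pixel count")
    }
    if (length(msgs)) msgs else TRUE
})

#' ClassMap: per-object classes and heights above the local soil baseline
#'
#' @slot object_class named character, "bare_soil", "herbaceous" or "tree"
#'   per object id of the associated [SegmentLevel].
#' @slot object_height named numeric, metres above the local baseline
#'   (maximum pixel height, i.e. the crown apex); NA until computed.
#' @slot pixel_height numeric matrix, metres above baseline on vegetation
#'   pixels, NA elsewhere.
#' @slot baseline_elev named numeric, baseline DSM elevation per vegetation
#'   object (metres).
#' @slot baseline_failed integer, ids of vegetation objects for which no
#'   bare soil was found within the widest search ring.
#' @export
setClass("ClassMap",
    representation(object_class = "character", object_height = "numeric",
                   pixel_height = "matrix", baseline_elev = "numeric",
                   baseline_failed = "integer"))

setValidity("ClassMap", function(object) {
    msgs <- character()
    bad <- setdiff(unique(object@object_class),
                   c("bare_soil", "herbaceous", "tree"))
    if (length(bad))
        msgs <- c(msgs, sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")))
    h <- object@object_height
    if (length(h) && any(h[!is.na(h)] < 0))
        msgs <- c(msgs, "object heights must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' OrchardConfig: parameters of the synthetic-orchard generator
#'
#' Defines a georeferenced synthetic scene: terrain (plane plus smooth
#' undulation), half-ellipsoid tree crowns on a planting grid or in rows,
#' optional low grass patches, a two-class (+grass) spectral model with
#' additive Gaussian sensor noise, and the sensor/GSD combination.
#' See [orchardPreset()] for presets mirroring common field layouts.
#'
#' @slot pattern "single_tree" or "tree_row".
#' @slot spacing numeric(2), inter-row and in-row spacing in metres.
#' @slot n_rows,n_cols integer grid dimensions (trees; for rows, n_cols is
#'   trees per row).
#' @slot rx_range,ry_range numeric(2), crown semi-axis ranges in metres
#'   (rx across rows / x, ry along rows / y).
#' @slot height_range numeric(2), crown height range in metres.
#' @slot gap_fraction fraction 0-1 of crown pixels removed as random gaps.
#' @slot slope terrain slope (m/m, along +x).
#' @slot undulation_amp,undulation_wavelength smooth terrain undulation
#'   amplitude (m) and wavelength (m).
#' @slot grass_fraction approximate fraction of soil area under grass patches.
#' @slot grass_height maximum grass height (m); must stay below the
#'   minimum crown height.
#' @slot sensor_kind "visible" or "multispectral".
#' @slot gsd ground sample distance (m/pixel).
#' @slot soil_mean,canopy_mean,grass_mean named numeric, per-band mean
#'   digital numbers (0-255).
#' @slot noise_sd additive Gaussian noise sigma (DN).
#' @slot margin scene margin around the planting grid (m).
#' @slot origin numeric(2), map coordinates of the lower-left corner (m).
#' @slot crs_id planar CRS identifier stamped on outputs.
#' @slot seed integer random seed; the same config and seed give
#'   bit-identical scenes.
#' @export
setClass("OrchardConfig",
    representation(pattern = "character", spacing = "numeric",
                   n_rows = "integer", n_cols = "integer",
                   rx_range = "numeric", ry_range = "numeric",
                   height_range = "numeric", gap_fraction = "numeric",
                   slope = "numeric", undulation_amp = "numeric",
                   undulation_wavelength = "numeric",
                   grass_fraction = "numeric", grass_height = "numeric",
                   sensor_kind = "character", gsd = "numeric",
                   soil_mean = "numeric", canopy_mean = "numeric",
                   grass_mean = "numeric", noise_sd = "numeric",
                   margin = "numeric", origin = "numeric",
                   crs_id = "character", seed = "integer"))

setValidity("OrchardConfig", function(object) {
    msgs <- character()
    if (!object@pattern %in% c("single_tree", "tree_row"))
        msgs <- c(msgs, "pattern must be 'single_tree' or 'tree_row'")
    if (object@gsd <= 0) msgs <- c(msgs, "gsd must be positive")
    if (any(object@spacing <= 0)) msgs <- c(msgs, "spacing must be positive")
    if (identical(object@pattern, "single_tree") &&
        (max(object@rx_range) >= object@spacing[1] / 2 ||
         max(object@ry_range) >= object@spacing[2] / 2))
        msgs <- c(msgs, "crown radii must be below half the spacing in single_tree mode")
    if (object@grass_height >= min(object@height_range))
        msgs <- c(msgs, "grass height must stay below the minimum crown height")
    if (object@gap_fraction < 0 || object@gap_fraction >= 1)
        msgs <- c(msgs, "gap_fraction must be in [0, 1)")
    if (length(msgs)) msgs else TRUE
})

#' GroundTruth: analytic truth for a synthetic orchard scene
#'
#' @slot trees data.frame with per-tree truth: `tree_id`, centre `x`, `y`
#'   (map m), semi-axes `rx`, `ry` (m), crown height `h` (m), closed-form
#'   `true_area` (pi * rx * ry, m^2) and `true_volume`
#'   ((2/3) * pi * rx * ry * h, m^3), plus `row_id` for row patterns.
#' @slot class_mask integer matrix: 0 soil, 1 grass, 2 tree crown.
#' @slot terrain numeric matrix, bare-terrain elevation (m).
#' @slot transform,gsd,crs_id georeference matching the generated scene.
#' @export
setClass("GroundTruth",
    representation(trees = "data.frame", class_mask = "matrix",
                   terrain = "matrix", transform = "numeric",
                   gsd = "numeric", crs_id = "character"))

#' ValidationReport: pipeline-vs-reference comparison statistics
#'
#' @slot overall_accuracy percent of pixels whose predicted tree/non-tree
#'   class matches the reference mask.
#' @slot features data.frame of per-feature paired statistics: mean absolute
#'   error, its standard deviation (absolute and as percent of the observed
#'   mean), RMSE, OLS slope/intercept/R-squared and n.
#' @slot n integer, number of compared entities.
#' @export
setClass("ValidationReport",
    representation(overall_accuracy = "numeric", features = "data.frame",
                   n = "integer"))

#' OrchardAnalysis: full result of the delineation pipeline
#'
#' @slot base_level [SegmentLevel] of the multiresolution segmentation.
#' @slot entities [SegmentLevel] of merged tree entities (upper level).
#' @slot classes [ClassMap] of the base-level objects.
#' @slot records data.frame of per-entity tree records (see [entityMetrics()]).
#' @slot polygons named list of entity footprint rings (matrices of map x, y).
#' @slot field_summary list, see [summarizeField()].
#' @export
setClass("OrchardAnalysis",
    representation(base_level = "SegmentLevel", entities = "SegmentLevel",
                   classes = "ClassMap", records = "data.frame",
                   polygons = "list", field_summary = "list"))
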