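#' @include AllClasses.R
NULL

#' Accessors for canopyOBIA classes
#'
#' Small accessor generics: `bands()`, `dsm()`, `gsd()`, `sceneTransform()`,
#' `nodataMask()`, `sensorKind()` for [SceneStack-class];
#' `segLabels()`, `segObjects()`, `segEdges()`, `nObjects()` for
#' [SegmentLevel-class]; `objectClass()`, `objectHeights()`, `pixelHeight()`,
#' `baselineElev()` for [ClassMap-class]; `truthTrees()`, `classMask()` for
#' [GroundTruth-class]; `treeRecords()`, `entityLevel()`, `fieldSummary()`
#' for [OrchardAnalysis-class]; `indexValues()` for [IndexLayer-class].
#'
#' @param x object to access.
#' @return the slot content.
#' @name accessors
#' @aliases bands dsm gsd sceneTransform nodataMask sensorKind segLabels
#'   segObjects segEdges nObjects objectClass objectHeights pixelHeight
#'   baselineElev truthTrees classMask treeRecords entityLevel fieldSummary
#'   indexValues
NULL

#' @rdname accessors
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))
#' @rdname accessors
#' @export
setGeneric("dsm", function(x) standardGeneric("dsm"))
#' @rdname accessors
#' @export
setGeneric("gsd", function(x) standardGeneric("gsd"))
#' @rdname accessors
#' @export
setGeneric("sceneTransform", function(x) standardGeneric("sceneTransform"))
#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname accessors
#' @export
setGeneric("sensorKind", function(x) standardGeneric("sensorKind"))
#' @rdname accessors
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))
#' @rdname accessors
#' @export
setGeneric("segObjects", function(x) standardGeneric("segObjects"))
#' @rdname accessors
#' @export
setGeneric("segEdges", function(x) standardGeneric("segEdges"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("objectClass", function(x) standardGeneric("objectClass"))
#' @rdname accessors
#' @export
setGeneric("objectHeights", function(x) standardGeneric("objectHeights"))
#' @rdname accessors
#' @export
setGeneric("pixelHeight", function(x) standardGeneric("pixelHeight"))
#' @rdname accessors
#' @export
setGeneric("baselineElev", function(x) standardGeneric("baselineElev"))
#' @rdname accessors
#' @export
setGeneric("truthTrees", function(x) standardGeneric("truthTrees"))
#' @rdname accessors
#' @export
setGeneric("classMask", function(x) standardGeneric("classMask"))
#' @rdname accessors
#' @export
setGeneric("treeRecords", function(x) standardGeneric("treeRecords"))
#' @rdname accessors
#' @export
setGeneric("entityLevel", function(x) standardGeneric("entityLevel"))
#' @rdname accessors
#' @export
setGeneric("fieldSummary", function(x) standardGeneric("fieldSummary"))
#' @rdname accessors
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))

setMethod("bands", "SceneStack", function(x) x@bands)
setMethod("dsm", "SceneStack", function(x) x@dsm)
setMethod("gsd", "SceneStack", function(x) x@gsd)
setMethod("sceneTransform", "SceneStack", function(x) x@transform)
setMethod("nodataMask", "SceneStack", function(x) x@nodata_mask)
setMethod("sensorKind", "SceneStack", function(x) x@sensor_kind)

setMethod("segLabels", "SegmentLevel", function(x) x@labels)
setMethod("segObjects", "SegmentLevel", function(x) x@objects)
setMethod("segEdges", "SegmentLevel", function(x) x@edges)
setMethod("nObjects", "SegmentLevel", function(x) nrow(x@objects))
setMethod("gsd", "SegmentLevel", function(x) x@gsd)
setMethod("sceneTransform", "SegmentLevel", function(x) x@transform)

setMethod("objectClass", "ClassMap", function(x) x@object_class)
setMethod("objectHeights", "ClassMap", function(x) x@object_height)
setMethod("pixelHeight", "ClassMap", function(x) x@pixel_height)
setMethod("baselineElev", "ClassMap", function(x) x@baseline_elev)

setMethod("truthTrees", "GroundTruth", function(x) x@trees)
setMethod("classMask", "GroundTruth", function(x) x@class_mask)
setMethod("gsd", "GroundTruth", function(x) x@gsd)
setMethod("sceneTransform", "GroundTruth", function(x) x@transform)

setMethod("treeRecords", "OrchardAnalysis", function(x) x@records)
setMethod("entityLevel", "OrchardAnalysis", function(x) x@entities)
setMethod("fieldSummary", "OrchardAnalysis", function(x) x@field_summary)
setMethod("objectClass", "OrchardAnalysis", function(x) x@classes@object_class)

setMethod("indexValues", "IndexLayer", function(x) x@values)
setMethod("nodataMask", "IndexLayer", function(x) x@nodata_mask)

setMethod("show", "SceneStack", function(object) {
    d <- dim(object@dsm)
    cat(sprintf("SceneStack: %d x %d px, %s sensor, gsd %.4f m\n",
                d[1], d[2], object@sensor_kind, object@gsd))
    cat(sprintf("  bands: %s (+ DSM)\n", paste(names(object@bands), collapse = ", ")))
    cat(sprintf("  extent: x [%.2f, %.2f], y [%.2f, %.2f] (%s)\n",
                object@transform[1], object@transform[1] + d[2] * object@transform[3],
                object@transform[2] - d[1] * object@transform[4], object@transform[2],
                object@crs_id))
    cat(sprintf("  nodata pixels: %d\n", sum(object@nodata_mask)))
})

setMethod("show", "IndexLayer", function(object) {
    v <- object@values[!object@nodata_mask]
    cat(sprintf("IndexLayer (%s): %d x %d px, range [%.3f, %.3f]\n",
                object@index_kind, nrow(object@values), ncol(object@values),
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "SegmentLevel", function(object) {
    cat(sprintf("SegmentLevel: %d objects over %d x %d px (%d labelled)\n",
                nrow(object@objects), nrow(object@labels), ncol(object@labels),
                sum(object@labels > 0L)))
})

setMethod("show", "ClassMap", function(object) {
    tab <- table(factor(object@object_class,
                        levels = c("bare_soil", "herbaceous", "tree")))
    cat("ClassMap:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    if (length(object@baseline_failed))
        cat("  baseline failures:", length(object@baseline_failed), "\n")
})

setMethod("show", "OrchardAnalysis", function(object) {
    cat(sprintf("OrchardAnalysis: %d tree entities\n", nrow(object@records)))
    if (nrow(object@records)) {
        cat(sprintf("  height: mean %.2f m; volume: mean %.2f m^3; area: mean %.2f m^2\n",
                    mean(object@records$height), mean(object@records$volume),
                    mean(object@records$projected_area)))
    }
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("ValidationReport (n = %d)\n", object@n))
    if (length(object@overall_accuracy) && is.finite(object@overall_accuracy))
        cat(sprintf("  overall classification accuracy: %.1f%%\n",
                    object@overall_accuracy))
    if (nrow(object@features)) {
        for (i in seq_len(nrow(object@features))) {
            f <- object@features[i, ]
            cat(sprintf("  %s: avg |err| %.3f (%.1f%% of mean), RMSE %.3f, R2 %.3f\n",
                        f$feature, f$avg_error, f$pct_of_mean, f$rmse, f$r_squared))
        }
    }
})
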