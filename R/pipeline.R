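#' @include synthetic.R
NULL

#' Run the full tree-delineation pipeline on a scene
#'
#' Executes the object-based workflow: vegetation index, multiresolution
#' segmentation on the weighted layers (DSM plus Green or NIR), object-level
#' Otsu isolation of vegetation from bare soil, per-object heights above the
#' local bare-soil baseline, removal of low herbaceous vegetation,
#' 8-connected merging of tree objects into trees/tree-rows, and per-entity
#' geometric features including pixel-integrated crown volume. Entities
#' smaller than `min_entity_area` are dropped as noise (at typical GSDs a
#' real crown covers thousands of pixels; a few pixels are below the
#' detectability limit).
#'
#' @param scene a [SceneStack-class].
#' @param params a [SegmentationParams-class].
#' @param min_tree_height herbaceous/tree height cut in metres.
#' @param ring_px bare-soil baseline ring width in pixels.
#' @param min_entity_area minimum entity footprint (m^2, default 0.1).
#' @param axes axis definition for [entityMetrics()].
#' @param verbose log stage timings to stderr.
#' @return an [OrchardAnalysis-class].
#' @export
runPipeline <- function(scene, params = segmentationParams(),
                        min_tree_height = 0.5, ring_px = 5L,
                        min_entity_area = 0.1,
                        axes = c("rectangle", "ellipse"), verbose = FALSE) {
    axes <- match.arg(axes)
    t0 <- proc.time()[["elapsed"]]
    say <- function(stage) {
        if (verbose)
            message(sprintf("[%7.1fs] %s", proc.time()[["elapsed"]] - t0, stage))
    }
    idx <- vegetationIndex(scene)
    say("vegetation index")
    level <- multiresolutionSegment(scene, params)
    say(sprintf("segmentation: %d objects", nObjects(level)))
    cm <- classifyVegetation(level, idx)
    say("vegetation/bare-soil classification")
    cm <- objectHeight(level, dsm(scene), cm, ring_px = ring_px)
    say("object heights above local baseline")
    cm <- removeHerbaceous(cm, min_tree_height = min_tree_height)
    say("herbaceous removal")
    ents <- mergeTreeEntities(level, cm)
    say(sprintf("entity merging: %d tree entities",
                sum(segObjects(ents)$tree_entity)))
    recs <- entityMetrics(ents, cm, axes = axes)
    keep <- recs$projected_area >= min_entity_area
    dropped_ids <- recs$tree_id[!keep]
    recs <- recs[keep, , drop = FALSE]
    if (length(dropped_ids)) {
        obj <- segObjects(ents)
        obj$tree_entity[obj$id %in% dropped_ids] <- FALSE
        ents@objects <- obj
    }
    rownames(recs) <- NULL
    say(sprintf("entity metrics: %d records", nrow(recs)))
    polys <- list()
    for (id in recs$tree_id) {
        fp <- entityFootprint(ents, id)
        if (!is.null(fp)) polys[[as.character(id)]] <- fp
    }
    fs <- if (nrow(recs)) summarizeField(recs) else list(n_trees = 0L)
    say("footprints and field summary")
    new("OrchardAnalysis", base_level = level, entities = ents, classes = cm,
        records = recs, polygons = polys, field_summary = fs)
}

#' Export pipeline results to vector, table and report files
#'
#' @param analysis an [OrchardAnalysis-class].
#' @param out_dir output directory.
#' @param crs_id CRS identifier for the GeoJSON.
#' @return named character vector of the paths written.
#' @export
writeAnalysis <- function(analysis, out_dir, crs_id = "LOCAL") {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(vector = file.path(out_dir, "entities.geojson"),
               table = file.path(out_dir, "trees.csv"),
               report = file.path(out_dir, "field_summary.json"))
    writeEntities(treeRecords(analysis), analysis@polygons,
                  paths[["vector"]], paths[["table"]], crs_id = crs_id)
    jsonlite::write_json(fieldSummary(analysis), paths[["report"]],
                         auto_unbox = TRUE, digits = NA, null = "null")
    paths
}
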