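#' @include sceneIO.R
NULL

#' Ground sample distance from flight and sensor geometry
#'
#' The on-ground footprint of one image pixel is
#' `GSD = sensor pixel size x flight altitude / focal length`,
#' with the pixel pitch and focal length in millimetres and the altitude in
#' metres, giving the GSD in metres per pixel. For sensors whose spec sheet
#' gives sensor width and pixel count rather than pixel pitch, pass
#' `sensor_width_mm / n_pixels` as the pixel size (e.g. a 17.3 mm wide,
#' 4032 px sensor has a 0.0042907 mm pitch).
#'
#' @param sensor_pixel_size pixel pitch in mm (> 0).
#' @param focal_length focal length in mm (> 0).
#' @param flight_altitude altitude above ground in m (>= 0).
#' @return GSD in metres per pixel.
#' @examples
#' computeGSD(17.3 / 4032, 14, 50)   # ~0.0153 m
#' computeGSD(0.0052, 9.6, 100)      # ~0.0542 m
#' @export
computeGSD <- function(sensor_pixel_size, focal_length, flight_altitude) {
    if (any(focal_length <= 0))
        .canopyError("domain_error", "focal_length must be positive")
    if (any(sensor_pixel_size <= 0))
        .canopyError("domain_error", "sensor_pixel_size must be positive")
    if (any(flight_altitude < 0))
        .canopyError("domain_error", "flight_altitude must be non-negative")
    sensor_pixel_size * flight_altitude / focal_length
}

#' Format a GSD in centimetres for presentation
#'
#' Rounds half-up to 2 decimals, matching how flight GSDs are usually
#' reported (e.g. 0.0153238 m -> "1.53").
#'
#' @param gsd_m GSD in metres.
#' @return character vector of centimetre values.
#' @export
formatGSDcm <- function(gsd_m) {
    cm <- gsd_m * 100
    # round half up at 2 decimals
    formatC(floor(cm * 100 + 0.5) / 100, format = "f", digits = 2)
}

.indexFromBands <- function(num, den, kind, nodata) {
    bad <- nodata | !is.finite(den) | den == 0
    v <- num / den
    v[bad] <- NA_real_
    new("IndexLayer", values = v, index_kind = kind, nodata_mask = bad)
}

#' Excess Green index (ExG)
#'
#' Chromatic coordinates `r = R/(R+G+B)`, `g = G/(R+G+B)`, `b = B/(R+G+B)`
#' and `ExG = 2g - r - b`. The chromatic normalisation makes the index
#' invariant to a positive rescaling of the bands, so 8-bit digital numbers
#' and calibrated reflectance give identical values. Pixels with
#' `R + G + B = 0` (dropouts) become nodata rather than 0.
#'
#' @param stack a [SceneStack-class] with R, G and B bands.
#' @return an [IndexLayer-class] with values in `[-1, 2]`.
#' @export
excessGreen <- function(stack) {
    b <- bands(stack)
    miss <- setdiff(c("R", "G", "B"), names(b))
    if (length(miss))
        .canopyError("schema_error", sprintf("ExG requires band(s): %s",
                                             paste(miss, collapse = ", ")))
    tot <- b$R + b$G + b$B
    .indexFromBands(2 * b$G - b$R - b$B, tot, "ExG", nodataMask(stack))
}

#' Normalised Difference Vegetation Index (NDVI)
#'
#' `NDVI = (NIR - R) / (NIR + R)`; scale-invariant in the two bands.
#' Pixels with `NIR + R = 0` become nodata.
#'
#' @param stack a [SceneStack-class] with R and NIR bands.
#' @return an [IndexLayer-class] with values in `[-1, 1]`.
#' @export
ndvi <- function(stack) {
    b <- bands(stack)
    miss <- setdiff(c("R", "NIR"), names(b))
    if (length(miss))
        .canopyError("schema_error", sprintf("NDVI requires band(s): %s",
                                             paste(miss, collapse = ", ")))
    .indexFromBands(b$NIR - b$R, b$NIR + b$R, "NDVI", nodataMask(stack))
}

#' Default vegetation index for a scene's sensor kind
#'
#' ExG for visible-light scenes, NDVI when a NIR band is available.
#'
#' @param stack a [SceneStack-class].
#' @return an [IndexLayer-class].
#' @export
vegetationIndex <- function(stack) {
    if (identical(sensorKind(stack), "visible")) excessGreen(stack) else ndvi(stack)
}
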