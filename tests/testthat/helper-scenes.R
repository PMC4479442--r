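# Fixture builders shared across the suite: all scenes are generated in
# code at test time, no files are shipped.

# A small synthetic orchard: n x n single trees at 5 m spacing, coarse GSD
# so segmentation stays fast.
tinyOrchard <- function(seed = 11, n = 2L, gsd = 0.05, sensor = "visible",
                        ...) {
    cfg <- orchardConfig(n_rows = n, n_cols = n, spacing = c(5, 5),
                         gsd = gsd, rx_range = c(1.2, 1.8),
                         ry_range = c(1.2, 1.8), sensor_kind = sensor,
                         margin = 1.5, seed = seed, ...)
    generateOrchard(cfg)
}

# A hand-built flat scene with one square "crown" of known height: soil DN
# contrasts with canopy DN, DSM = base + height inside the crown square.
squareCrownScene <- function(nr = 60, nc = 60, crown_rows = 20:39,
                             crown_cols = 20:39, height = 3, base = 100,
                             slope = 0, gsd = 0.1) {
    soil <- list(R = 150, G = 130, B = 105)
    can <- list(R = 70, G = 110, B = 60)
    bands <- lapply(stats::setNames(nm = c("R", "G", "B")), function(b) {
        m <- matrix(soil[[b]], nr, nc)
        m[crown_rows, crown_cols] <- can[[b]]
        m
    })
    xs <- (seq_len(nc) - 0.5) * gsd
    dsm_m <- matrix(rep(base + slope * xs, each = nr), nr, nc)
    dsm_m[crown_rows, crown_cols] <- dsm_m[crown_rows, crown_cols] + height
    SceneStack(bands = bands, dsm = dsm_m,
               transform = c(0, nr * gsd, gsd, gsd), sensor_kind = "visible")
}

# One isolated half-ellipsoid crown on flat (or tilted) terrain, analytic
# truth rx, ry, h known exactly.
halfEllipsoidScene <- function(rx = 2, ry = 2, h = 3, gsd = 0.05,
                               slope = 0, extent = 8, noise_sd = 0,
                               seed = 1) {
    cfg <- orchardConfig(pattern = "single_tree", spacing = c(extent, extent),
                         n_rows = 1L, n_cols = 1L, gsd = gsd,
                         rx_range = c(rx, rx), ry_range = c(ry, ry),
                         height_range = c(h, h), slope = slope,
                         undulation_amp = 0, grass_fraction = 0,
                         noise_sd = noise_sd, sensor_kind = "visible",
                         margin = 1, seed = seed)
    generateOrchard(cfg)
}

# Weighted brute-force Otsu oracle: exhaustive search over all 256 bin
# edges maximising between-class variance. Kept independent of the
# implementation under test.
bruteForceOtsu <- function(values, weights, n_bins = 256L) {
    values <- as.numeric(values)
    weights <- as.numeric(weights)
    rng <- range(values)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(values, breaks, rightmost.closed = TRUE)
    bin[bin < 1] <- 1L; bin[bin > n_bins] <- n_bins
    best_sigma <- -Inf
    best_k <- NA_integer_
    for (k in seq_len(n_bins - 1L)) {
        lo <- bin <= k
        w0 <- sum(weights[lo]); w1 <- sum(weights[!lo])
        if (w0 == 0 || w1 == 0) next
        mu0 <- sum(weights[lo] * values[lo]) / w0
        mu1 <- sum(weights[!lo] * values[!lo]) / w1
        sig <- w0 * w1 * (mu0 - mu1)^2
        if (sig > best_sigma) {
            best_sigma <- sig
            best_k <- k
        }
    }
    breaks[best_k + 1L]
}
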