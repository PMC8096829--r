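# Shared fixtures: small simulator configs and hand-built landmark maps.

tiny_sim_config <- function(seed = 42, ...) {
  spine_sim_config(image_height = 160L, image_width = 160L, seed = seed, ...)
}

# A rectangle-vertebra landmark map with known geometry, for exact
# arithmetic on errors and angles. All endplates horizontal by default.
rect_corners <- function(x0, y0, w, h) {
  corner_set(rbind(c(x0 + w, y0), c(x0, y0),
                   c(x0 + w, y0 + h), c(x0, y0 + h)))
}

toy_landmarks <- function() {
  list(
    L1 = rect_corners(40, 10, 30, 20),
    L2 = rect_corners(40, 40, 30, 20),
    L5 = rect_corners(40, 70, 30, 20),
    S1 = corner_set(rbind(c(72, 100), c(42, 100), c(NA, NA), c(NA, NA)))
  )
}

# shift every valid corner of a landmark map by (dx, dy)
shift_landmarks <- function(lm, dx, dy) {
  lapply(lm, function(cs) {
    p <- cs$points
    p[cs$valid, 1] <- p[cs$valid, 1] + dx
    p[cs$valid, 2] <- p[cs$valid, 2] + dy
    corner_set(p, cs$valid)
  })
}
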