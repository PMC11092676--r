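# Per-component morphology of fat and glandular tissue plus the whole
# breast region.

MORPH_PROPS <- c("area", "perimeter", "hull_area", "hull_perimeter",
                 "solidity", "convexity_perimeter", "eccentricity",
                 "major_axis", "minor_axis", "orientation", "extent",
                 "equiv_diameter", "circularity", "euler")

# Count holes in a single-component mask given its pixel rows/cols.
count_holes <- function(rc) {
  r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
  h <- max(rc[, 1]) - r0 + 1L; w <- max(rc[, 2]) - c0 + 1L
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[cbind(rc[, 1] - r0 + 2L, rc[, 2] - c0 + 2L)] <- TRUE
  bg <- label_components(!m, connectivity = 4)
  max(bg) - 1L
}

# 14 shape properties for each labelled component.
component_props <- function(lab) {
  n_comp <- max(lab)
  if (n_comp == 0L) return(matrix(numeric(0), 0, length(MORPH_PROPS),
                                  dimnames = list(NULL, MORPH_PROPS)))
  contours <- object_contours(lab)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rc_all <- cbind((idx - 1L) %% nrow(lab) + 1L, (idx - 1L) %/% nrow(lab) + 1L)
  by_comp <- split(seq_along(idx), labs)
  out <- matrix(NA_real_, n_comp, length(MORPH_PROPS),
                dimnames = list(NULL, MORPH_PROPS))
  for (ci in seq_len(n_comp)) {
    rc <- rc_all[by_comp[[as.character(ci)]], , drop = FALSE]
    area <- nrow(rc)
    cont <- contours[[as.character(ci)]]
    if (is.null(cont)) cont <- contours[[ci]]
    per <- max(chain_length(cont), 1)
    hs <- hull_stats(rc)
    # moments of the binary component, pixel centres
    y <- rc[, 1]; x <- rc[, 2]
    mu20 <- mean((x - mean(x))^2); mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    tr2 <- (mu20 + mu02) / 2
    det4 <- sqrt(pmax(0, ((mu20 - mu02) / 2)^2 + mu11^2))
    l1 <- tr2 + det4; l2 <- pmax(0, tr2 - det4)
    out[ci, ] <- c(
      area, per, hs$area, hs$perimeter,
      if (hs$area > 0) area / hs$area else NA_real_,
      if (per > 0) hs$perimeter / per else NA_real_,
      if (l1 > 0) sqrt(1 - l2 / l1) else 0,
      4 * sqrt(l1), 4 * sqrt(l2),
      0.5 * atan2(2 * mu11, mu20 - mu02),
      area / ((diff(range(y)) + 1) * (diff(range(x)) + 1)),
      sqrt(4 * area / pi),
      4 * pi * area / per^2,
      1 - count_holes(rc))
  }
  out
}

morphology_feature_names <- function() {
  c(unlist(lapply(c("F", "G"), function(t)
    unlist(lapply(MORPH_PROPS, function(p)
      sprintf("morph_%s_%s_%s", t, p, SUMMARY_STATS))))),
    sprintf("morph_B_%s", MORPH_PROPS))
}

#' Morphological features of tissue components
#'
#' The 14 shape properties (area, perimeter, convex-hull area and perimeter,
#' solidity, convexity-perimeter ratio, eccentricity, major/minor axis,
#' orientation, extent, equivalent diameter, circularity `4*pi*A/P^2`, Euler
#' number) for every 8-connected component of fat and of glandular tissue,
#' each summarised by the eight-statistic scheme, plus the same properties of
#' the single whole-breast region reported directly. Perimeters are lengths
#' of the 8-connected outer contour chain; hulls are computed on pixel
#' corners so hull area bounds pixel area.
#'
#' @param label_map Segmented label map.
#' @return Named numeric vector (`14 * 8 * 2 + 14`).
#' @export
morphology_features <- function(label_map) {
  vals <- unlist(lapply(c(1L, 2L), function(lv) {
    props <- component_props(label_components(label_map == lv, 8))
    unlist(lapply(MORPH_PROPS, function(p) summary8(props[, p])))
  }))
  fg <- largest_component(label_map > 0L)
  b <- if (any(fg)) component_props(fg * 1L)[1, ]
  else rep(NA_real_, length(MORPH_PROPS))
  stats::setNames(c(vals, b), morphology_feature_names())
}
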