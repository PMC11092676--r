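# Box-counting dimension and gliding-box lacunarity of binary masks.

FRACTAL_SIZES <- c(2L, 4L, 8L, 16L, 32L, 64L)

#' Box-counting dimension
#'
#' Least-squares slope of `log N(r)` against `log(1 / r)` over dyadic box
#' sizes, with the counting grid anchored at the image origin (no offset
#' averaging).
#'
#' @param mask Logical matrix.
#' @param sizes Dyadic box sizes (default 2, 4, ..., 64).
#' @return Scalar dimension estimate, or `NA` when the mask occupies fewer
#'   than two boxes at every scale.
#' @export
box_dimension <- function(mask, sizes = FRACTAL_SIZES) {
  counts <- vapply(sizes, function(r) {
    nr <- ceiling(nrow(mask) / r) * r
    nc <- ceiling(ncol(mask) / r) * r
    m <- matrix(0, nr, nc)
    m[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
    dim(m) <- c(r, nr / r, nc)
    m <- colSums(m) > 0
    m <- t(m) * 1
    dim(m) <- c(r, nc / r, nr / r)
    sum(colSums(m) > 0)
  }, numeric(1))
  if (max(counts) < 2) return(NA_real_)
  keep <- counts >= 1
  stats::coef(stats::lm(log(counts[keep]) ~ log(1 / sizes[keep])))[[2]]
}

#' Gliding-box lacunarity
#'
#' `Lambda(r) = 1 + var(mass) / mean(mass)^2` over all `r x r` windows
#' (stride 1, population variance) of the mask cropped to its bounding box.
#' A uniformly filled mask has `Lambda = 1` at every size; sparse or clumpy
#' masks score higher.
#'
#' @inheritParams box_dimension
#' @return Named numeric vector of `Lambda(r)` per size (NA where the
#'   bounding box is smaller than the window).
#' @export
lacunarity <- function(mask, sizes = FRACTAL_SIZES) {
  out <- stats::setNames(rep(NA_real_, length(sizes)),
                         sprintf("r%d", sizes))
  if (!any(mask)) return(out)
  rc <- which(mask, arr.ind = TRUE)
  m <- mask[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2]), drop = FALSE]
  for (i in seq_along(sizes)) {
    s <- box_sums(m * 1, sizes[i])
    if (!length(s)) next
    mu <- mean(s)
    if (mu > 0) out[i] <- 1 + (mean(s^2) - mu^2) / mu^2
  }
  out
}

fractal_feature_names <- function() {
  unlist(lapply(c("F", "G", "L"), function(t)
    c(sprintf("frac_%s_boxdim", t),
      sprintf("frac_%s_lac_r%d", t, FRACTAL_SIZES),
      sprintf("frac_%s_lac_mean", t))), use.names = FALSE)
}

#' Fractal features of the fat, glandular and ligament masks
#'
#' @param label_map Segmented label map.
#' @return Named numeric vector: per tissue the box dimension, lacunarity at
#'   each dyadic size and its mean over sizes.
#' @export
fractal_features <- function(label_map) {
  vals <- unlist(lapply(c(1L, 2L, 4L), function(lv) {
    m <- label_map == lv
    lac <- lacunarity(m)
    c(box_dimension(m), lac,
      if (all(is.na(lac))) NA_real_ else mean(lac, na.rm = TRUE))
  }))
  stats::setNames(vals, fractal_feature_names())
}
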