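# Gray-level co-occurrence texture (14 classical statistics over a
# distance/angle grid at 64 gray levels) and first-order intensity
# statistics per tissue.

GLCM_ANGLES <- c(0, 45, 90, 135)
GLCM_DISTANCES <- c(1, 2, 4, 8)
HARALICK_NAMES <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "diff_variance", "diff_entropy", "imc1", "imc2", "mcc")

glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
         "0"   = c(0, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0),
         "135" = c(-distance, -distance),
         abort("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric, normalised GLCM at `levels` equal-width bins over `[0, 255]`,
#' counting only pixel pairs with both ends inside `mask`.
#'
#' @param image 8-bit image matrix.
#' @param mask Logical foreground mask.
#' @param distance,angle Offset in pixels and direction in degrees
#'   (0, 45, 90, 135).
#' @param levels Number of gray-level bins (default 64).
#' @return `levels x levels` matrix summing to 1, or all zeros when the mask
#'   admits no pair at this offset.
#' @export
glcm <- function(image, mask, distance = 1, angle = 0, levels = 64) {
  stopifnot_image8(image)
  off <- glcm_offset(distance, angle)
  bin <- pmin(image %/% (256L %/% levels) + 1L, levels)
  b2 <- shift_mat(bin, -off[1], -off[2], 0L)
  m2 <- shift_mat(mask, -off[1], -off[2], FALSE)
  sel <- mask & m2
  if (!any(sel)) return(matrix(0, levels, levels))
  idx <- bin[sel] + levels * (b2[sel] - 1L)
  counts <- matrix(tabulate(idx, levels * levels), levels, levels)
  counts <- counts + t(counts)
  counts / sum(counts)
}

#' The 14 classical co-occurrence (Haralick) statistics
#'
#' Angular second moment, contrast, correlation, variance, inverse difference
#' moment, sum average/variance/entropy, entropy, difference
#' variance/entropy, two information measures of correlation, and the maximal
#' correlation coefficient. Natural logs; `0 log 0 = 0`. Statistics that are
#' undefined for a degenerate matrix (a single occupied gray level) are `NA`.
#'
#' @param p Normalised symmetric GLCM.
#' @return Named numeric vector of length 14.
#' @export
haralick_stats <- function(p) {
  L <- nrow(p)
  out <- stats::setNames(rep(NA_real_, 14), HARALICK_NAMES)
  tot <- sum(p)
  if (!isTRUE(all.equal(tot, 1)) || tot == 0) return(out)
  I <- row(p); J <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  pv <- as.vector(p)
  psum <- as.vector(rowsum(pv, as.vector(I + J)))        # k = 2..2L present
  ksum <- sort(unique(as.vector(I + J)))
  pdif <- as.vector(rowsum(pv, as.vector(abs(I - J))))
  kdif <- sort(unique(as.vector(abs(I - J))))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  out["asm"] <- sum(p^2)
  out["contrast"] <- sum(kdif^2 * pdif)
  out["correlation"] <- if (sx > 0 && sy > 0)
    (sum(I * J * p) - mux * muy) / (sx * sy) else NA_real_
  out["variance"] <- sum((I - mux)^2 * p)
  out["idm"] <- sum(p / (1 + (I - J)^2))
  f6 <- sum(ksum * psum)
  out["sum_average"] <- f6
  out["sum_variance"] <- sum((ksum - f6)^2 * psum)
  out["sum_entropy"] <- ent(psum)
  hxy <- ent(p)
  out["entropy"] <- hxy
  mud <- sum(kdif * pdif)
  out["diff_variance"] <- sum((kdif - mud)^2 * pdif)
  out["diff_entropy"] <- ent(pdif)
  ppxy <- outer(px, py)
  sel <- p > 0 & ppxy > 0
  hxy1 <- -sum(p[sel] * log(ppxy[sel]))
  hxy2 <- ent(ppxy)
  hx <- ent(px); hy <- ent(py)
  out["imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  out["imc2"] <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  act <- which(px > 0)
  if (length(act) >= 2) {
    A <- sweep(p[act, act, drop = FALSE], 1, px[act], "/")
    C <- sweep(p[act, act, drop = FALSE], 2, py[act], "/")
    q <- A %*% t(C)
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    out["mcc"] <- sqrt(pmax(0, ev[2]))
  }
  out
}

texture_feature_names <- function(distances = GLCM_DISTANCES,
                                  angles = GLCM_ANGLES) {
  unlist(lapply(distances, function(d) {
    c(unlist(lapply(angles, function(a)
      sprintf("tex_d%d_a%d_%s", d, a, HARALICK_NAMES))),
      sprintf("tex_d%d_amean_%s", d, HARALICK_NAMES))
  }), use.names = FALSE)
}

#' Co-occurrence texture features of the breast region
#'
#' GLCMs over the full foreground at 64 gray levels for distances
#' `{1, 2, 4, 8}` and angles `{0, 45, 90, 135}` degrees; the 14 statistics per
#' (distance, angle) plus their per-distance angular means. Offsets for which
#' the foreground admits no pixel pair yield missing values.
#'
#' @param image 8-bit image matrix.
#' @param label_map Segmented label map; the scope is the whole breast
#'   region (labels > 0).
#' @param distances,angles Co-occurrence offset grid.
#' @param levels Gray-level bins.
#' @return Named numeric vector (`14 * (length(distances) * (length(angles) + 1))`).
#' @export
texture_features <- function(image, label_map, distances = GLCM_DISTANCES,
                             angles = GLCM_ANGLES, levels = 64) {
  mask <- label_map > 0L
  vals <- lapply(distances, function(d) {
    per_angle <- vapply(angles, function(a)
      haralick_stats(glcm(image, mask, d, a, levels)), numeric(14))
    amean <- rowMeans(per_angle)
    c(as.vector(per_angle), amean)
  })
  stats::setNames(unlist(vals), texture_feature_names(distances, angles))
}

INTENSITY_STATS <- c("area", "mean", "sd", "min", "max", "q1", "q2", "q3",
                     "skewness", "kurtosis", "energy", "entropy")
INTENSITY_SCOPES <- c("F", "G", "S", "L", "B")

intensity_feature_names <- function() {
  unlist(lapply(INTENSITY_SCOPES, function(s)
    sprintf("int_%s_%s", s, INTENSITY_STATS)), use.names = FALSE)
}

scope_mask <- function(label_map, scope) {
  switch(scope,
         F = label_map == 1L, G = label_map == 2L,
         S = label_map == 3L, L = label_map == 4L,
         B = label_map > 0L)
}

#' First-order intensity statistics per tissue
#'
#' For each scope (F, G, S, L tissues and the whole breast B): pixel count
#' (area), mean, sd, min, max, quartiles (linear interpolation), skewness,
#' excess-free kurtosis (fourth standardised moment), and histogram energy
#' and entropy at 64 bins. These carry the tissue areas and intensity
#' histogram summaries that the public ranking metric uses.
#'
#' @inheritParams texture_features
#' @return Named numeric vector (12 statistics x 5 scopes).
#' @export
intensity_features <- function(image, label_map) {
  out <- lapply(INTENSITY_SCOPES, function(s) {
    v <- image[scope_mask(label_map, s)]
    n <- length(v)
    if (n == 0) return(c(0, rep(NA_real_, 11)))
    m <- mean(v); s2 <- mean((v - m)^2)
    h <- tabulate(pmin(v %/% 4L + 1L, 64L), 64L) / n
    hp <- h[h > 0]
    c(n, m, stats::sd(v), min(v), max(v),
      stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7),
      if (s2 > 0) mean((v - m)^3) / s2^1.5 else NA_real_,
      if (s2 > 0) mean((v - m)^4) / s2^2 else NA_real_,
      sum(h^2), -sum(hp * log(hp)))
  })
  stats::setNames(unlist(out), intensity_feature_names())
}
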