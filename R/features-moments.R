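# Raw, central, normalised and Hu image moments, binary and
# intensity-weighted, per tissue scope.

MOMENT_RAW <- c("m00", "m10", "m01", "m20", "m11", "m02", "m30", "m21",
                "m12", "m03")
MOMENT_CENTRAL <- c("mu20", "mu11", "mu02", "mu30", "mu21", "mu12", "mu03")
MOMENT_ETA <- sub("mu", "eta", MOMENT_CENTRAL)
MOMENT_HU <- sprintf("hu%d", 1:7)
MOMENT_SCOPES <- c("F", "G", "B")

#' Image moments of a weighted pixel set
#'
#' Raw moments `m_pq` (p + q <= 3) in 0-based pixel coordinates (x = column,
#' y = row), central moments `mu_pq` (2 <= p + q <= 3), scale-normalised
#' `eta_pq = mu_pq / mu00^(1 + (p+q)/2)`, and the seven Hu rotation
#' invariants.
#'
#' @param mask Logical matrix selecting pixels.
#' @param weights Optional matrix of weights (e.g. intensities); `NULL` for
#'   binary moments.
#' @return Named numeric vector of length 31, or all-`NA` for an empty mask.
#' @export
image_moments <- function(mask, weights = NULL) {
  nm <- c(MOMENT_RAW, MOMENT_CENTRAL, MOMENT_ETA, MOMENT_HU)
  if (!any(mask)) return(stats::setNames(rep(NA_real_, length(nm)), nm))
  rc <- which(mask, arr.ind = TRUE)
  x <- rc[, 2] - 1; y <- rc[, 1] - 1
  w <- if (is.null(weights)) rep(1, nrow(rc)) else as.numeric(weights[mask])
  m <- function(p, q) sum(w * x^p * y^q)
  m00 <- m(0, 0)
  if (m00 <= 0) return(stats::setNames(rep(NA_real_, length(nm)), nm))
  xb <- m(1, 0) / m00; yb <- m(0, 1) / m00
  mu <- function(p, q) sum(w * (x - xb)^p * (y - yb)^q)
  raw <- c(m00, m(1, 0), m(0, 1), m(2, 0), m(1, 1), m(0, 2),
           m(3, 0), m(2, 1), m(1, 2), m(0, 3))
  cen <- c(mu(2, 0), mu(1, 1), mu(0, 2), mu(3, 0), mu(2, 1), mu(1, 2),
           mu(0, 3))
  ord <- c(2, 2, 2, 3, 3, 3, 3)
  eta <- cen / m00^(1 + ord / 2)
  e <- stats::setNames(eta, MOMENT_ETA)
  h1 <- e["eta20"] + e["eta02"]
  h2 <- (e["eta20"] - e["eta02"])^2 + 4 * e["eta11"]^2
  h3 <- (e["eta30"] - 3 * e["eta12"])^2 + (3 * e["eta21"] - e["eta03"])^2
  h4 <- (e["eta30"] + e["eta12"])^2 + (e["eta21"] + e["eta03"])^2
  h5 <- (e["eta30"] - 3 * e["eta12"]) * (e["eta30"] + e["eta12"]) *
    ((e["eta30"] + e["eta12"])^2 - 3 * (e["eta21"] + e["eta03"])^2) +
    (3 * e["eta21"] - e["eta03"]) * (e["eta21"] + e["eta03"]) *
    (3 * (e["eta30"] + e["eta12"])^2 - (e["eta21"] + e["eta03"])^2)
  h6 <- (e["eta20"] - e["eta02"]) *
    ((e["eta30"] + e["eta12"])^2 - (e["eta21"] + e["eta03"])^2) +
    4 * e["eta11"] * (e["eta30"] + e["eta12"]) * (e["eta21"] + e["eta03"])
  h7 <- (3 * e["eta21"] - e["eta03"]) * (e["eta30"] + e["eta12"]) *
    ((e["eta30"] + e["eta12"])^2 - 3 * (e["eta21"] + e["eta03"])^2) -
    (e["eta30"] - 3 * e["eta12"]) * (e["eta21"] + e["eta03"]) *
    (3 * (e["eta30"] + e["eta12"])^2 - (e["eta21"] + e["eta03"])^2)
  stats::setNames(c(raw, cen, eta, h1, h2, h3, h4, h5, h6, h7), nm)
}

moment_feature_names <- function() {
  unlist(lapply(MOMENT_SCOPES, function(s)
    unlist(lapply(c("bin", "wt"), function(k)
      sprintf("mom_%s_%s_%s", s, k,
              c(MOMENT_RAW, MOMENT_CENTRAL, MOMENT_ETA, MOMENT_HU))))),
    use.names = FALSE)
}

#' Moment features per tissue scope
#'
#' [image_moments()] for the fat mask, glandular mask and whole breast
#' region, each computed twice: on the binary mask and intensity-weighted
#' (raw 8-bit gray values) within the mask.
#'
#' @inheritParams texture_features
#' @return Named numeric vector (31 moments x 2 weightings x 3 scopes).
#' @export
moment_features <- function(image, label_map) {
  vals <- unlist(lapply(MOMENT_SCOPES, function(s) {
    m <- scope_mask(label_map, s)
    c(image_moments(m), image_moments(m, weights = image))
  }))
  stats::setNames(vals, moment_feature_names())
}
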