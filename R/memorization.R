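# Stage-1 memorization screening: maximum correlation of each generated
# image's fat-glandular boundary mask against all training boundary masks.

ensemble_images <- function(x) {
  if (inherits(x, "dgm_ensemble")) {
    if (is.null(x$images)) abort("ensemble was generated without keep_images")
    imgs <- x$images
    names(imgs) <- x$manifest$filename
    return(imgs)
  }
  if (is.character(x) && length(x) == 1) return(ensemble_images(read_ensemble(x)))
  stopifnot(is.list(x))
  if (is.null(names(x))) names(x) <- sprintf("img_%05d", seq_along(x))
  x
}

#' Dilated fat-glandular boundary masks of an ensemble
#'
#' @param x Ensemble, list of images, or directory.
#' @param radius Boundary dilation radius in pixels (default 2).
#' @param thresholds Segmentation thresholds.
#' @return Named list of logical masks (empty mask when segmentation fails
#'   or no fat/glandular interface exists).
#' @export
boundary_masks <- function(x, radius = 2,
                           thresholds = segmentation_thresholds()) {
  imgs <- ensemble_images(x)
  lapply(imgs, function(im) {
    lm <- tryCatch(segment_tissues(im, thresholds), error = function(e) NULL)
    if (is.null(lm)) return(matrix(FALSE, nrow(im), ncol(im)))
    fg_boundary_mask(lm, dilation_radius = radius)
  })
}

masks_to_matrix <- function(masks) {
  vapply(masks, as.logical, logical(length(masks[[1]])))
}

#' Memorization measure of a generated ensemble
#'
#' For every generated image, the maximum over the training ensemble of the
#' zero-lag Pearson correlation between the flattened, dilated
#' fat-glandular boundary masks (global alignment is assumed: breasts are
#' centred). Candidates are prefiltered on 4x max-pooled masks, keeping the
#' top `n_candidates` per generated image, then re-scored at full
#' resolution; `n_candidates = Inf` disables prefiltering (exhaustive
#' search).
#'
#' @param gen,train Ensembles, lists of images, or directories.
#' @param radius Boundary-mask dilation radius (default 2).
#' @param threshold Flagging threshold on the measure (default 0.9).
#' @param n_candidates Prefilter pool size (default 50).
#' @param thresholds Segmentation thresholds.
#' @param gen_masks,train_masks Optional precomputed boundary masks.
#' @return Object of class `dgm_memorization`: tibble with `image_id`,
#'   `measure`, `best_match`, `flagged`, plus the threshold used.
#' @export
memorization_measure <- function(gen, train, radius = 2, threshold = 0.9,
                                 n_candidates = 50,
                                 thresholds = segmentation_thresholds(),
                                 gen_masks = NULL, train_masks = NULL) {
  gm <- gen_masks %||% boundary_masks(gen, radius, thresholds)
  tm <- train_masks %||% boundary_masks(train, radius, thresholds)
  tmat <- masks_to_matrix(tm)
  pooled <- lapply(tm, block_maxpool, factor = 4L)
  pmat <- masks_to_matrix(pooled)
  n_empty <- 0L
  res <- lapply(seq_along(gm), function(i) {
    mask <- gm[[i]]
    if (!any(mask)) {
      n_empty <<- n_empty + 1L
      return(c(measure = 0, best = NA_integer_))
    }
    cand <- seq_len(ncol(tmat))
    if (is.finite(n_candidates) && n_candidates < length(cand)) {
      pc <- binary_corr(as.logical(block_maxpool(mask, 4L)), pmat)
      cand <- order(pc, decreasing = TRUE)[seq_len(n_candidates)]
    }
    cc <- binary_corr(as.logical(mask), tmat[, cand, drop = FALSE])
    best <- which.max(cc)
    c(measure = max(0, cc[best]), best = cand[best])
  })
  if (n_empty > 0)
    warn(sprintf("%d generated images had an empty boundary mask (measure 0)",
                 n_empty))
  m <- do.call(rbind, res)
  out <- tibble(image_id = names(gm),
                measure = m[, "measure"],
                best_match = names(tm)[m[, "best"]],
                flagged = m[, "measure"] > threshold)
  structure(list(report = out, threshold = threshold, radius = radius,
                 n_candidates = n_candidates),
            class = "dgm_memorization")
}

#' @export
print.dgm_memorization <- function(x, ...) {
  cat(sprintf("<dgm_memorization> %d images, %d flagged at threshold %.3f\n",
              nrow(x$report), sum(x$report$flagged), x$threshold))
  invisible(x)
}

#' @method tidy dgm_memorization
#' @export
tidy.dgm_memorization <- function(x, ...) x$report

#' @method glance dgm_memorization
#' @export
glance.dgm_memorization <- function(x, ...) {
  tibble(n_images = nrow(x$report), n_flagged = sum(x$report$flagged),
         max_measure = max(x$report$measure), threshold = x$threshold)
}

#' Calibrate the memorization threshold on held-out training images
#'
#' Measures `n_holdout` randomly held-out training images against the
#' remainder of the ensemble and returns `max + 1 sd` of the held-out
#' measures. A degenerate spread (sd 0) returns the maximum with a warning.
#'
#' @param train Ensemble, list of images, or directory.
#' @param n_holdout Held-out subset size (default 3000; must be smaller than
#'   the ensemble).
#' @param seed Seed for the holdout draw.
#' @inheritParams memorization_measure
#' @return Object of class `dgm_mem_calibration`: list with `threshold`,
#'   `measures`, `max`, `sd`.
#' @export
calibrate_memorization_threshold <- function(train, n_holdout = 3000,
                                             seed = 1L, radius = 2,
                                             n_candidates = 50,
                                             thresholds = segmentation_thresholds()) {
  masks <- boundary_masks(train, radius, thresholds)
  n <- length(masks)
  if (n_holdout >= n)
    abort(sprintf("n_holdout (%d) must be smaller than the ensemble (%d)",
                  n_holdout, n))
  hold <- with_seed(seed, sample.int(n, n_holdout))
  mm <- memorization_measure(gen = NULL, train = NULL, radius = radius,
                             threshold = 1, n_candidates = n_candidates,
                             gen_masks = masks[hold],
                             train_masks = masks[-hold])
  meas <- mm$report$measure
  s <- stats::sd(meas)
  if (is.na(s) || s == 0) {
    warn("degenerate calibration spread (sd = 0); threshold set to the maximum")
    s <- 0
  }
  structure(list(threshold = max(meas) + s, measures = meas,
                 max = max(meas), sd = s, n_holdout = n_holdout, seed = seed),
            class = "dgm_mem_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
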