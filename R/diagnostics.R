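# Class-based analyses (prevalence, density/coverage in top-2 PC space),
# ensemble-mean semivariance, and artifact detectors.

#' Classify a breast image by glandularity
#'
#' Rule-based class predictor: the glandular fraction g = G / (G + F) of the
#' segmented map against the class bands (left-closed; defaults =
#' generator bands). Replaces a learned classifier; class in this data is
#' glandularity-driven by construction.
#'
#' @param label_map Segmented label map.
#' @param bands Named lower band edges as from [glandularity_bands()].
#' @return Breast class string.
#' @export
classify_by_glandularity <- function(label_map, bands = glandularity_bands()) {
  f <- sum(label_map == 1L); g <- sum(label_map == 2L)
  if (f + g == 0) abort("no fat or glandular tissue present")
  if (g == 0) {
    warn("no glandular tissue; classifying as fatty")
    return(names(bands)[1])
  }
  gf <- g / (f + g)
  names(bands)[findInterval(gf, unname(bands))]
}

#' k-NN density and coverage of a generated set
#'
#' With `NND_k(x)` the distance from training point `x` to its k-th nearest
#' training neighbour: density is the mean, over generated points and
#' training balls, of ball membership scaled by `1/k` (fidelity; `(k+1)/k`
#' for an identical point set), and coverage is the fraction of training
#' points whose ball contains at least one generated point (diversity; 1
#' for an identical set). Computed overall and per class when labels are
#' given; a class with fewer than `k + 1` training points is missing.
#'
#' @param train_pts,gen_pts Numeric matrices (rows = points), typically
#'   top-2 PC scores.
#' @param k Neighbourhood size (default 5).
#' @param train_class,gen_class Optional class labels for per-class results.
#' @return Tibble with columns `class` ("overall" plus classes), `density`,
#'   `coverage`, `n_train`, `n_gen`.
#' @export
density_coverage <- function(train_pts, gen_pts, k = 5,
                             train_class = NULL, gen_class = NULL) {
  one <- function(x, y) {
    x <- as.matrix(x); y <- as.matrix(y)
    n <- nrow(x); m <- nrow(y)
    if (n < k + 1) return(c(density = NA_real_, coverage = NA_real_))
    dxx <- as.matrix(stats::dist(x))
    nnd <- apply(dxx, 1, function(r) sort(r)[k + 1])  # k-th nonself neighbour
    d2 <- outer(rowSums(x^2), rep(1, m)) +
      outer(rep(1, n), rowSums(y^2)) - 2 * x %*% t(y)
    d2[d2 < 0] <- 0
    # n x m: generated j inside the ball of training i (tolerance keeps the
    # k-th neighbour itself inside despite floating-point noise)
    inside <- sqrt(d2) <= nnd + 1e-9 * (nnd + 1)
    c(density = sum(inside) / (k * m), coverage = mean(rowSums(inside) > 0))
  }
  res <- list(c(class = "overall", one(train_pts, gen_pts),
                n_train = nrow(as.matrix(train_pts)),
                n_gen = nrow(as.matrix(gen_pts))))
  if (!is.null(train_class) && !is.null(gen_class)) {
    for (cl in unique(train_class)) {
      ti <- train_class == cl; gi <- gen_class == cl
      v <- if (sum(gi) > 0) one(as.matrix(train_pts)[ti, , drop = FALSE],
                                as.matrix(gen_pts)[gi, , drop = FALSE])
      else c(density = NA_real_, coverage = NA_real_)
      res <- c(res, list(c(class = cl, v, n_train = sum(ti), n_gen = sum(gi))))
    }
  }
  out <- as_tibble(do.call(rbind, res))
  out$density <- as.numeric(out$density)
  out$coverage <- as.numeric(out$coverage)
  out$n_train <- as.integer(out$n_train)
  out$n_gen <- as.integer(out$n_gen)
  out
}

#' Isotropic empirical semivariogram of an image
#'
#' `gamma(h) = 0.5 * mean[(z_p - z_q)^2]` over sampled pixel pairs within
#' the support whose separation falls in `[h - 0.5, h + 0.5)`.
#'
#' @param img Numeric image matrix.
#' @param support Logical mask of pixels to use.
#' @param lag_max Largest lag in pixels (default 100).
#' @param n_pair_samples Pairs sampled per lag (default 2000).
#' @param seed RNG seed.
#' @return Tibble with `lag`, `gamma`, `n_pairs`.
#' @export
image_semivariance <- function(img, support = NULL, lag_max = 100,
                               n_pair_samples = 2000, seed = 1L) {
  if (is.null(support)) support <- matrix(TRUE, nrow(img), ncol(img))
  idx <- which(support)
  if (!length(idx)) abort("empty support")
  nr <- nrow(img)
  py <- (idx - 1L) %% nr + 1L
  px <- (idx - 1L) %/% nr + 1L
  inb <- matrix(FALSE, nrow(img), ncol(img)); inb[idx] <- TRUE
  with_seed(seed, {
    rows <- lapply(seq_len(lag_max), function(h) {
      s <- sample.int(length(idx), n_pair_samples, replace = TRUE)
      th <- runif(n_pair_samples, 0, 2 * pi)
      qy <- round(py[s] + h * sin(th))
      qx <- round(px[s] + h * cos(th))
      ok <- qy >= 1 & qy <= nr & qx >= 1 & qx <= ncol(img)
      ok[ok] <- inb[cbind(qy[ok], qx[ok])]
      if (!any(ok)) return(tibble(lag = h, gamma = NA_real_, n_pairs = 0L))
      d2 <- (img[cbind(py[s][ok], px[s][ok])] - img[cbind(qy[ok], qx[ok])])^2
      tibble(lag = h, gamma = mean(d2) / 2, n_pairs = sum(ok))
    })
    dplyr::bind_rows(rows)
  })
}

#' Semivariance of the ensemble-mean image
#'
#' Computes the pixelwise mean image of the ensemble, restricts to pixels
#' where the mean exceeds a small threshold, and returns its isotropic
#' semivariogram with a sill estimate (mean of gamma over the last quartile
#' of lags) and a flatness measure (relative slope of a linear fit over that
#' tail). A flat, low sill indicates an ergodic (diverse) ensemble — pixel
#' position carries no tissue identity; persistent structure in the mean
#' image raises and tilts the tail.
#'
#' Because object sizes vary across an ensemble, the mean image always
#' carries a smooth ramp near the edge of the union footprint; that ramp
#' reflects size variation, not positional tissue bias. Setting `erode_px`
#' (and a `support_threshold` near the bulk intensity) restricts the
#' analysis to the interior bulk, where an ergodic ensemble is flat.
#'
#' @param x Ensemble, list of images, or directory.
#' @param lag_max Largest lag (default 100, clipped to half the image side).
#' @param n_pair_samples Pairs sampled per lag.
#' @param support_threshold Mean-intensity threshold defining the support.
#' @param erode_px Erode the support by this many pixels (default 0: the
#'   full support).
#' @param seed RNG seed.
#' @return Object of class `dgm_semivariance`: list with `variogram`
#'   (tibble), `sill`, `rel_slope`, `mean_image`.
#' @export
mean_image_semivariance <- function(x, lag_max = 100, n_pair_samples = 2000,
                                    support_threshold = 1, erode_px = 0,
                                    seed = 1L) {
  imgs <- ensemble_images(x)
  if (length(imgs) < 2) abort("need at least 2 images")
  mi <- Reduce(`+`, lapply(imgs, function(m) m / length(imgs)))
  support <- mi > support_threshold
  if (erode_px > 0 && any(support))
    support <- support & distmap_mat(support) > erode_px
  lag_max <- min(lag_max, floor(min(dim(mi)) / 2))
  vg <- image_semivariance(mi, support, lag_max, n_pair_samples, seed)
  tail_idx <- vg$lag > 0.75 * lag_max & is.finite(vg$gamma)
  sill <- mean(vg$gamma[tail_idx])
  fit <- stats::lm(gamma ~ lag, data = vg[tail_idx, ])
  rel_slope <- stats::coef(fit)[[2]] * lag_max / max(sill, 1e-12)
  structure(list(variogram = vg, sill = sill, rel_slope = rel_slope,
                 mean_image = mi, support = support),
            class = "dgm_semivariance")
}

#' @method tidy dgm_semivariance
#' @export
tidy.dgm_semivariance <- function(x, ...) x$variogram

#' @method glance dgm_semivariance
#' @export
glance.dgm_semivariance <- function(x, ...) {
  tibble(sill = x$sill, rel_slope = x$rel_slope,
         support_px = sum(x$support))
}

#' @method autoplot dgm_semivariance
#' @export
autoplot.dgm_semivariance <- function(object, ...) {
  ggplot2::ggplot(object$variogram, ggplot2::aes(.data$lag, .data$gamma)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$sill, linetype = 2) +
    ggplot2::labs(x = "lag h (px)", y = expression(gamma(h)),
                  title = sprintf("sill = %.2f", object$sill)) +
    ggplot2::theme_minimal()
}

# Convexity-perimeter ratio of the breast (foreground) mask: convex-hull
# perimeter over outer-contour perimeter; <= 1 + eps up to discretisation.
breast_convexity_perimeter <- function(mask) {
  mask <- largest_component(mask)
  if (!any(mask)) return(NA_real_)
  rc <- which(mask, arr.ind = TRUE)
  cont <- object_contours(mask * 1L)[[1]]
  per <- chain_length(cont)
  if (per <= 0) return(NA_real_)
  hull_stats(rc)$perimeter / per
}

#' Scan an ensemble for known generation artifacts
#'
#' Per image: breast-mask convexity-perimeter ratio (values below
#' `convexity_threshold` flag boundary breaks), disconnected-skeleton count
#' and median bounded-region area, background statistics (fraction of
#' nonzero background pixels and mean/sd of their values), and the
#' glandularity class. Ensemble level: a ligament-sticking score (mean
#' pairwise zero-lag correlation of ligament masks over sampled pairs; near
#' 1 means a constant ligament structure) and the lacunarity distribution of
#' the glandular mask restricted to images classified heterogeneous. When a
#' training reference is given its sticking score and heterogeneous
#' lacunarity distribution are attached for comparison.
#'
#' @param x Ensemble, list of images, or directory.
#' @param train_reference Optional training ensemble for reference values.
#' @param convexity_threshold Boundary-break flag threshold (default 0.9).
#' @param n_stick_pairs Sampled mask pairs for the sticking score (default
#'   1000; exact all-pairs when fewer exist).
#' @param thresholds Segmentation thresholds.
#' @param seed RNG seed for pair sampling.
#' @return Object of class `dgm_artifacts`: list with `per_image` (tibble),
#'   `sticking_score`, `train_sticking_score`, `het_lacunarity`,
#'   `train_het_lacunarity`, `n_failed`.
#' @export
artifact_scan <- function(x, train_reference = NULL,
                          convexity_threshold = 0.9, n_stick_pairs = 1000,
                          thresholds = segmentation_thresholds(), seed = 1L) {
  scan_one_side <- function(imgs) {
    ids <- names(imgs)
    lig_masks <- vector("list", length(imgs))
    rows <- vector("list", length(imgs))
    for (i in seq_along(imgs)) {
      im <- imgs[[i]]
      row <- tryCatch({
        lm <- segment_tissues(im, thresholds)
        bg <- lm == 0L
        bgv <- im[bg]
        nz <- bgv[bgv > 0]
        lig_masks[[i]] <- lm == 4L
        sk <- skeleton_features(lm)
        conv <- breast_convexity_perimeter(lm > 0L)
        lac <- lacunarity(lm == 2L)
        tibble(image_id = ids[i],
               convexity_perimeter = conv,
               boundary_break = is.finite(conv) & conv < convexity_threshold,
               n_skeletons = sk[["skel_n_skeletons"]],
               median_region_area = sk[["skel_region_area_q2"]],
               background_fraction = mean(bgv > 0),
               background_mean = if (length(nz)) mean(nz) else 0,
               background_sd = if (length(nz) > 1) stats::sd(nz) else 0,
               glandular_lacunarity = mean(lac, na.rm = TRUE),
               class = classify_by_glandularity(lm),
               failed = FALSE)
      }, error = function(e)
        tibble(image_id = ids[i], convexity_perimeter = NA_real_,
               boundary_break = NA, n_skeletons = NA_real_,
               median_region_area = NA_real_, background_fraction = NA_real_,
               background_mean = NA_real_, background_sd = NA_real_,
               glandular_lacunarity = NA_real_, class = NA_character_,
               failed = TRUE))
      rows[[i]] <- row
    }
    list(per_image = dplyr::bind_rows(rows), lig_masks = lig_masks)
  }
  sticking <- function(lig_masks, seed_off = 0L) {
    ok <- !vapply(lig_masks, is.null, logical(1))
    masks <- lig_masks[ok]
    n <- length(masks)
    if (n < 2) return(NA_real_)
    all_pairs <- n * (n - 1) / 2
    with_seed(seed + seed_off, {
      if (all_pairs <= n_stick_pairs) {
        pr <- t(utils::combn(n, 2))
      } else {
        k <- sample.int(n * (n - 1), n_stick_pairs)
        i <- (k - 1L) %% n + 1L
        j <- (k - 1L) %/% n + 1L
        j <- j + (j >= i)
        pr <- cbind(i, j)
      }
      mean(vapply(seq_len(nrow(pr)), function(r)
        binary_corr(as.logical(masks[[pr[r, 1]]]),
                    matrix(as.logical(masks[[pr[r, 2]]]), ncol = 1)),
        numeric(1)))
    })
  }
  imgs <- ensemble_images(x)
  main <- scan_one_side(imgs)
  het <- main$per_image$class %in% "heterogeneous"
  train_stick <- NA_real_
  train_lac <- NULL
  if (!is.null(train_reference)) {
    tr <- scan_one_side(ensemble_images(train_reference))
    train_stick <- sticking(tr$lig_masks, 1L)
    train_lac <- tr$per_image$glandular_lacunarity[
      tr$per_image$class %in% "heterogeneous"]
  }
  structure(list(per_image = main$per_image,
                 sticking_score = sticking(main$lig_masks),
                 train_sticking_score = train_stick,
                 het_lacunarity = main$per_image$glandular_lacunarity[het],
                 train_het_lacunarity = train_lac,
                 n_failed = sum(main$per_image$failed)),
            class = "dgm_artifacts")
}

#' @method tidy dgm_artifacts
#' @export
tidy.dgm_artifacts <- function(x, ...) x$per_image

#' @method glance dgm_artifacts
#' @export
glance.dgm_artifacts <- function(x, ...) {
  tibble(n_images = nrow(x$per_image),
         n_boundary_break = sum(x$per_image$boundary_break, na.rm = TRUE),
         mean_background_fraction = mean(x$per_image$background_fraction,
                                         na.rm = TRUE),
         sticking_score = x$sticking_score,
         train_sticking_score = x$train_sticking_score,
         n_failed = x$n_failed)
}

#' PC scatter of training vs generated features
#'
#' @param train,gen Feature tables.
#' @param model Optional fitted [fit_pc_space()]; fitted on `train` if
#'   missing.
#' @return A ggplot of the top-2 PC scores.
#' @export
plot_pc_scatter <- function(train, gen, model = NULL) {
  if (is.null(model)) model <- fit_pc_space(train, n_components = 2)
  st <- project_pc(model, train, 2)
  sg <- project_pc(model, gen, 2)
  df <- dplyr::bind_rows(
    tibble(set = "training", pc1 = st[, 1], pc2 = st[, 2]),
    tibble(set = "generated", pc1 = sg[, 1], pc2 = sg[, 2]))
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                   colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
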