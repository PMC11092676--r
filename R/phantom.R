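# Synthetic anthropomorphic-slice generator: procedural 2D tissue layouts
# (superellipse outline, thin skin band, Voronoi-skeleton ligaments,
# class-dependent glandular compartments) with prescribed per-tissue
# affine-scaled Beta intensity laws and Gaussian-smoothed texture.

BREAST_CLASSES <- c("fatty", "scattered", "heterogeneous", "dense")

TISSUE_LABELS <- c(background = 0L, fat = 1L, glandular = 2L,
                   skin = 3L, ligament = 4L)

#' Per-tissue intensity model
#'
#' The four retained tissues carry affine-scaled Beta intensity laws
#' `scale * X + offset`, `X ~ Beta(alpha, beta)`, chosen so tissues occupy
#' separable gray-level bands: fat `60 X + 52` with Beta(2, 4), glandular
#' `96 X + 128` with Beta(4, 2), skin `16 X + 228` with Beta(3, 3) and
#' ligament `16 X + 232` with Beta(3, 3). Texture is induced by Gaussian
#' smoothing (`sigma`, in pixels) followed by rank-based restoration of the
#' prescribed marginal.
#'
#' @param sigma Gaussian smoothing parameter in pixels (default 0.8).
#' @param tissues Data frame overriding the default per-tissue parameters;
#'   columns `tissue, scale, offset, alpha, beta`.
#' @return An object of class `dgm_intensity_model`.
#' @export
intensity_model <- function(sigma = 0.8, tissues = NULL) {
  if (is.null(tissues)) {
    tissues <- tibble(
      tissue = c("fat", "glandular", "skin", "ligament"),
      scale  = c(60, 96, 16, 16),
      offset = c(52, 128, 228, 232),
      alpha  = c(2, 4, 3, 3),
      beta   = c(4, 2, 3, 3)
    )
  }
  tissues <- as_tibble(tissues)
  stopifnot(all(c("tissue", "scale", "offset", "alpha", "beta") %in% names(tissues)))
  if (any(tissues$offset < 0 | tissues$scale + tissues$offset > 255))
    abort("per-tissue support [offset, scale + offset] must lie within [0, 255]")
  structure(list(tissues = tissues, sigma = sigma, bit_depth = 8L),
            class = "dgm_intensity_model")
}

#' Glandularity bands defining the four breast classes
#'
#' Breast class is driven by the glandular fraction g = G / (G + F).
#' Bands are left-closed: fatty `[0, 0.20)`, scattered `[0.20, 0.40)`,
#' heterogeneous `[0.40, 0.65)`, dense `[0.65, 1]`.
#'
#' @return Named numeric vector of lower band edges, one per class.
#' @export
glandularity_bands <- function() {
  c(fatty = 0, scattered = 0.20, heterogeneous = 0.40, dense = 0.65)
}

#' Generator configuration
#'
#' @param n_images Number of images in the ensemble.
#' @param image_size Side length in pixels (square images, >= 64; default 512).
#' @param prevalence Named class prevalence, normalised to sum 1. Default is
#'   the population-motivated 1:4:4:1 over fatty, scattered, heterogeneous,
#'   dense.
#' @param class_targets Named list of per-class glandular-fraction target
#'   ranges, each `c(lo, hi)`; the per-image target is drawn uniformly.
#' @param fraction_tol Tolerance on the achieved glandular fraction relative
#'   to the per-image target (default 0.05).
#' @param ligament_seed_density Interior Voronoi seeds per pixel of interior
#'   area (default 1.3e-3, giving cells tens of pixels across at side 512).
#' @param skin_width Skin band width in pixels, 2-3 typical (default 3).
#' @param seed Integer RNG seed; seeded runs are bit-reproducible.
#' @return An object of class `dgm_generator_config`.
#' @export
generator_config <- function(n_images = 100,
                             image_size = 512,
                             prevalence = c(fatty = 1, scattered = 4,
                                            heterogeneous = 4, dense = 1),
                             class_targets = list(
                               fatty = c(0.06, 0.17),
                               scattered = c(0.22, 0.38),
                               heterogeneous = c(0.42, 0.62),
                               dense = c(0.66, 0.80)),
                             fraction_tol = 0.05,
                             ligament_seed_density = 1.3e-3,
                             skin_width = 3,
                             seed = 1L) {
  if (image_size < 64) abort("image_size must be at least 64")
  if (!setequal(names(prevalence), BREAST_CLASSES))
    abort("prevalence must be named with the four breast classes")
  prevalence <- prevalence[BREAST_CLASSES] / sum(prevalence)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 prevalence = prevalence,
                 class_targets = class_targets[BREAST_CLASSES],
                 fraction_tol = fraction_tol,
                 ligament_seed_density = ligament_seed_density,
                 skin_width = skin_width,
                 seed = as.integer(seed)),
            class = "dgm_generator_config")
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Star-shaped breast outline: superellipse radius with low-order random
# radial perturbation, guaranteed single connected component.
sample_outline_mask <- function(size) {
  cx <- size / 2 + runif(1, -0.02, 0.02) * size
  cy <- size / 2 + runif(1, -0.02, 0.02) * size
  r0 <- size * runif(1, 0.33, 0.40)
  ecc <- runif(1, 0.85, 1.1)
  p <- runif(1, 1.9, 2.6)
  a_k <- rnorm(3, 0, 0.025)
  phi <- runif(3, 0, 2 * pi)
  egg <- runif(1, 0.02, 0.06)
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # col index
  ys <- matrix(rep(seq_len(size), size), size, size)         # row index
  dx <- xs - cx
  dy <- ys - cy
  th <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  r_se <- (abs(cos(th) / 1)^p + abs(sin(th) / ecc)^p)^(-1 / p) * r0
  pert <- 1 + egg * cos(th) +
    a_k[1] * cos(2 * th + phi[1]) +
    a_k[2] * cos(3 * th + phi[2]) +
    a_k[3] * cos(4 * th + phi[3])
  lim <- (size / 2 - 3) / max(r_se * pert)
  if (lim < 1) r_se <- r_se * lim
  rr <= r_se * pmax(pert, 0.5)
}

distmap_mat <- function(mask) {
  d <- EBImage::distmap(mask * 1)
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# Voronoi labels of interior pixels for given seed points; 0 outside.
voronoi_labels <- function(interior, seeds_rc) {
  idx <- which(interior)
  nr <- nrow(interior)
  py <- (idx - 1L) %% nr + 1L
  px <- (idx - 1L) %/% nr + 1L
  best_d <- rep(Inf, length(idx))
  best_i <- rep(0L, length(idx))
  for (s in seq_len(nrow(seeds_rc))) {
    d <- (py - seeds_rc[s, 1])^2 + (px - seeds_rc[s, 2])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- s
  }
  v <- matrix(0L, nrow(interior), ncol(interior))
  v[idx] <- best_i
  v
}

# Draw a spiculated "burst" star; returns logical mask of its pixels.
burst_mask <- function(size, center_rc, n_spikes, max_len) {
  m <- matrix(FALSE, size, size)
  angles <- runif(n_spikes, 0, 2 * pi)
  lens <- runif(n_spikes, 0.35, 1) * max_len
  for (k in seq_len(n_spikes)) {
    t <- seq(0, 1, length.out = ceiling(lens[k] * 2))
    rr <- round(center_rc[1] + t * lens[k] * sin(angles[k]))
    cc <- round(center_rc[2] + t * lens[k] * cos(angles[k]))
    ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
    m[cbind(rr[ok], cc[ok])] <- TRUE
    # thicken the spike root
    root <- t < 0.4
    rr2 <- rr[ok & root] + 1L
    ok2 <- rr2 <= size
    m[cbind(rr2[ok2], cc[ok & root][ok2])] <- TRUE
  }
  m
}

#' Sample a tissue layout for one breast class
#'
#' Builds a procedural 2D stand-in for a coronal phantom slice: an egg-like
#' foreground region (single connected component), a thin peripheral skin
#' band, interior ligaments as the skeletonised edges of a Voronoi
#' tessellation of Poisson-sampled seeds (1-pixel-wide curves partitioning
#' the interior into bounded compartments), and glandular compartments
#' accreted around a random focus until the class glandular-fraction target
#' is met (the last compartment is trimmed so the achieved fraction matches
#' the target to within `config$fraction_tol`). Heterogeneous layouts
#' additionally receive spiculated "burst" glandular stars.
#'
#' @param breast_class One of `"fatty"`, `"scattered"`, `"heterogeneous"`,
#'   `"dense"`.
#' @param config A [generator_config()].
#' @param seed Integer seed for this layout.
#' @return An object of class `dgm_layout`: list with integer `label_map`
#'   (0 background, 1 fat, 2 glandular, 3 skin, 4 ligament), `breast_class`
#'   and achieved `glandular_fraction`.
#' @export
sample_layout <- function(breast_class, config = generator_config(), seed = 1L) {
  breast_class <- match.arg(breast_class, BREAST_CLASSES)
  with_seed(seed, {
    size <- config$image_size
    fg <- largest_component(sample_outline_mask(size))
    d <- distmap_mat(fg)
    skin <- fg & d <= config$skin_width & d > 0
    interior <- fg & !skin
    n_int <- sum(interior)
    n_seeds <- max(6L, round(config$ligament_seed_density * n_int))
    int_idx <- which(interior)
    tr <- config$class_targets[[breast_class]]
    target <- runif(1, tr[1], tr[2])
    for (attempt in 1:25) {
      sel <- sample(int_idx, n_seeds)
      nr <- size
      seeds_rc <- cbind((sel - 1L) %% nr + 1L, (sel - 1L) %/% nr + 1L)
      v <- voronoi_labels(interior, seeds_rc)
      edge <- (v != shift_mat(v, 0, 1, -1L) | v != shift_mat(v, 1, 0, -1L)) &
        interior
      lig <- thin_mask(edge) & interior
      tissue <- interior & !lig
      gland <- matrix(FALSE, size, size)
      if (breast_class == "heterogeneous") {
        nb <- sample(2:4, 1)
        for (b in seq_len(nb)) {
          ctr <- sel[sample.int(length(sel), 1)]
          ctr_rc <- c((ctr - 1L) %% nr + 1L, (ctr - 1L) %/% nr + 1L)
          gland <- gland | (burst_mask(size, ctr_rc, sample(8:14, 1),
                                       size * runif(1, 0.06, 0.13)) & tissue)
        }
      }
      n_tissue <- sum(tissue)
      n_target <- target * n_tissue
      # accrete whole Voronoi compartments around a random focus
      focus <- seeds_rc[sample.int(n_seeds, 1), ]
      ord <- order(sqrt((seeds_rc[, 1] - focus[1])^2 +
                          (seeds_rc[, 2] - focus[2])^2) +
                     rnorm(n_seeds, 0, size * 0.04))
      g_count <- sum(gland)
      for (ci in ord) {
        if (g_count >= n_target) break
        cell <- which(v == ci & tissue & !gland)
        if (!length(cell)) next
        need <- n_target - g_count
        if (length(cell) > need) {
          # trim the final compartment: keep pixels nearest its seed
          cy <- (cell - 1L) %% nr + 1L
          cx <- (cell - 1L) %/% nr + 1L
          dd <- (cy - seeds_rc[ci, 1])^2 + (cx - seeds_rc[ci, 2])^2
          cell <- cell[order(dd)][seq_len(round(need))]
        }
        gland[cell] <- TRUE
        g_count <- sum(gland)
      }
      g <- g_count / n_tissue
      if (abs(g - target) <= config$fraction_tol && g_count > 0 &&
          g_count < n_tissue)
        break
      if (attempt == 25)
        abort(sprintf(
          "could not reach glandular-fraction target %.3f for class '%s'",
          target, breast_class))
    }
    label_map <- matrix(TISSUE_LABELS[["background"]], size, size)
    label_map[interior & !lig] <- TISSUE_LABELS[["fat"]]
    label_map[gland] <- TISSUE_LABELS[["glandular"]]
    label_map[skin] <- TISSUE_LABELS[["skin"]]
    label_map[lig] <- TISSUE_LABELS[["ligament"]]
    storage.mode(label_map) <- "integer"
    structure(list(label_map = label_map,
                   breast_class = breast_class,
                   glandular_fraction = g),
              class = "dgm_layout")
  })
}

gblur_mat <- function(m, sigma) {
  r <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(r), nrow(m), ncol(m))
}

# Rank-based restoration of the affine-scaled Beta marginal after smoothing.
# The analytic quantile grid depends only on (n, alpha, beta) and is cached.
qbeta_grid_env <- new.env(parent = emptyenv())

qbeta_grid <- function(n, alpha, beta) {
  key <- sprintf("%d_%g_%g", n, alpha, beta)
  g <- qbeta_grid_env[[key]]
  if (is.null(g)) {
    g <- qbeta((seq_len(n) - 0.5) / n, alpha, beta)
    qbeta_grid_env[[key]] <- g
  }
  g
}

restore_marginal <- function(field, scale, offset, alpha, beta) {
  n <- length(field)
  r <- rank(field, ties.method = "first")
  offset + scale * qbeta_grid(n, alpha, beta)[r]
}

#' Render a tissue layout into an 8-bit grayscale image
#'
#' For each tissue a full-size field of Beta variates is drawn, smoothed with
#' a Gaussian filter (`sigma` from the model) to induce spatial correlation,
#' then rank-transformed back to the prescribed affine-scaled Beta marginal.
#' The four fields are masked by their tissue pixels and summed; background
#' pixels are exactly 0. Quantisation to 8 bits happens once at the end, by
#' round-half-to-even with clipping to `[0, 255]`.
#'
#' @param layout A [sample_layout()] result.
#' @param model An [intensity_model()].
#' @param seed Integer seed for the intensity fields.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
assign_intensities <- function(layout, model = intensity_model(), seed = 1L) {
  stopifnot(inherits(layout, "dgm_layout"), inherits(model, "dgm_intensity_model"))
  with_seed(seed, {
    lm <- layout$label_map
    out <- matrix(0, nrow(lm), ncol(lm))
    for (i in seq_len(nrow(model$tissues))) {
      tt <- model$tissues[i, ]
      mask <- lm == TISSUE_LABELS[[tt$tissue]]
      raw <- matrix(rbeta(length(lm), tt$alpha, tt$beta), nrow(lm), ncol(lm))
      sm <- gblur_mat(raw, model$sigma)
      restored <- restore_marginal(sm, tt$scale, tt$offset, tt$alpha, tt$beta)
      out[mask] <- restored[mask]
    }
    img <- pmin(pmax(round(out), 0), 255)
    storage.mode(img) <- "integer"
    img
  })
}

#' Largest-remainder allocation of class counts
#'
#' Allocates `n` images to the four classes so counts sum to `n` and match
#' the prevalence as closely as possible; remainders are assigned by largest
#' fractional part, ties broken in class order (fatty, scattered,
#' heterogeneous, dense).
#'
#' @param n Total number of images.
#' @param prevalence Named prevalence vector (normalised internally).
#' @return Named integer vector of per-class counts summing to `n`.
#' @export
allocate_prevalence <- function(n, prevalence = generator_config()$prevalence) {
  p <- prevalence[BREAST_CLASSES]
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), BREAST_CLASSES)
}

#' Generate a training-like phantom ensemble
#'
#' Draws layouts and intensities for `config$n_images` images with exact
#' largest-remainder class allocation, optionally writing lossless 8-bit
#' grayscale PNGs plus a manifest CSV (`filename,class,glandular_fraction,seed`).
#' Runs are bit-reproducible given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory for PNGs and `manifest.csv`, or `NULL` to
#'   keep the ensemble in memory only.
#' @param model An [intensity_model()].
#' @param keep_images Keep the image matrices in the returned object
#'   (default `TRUE` when `out_dir` is `NULL`).
#' @param keep_layouts Keep ground-truth layouts (default `FALSE`).
#' @param progress Print progress every 100 images.
#' @return An object of class `dgm_ensemble`: list with `manifest` (tibble),
#'   `images` (list of integer matrices or `NULL`), `layouts` (optional) and
#'   the `config` used.
#' @export
generate_ensemble <- function(config = generator_config(), out_dir = NULL,
                              model = intensity_model(),
                              keep_images = is.null(out_dir),
                              keep_layouts = FALSE,
                              progress = FALSE) {
  counts <- allocate_prevalence(config$n_images, config$prevalence)
  classes <- rep(BREAST_CLASSES, counts)
  n <- length(classes)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, n))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  images <- if (keep_images) vector("list", n)
  layouts <- if (keep_layouts) vector("list", n)
  fnames <- sprintf("img_%05d.png", seq_len(n))
  gfrac <- numeric(n)
  for (i in seq_len(n)) {
    lay <- sample_layout(classes[i], config, seed = seeds[i])
    img <- assign_intensities(lay, model, seed = seeds[i] %% 2147483646L + 1L)
    gfrac[i] <- lay$glandular_fraction
    if (keep_images) images[[i]] <- img
    if (keep_layouts) layouts[[i]] <- lay
    if (!is.null(out_dir)) write_image8(img, file.path(out_dir, fnames[i]))
    if (progress && i %% 100 == 0) message(sprintf("  generated %d / %d", i, n))
  }
  manifest <- tibble(filename = fnames, class = classes,
                     glandular_fraction = gfrac, seed = seeds)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(manifest = manifest, images = images, layouts = layouts,
                 config = config),
            class = "dgm_ensemble")
}

#' @export
print.dgm_ensemble <- function(x, ...) {
  cat(sprintf("<dgm_ensemble> %d images, side %d\n",
              nrow(x$manifest), x$config$image_size))
  print(table(x$manifest$class)[BREAST_CLASSES])
  invisible(x)
}
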