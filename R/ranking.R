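# Stage-2 ranking: PCA of training features, cosine-distance distributions in
# the top-PC space, bootstrapped two-sample KS statistic; plus the Frechet
# distance used in stage-1 screening.

#' Frechet distance between Gaussian fits of two embedding sets
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`, with covariances
#' regularised by `epsilon * I`. The matrix square root is taken through the
#' symmetric form `S1^{1/2} S2 S1^{1/2}` (eigendecomposition with negative
#' eigenvalues clamped at zero), so no imaginary residue can arise.
#'
#' @param a,b Numeric matrices, one embedding vector per row.
#' @param epsilon Covariance ridge (default 1e-6).
#' @return Scalar distance (0 for identical sets).
#' @export
frechet_distance <- function(a, b, epsilon = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  for (nmx in list(list(a, "a"), list(b, "b"))) {
    bad <- which(!stats::complete.cases(nmx[[1]]) |
                   apply(nmx[[1]], 1, function(r) any(!is.finite(r))))
    if (length(bad))
      abort(sprintf("non-finite embeddings in '%s', rows: %s", nmx[[2]],
                    paste(head(bad, 5), collapse = ", ")))
  }
  if (ncol(a) != ncol(b)) abort("embedding dimensions differ")
  d <- ncol(a)
  mu1 <- colMeans(a); mu2 <- colMeans(b)
  s1 <- stats::cov(a) + diag(epsilon, d)
  s2 <- stats::cov(b) + diag(epsilon, d)
  e1 <- eigen(s1, symmetric = TRUE)
  s1h <- e1$vectors %*% (sqrt(pmax(e1$values, 0)) * t(e1$vectors))
  m <- s1h %*% s2 %*% s1h
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(sqrt(pmax(ev, 0)))
}

#' Embed an ensemble for the Frechet-distance screen
#'
#' The Frechet distance needs a fixed-length embedding per image. Named
#' embedders: `"feature-registry"` (the package's feature vector, missing
#' values imputed by ensemble column means), `"random-projection"` (seeded
#' Gaussian projection of raw pixels to `dim` components) and `"external"`
#' (pass-through of user-supplied `vectors`, e.g. from a pretrained network).
#'
#' @param x Ensemble, list of images, or feature table (for
#'   `"feature-registry"`).
#' @param method Embedder name.
#' @param vectors Matrix of externally computed embeddings.
#' @param dim Output dimension for the random projection.
#' @param seed Seed fixing the random projection.
#' @return Numeric matrix, one row per image.
#' @export
embed_ensemble <- function(x, method = c("feature-registry",
                                         "random-projection", "external"),
                           vectors = NULL, dim = 64, seed = 1L) {
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(vectors)) abort("external embedder needs 'vectors'")
    return(as.matrix(vectors))
  }
  if (method == "feature-registry") {
    tab <- if (is.data.frame(x)) x else feature_table(x)
    m <- feature_matrix(tab)
    mu <- colMeans(m, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
    return(m)
  }
  imgs <- if (inherits(x, "dgm_ensemble")) x$images else x
  stopifnot(is.list(imgs), length(imgs) >= 1)
  npix <- length(imgs[[1]])
  proj <- with_seed(seed, matrix(rnorm(npix * dim), npix, dim)) / sqrt(dim)
  t(vapply(imgs, function(im) as.numeric(crossprod(proj, as.numeric(im) / 255)),
           numeric(dim)))
}

#' Fit the training principal-component space
#'
#' Missing values are imputed with training column means, columns are
#' z-scored with training statistics (zero-variance columns dropped and
#' recorded), and PCA is fitted. The returned model carries everything
#' needed to project new feature tables; imputation and standardisation
#' always derive from the training side only.
#'
#' @param train Feature table (tibble from [feature_table()]) or numeric
#'   matrix.
#' @param n_components Number of components retained for projections.
#' @return Object of class `dgm_pc`.
#' @export
fit_pc_space <- function(train, n_components = 10) {
  x <- if (is.data.frame(train)) feature_matrix(train) else as.matrix(train)
  mu_imp <- colMeans(x, na.rm = TRUE)
  all_na <- !is.finite(mu_imp)
  for (j in which(!all_na)) x[is.na(x[, j]), j] <- mu_imp[j]
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  keep <- !all_na & is.finite(sc) & sc > 0
  if (!any(keep)) abort("no informative feature columns")
  if (nrow(x) <= n_components)
    abort(sprintf("need more than %d images to fit %d components",
                  n_components, n_components))
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sc[keep], "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  structure(list(impute_means = mu_imp, center = ctr, scale = sc,
                 keep = keep, rotation = pc$rotation,
                 sdev = pc$sdev,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 dropped = names(which(!keep)),
                 n_components = k),
            class = "dgm_pc")
}

#' Project a feature table into a fitted PC space
#'
#' @param model A [fit_pc_space()] model.
#' @param tab Feature table or matrix with the training columns.
#' @param n_components Components to return (default the model's).
#' @return Numeric score matrix, one row per image.
#' @export
project_pc <- function(model, tab, n_components = model$n_components) {
  x <- if (is.data.frame(tab)) feature_matrix(tab) else as.matrix(tab)
  x <- x[, names(model$impute_means), drop = FALSE]
  for (j in seq_len(ncol(x))) {
    v <- model$impute_means[j]
    x[is.na(x[, j]), j] <- if (is.finite(v)) v else 0
  }
  xs <- sweep(sweep(x[, model$keep, drop = FALSE], 2,
                    model$center[model$keep]), 2,
              model$scale[model$keep], "/")
  sc <- xs %*% model$rotation
  sc[, seq_len(min(n_components, ncol(sc))), drop = FALSE]
}

#' @method tidy dgm_pc
#' @export
tidy.dgm_pc <- function(x, ...) {
  rot <- x$rotation
  tibble(feature = rep(rownames(rot), ncol(rot)),
         component = rep(seq_len(ncol(rot)), each = nrow(rot)),
         loading = as.numeric(rot))
}

#' @method glance dgm_pc
#' @export
glance.dgm_pc <- function(x, ...) {
  tibble(n_features = length(x$impute_means),
         n_dropped = length(x$dropped),
         n_components = x$n_components,
         var_explained_retained = sum(x$var_explained[seq_len(x$n_components)]))
}

#' Sample cosine distances between two point sets
#'
#' Draws `n_pairs` index pairs without replacement (one point from each
#' side; for the within-set baseline, two distinct points) and returns
#' `1 - u . v / (|u| |v|)`. Zero-norm points give a distance computed against
#' resampled partners, with a warning.
#'
#' @param a Score matrix (rows = points), typically top-10 PC scores.
#' @param b Second score matrix, or `NULL` for the within-`a` baseline.
#' @param n_pairs Number of pairs to draw.
#' @return Numeric vector of length `n_pairs`.
#' @export
cosine_distance_distribution <- function(a, b = NULL, n_pairs = 10000) {
  a <- as.matrix(a)
  same <- is.null(b)
  b <- if (same) a else as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) abort("each side needs at least 2 points")
  total <- if (same) na * (nb - 1) else na * nb
  replace <- n_pairs > total
  k <- sample.int(total, n_pairs, replace = replace)
  i <- (k - 1L) %% na + 1L
  j <- (k - 1L) %/% na + 1L
  if (same) j <- j + (j >= i)
  u <- a[i, , drop = FALSE]; v <- b[j, , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  bad <- nu == 0 | nv == 0
  if (any(bad)) {
    warn(sprintf("%d zero-norm points encountered; pairs resampled",
                 sum(bad)))
    ok <- which(!bad)
    rep_idx <- sample(ok, sum(bad), replace = TRUE)
    i[bad] <- i[rep_idx]; j[bad] <- j[rep_idx]
    u <- a[i, , drop = FALSE]; v <- b[j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  }
  1 - rowSums(u * v) / (nu * nv)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs (tie-aware);
#' the statistic only, no test.
#'
#' @param x,y Numeric samples.
#' @return Scalar in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= nx, 1 / nx, -1 / ny))
  # evaluate only at the end of tie groups
  sw <- w[ord]
  last <- c(sw[-1] != sw[-length(sw)], TRUE)
  max(abs(z[last]))
}

#' Bootstrapped KS ranking metric
#'
#' Fits the PC space on the training features, projects both ensembles to
#' the top `n_pcs` components, then per bootstrap replicate (images
#' resampled with replacement on both sides) draws a baseline
#' (train-vs-train) and a cross (train-vs-generated) cosine-distance sample
#' of `n_pairs` each and computes their two-sample KS statistic. The mean KS
#' over replicates is the ranking metric; lower is better.
#'
#' @param train,gen Feature tables from [feature_table()] (same registry).
#' @param n_pcs Components retained (default 10).
#' @param n_pairs Cosine-distance pairs per sample (default 10000).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed (logged in the result).
#' @param families Also compute per-family sub-metrics (slower).
#' @param feature_subset Optional character vector restricting the registry
#'   (used by [public_metric()]).
#' @return Object of class `dgm_ranking`.
#' @export
ranking_metric <- function(train, gen, n_pcs = 10, n_pairs = 10000,
                           n_boot = 1000, seed = 1L, families = FALSE,
                           feature_subset = NULL) {
  reg <- feature_registry()
  core <- function(cols, npc, nb) {
    tt <- train[, c("image_id", cols), drop = FALSE]
    gg <- gen[, c("image_id", cols), drop = FALSE]
    npc <- min(npc, length(cols), nrow(tt) - 1)
    model <- fit_pc_space(tt, n_components = npc)
    st <- project_pc(model, tt)
    sg <- project_pc(model, gg)
    ks <- numeric(nb)
    sample_pair <- NULL
    for (bset in seq_len(nb)) {
      it <- sample.int(nrow(st), replace = TRUE)
      ig <- sample.int(nrow(sg), replace = TRUE)
      base <- cosine_distance_distribution(st[it, , drop = FALSE],
                                           n_pairs = n_pairs)
      cross <- cosine_distance_distribution(st[it, , drop = FALSE],
                                            sg[ig, , drop = FALSE],
                                            n_pairs = n_pairs)
      ks[bset] <- ks_statistic(base, cross)
      if (bset == 1) sample_pair <- list(baseline = base, cross = cross)
    }
    list(ks = ks, model = model, samples = sample_pair)
  }
  cols <- if (is.null(feature_subset)) reg$name else feature_subset
  cols <- intersect(cols, names(train))
  res <- with_seed(seed, {
    main <- core(cols, n_pcs, n_boot)
    fam <- NULL
    if (families) {
      fam <- dplyr::bind_rows(lapply(unique(reg$family), function(fm) {
        fcols <- intersect(reg$name[reg$family == fm], cols)
        if (!length(fcols)) return(NULL)
        r <- core(fcols, n_pcs, n_boot)
        tibble(family = fm, mean_ks = mean(r$ks), sd_ks = stats::sd(r$ks),
               n_features = length(fcols))
      }))
    }
    list(main = main, fam = fam)
  })
  structure(list(mean_ks = mean(res$main$ks),
                 sd_ks = stats::sd(res$main$ks),
                 ks_values = res$main$ks,
                 per_family = res$fam,
                 samples = res$main$samples,
                 pc_model = res$main$model,
                 config = list(n_pcs = n_pcs, n_pairs = n_pairs,
                               n_boot = n_boot, seed = seed,
                               n_features = length(cols))),
            class = "dgm_ranking")
}

#' Public ranking metric (nine-feature subset)
#'
#' The identical pipeline restricted to the nine public features: per-tissue
#' areas and mean intensities (F, G, S, L) and the fat-to-glandular ratio.
#'
#' @inheritParams ranking_metric
#' @return Object of class `dgm_ranking`.
#' @export
public_metric <- function(train, gen, n_pairs = 10000, n_boot = 1000,
                          seed = 1L) {
  ranking_metric(train, gen, n_pcs = 9, n_pairs = n_pairs, n_boot = n_boot,
                 seed = seed, feature_subset = public_metric_features())
}

#' @export
print.dgm_ranking <- function(x, ...) {
  cat(sprintf("<dgm_ranking> mean KS = %.4f (sd %.4f), %d bootstraps\n",
              x$mean_ks, x$sd_ks, x$config$n_boot))
  if (!is.null(x$per_family)) print(x$per_family)
  invisible(x)
}

#' @method tidy dgm_ranking
#' @export
tidy.dgm_ranking <- function(x, ...) {
  tibble(bootstrap = seq_along(x$ks_values), ks = x$ks_values)
}

#' @method glance dgm_ranking
#' @export
glance.dgm_ranking <- function(x, ...) {
  tibble(mean_ks = x$mean_ks, sd_ks = x$sd_ks,
         n_boot = x$config$n_boot, n_pairs = x$config$n_pairs,
         n_pcs = x$config$n_pcs, n_features = x$config$n_features)
}

#' @method autoplot dgm_ranking
#' @export
autoplot.dgm_ranking <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(sample = "train-train baseline", d = object$samples$baseline),
    tibble(sample = "train-generated", d = object$samples$cross))
  ggplot2::ggplot(df, ggplot2::aes(.data$d, colour = .data$sample)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "cosine distance (top-PC space)", y = "ECDF",
                  title = sprintf("mean KS = %.3f", object$mean_ks)) +
    ggplot2::theme_minimal()
}
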