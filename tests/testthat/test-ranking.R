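test_that("Frechet distance matches Gaussian closed forms", {
  set.seed(1)
  a <- matrix(rnorm(200 * 4), 200, 4)
  expect_equal(frechet_distance(a, a), 0, tolerance = 1e-8)
  # 1-D N(0,1) vs N(1,1): closed form (mu1-mu2)^2 + (s1-s2)^2 = 1
  x <- matrix(rnorm(1e5), ncol = 1)
  y <- matrix(rnorm(1e5, mean = 1), ncol = 1)
  expect_equal(frechet_distance(x, y), 1, tolerance = 0.05)
  # exactly-diagonal covariances: elementwise closed form
  whiten <- function(m) scale(m, scale = FALSE) %*%
    backsolve(chol(stats::cov(m)), diag(ncol(m)))
  s1 <- c(1, 2, 0.5); s2 <- c(2, 1, 1.5)
  mu1 <- c(0, 1, -1); mu2 <- c(1, 0, 2)
  b1 <- sweep(whiten(matrix(rnorm(300 * 3), 300, 3)) %*% diag(sqrt(s1)), 2,
              mu1, "+")
  b2 <- sweep(whiten(matrix(rnorm(300 * 3), 300, 3)) %*% diag(sqrt(s2)), 2,
              mu2, "+")
  closed <- sum((mu1 - mu2)^2) + sum((sqrt(s1) - sqrt(s2))^2)
  expect_equal(frechet_distance(b1, b2), closed, tolerance = 1e-4)
  # symmetry and error on non-finite rows
  expect_equal(frechet_distance(b1, b2), frechet_distance(b2, b1),
               tolerance = 1e-8)
  bad <- b1; bad[3, 2] <- NA
  expect_error(frechet_distance(bad, b2), "non-finite")
})

test_that("the KS statistic agrees with stats::ks.test and hits its edges", {
  set.seed(2)
  x <- rnorm(150); y <- rnorm(180, 0.4)
  expect_equal(ks_statistic(x, y),
               unname(stats::ks.test(x, y)$statistic))
  expect_equal(ks_statistic(x, x), 0)
  expect_equal(ks_statistic(runif(50), runif(60) + 5), 1)
  # tie-heavy integer samples stay within [0, 1] and match ecdf enumeration
  xi <- sample(1:5, 100, replace = TRUE)
  yi <- sample(2:6, 80, replace = TRUE)
  grid <- sort(unique(c(xi, yi)))
  d_brute <- max(abs(stats::ecdf(xi)(grid) - stats::ecdf(yi)(grid)))
  expect_equal(ks_statistic(xi, yi), d_brute)
})

test_that("the PC space reproduces analytic eigenstructure and projections", {
  set.seed(3)
  # 3-feature toy with known covariance
  sigma <- matrix(c(4, 2, 0, 2, 3, 1, 0, 1, 2), 3, 3)
  x <- matrix(rnorm(4000 * 3), 4000, 3) %*% chol(sigma)
  tab <- dplyr::bind_cols(tibble::tibble(image_id = as.character(1:4000)),
                          tibble::as_tibble(as.data.frame(x)))
  model <- fit_pc_space(tab, n_components = 3)
  # PCA identity: projected training variance = model explained variance
  sc <- project_pc(model, tab, 3)
  expect_equal(apply(sc, 2, var), model$sdev[1:3]^2, tolerance = 1e-8,
               ignore_attr = TRUE)
  # components match eigenvectors of the standardised sample correlation
  xs <- scale(x)
  ev <- eigen(crossprod(xs) / (nrow(xs) - 1))$vectors
  for (k in 1:3)
    expect_equal(abs(sum(model$rotation[, k] * ev[, k])), 1, tolerance = 1e-6)
  # duplicated and constant columns are handled
  tab2 <- tab
  tab2$dup <- tab$V1
  tab2$flat <- 1
  m2 <- fit_pc_space(tab2, n_components = 3)
  expect_true("flat" %in% m2$dropped)
  expect_equal(ncol(project_pc(m2, tab2)), 3)
  expect_error(fit_pc_space(tab[1:3, ], n_components = 5), "components")
})

test_that("cosine distances hit their geometric edge cases", {
  # identical rows: baseline pairs are forced onto coincident points
  a <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  expect_true(all(cosine_distance_distribution(a, n_pairs = 50) < 1e-12))
  orth <- rbind(c(1, 0), c(0, 1))
  expect_equal(unique(round(cosine_distance_distribution(orth, n_pairs = 10),
                            12)), 1)
  opp <- rbind(c(1, 0), c(-1, 0))
  expect_equal(unique(round(cosine_distance_distribution(opp, n_pairs = 10),
                            12)), 2)
  expect_error(cosine_distance_distribution(matrix(1, 1, 2), n_pairs = 5),
               "at least 2")
})

test_that("planted training copies are flagged with measure 1", {
  ens <- shared_ensemble()
  train <- ens$images[1:40]
  gen <- ens$images[c(3, 7, 21, 30, 38)]
  mm <- memorization_measure(gen, train, threshold = 0.9)
  expect_true(all(mm$report$flagged))
  expect_equal(mm$report$measure, rep(1, 5), tolerance = 1e-12)
  expect_equal(mm$report$best_match,
               names(dgmeval:::ensemble_images(train))[c(3, 7, 21, 30, 38)])
  # disjoint-support masks anticorrelate
  m1 <- matrix(FALSE, 8, 8); m1[1:4, ] <- TRUE
  m2 <- !m1
  expect_lte(dgmeval:::binary_corr(as.logical(m1),
                                   matrix(as.logical(m2), ncol = 1)), 0)
})

test_that("prefiltered search equals exhaustive search", {
  ens <- shared_ensemble()
  train <- ens$images[41:100]
  gen <- ens$images[101:115]
  pre <- memorization_measure(gen, train, n_candidates = 10)
  full <- memorization_measure(gen, train, n_candidates = Inf)
  expect_equal(pre$report$measure, full$report$measure, tolerance = 1e-12)
  expect_identical(pre$report$best_match, full$report$best_match)
})

test_that("threshold calibration reproduces the max-plus-sd construction", {
  ens <- shared_ensemble()
  train <- ens$images[1:40]
  cal <- calibrate_memorization_threshold(train, n_holdout = 10, seed = 5)
  expect_gte(cal$threshold, cal$max)
  expect_equal(cal$threshold, cal$max + cal$sd)
  expect_lt(cal$threshold, 1)
  # independent reconstruction with the same holdout draw
  masks <- boundary_masks(train)
  hold <- dgmeval:::with_seed(5L, sample.int(40, 10))
  mm <- memorization_measure(NULL, NULL, gen_masks = masks[hold],
                             train_masks = masks[-hold], threshold = 1)
  expect_equal(sort(cal$measures), sort(mm$report$measure))
  expect_equal(cal$threshold, max(mm$report$measure) + sd(mm$report$measure))
  # degenerate case: identical images give sd 0 and threshold = max = 1
  same <- ens$images[c(1, 1, 1, 1, 1, 1)]
  expect_warning(cal0 <- calibrate_memorization_threshold(same, n_holdout = 2,
                                                          seed = 1),
                 "degenerate")
  expect_equal(cal0$threshold, 1)
})

test_that("the ranking metric separates null splits from corrupted features", {
  feats <- shared_features()
  h <- half_indices(nrow(feats))
  tr <- feats[h$a, ]; ge <- feats[h$b, ]
  null_rank <- ranking_metric(tr, ge, n_pcs = 10, n_pairs = 1000,
                              n_boot = 30, seed = 9)
  expect_true(all(null_rank$ks_values >= 0 & null_rank$ks_values <= 1))
  # a constant shift of several training sds per feature clearly separates
  # the cross distances from the baseline
  shifted <- ge
  num <- setdiff(names(shifted), "image_id")
  sds <- vapply(tr[num], function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  sds[!is.finite(sds) | sds == 0] <- 1
  shifted[num] <- purrr::map2(shifted[num], sds, function(v, s) v + 8 * s)
  shift_rank <- ranking_metric(tr, shifted, n_pcs = 10, n_pairs = 1000,
                               n_boot = 30, seed = 9)
  expect_lt(null_rank$mean_ks, 0.35)
  expect_gt(shift_rank$mean_ks, 1.5 * null_rank$mean_ks)
  expect_lt(max(null_rank$ks_values), min(1, max(shift_rank$ks_values) + 1))
  # bootstrap spread shrinks with more pairs on null data
  small <- ranking_metric(tr, ge, n_pairs = 150, n_boot = 25, seed = 4)
  big <- ranking_metric(tr, ge, n_pairs = 1500, n_boot = 25, seed = 4)
  expect_gt(small$sd_ks, big$sd_ks)
})

test_that("the public metric uses nine features and preserves ordering", {
  expect_length(public_metric_features(), 9)
  expect_true(all(public_metric_features() %in% feature_registry()$name))
  feats <- shared_features()
  h <- half_indices(nrow(feats))
  tr <- feats[h$a, ]; ge <- feats[h$b, ]
  pub_null <- public_metric(tr, ge, n_pairs = 800, n_boot = 20, seed = 2)
  expect_equal(pub_null$config$n_features, 9)
  expect_lt(pub_null$mean_ks, 0.35)
  # a corruption that degrades tissue areas worsens both metrics
  corrupt <- ge
  corrupt$int_F_area <- corrupt$int_F_area * 3
  corrupt$int_G_area <- corrupt$int_G_area * 0.2
  corrupt$fg_ratio <- corrupt$fg_ratio * 15
  pub_bad <- public_metric(tr, corrupt, n_pairs = 800, n_boot = 20, seed = 2)
  full_null <- ranking_metric(tr, ge, n_pairs = 800, n_boot = 20, seed = 2)
  full_bad <- ranking_metric(tr, corrupt, n_pairs = 800, n_boot = 20, seed = 2)
  expect_gt(pub_bad$mean_ks, pub_null$mean_ks)
  expect_gt(full_bad$mean_ks, full_null$mean_ks)
})

test_that("broom methods and the embedders return consistent shapes", {
  feats <- shared_features()
  h <- half_indices(nrow(feats))
  rk <- ranking_metric(feats[h$a, ], feats[h$b, ], n_pairs = 300,
                       n_boot = 10, seed = 1)
  expect_equal(nrow(tidy(rk)), 10)
  expect_equal(glance(rk)$mean_ks, rk$mean_ks)
  emb <- embed_ensemble(feats[h$a, ])
  expect_equal(nrow(emb), length(h$a))
  expect_false(anyNA(emb))
  ens <- shared_ensemble()
  rp <- embed_ensemble(ens$images[1:4], method = "random-projection",
                       dim = 16, seed = 3)
  rp2 <- embed_ensemble(ens$images[1:4], method = "random-projection",
                        dim = 16, seed = 3)
  expect_identical(rp, rp2)
  expect_equal(dim(rp), c(4, 16))
})
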