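test_that("glandularity classification uses left-closed bands", {
  mk <- function(g, n = 1000) {
    lab <- matrix(0L, 40, 40)
    px <- sample(1600, n)
    lab[px] <- 1L
    lab[px[seq_len(round(g * n))]] <- 2L
    lab
  }
  set.seed(1)
  expect_equal(classify_by_glandularity(mk(0.05)), "fatty")
  expect_equal(classify_by_glandularity(mk(0.20)), "scattered")
  expect_equal(classify_by_glandularity(mk(0.40)), "heterogeneous")
  expect_equal(classify_by_glandularity(mk(0.65)), "dense")
  expect_equal(classify_by_glandularity(mk(0.90)), "dense")
})

test_that("segmented generator images recover the manifest class", {
  ens <- shared_ensemble()
  idx <- seq(1, 160, by = 4)
  pred <- vapply(idx, function(i)
    classify_by_glandularity(segment_tissues(ens$images[[i]])), character(1))
  expect_gte(mean(pred == ens$manifest$class[idx]), 0.95)
})

test_that("density and coverage match the brute-force oracle exactly", {
  set.seed(6)
  k <- 4
  x <- matrix(rnorm(60 * 2), 60, 2)
  y <- matrix(rnorm(80 * 2, sd = 1.3), 80, 2)
  got <- density_coverage(x, y, k = k)
  # brute force: all pairwise distances, explicit ball membership
  nnd <- numeric(60); inside <- matrix(FALSE, 60, 80)
  for (i in 1:60) {
    di <- sqrt(colSums((t(x) - x[i, ])^2))
    nnd[i] <- sort(di[-i])[k]
    for (j in 1:80)
      inside[i, j] <- sqrt(sum((x[i, ] - y[j, ])^2)) <= nnd[i]
  }
  expect_equal(got$density[1], sum(inside) / (k * 80))
  expect_equal(got$coverage[1], mean(rowSums(inside) > 0))
  # identical distinct point sets: coverage 1 and density (k+1)/k
  idt <- density_coverage(x, x, k = k)
  expect_equal(idt$coverage[1], 1)
  expect_equal(idt$density[1], (k + 1) / k)
  # generated points far outside the training hull
  far <- density_coverage(x, y + 100, k = k)
  expect_equal(far$density[1], 0)
  expect_equal(far$coverage[1], 0)
  # class with too few training points is missing
  cls_t <- rep(c("a", "b"), c(57, 3))
  cls_g <- rep(c("a", "b"), c(70, 10))
  pc <- density_coverage(x, y, k = k, train_class = cls_t, gen_class = cls_g)
  expect_true(is.na(pc$density[pc$class == "b"]))
  expect_false(is.na(pc$density[pc$class == "a"]))
})

test_that("semivariograms are zero for constant fields and flat for noise", {
  const <- matrix(42, 64, 64)
  vg <- image_semivariance(const, lag_max = 20, seed = 2)
  expect_true(all(vg$gamma == 0))
  # ensemble of identical constant images
  sv <- mean_image_semivariance(replicate(3, const, simplify = FALSE),
                                lag_max = 20)
  expect_equal(sv$sill, 0)
  # white noise: flat semivariogram at the field variance
  set.seed(3)
  noise <- matrix(rnorm(128 * 128, mean = 50, sd = 10), 128, 128)
  vgn <- image_semivariance(noise, lag_max = 30, n_pair_samples = 4000,
                            seed = 4)
  expect_true(all(abs(vgn$gamma - 100) / 100 < 0.25))
  expect_lt(abs(mean(vgn$gamma) - 100) / 100, 0.05)
})

test_that("the generator ensemble is ergodic where a biased fixture is not", {
  ens <- shared_ensemble()
  sv <- mean_image_semivariance(ens, support_threshold = 50, erode_px = 4,
                                n_pair_samples = 6000, seed = 1)
  # one fixed layout re-rendered many times: position carries tissue identity
  lay <- ens$layouts[[10]]
  biased <- lapply(1:25, function(i) assign_intensities(lay, seed = 100 + i))
  svb <- mean_image_semivariance(biased, support_threshold = 50,
                                 erode_px = 4, n_pair_samples = 6000,
                                 seed = 1)
  # flat sill: the last-quartile plateau matches the preceding band
  vg <- sv$variogram
  lmax <- max(vg$lag)
  mid <- mean(vg$gamma[vg$lag > 0.5 * lmax & vg$lag <= 0.75 * lmax])
  expect_gt(sv$sill / mid, 0.7)
  expect_lt(sv$sill / mid, 1.4)
  expect_gt(svb$sill, 5 * sv$sill)
})

test_that("the convexity-perimeter detector flags notched masks only", {
  disk <- disk_mask(64, 22)
  r_disk <- dgmeval:::breast_convexity_perimeter(disk)
  expect_gt(r_disk, 0.9)
  expect_lte(r_disk, 1.02)
  r_notch <- dgmeval:::breast_convexity_perimeter(notched_disk(64, 22))
  expect_lt(r_notch, 0.9)
})

test_that("artifact scan reports sticking, background and boundary breaks", {
  ens <- shared_ensemble()
  train_imgs <- ens$images[1:12]
  # fixture sharing one ligament structure across all images
  lay <- ens$layouts[[5]]
  stuck <- lapply(1:10, function(i) assign_intensities(lay, seed = 50 + i))
  art <- artifact_scan(stuck, train_reference = train_imgs,
                       n_stick_pairs = 40, seed = 2)
  expect_gt(art$sticking_score, 0.95)
  expect_lt(art$train_sticking_score, 0.3)
  # generator output has exactly-zero background
  expect_true(all(art$per_image$background_fraction == 0))
  expect_false(any(art$per_image$boundary_break))
  # injected background noise is detected but stays faint
  noisy <- lapply(ens$images[13:16], function(im) {
    bg <- im == 0L
    im[bg][1:500] <- 3L
    im
  })
  names(noisy) <- sprintf("noisy_%02d", 13:16)
  art2 <- artifact_scan(noisy, seed = 2)
  expect_true(all(art2$per_image$background_fraction > 0))
  expect_true(all(art2$per_image$background_mean < 6))
  # ensemble order permutation leaves per-image rows unchanged
  art3 <- artifact_scan(rev(noisy), seed = 2)
  expect_equal(dplyr::arrange(art2$per_image, image_id),
               dplyr::arrange(art3$per_image, image_id))
})
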