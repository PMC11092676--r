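test_that("co-occurrence matrices and statistics match brute force on toys", {
  # constant foreground: a single occupied diagonal cell
  img <- matrix(100L, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  p <- glcm(img, mask, distance = 1, angle = 0)
  st <- haralick_stats(p)
  expect_equal(st[["asm"]], 1)
  expect_equal(st[["contrast"]], 0)
  # 2x2 checkerboard of two gray levels, distance 1, 0 degrees
  img2 <- matrix(0L, 8, 8)
  img2[(row(img2) + col(img2)) %% 2 == 0] <- 40L
  img2[(row(img2) + col(img2)) %% 2 == 1] <- 200L
  p2 <- glcm(img2, matrix(TRUE, 8, 8), 1, 0)
  # oracle: enumerate all horizontal pixel pairs in both directions
  lv <- function(v) v %/% 4L + 1L
  counts <- matrix(0, 64, 64)
  for (r in 1:8) for (c in 1:7) {
    i <- lv(img2[r, c]); j <- lv(img2[r, c + 1])
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1
  }
  expect_equal(p2, counts / sum(counts))
  st2 <- haralick_stats(p2)
  brute_contrast <- sum(abs(row(counts) - col(counts))^2 * counts / sum(counts))
  expect_equal(st2[["contrast"]], brute_contrast)
  # every adjacent pair differs -> asm of a two-cell matrix
  expect_equal(st2[["asm"]], 0.5)
})

test_that("the registry enumerates all families with unique, stable names", {
  reg <- feature_registry()
  expect_false(anyDuplicated(reg$name) > 0)
  expect_setequal(unique(reg$family),
                  c("texture", "intensity", "morphology", "skeleton",
                    "fractal", "moments", "fg_ratio"))
  # texture family: 14 statistics x (4 distances x 4 angles + 4 angular means)
  expect_equal(sum(reg$family == "texture"), 14 * (4 * 4 + 4))
  expect_equal(sum(reg$family == "moments"), 31 * 2 * 3)
  expect_equal(nrow(reg), 832)
  expect_match(registry_version(), "^[0-9a-f]+$")
})

test_that("morphology features behave on canonical shapes", {
  lab <- matrix(0L, 64, 64)
  lab[disk_mask(64, 20)] <- 1L
  f <- morphology_features(lab)
  expect_equal(f[["morph_F_area_count"]], 1)
  expect_equal(f[["morph_F_area_mean"]], sum(disk_mask(64, 20)))
  expect_gt(f[["morph_F_solidity_mean"]], 0.95)
  expect_lte(f[["morph_F_solidity_mean"]], 1)
  expect_gt(f[["morph_F_circularity_mean"]], 0.8)
  expect_gt(f[["morph_F_convexity_perimeter_mean"]], 0.93)
  expect_equal(f[["morph_F_euler_mean"]], 1)
  # notched disk: convexity-perimeter ratio drops below the 0.9 flag line
  lab2 <- matrix(0L, 64, 64)
  lab2[notched_disk(64, 20)] <- 1L
  f2 <- morphology_features(lab2)
  expect_lt(f2[["morph_F_convexity_perimeter_mean"]], 0.9)
  # two disjoint squares
  lab3 <- matrix(0L, 32, 32)
  lab3[2:7, 2:7] <- 1L       # 36 px
  lab3[20:29, 20:29] <- 1L   # 100 px
  f3 <- morphology_features(lab3)
  expect_equal(f3[["morph_F_area_count"]], 2)
  expect_equal(f3[["morph_F_area_min"]], 36)
  expect_equal(f3[["morph_F_area_max"]], 100)
  # empty glandular tissue: count 0, summaries missing
  expect_equal(f3[["morph_G_area_count"]], 0)
  expect_true(is.na(f3[["morph_G_area_mean"]]))
})

test_that("convexity-perimeter ratio never exceeds 1 beyond discretisation", {
  set.seed(7)
  for (i in 1:5) {
    m <- disk_mask(48, 12 + 4 * runif(1), c0 = c(24, 24)) |
      disk_mask(48, 10, c0 = c(24 + runif(1, -6, 6), 24 + runif(1, -6, 6)))
    lab <- matrix(0L, 48, 48)
    lab[m] <- 1L
    f <- morphology_features(lab)
    expect_lte(f[["morph_F_convexity_perimeter_max"]], 1.02)
  }
})

test_that("skeleton statistics count endpoints, branches and regions", {
  lab <- matrix(0L, 64, 64)
  lab[32, 8:57] <- 4L            # straight 50-px line
  f <- skeleton_features(lab)
  expect_equal(f[["skel_n_skeletons"]], 1)
  expect_equal(f[["skel_endpoints_mean"]] * f[["skel_endpoints_count"]], 2)
  expect_equal(f[["skel_branchpoints_mean"]], 0)
  expect_equal(f[["skel_total_length"]], 50)
  # a "+" cross: 4 endpoints, 1 branch point
  lab2 <- matrix(0L, 32, 32)
  lab2[16, 6:26] <- 4L
  lab2[6:26, 16] <- 4L
  f2 <- skeleton_features(lab2)
  expect_equal(f2[["skel_n_skeletons"]], 1)
  expect_equal(f2[["skel_endpoints_mean"]], 4)
  expect_equal(f2[["skel_branchpoints_mean"]], 1)
  # ligament ring inside a filled foreground disk bounds one region
  lab3 <- matrix(0L, 64, 64)
  lab3[disk_mask(64, 20)] <- 1L
  ring <- disk_mask(64, 20) & !disk_mask(64, 19)
  lab3[ring] <- 4L
  f3 <- skeleton_features(lab3)
  expect_equal(f3[["skel_n_regions"]], 1)
  # empty ligament mask: zero counts
  f4 <- skeleton_features(matrix(1L, 16, 16))
  expect_equal(f4[["skel_n_skeletons"]], 0)
})

test_that("fractal features match closed forms and brute-force gliding boxes", {
  full <- matrix(TRUE, 64, 64)
  expect_equal(box_dimension(full), 2, tolerance = 0.01)
  expect_true(all(abs(lacunarity(full) - 1) < 1e-12, na.rm = TRUE))
  line <- matrix(FALSE, 64, 64); line[30, ] <- TRUE
  expect_equal(box_dimension(line), 1, tolerance = 0.05)
  # sparse scatter is gappier than dense fill at r = 2
  set.seed(11)
  sparse <- matrix(runif(64 * 64) < 0.01, 64, 64)
  dense <- matrix(runif(64 * 64) < 0.5, 64, 64)
  ls <- lacunarity(sparse)[["r2"]]
  ld <- lacunarity(dense)[["r2"]]
  expect_gt(ls, ld)
  # brute-force gliding-box oracle at r = 2 on the cropped sparse mask
  rc <- which(sparse, arr.ind = TRUE)
  m <- sparse[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2])]
  masses <- c()
  for (r in 1:(nrow(m) - 1)) for (c in 1:(ncol(m) - 1))
    masses <- c(masses, sum(m[r:(r + 1), c:(c + 1)]))
  mu <- mean(masses)
  expect_equal(ls, 1 + (mean(masses^2) - mu^2) / mu^2)
})

test_that("moments obey translation and rotation invariance", {
  m <- matrix(FALSE, 32, 32)
  m[10:11, 10:11] <- TRUE
  mom <- image_moments(m)
  expect_equal(mom[["m00"]], 4)
  expect_equal(mom[["m10"]] / mom[["m00"]], mean(c(9, 10)))  # 0-based x
  # translation leaves central, normalised and Hu moments unchanged
  m2 <- matrix(FALSE, 32, 32)
  m2[17:18, 3:4] <- TRUE
  mom2 <- image_moments(m2)
  keep <- grep("^(mu|eta|hu)", names(mom))
  expect_equal(mom[keep], mom2[keep])
  # 90-degree rotation of an L-shape leaves the 7 Hu invariants unchanged
  L <- matrix(FALSE, 40, 40)
  L[10:30, 10:13] <- TRUE
  L[27:30, 10:25] <- TRUE
  Lr <- t(L)[, rev(seq_len(nrow(L)))]          # exact 90-degree rotation
  h1 <- image_moments(L)[sprintf("hu%d", 1:7)]
  h2 <- image_moments(Lr)[sprintf("hu%d", 1:7)]
  expect_equal(h1, h2, tolerance = 1e-6)
  # intensity-weighted version is likewise rotation invariant
  w <- matrix(0L, 40, 40); w[L] <- seq_len(sum(L)) %% 100L + 50L
  wr <- t(w)[, rev(seq_len(nrow(w)))]
  hw1 <- image_moments(L, w)[sprintf("hu%d", 1:7)]
  hw2 <- image_moments(Lr, wr)[sprintf("hu%d", 1:7)]
  expect_equal(hw1, hw2, tolerance = 1e-6)
})

test_that("fat-to-glandular ratio follows pixel counts", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L
  lab[11:20, 1:10] <- 2L
  expect_equal(fg_ratio(lab), 1)
  lab2 <- matrix(0L, 20, 20)
  lab2[1:15, 1:20] <- 1L
  lab2[16:20, 1:20] <- 2L
  expect_equal(fg_ratio(lab2), 3)
  expect_warning(r <- fg_ratio(matrix(1L, 5, 5)), "glandular")
  expect_true(is.na(r))
  # generator image: ratio consistent with the manifest glandular fraction
  ens <- shared_ensemble()
  i <- 30
  g <- ens$manifest$glandular_fraction[i]
  seg <- segment_tissues(ens$images[[i]])
  expect_equal(fg_ratio(seg), (1 - g) / g, tolerance = 0.1)
})

test_that("feature extraction is deterministic and batch-order invariant", {
  ens <- shared_ensemble()
  v1 <- extract_features(ens$images[[5]])
  v2 <- extract_features(ens$images[[5]])
  expect_identical(v1, v2)
  expect_equal(length(v1), nrow(feature_registry()))
  expect_identical(names(v1), feature_registry()$name)
  tab <- feature_table(ens$images[c(5, 9, 12)])
  tab_perm <- feature_table(ens$images[c(12, 5, 9)])
  expect_equal(as.numeric(tab[1, -1]), as.numeric(tab_perm[2, -1]))
  expect_identical(names(tab)[-1], feature_registry()$name)
})

test_that("intensity statistics report areas and means per tissue", {
  img <- matrix(0L, 32, 32)
  lab <- matrix(0L, 32, 32)
  img[5:14, 5:14] <- 60L;  lab[5:14, 5:14] <- 1L
  img[20:24, 20:24] <- 150L; lab[20:24, 20:24] <- 2L
  f <- intensity_features(img, lab)
  expect_equal(f[["int_F_area"]], 100)
  expect_equal(f[["int_F_mean"]], 60)
  expect_equal(f[["int_G_area"]], 25)
  expect_equal(f[["int_B_area"]], 125)
  expect_equal(f[["int_S_area"]], 0)
  expect_true(is.na(f[["int_S_mean"]]))
  expect_equal(f[["int_F_q2"]], 60)
})
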