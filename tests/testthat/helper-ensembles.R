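# Shared fixtures, generated once per test run and memoised. Sizes are kept
# small (side 96) so the suite stays fast while exercising the full pipeline.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

shared_config <- function(n = 160, size = 96, seed = 42L) {
  generator_config(n_images = n, image_size = size, seed = seed)
}

# The main training-like ensemble: 160 images, side 96, default prevalence.
shared_ensemble <- function() {
  memo("ens", generate_ensemble(shared_config(), keep_layouts = TRUE))
}

shared_features <- function() {
  memo("feat", feature_table(shared_ensemble()))
}

# Deterministic disjoint halves (stratified by generation order, which is
# grouped by class, so both halves keep the class mix).
half_indices <- function(n) {
  list(a = seq(1, n, by = 2), b = seq(2, n, by = 2))
}

# --- corruption helpers (applied to images) ---

shift_foreground <- function(img, delta) {
  out <- img
  out[out > 0] <- pmin(out[out > 0] + delta, 255L)
  storage.mode(out) <- "integer"
  out
}

shuffle_foreground <- function(img, seed = 1L) {
  out <- img
  fg <- which(out > 0)
  out[fg] <- dgmeval:::with_seed(seed, sample(out[fg]))
  storage.mode(out) <- "integer"
  out
}

# --- toy masks ---

disk_mask <- function(size = 64, r = size * 0.35,
                      c0 = c(size / 2, size / 2)) {
  rr <- matrix(rep(seq_len(size), size), size, size)
  cc <- t(rr)
  (rr - c0[1])^2 + (cc - c0[2])^2 <= r^2
}

notched_disk <- function(size = 64, r = size * 0.35) {
  m <- disk_mask(size, r)
  ctr <- round(size / 2)
  # deep, narrow rectangular notch reaching the centre
  m[(ctr - 2):(ctr + 2), ctr:size] <- FALSE
  m
}

# Values of one tissue on a spaced lattice (every `step`-th row/column):
# spacing beyond the smoothing correlation length makes the retained pixels
# effectively independent draws from the prescribed marginal.
spaced_tissue_values <- function(img, label_map, label, step = 4) {
  keep <- matrix(FALSE, nrow(img), ncol(img))
  keep[seq(1, nrow(img), by = step), seq(1, ncol(img), by = step)] <- TRUE
  img[label_map == label & keep]
}

# Jittered KS test of quantised tissue values against the scaled Beta law
# (uniform dequantisation makes the continuous-law test applicable).
ks_tissue_p <- function(vals, scale, offset, alpha, beta) {
  u <- (vals + stats::runif(length(vals), -0.5, 0.5) - offset) / scale
  suppressWarnings(stats::ks.test(u, stats::pbeta, alpha, beta)$p.value)
}

default_beta_params <- function() {
  m <- intensity_model()$tissues
  split(m[, c("scale", "offset", "alpha", "beta")], m$tissue)
}
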