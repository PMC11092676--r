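# Feature registry: the fixed, versioned enumeration of every scalar feature,
# and the driver that extracts an aligned vector per image.

SUMMARY_STATS <- c("count", "mean", "sd", "min", "max", "q1", "q2", "q3")

#' Eight-statistic summary of a multi-valued feature
#'
#' Count, mean, standard deviation, minimum, maximum and quartiles (type-7
#' linear interpolation), applied identically to every feature that yields
#' several values per image. An empty input gives count 0 and missing
#' summaries.
#'
#' @param x Numeric vector.
#' @return Named numeric vector of length 8.
#' @export
summary8 <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x))
    return(stats::setNames(c(0, rep(NA_real_, 7)), SUMMARY_STATS))
  stats::setNames(
    c(length(x), mean(x), stats::sd(x), min(x), max(x),
      stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)),
    SUMMARY_STATS)
}

registry_env <- new.env(parent = emptyenv())

#' The default feature registry
#'
#' Ordered enumeration of every feature the extractor produces, with its
#' family (texture, intensity, morphology, skeleton, fractal, moments,
#' fg_ratio), tissue scope (F, G, S, L or whole-breast B) and whether it is
#' an eight-statistic summary of a multi-valued feature. The registry order
#' is fixed; `attr(, "version")` is a hash of the name vector so feature
#' tables can be checked for compatibility.
#'
#' @return Tibble with columns `name`, `family`, `scope`, `summarized`.
#' @export
feature_registry <- function() {
  if (!is.null(registry_env$registry)) return(registry_env$registry)
  scope_of <- function(nm) {
    s <- sub("^(tex|int|morph|skel|frac|mom)_([FGSLB])_.*$", "\\2", nm)
    ifelse(s %in% c("F", "G", "S", "L", "B"), s, "B")
  }
  blocks <- list(
    tibble(name = texture_feature_names(), family = "texture", scope = "B",
           summarized = grepl("_amean_", texture_feature_names())),
    tibble(name = intensity_feature_names(), family = "intensity",
           scope = scope_of(intensity_feature_names()), summarized = FALSE),
    tibble(name = morphology_feature_names(), family = "morphology",
           scope = scope_of(morphology_feature_names()),
           summarized = !grepl("^morph_B_", morphology_feature_names())),
    tibble(name = skeleton_feature_names(), family = "skeleton", scope = "L",
           summarized = grepl(paste(SUMMARY_STATS, collapse = "|"),
                              skeleton_feature_names())),
    tibble(name = fractal_feature_names(), family = "fractal",
           scope = scope_of(fractal_feature_names()), summarized = FALSE),
    tibble(name = moment_feature_names(), family = "moments",
           scope = scope_of(moment_feature_names()), summarized = FALSE),
    tibble(name = "fg_ratio", family = "fg_ratio", scope = "B",
           summarized = FALSE)
  )
  reg <- dplyr::bind_rows(blocks)
  stopifnot(!anyDuplicated(reg$name))
  attr(reg, "version") <- rlang::hash(reg$name)
  registry_env$registry <- reg
  reg
}

#' @rdname feature_registry
#' @export
registry_version <- function() attr(feature_registry(), "version")

#' The nine-feature public-metric subset
#'
#' Per-tissue areas (F, G, S, L), per-tissue mean intensities (F, G, S, L)
#' and the fat-to-glandular ratio.
#'
#' @return Character vector of nine registry names.
#' @export
public_metric_features <- function() {
  c(sprintf("int_%s_area", c("F", "G", "S", "L")),
    sprintf("int_%s_mean", c("F", "G", "S", "L")),
    "fg_ratio")
}

#' Fat-to-glandular tissue ratio
#'
#' @param label_map Segmented label map.
#' @return Fat pixel count over glandular pixel count; `NA` (with a warning)
#'   when no glandular tissue is present.
#' @export
fg_ratio <- function(label_map) {
  g <- sum(label_map == 2L)
  if (g == 0) {
    warn("no glandular tissue: fat-to-glandular ratio is missing")
    return(NA_real_)
  }
  sum(label_map == 1L) / g
}

#' Extract the full feature vector of one image
#'
#' Segments the image, runs every feature family and returns the values
#' aligned to the registry. A failure inside one family yields missing values
#' for that family only.
#'
#' @param image 8-bit image matrix.
#' @param thresholds Segmentation thresholds.
#' @param label_map Optional precomputed label map (skips segmentation).
#' @return Named numeric vector aligned to [feature_registry()].
#' @export
extract_features <- function(image, thresholds = segmentation_thresholds(),
                             label_map = NULL) {
  reg <- feature_registry()
  out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  lm <- tryCatch(
    if (is.null(label_map)) segment_tissues(image, thresholds) else label_map,
    error = function(e) NULL)
  if (is.null(lm)) return(out)
  fam <- list(
    function() texture_features(image, lm),
    function() intensity_features(image, lm),
    function() morphology_features(lm),
    function() skeleton_features(lm),
    function() fractal_features(lm),
    function() moment_features(image, lm),
    function() c(fg_ratio = suppressWarnings(fg_ratio(lm)))
  )
  for (f in fam) {
    v <- tryCatch(f(), error = function(e) NULL)
    if (!is.null(v)) out[names(v)] <- v
  }
  out
}

#' Feature table of an ensemble
#'
#' Applies [extract_features()] to every image and returns a tibble with one
#' row per image, columns aligned to the registry; deterministic and
#' independent of batch order.
#'
#' @param x A `dgm_ensemble` (with images kept), a list of image matrices, or
#'   a directory path readable by [read_ensemble()].
#' @param thresholds Segmentation thresholds.
#' @param ids Optional image identifiers (defaults to manifest filenames or
#'   list names/indices).
#' @param progress Print progress every 100 images.
#' @return Tibble: `image_id` plus one column per registry feature, with the
#'   registry version in `attr(, "registry_version")`.
#' @export
feature_table <- function(x, thresholds = segmentation_thresholds(),
                          ids = NULL, progress = FALSE) {
  if (is.character(x) && length(x) == 1) x <- read_ensemble(x)
  if (inherits(x, "dgm_ensemble")) {
    if (is.null(x$images)) abort("ensemble was generated without keep_images")
    if (is.null(ids)) ids <- x$manifest$filename
    x <- x$images
  }
  stopifnot(is.list(x))
  if (is.null(ids))
    ids <- if (!is.null(names(x))) names(x) else sprintf("img_%05d", seq_along(x))
  rows <- vector("list", length(x))
  for (i in seq_along(x)) {
    rows[[i]] <- extract_features(x[[i]], thresholds)
    if (progress && i %% 100 == 0)
      message(sprintf("  features %d / %d", i, length(x)))
  }
  tab <- as_tibble(do.call(rbind, rows))
  tab <- dplyr::bind_cols(tibble(image_id = ids), tab)
  attr(tab, "registry_version") <- registry_version()
  tab
}

# Numeric feature matrix (drops image_id), rows named by image id.
feature_matrix <- function(tab) {
  m <- as.matrix(tab[, setdiff(names(tab), "image_id"), drop = FALSE])
  rownames(m) <- tab$image_id
  m
}
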