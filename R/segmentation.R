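# Threshold-based tissue segmentation. Gray-level bands follow the prescribed
# tissue intensity laws; skin and ligament share a band and are split by
# peripheral vs central location.

#' Segmentation thresholds
#'
#' Gray-level bands partitioning `[0, 255]`: background `[0, 30)`, fat
#' `[30, 120)`, glandular `[120, 226)`, skin/ligament `[226, 255]`.
#' Printed band endpoints overlap (120 and 226 appear in two bands); they are
#' resolved half-open, so 120 is glandular and 226 is skin/ligament.
#'
#' @param background_max Upper edge of the background band (exclusive).
#' @param fat_max Upper edge of the fat band (exclusive).
#' @param glandular_max Upper edge of the glandular band (exclusive).
#' @param skin_band_width Distance (pixels) from the foreground boundary
#'   within which high-intensity pixels are labelled skin rather than
#'   ligament (default 4).
#' @return An object of class `dgm_thresholds`.
#' @export
segmentation_thresholds <- function(background_max = 30, fat_max = 120,
                                    glandular_max = 226, skin_band_width = 4) {
  if (!(0 < background_max && background_max < fat_max &&
        fat_max < glandular_max && glandular_max <= 255))
    abort("thresholds must satisfy 0 < background < fat < glandular <= 255")
  if (skin_band_width < 1) abort("skin_band_width must be >= 1")
  structure(list(background_max = background_max, fat_max = fat_max,
                 glandular_max = glandular_max,
                 skin_band_width = skin_band_width),
            class = "dgm_thresholds")
}

#' Gray-level classification without spatial rules
#'
#' Maps each pixel to background/fat/glandular/high by the threshold bands
#' alone; 3 denotes the high band (skin or ligament, not yet disambiguated).
#' [segment_tissues()] builds on this.
#'
#' @inheritParams segment_tissues
#' @return Integer matrix with values 0-3.
#' @export
threshold_labels <- function(image, thresholds = segmentation_thresholds()) {
  stopifnot_image8(image)
  lab <- matrix(0L, nrow(image), ncol(image))
  lab[image >= thresholds$background_max & image < thresholds$fat_max] <- 1L
  lab[image >= thresholds$fat_max & image < thresholds$glandular_max] <- 2L
  lab[image >= thresholds$glandular_max] <- 3L
  lab
}

#' Segment an image into the four tissue labels
#'
#' Global thresholding by the prescribed intensity bands, followed by:
#' foreground restricted to the largest connected component of non-background
#' pixels (floating specks relabelled background), and the skin/ligament band
#' split by location — high-intensity pixels within `skin_band_width` of the
#' foreground boundary become skin (3), the remaining high pixels ligament (4).
#'
#' @param image 8-bit grayscale image matrix.
#' @param thresholds A [segmentation_thresholds()].
#' @return Integer label map (0 background, 1 fat, 2 glandular, 3 skin,
#'   4 ligament) with attribute `provenance = "segmented"`.
#' @export
segment_tissues <- function(image, thresholds = segmentation_thresholds()) {
  lab <- threshold_labels(image, thresholds)
  fg <- largest_component(lab > 0L)
  if (!any(fg)) abort("no breast region: thresholding found no foreground")
  lab[!fg] <- 0L
  high <- lab == 3L
  if (any(high)) {
    d <- distmap_mat(fg)
    skin <- high & d <= thresholds$skin_band_width
    lab[high & !skin] <- 4L
    lab[skin] <- 3L
  }
  attr(lab, "provenance") <- "segmented"
  lab
}

#' Fat-glandular boundary mask
#'
#' Pixels where fat and glandular labels are 8-adjacent (the morphological
#' gradient of the glandular mask restricted to fat-adjacent pixels), dilated
#' by `dilation_radius`. This mask underlies the memorization measure.
#'
#' @param label_map Segmented (or ground-truth) label map.
#' @param dilation_radius Dilation radius in pixels (default 2).
#' @return Logical matrix.
#' @export
fg_boundary_mask <- function(label_map, dilation_radius = 2) {
  fat <- label_map == 1L
  gl <- label_map == 2L
  if (!any(gl) || !any(fat))
    return(matrix(FALSE, nrow(label_map), ncol(label_map)))
  near_fat <- neighbor_count8(fat) > 0L
  near_gl <- neighbor_count8(gl) > 0L
  b <- (gl & near_fat) | (fat & near_gl)
  if (dilation_radius >= 1) {
    brush <- EBImage::makeBrush(2 * floor(dilation_radius) + 1, shape = "disc")
    b <- EBImage::dilate(b * 1, brush) > 0
    b <- matrix(b, nrow(label_map), ncol(label_map))
  }
  b
}

#' Per-tissue pixel counts of a label map
#'
#' @param label_map Integer label map with the 0-4 coding.
#' @return Tibble with one row per tissue (including background) and columns
#'   `tissue`, `label`, `n_pixels`.
#' @export
tissue_counts <- function(label_map) {
  n <- vapply(TISSUE_LABELS, function(l) sum(label_map == l), numeric(1))
  tibble(tissue = names(TISSUE_LABELS), label = unname(TISSUE_LABELS),
         n_pixels = unname(n))
}
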