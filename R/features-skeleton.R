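# Skeleton statistics of the ligament network and the compartments it bounds.

skeleton_feature_names <- function() {
  c("skel_n_skeletons", "skel_total_length",
    sprintf("skel_endpoints_%s", SUMMARY_STATS),
    sprintf("skel_branchpoints_%s", SUMMARY_STATS),
    sprintf("skel_length_%s", SUMMARY_STATS),
    sprintf("skel_segment_length_%s", SUMMARY_STATS),
    "skel_n_regions",
    sprintf("skel_region_area_%s", SUMMARY_STATS))
}

#' Skeleton statistics of the ligament network
#'
#' The ligament mask is defensively re-thinned to 1-pixel width, then: number
#' of connected skeletons (8-connectivity) and total pixel length; per
#' skeleton the endpoint count (exactly one 8-neighbour), branch-point count
#' (8-connected clusters of pixels with three or more 8-neighbours, so
#' adjacent branch pixels form one junction) and pixel length, each summarised by the
#' eight-statistic scheme; branch-segment pixel lengths (components after
#' branch points are removed) summarised; and the compartments bounded by
#' the network — 4-connected components of foreground minus ligament — as a
#' count plus summarised areas (the median region area is the `q2` entry).
#'
#' @param label_map Segmented label map (ligament label 4; foreground > 0).
#' @return Named numeric vector.
#' @export
skeleton_features <- function(label_map) {
  lig <- thin_mask(label_map == 4L)
  fg <- label_map > 0L
  if (!any(lig)) {
    out <- stats::setNames(rep(NA_real_, length(skeleton_feature_names())),
                           skeleton_feature_names())
    out[c("skel_n_skeletons", "skel_total_length")] <- 0
    out["skel_n_regions"] <- max(label_components(fg, 4))
    return(out)
  }
  labs <- label_components(lig, 8)
  nsk <- max(labs)
  nb <- neighbor_count8(lig)
  lv <- labs[lig]
  lengths <- tabulate(lv, nsk)
  endpoints <- tabulate(labs[lig & nb == 1L], nsk)
  # adjacent branch pixels belong to one junction: count 8-connected
  # clusters of >= 3-neighbour pixels, attributed to their skeleton
  bl <- label_components(lig & nb >= 3L, 8)
  branchpoints <- if (max(bl) > 0L) {
    bidx <- which(bl > 0L)
    sk_of <- vapply(split(labs[bidx], bl[bidx]), `[`, integer(1), 1)
    tabulate(sk_of, nsk)
  } else rep(0L, nsk)
  segs <- label_components(lig & nb < 3L, 8)
  seg_len <- tabulate(segs[segs > 0L], max(segs))
  regions <- label_components(fg & !lig, 4)
  region_area <- tabulate(regions[regions > 0L], max(regions))
  stats::setNames(
    c(nsk, sum(lig),
      summary8(endpoints), summary8(branchpoints), summary8(lengths),
      summary8(seg_len), max(regions), summary8(region_area)),
    skeleton_feature_names())
}
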