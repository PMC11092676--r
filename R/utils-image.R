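# Low-level raster helpers shared across modules. Images are integer matrices
# (rows = image rows, values 0..255); masks are logical matrices.

# Shift a matrix by (dr, dc), filling vacated cells.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-neighbour offsets (dr, dc)
NEIGH8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1,  0,  1, -1, 1, -1, 0, 1))

# All 8 shifted copies of a matrix at once, via a zero-padded frame.
shifted8 <- function(m, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(fill, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  lapply(seq_len(nrow(NEIGH8)), function(k) {
    pad[(2:(nr + 1L)) + NEIGH8[k, 1], (2:(nc + 1L)) + NEIGH8[k, 2]]
  })
}

# Count of 8-neighbours set, per pixel.
neighbor_count8 <- function(mask) {
  Reduce(`+`, shifted8(mask * 1L))
}

# Connected-component labelling. EBImage::bwlabel is 4-connectivity; for
# connectivity = 8 diagonal-adjacent labels are merged via union-find
# (igraph components) on the label adjacency graph.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1L) return(lab)
  edges <- NULL
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab
    b <- shift_mat(lab, off[1], off[2], 0L)
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) edges <- rbind(edges, cbind(a[sel], b[sel]))
  }
  if (is.null(edges)) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, max(lab) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  relab <- comp[lab[lab > 0L]]
  lab[lab > 0L] <- match(relab, sort(unique(relab)))
  lab
}

# Keep only the largest connected component of a mask.
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# Zhang-Suen thinning to a 1-pixel-wide skeleton (vectorised passes).
thin_mask <- function(mask) {
  m <- mask * 1L
  # neighbours in circular order P2..P9: N, NE, E, SE, S, SW, W, NW
  ord <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      pad[2:(nr + 1L), 2:(nc + 1L)] <- m
      p <- lapply(ord, function(o)
        pad[(2:(nr + 1L)) + o[1], (2:(nc + 1L)) + o[2]])
      b <- Reduce(`+`, p)
      a <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- p[[if (k == 8) 1 else k + 1]]
        a <- a + (p[[k]] == 0L & nxt == 1L)
      }
      if (step == 1) {
        cond <- p[[1]] * p[[3]] * p[[5]] == 0L & p[[3]] * p[[5]] * p[[7]] == 0L
      } else {
        cond <- p[[1]] * p[[3]] * p[[7]] == 0L & p[[1]] * p[[5]] * p[[7]] == 0L
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Oriented outer contours of labelled objects; list of n x 2 matrices of
# 0-based (x, y) coordinates as returned by EBImage::ocontour.
object_contours <- function(lab) {
  EBImage::ocontour(lab)
}

# Length of a closed polygonal chain through the given points (n x 2).
chain_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  d <- sqrt(rowSums((pts - pts[c(2:n, 1), , drop = FALSE])^2))
  sum(d)
}

# Convex hull of pixels given by (row, col) index matrix, computed on pixel
# corners so hull area always bounds pixel area. Returns area and perimeter.
hull_stats <- function(rc) {
  # 4 corners per pixel, in (x, y) = (col, row) coordinates
  x <- c(rc[, 2] - 0.5, rc[, 2] + 0.5, rc[, 2] - 0.5, rc[, 2] + 0.5)
  y <- c(rc[, 1] - 0.5, rc[, 1] - 0.5, rc[, 1] + 0.5, rc[, 1] + 0.5)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(h)
  if (n < 3) return(list(area = 0, perimeter = 0))
  j <- c(2:n, 1)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  per <- sum(sqrt((hx - hx[j])^2 + (hy - hy[j])^2))
  list(area = area, perimeter = per)
}

# 2^k max-pool downsampling of a logical mask (pads with FALSE).
block_maxpool <- function(mask, factor = 4L) {
  nr <- ceiling(nrow(mask) / factor) * factor
  nc <- ceiling(ncol(mask) / factor) * factor
  m <- matrix(0, nr, nc)
  m[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  # reduce rows then columns via colSums over the folded first dimension
  dim(m) <- c(factor, nr / factor, nc)
  m <- colSums(m) > 0
  m <- t(m) * 1
  dim(m) <- c(factor, nc / factor, nr / factor)
  t(colSums(m) > 0)
}

# Integral-image box sums: sum of m over all r x r windows (stride 1).
box_sums <- function(m, r) {
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  cs <- rbind(0, cbind(0, cs))
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc) return(numeric(0))
  i <- seq_len(nr - r + 1); j <- seq_len(nc - r + 1)
  cs[i + r, j + r, drop = FALSE] - cs[i, j + r, drop = FALSE] -
    cs[i + r, j, drop = FALSE] + cs[i, j, drop = FALSE]
}

# Pearson correlation between a logical vector and each column of a logical
# matrix, via binary counts (exact, fast).
binary_corr <- function(v, m) {
  n <- length(v)
  n1 <- sum(v)
  n2 <- colSums(m)
  n11 <- as.numeric(crossprod(m, v))
  num <- n * n11 - n1 * n2
  den <- sqrt(n1 * (n - n1)) * sqrt(n2 * (n - n2))
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

stopifnot_image8 <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    abort("expected an image as a numeric matrix")
  if (any(img < 0 | img > 255, na.rm = TRUE))
    abort("image values must lie in [0, 255]")
  invisible(img)
}
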