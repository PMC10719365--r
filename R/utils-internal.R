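# Internal array/morphology helpers shared across the pipeline.
# Conventions: 2D masks are logical (y, x) matrices; 3D masks logical
# (z, y, x) arrays; bounding boxes are 1-based inclusive.

#' @import EBImage
#' @importFrom stats median quantile sd var cor cov rnorm runif rpois t.test
#'   p.adjust wilcox.test prcomp dnorm uniroot setNames predict approx dist
#' @importFrom utils head read.csv write.csv combn
#' @importFrom grDevices chull
#' @importFrom tools md5sum
#' @importFrom MASS lda
#' @importFrom mclust Mclust mclustBIC
#' @importFrom randomForest randomForest
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

# vectorised median over a fixed set of shifted copies (full bubble sort
# network; m is tiny so O(m^2) compare-exchanges is fine)
.vec_median <- function(cols) {
  m <- length(cols)
  for (p in seq_len(m - 1L)) {
    for (q in seq_len(m - p)) {
      lo <- pmin(cols[[q]], cols[[q + 1L]])
      hi <- pmax(cols[[q]], cols[[q + 1L]])
      cols[[q]] <- lo
      cols[[q + 1L]] <- hi
    }
  }
  if (m %% 2L == 1L) {
    cols[[(m + 1L) %/% 2L]]
  } else {
    (cols[[m %/% 2L]] + cols[[m %/% 2L + 1L]]) / 2
  }
}

# reflective padding of a matrix by r pixels (mirror across the edge,
# edge row/col not repeated)
.pad_reflect <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(m), m - seq_len(r))
  x[ri, ci, drop = FALSE]
}

# shift a matrix by (dy, dx) with zero fill
.shift2d <- function(x, dy, dx, fill = 0) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  ys <- max(1L, 1L + dy):min(n, n + dy)
  xs <- max(1L, 1L + dx):min(m, m + dx)
  out[ys, xs] <- x[ys - dy, xs - dx]
  out
}

# 3D connected components, 6-connectivity: label each z-slice with
# EBImage::bwlabel, then merge slice labels touching across z via union-find.
.label3d <- function(mask) {
  d <- dim(mask)
  nz <- d[1]
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(nz)) {
    sl <- matrix(as.numeric(mask[z, , ]), d[2], d[3])
    if (!any(sl > 0)) next
    bl <- EBImage::bwlabel(sl)
    bl <- matrix(as.integer(bl), d[2], d[3])
    bl[bl > 0L] <- bl[bl > 0L] + offset
    lab[z, , ] <- bl
    offset <- max(bl)
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  for (z in seq_len(nz - 1L)) {
    a <- lab[z, , ]
    b <- lab[z + 1L, , ]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(pairs))) union(pairs[k, 1L], pairs[k, 2L])
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  nz_idx <- lab > 0L
  lab[nz_idx] <- relabel[lab[nz_idx]]
  lab
}

# iterated dilation of a 2D mask with the 3x3 cross structuring element
.dilate_cross2d <- function(mask, n_iter) {
  kern <- EBImage::makeBrush(3L, shape = "diamond")
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  for (i in seq_len(n_iter)) img <- EBImage::dilate(img, kern)
  matrix(img > 0.5, nrow(mask), ncol(mask))
}

# separable box dilation of a 3D mask: +/- rxy laterally, +/- rz axially
.dilate_box3d <- function(mask, rxy, rz) {
  d <- dim(mask)
  out <- mask
  if (rxy > 0L) {
    acc <- out
    for (s in seq_len(rxy)) {
      acc <- acc |
        .shift3d(out, 0L, s, 0L) | .shift3d(out, 0L, -s, 0L)
    }
    out <- acc
    acc <- out
    for (s in seq_len(rxy)) {
      acc <- acc |
        .shift3d(out, 0L, 0L, s) | .shift3d(out, 0L, 0L, -s)
    }
    out <- acc
  }
  if (rz > 0L) {
    acc <- out
    for (s in seq_len(rz)) {
      acc <- acc |
        .shift3d(out, s, 0L, 0L) | .shift3d(out, -s, 0L, 0L)
    }
    out <- acc
  }
  out
}

# shift a 3D logical array by (dz, dy, dx), FALSE fill
.shift3d <- function(x, dz, dy, dx) {
  d <- dim(x)
  out <- array(FALSE, d)
  zs <- max(1L, 1L + dz):min(d[1], d[1] + dz)
  ys <- max(1L, 1L + dy):min(d[2], d[2] + dy)
  xs <- max(1L, 1L + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- x[zs - dz, ys - dy, xs - dx]
  out
}

# convex hull of the TRUE pixels of a 2D mask, returned as a filled mask.
# Membership is tested against every hull edge's half-plane (hull is convex).
.convex_hull_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask & FALSE)
  if (nrow(idx) <= 2L) return(mask)
  pts <- idx[grDevices::chull(idx[, 2], idx[, 1]), , drop = FALSE]
  if (nrow(pts) <= 2L) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  yy <- matrix(rep(seq_len(n), m), n, m)
  xx <- matrix(rep(seq_len(m), each = n), n, m)
  inside <- matrix(TRUE, n, m)
  k <- nrow(pts)
  # chull() returns vertices clockwise in (x, y); our pts are (y, x) rows
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    ey <- pts[j, 1] - pts[i, 1]
    ex <- pts[j, 2] - pts[i, 2]
    # cross product sign; allow both orientations by fixing sign from centroid
    s <- ex * (mean(pts[, 1]) - pts[i, 1]) - ey * (mean(pts[, 2]) - pts[i, 2])
    cr <- ex * (yy - pts[i, 1]) - ey * (xx - pts[i, 2])
    if (s >= 0) inside <- inside & (cr >= -1e-9) else inside <- inside & (cr <= 1e-9)
  }
  inside
}

# bounding box of a logical mask, 1-based inclusive: c(y0, y1, x0, x1)
.bbox2d <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

.is_binary_array <- function(x) is.logical(x) || all(x %in% c(0, 1))

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
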