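# Fixed morphometric feature schema: 42 cellular features per cell (12 shape,
# 18 color, 12 texture) and 11 additional nuclear features per WBC (53 total).

#' The ordered morphometric feature schema
#'
#' @param cell_type `"RBC"` (42 cellular features) or `"WBC"` (42 cellular +
#'   11 nuclear = 53).
#' @return Character vector of ordered feature names.
#' @export
feature_schema <- function(cell_type = c("RBC", "WBC")) {
  cell_type <- match.arg(cell_type)
  shape <- c("area", "perimeter", "circularity", "eccentricity", "solidity",
             "convexity", "major_axis", "minor_axis", "aspect_ratio",
             "cdf_mean", "cdf_sd", "cdf_max_min_ratio")
  color <- as.vector(t(outer(c("r", "g", "b"),
                             c("mean", "sd", "skew", "q05", "q50", "q95"),
                             paste, sep = "_")))
  texture <- as.vector(t(outer(c("contrast", "dissimilarity", "homogeneity",
                                 "energy", "correlation", "asm"),
                               c("d1", "d3"),
                               function(a, b) paste0("glcm_", a, "_", b))))
  cellular <- c(shape, color, texture)
  stopifnot(length(cellular) == 42)
  if (cell_type == "RBC") return(cellular)
  nuclear <- c("nuc_area", "nuc_perimeter", "nuc_circularity",
               "nuc_eccentricity", "nuc_solidity", "nuc_convexity",
               "nuc_cell_area_ratio", "nuc_cdf_sd", "nuc_mean_intensity",
               "nuc_sd_intensity", "nuc_cyto_intensity_ratio")
  stopifnot(length(nuclear) == 11)
  c(cellular, nuclear)
}

#' Centroid distance function of a polygon
#'
#' The boundary is resampled at `n_samples` points equally spaced by arc
#' length (starting at the first vertex); the output is the Euclidean
#' distance from each resampled point to the polygon's area centroid. The
#' standard deviation of this vector is the contour-irregularity feature
#' `cdf_sd`.
#'
#' @param boundary n x 2 matrix of polygon vertices (open ring).
#' @param n_samples Number of resampled points (>= 8).
#' @return Numeric vector of length `n_samples`.
#' @export
centroid_distance_function <- function(boundary, n_samples = 128L) {
  boundary <- as.matrix(boundary)
  stopifnot(n_samples >= 8)
  a <- polygon_area_signed(boundary)
  if (abs(a) < .Machine$double.eps * 100) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  x <- boundary[, 1]; y <- boundary[, 2]
  n <- nrow(boundary)
  j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  cx <- sum((x + x[j]) * cross) / (6 * a)
  cy <- sum((y + y[j]) * cross) / (6 * a)
  seg <- sqrt((x[j] - x)^2 + (y[j] - y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1]
  t_at <- (seq_len(n_samples) - 1) * total / n_samples
  idx <- findInterval(t_at, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (t_at - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  px <- x[idx] + frac * (x[j][idx] - x[idx])
  py <- y[idx] + frac * (y[j][idx] - y[idx])
  sqrt((px - cx)^2 + (py - cy)^2)
}

# Cauchy-Crofton perimeter from neighbor transitions in 4 directions;
# less raster bias than counting boundary-pixel steps.
crofton_perimeter <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  c0 <- sum(m[, -1] != m[, -w]) + sum(m[, 1]) + sum(m[, w])
  c90 <- sum(m[-1, ] != m[-h, ]) + sum(m[1, ]) + sum(m[h, ])
  c45 <- sum(m[-h, -w] != m[-1, -1])
  c135 <- sum(m[-1, -w] != m[-h, -1])
  (pi / 8) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

# boundary polygon (0-based x,y) of the largest object in a mask
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(to_eb(matrix(as.integer(mask != 0), nrow(mask))))
  if (!length(oc)) stop("empty mask: no contour", call. = FALSE)
  sizes <- vapply(oc, nrow, integer(1))
  poly <- oc[[which.max(sizes)]]
  storage.mode(poly) <- "double"
  poly
}

# second-moment axes of a pixel mask
mask_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  cov <- crossprod(d) / nrow(d) + diag(1 / 12, 2)  # pixel-extent correction
  ev <- eigen(cov, symmetric = TRUE)$values
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  list(major = major, minor = minor,
       eccentricity = sqrt(pmax(1 - ev[2] / ev[1], 0)))
}

# convex hull of a point set: area and perimeter
points_hull <- function(xy) {
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  list(area = abs(polygon_area_signed(hull)),
       perimeter = polygon_perimeter(hull))
}

glcm_levels <- 32L

# angle-averaged symmetric normalized co-occurrence statistics at one distance
glcm_stats <- function(levels_mat, mask, dist) {
  h <- nrow(levels_mat); w <- ncol(levels_mat)
  offsets <- list(c(0, dist), c(dist, dist), c(dist, 0), c(-dist, dist))
  acc <- numeric(6)
  L <- glcm_levels
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    r1 <- max(1, 1 - dy):min(h, h - dy)
    c1 <- max(1, 1 - dx):min(w, w - dx)
    a <- levels_mat[r1, c1, drop = FALSE]
    b <- levels_mat[r1 + dy, c1 + dx, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dy, c1 + dx, drop = FALSE]
    av <- a[ok]; bv <- b[ok]
    counts <- tabulate(av + L * (bv - 1L), nbins = L * L)
    P <- matrix(counts, L, L)
    P <- P + t(P)
    if (sum(P) == 0) { acc <- acc + c(0, 0, 1, 1, 1, 1); next }
    P <- P / sum(P)
    ii <- matrix(rep(1:L, times = L), L)
    jj <- matrix(rep(1:L, each = L), L)
    dif <- ii - jj
    mu_i <- sum(ii * P); mu_j <- sum(jj * P)
    s_i <- sqrt(sum((ii - mu_i)^2 * P)); s_j <- sqrt(sum((jj - mu_j)^2 * P))
    corr <- if (s_i * s_j < 1e-12) 1 else
      sum((ii - mu_i) * (jj - mu_j) * P) / (s_i * s_j)
    asm <- sum(P^2)
    acc <- acc + c(sum(P * dif^2), sum(P * abs(dif)),
                   sum(P / (1 + dif^2)), sqrt(asm), corr, asm)
  }
  stats::setNames(acc / length(offsets),
                  c("contrast", "dissimilarity", "homogeneity", "energy",
                    "correlation", "asm"))
}

shape_features <- function(mask, prefix = "") {
  area <- sum(mask != 0)
  per <- crofton_perimeter(mask)
  poly <- mask_contour(mask)
  if (nrow(poly) < 3 || abs(polygon_area_signed(poly)) < 1e-9) {
    # sliver object: fall back to the hull of pixel corners as the boundary
    idx <- which(mask != 0, arr.ind = TRUE)
    x <- idx[, 2] - 1; y <- idx[, 1] - 1
    corners <- cbind(c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
                     c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
    poly <- corners[grDevices::chull(corners), , drop = FALSE]
  }
  # solidity/convexity compare the traced boundary polygon with the convex
  # hull of its vertices, so both are bounded by 1 up to float error
  poly_area <- abs(polygon_area_signed(poly))
  hull <- points_hull(poly)
  mom <- mask_moments(mask)
  cdf <- centroid_distance_function(poly, 128L)
  contour_per <- polygon_perimeter(poly)
  out <- c(
    area = area,
    perimeter = per,
    circularity = 4 * pi * area / per^2,
    eccentricity = mom$eccentricity,
    solidity = poly_area / max(hull$area, .Machine$double.eps),
    convexity = hull$perimeter / max(contour_per, .Machine$double.eps),
    major_axis = mom$major,
    minor_axis = mom$minor,
    aspect_ratio = mom$major / max(mom$minor, .Machine$double.eps),
    cdf_mean = mean(cdf),
    cdf_sd = stats::sd(cdf),
    cdf_max_min_ratio = max(cdf) / max(min(cdf), .Machine$double.eps)
  )
  if (nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  out
}

#' Extract the 42 cellular morphometric features
#'
#' Quantifies size and shape (area, Crofton perimeter, circularity,
#' eccentricity, solidity, convexity, principal axes, centroid-distance-
#' function statistics), the in-mask color distribution (mean, SD, skewness
#' and the 5/50/95% quantiles per RGB channel) and gray-level co-occurrence
#' texture (6 statistics at pixel distances 1 and 3, angle-averaged over the
#' 4 principal directions, 32 gray levels, symmetric normalized).
#'
#' @param pixels RGB array (H, W, 3), values 0..255.
#' @param mask Logical/integer matrix (H, W) marking the cell's pixels.
#' @return Named numeric vector following `feature_schema("RBC")`. A
#'   `border` attribute flags masks touching the tile border.
#' @export
extract_cell_features <- function(pixels, mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  stopifnot(all(dim(mask) == dim(pixels)[1:2]))
  border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  shape <- shape_features(mask)
  color <- numeric(0)
  for (ch in 1:3) {
    v <- pixels[, , ch][mask]
    q <- stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
    color <- c(color, mean(v), stats::sd(v), skewness_moment(v),
               q[1], q[2], q[3])
  }
  gray <- rgb_to_gray(pixels)
  lv <- pmin(floor(gray / (256 / glcm_levels)) + 1L, glcm_levels)
  storage.mode(lv) <- "integer"
  tex <- c(glcm_stats(lv, mask, 1L), glcm_stats(lv, mask, 3L))
  # interleave texture stats to match schema ordering (stat x distance)
  tex <- tex[as.vector(t(matrix(seq_len(12), 6)))]
  out <- c(shape, color, tex)
  out[!is.finite(out)] <- 0
  names(out) <- feature_schema("RBC")
  attr(out, "border") <- border
  out
}

#' Extract the 11 nuclear features of a WBC
#'
#' Nuclear size and shape (area, perimeter, circularity, eccentricity,
#' solidity, convexity), the nucleus:cell area ratio, the nuclear
#' centroid-distance-function SD, nuclear intensity statistics and the
#' nucleus:cytoplasm mean-intensity ratio.
#'
#' @param pixels RGB array (H, W, 3), values 0..255.
#' @param cell_mask,nucleus_mask Logical matrices; the nucleus must be a
#'   non-empty subset of the cell.
#' @return Named numeric vector following the nuclear block of
#'   `feature_schema("WBC")`, or all-NA with attribute `quality = "missing"`
#'   when the nucleus mask is empty.
#' @export
extract_nuclear_features <- function(pixels, cell_mask, nucleus_mask) {
  cell_mask <- cell_mask != 0
  nucleus_mask <- nucleus_mask != 0
  nuc_names <- setdiff(feature_schema("WBC"), feature_schema("RBC"))
  if (!any(nucleus_mask)) {
    out <- stats::setNames(rep(NA_real_, 11), nuc_names)
    attr(out, "quality") <- "missing"
    return(out)
  }
  if (any(nucleus_mask & !cell_mask)) {
    stop("nucleus mask must lie within the cell mask", call. = FALSE)
  }
  shp <- shape_features(nucleus_mask)
  gray <- rgb_to_gray(pixels)
  nuc_px <- gray[nucleus_mask]
  cyto <- cell_mask & !nucleus_mask
  cyto_mean <- if (any(cyto)) mean(gray[cyto]) else NA_real_
  out <- c(
    shp[["area"]], shp[["perimeter"]], shp[["circularity"]],
    shp[["eccentricity"]], shp[["solidity"]], shp[["convexity"]],
    sum(nucleus_mask) / sum(cell_mask),
    shp[["cdf_sd"]],
    mean(nuc_px), stats::sd(nuc_px),
    if (is.na(cyto_mean) || cyto_mean < 1e-12) 1 else mean(nuc_px) / cyto_mean
  )
  out[is.na(out)] <- 0
  stats::setNames(out, nuc_names)
}

#' Full feature vector for a detected cell
#'
#' @param pixels RGB tile pixels.
#' @param mask Cell mask.
#' @param nucleus_mask Optional nucleus mask (WBC).
#' @param cell_type `"RBC"` or `"WBC"`.
#' @return Named vector of 42 (RBC) or 53 (WBC) features.
#' @export
extract_features <- function(pixels, mask, nucleus_mask = NULL,
                             cell_type = c("RBC", "WBC")) {
  cell_type <- match.arg(cell_type)
  cellular <- extract_cell_features(pixels, mask)
  if (cell_type == "RBC") return(cellular)
  if (is.null(nucleus_mask)) nucleus_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  nuclear <- extract_nuclear_features(pixels, mask, nucleus_mask)
  out <- c(cellular, nuclear)
  names(out) <- feature_schema("WBC")
  out
}
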