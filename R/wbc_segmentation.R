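# WBC instance segmentation: a pluggable pixel-probability backend (here a
# gradient-trained logistic pixel classifier over color/context features),
# dihedral test-time augmentation, rule-based post-processing, and nucleus
# partitioning by 2-cluster intensity clustering.

# per-pixel design matrix: raw RGB, smoothed RGB (context), local intensity SD
pixel_features <- function(px, sigma = 4) {
  g <- rgb_to_gray(px)
  sm <- array(0, dim(px))
  for (ch in 1:3) sm[, , ch] <- from_eb(EBImage::gblur(to_eb(px[, , ch]), sigma))
  g2 <- from_eb(EBImage::gblur(to_eb(g^2), sigma))
  g1 <- from_eb(EBImage::gblur(to_eb(g), sigma))
  lsd <- sqrt(pmax(g2 - g1^2, 0))
  cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]),
        as.vector(sm[, , 1]), as.vector(sm[, , 2]), as.vector(sm[, , 3]),
        as.vector(lsd))
}

n_pixel_features <- 7L

#' Initialize a pixel-probability segmenter
#'
#' @param input_size Expected tile side (px).
#' @return Object of class `segmenter_model` with zero weights.
#' @export
init_segmenter <- function(input_size = 512L) {
  structure(list(backend = "pixel_logistic",
                 w = numeric(n_pixel_features + 1L),
                 center = rep(0, n_pixel_features),
                 scale = rep(1, n_pixel_features),
                 input_size = as.integer(input_size)),
            class = "segmenter_model")
}

predict_prob_map <- function(model, px) {
  X <- pixel_features(px)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- sigmoid(model$w[1] + Xs %*% model$w[-1])
  matrix(p, dim(px)[1], dim(px)[2])
}

#' The 8 dihedral transforms of a square image
#'
#' Each element carries a `forward` and `inverse` function acting on matrices
#' (and, with `apply_rgb()`, on RGB arrays). Used for test-time augmentation.
#'
#' @return List of 8 transform pairs; the first is the identity.
#' @export
dihedral_transforms <- function() {
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])        # 90 deg CW
  rotk <- function(m, k) { for (i in seq_len(k %% 4)) m <- rot(m); m }
  flip <- function(m) m[, ncol(m):1, drop = FALSE]
  out <- list()
  for (k in 0:3) {
    out[[length(out) + 1]] <- list(
      forward = local({ kk <- k; function(m) rotk(m, kk) }),
      inverse = local({ kk <- k; function(m) rotk(m, (4 - kk) %% 4) }))
    out[[length(out) + 1]] <- list(
      forward = local({ kk <- k; function(m) flip(rotk(m, kk)) }),
      inverse = local({ kk <- k; function(m) rotk(flip(m), (4 - kk) %% 4) }))
  }
  out
}

apply_rgb <- function(f, px) {
  planes <- lapply(1:3, function(ch) f(px[, , ch]))
  array(unlist(planes), c(dim(planes[[1]]), 3))
}

#' Pixel probability map for a tile, with optional test-time augmentation
#'
#' With `tta`, the tile is passed through every transform of the supplied
#' symmetry group, predictions are inverse-transformed and averaged; over the
#' full 8-element dihedral group this reduces prediction variance and makes
#' the output equivariant.
#'
#' @param model A `segmenter_model`.
#' @param tl A [tile()] matching the model input size.
#' @param tta Use test-time augmentation?
#' @param transforms Symmetry group to average over (default the 8 dihedral
#'   transforms; pass a sublist such as the identity only to restrict it).
#' @return Matrix (H, W) of probabilities in \[0, 1\].
#' @export
segment_probabilities <- function(model, tl, tta = TRUE,
                                  transforms = dihedral_transforms()) {
  stopifnot(inherits(model, "segmenter_model"))
  px <- if (inherits(tl, "cyto_tile")) tl$pixels else tl
  if (dim(px)[1] != model$input_size || dim(px)[2] != model$input_size) {
    stop("tile size does not match segmenter input size", call. = FALSE)
  }
  if (!tta) return(predict_prob_map(model, px))
  maps <- lapply(transforms, function(tr) {
    tr$inverse(predict_prob_map(model, apply_rgb(tr$forward, px)))
  })
  Reduce(`+`, maps) / length(maps)
}

#' Post-processing parameters for WBC instance extraction
#'
#' Defaults assume 40x magnification at ~0.25 um/px, where plausible
#' leukocyte areas fall between 300 and 15000 px^2.
#'
#' @param prob_threshold Probability cut in \[0, 1\].
#' @param min_area,max_area Component area gates (px^2), 0 < min < max.
#' @param hole_fill Fill holes inside components?
#' @param split_touching Split touching cells by distance-transform
#'   watershed? Off by default (undersegmentation is rare).
#' @return Object of class `postprocess_params`.
#' @export
postprocess_params <- function(prob_threshold = 0.5, min_area = 300,
                               max_area = 15000, hole_fill = TRUE,
                               split_touching = FALSE) {
  stopifnot(prob_threshold >= 0, prob_threshold <= 1,
            min_area > 0, min_area < max_area)
  structure(list(prob_threshold = prob_threshold, min_area = min_area,
                 max_area = max_area, hole_fill = hole_fill,
                 split_touching = split_touching),
            class = "postprocess_params")
}

#' Extract WBC instance masks from a probability map
#'
#' Threshold, 8-connected components, hole filling, area gating and optional
#' watershed splitting of touching cells. Returned instances are pairwise
#' disjoint.
#'
#' @param prob_map Matrix of probabilities in \[0, 1\].
#' @param params A [postprocess_params()].
#' @return List of logical instance masks (possibly empty).
#' @export
postprocess <- function(prob_map, params = postprocess_params()) {
  stopifnot(min(prob_map) >= 0, max(prob_map) <= 1)
  mask <- prob_map >= params$prob_threshold
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  if (params$hole_fill) {
    lab <- from_eb(EBImage::fillHull(to_eb(lab)))
  }
  if (params$split_touching) {
    dm <- EBImage::distmap(to_eb(matrix(as.integer(lab > 0), nrow(lab))))
    lab <- from_eb(EBImage::watershed(dm, tolerance = 1, ext = 1))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_area & sizes <= params$max_area)
  lapply(keep, function(k) lab == k)
}

#' Partition a WBC into nucleus and cytoplasm
#'
#' Grayscale intensities under the cell mask are split into 2 clusters with
#' k-means (10 restarts, seeded); the cluster with lower mean intensity is
#' taken as the nucleus and its largest connected component(s) retained.
#' Under inverted contrast (nucleus lighter than cytoplasm) the darker region
#' is still returned -- a documented low-contrast failure mode.
#'
#' @param px RGB tile pixels.
#' @param cell_mask Logical cell mask.
#' @param keep_fraction Secondary components at least this fraction of the
#'   largest are kept (lobed nuclei can disconnect).
#' @return Logical nucleus mask, subset of `cell_mask`.
#' @export
segment_nucleus <- function(px, cell_mask, keep_fraction = 0.25) {
  cell_mask <- cell_mask != 0
  g <- rgb_to_gray(px)
  vals <- g[cell_mask]
  if (length(unique(round(vals, 6))) < 2) {
    stop("degenerate cell: constant intensity, nucleus undefined",
         call. = FALSE)
  }
  km <- with_seed(7L, stats::kmeans(vals, centers = 2, nstart = 10))
  dark <- which.min(km$centers)
  idx_cell <- which(cell_mask)
  nucleus <- matrix(FALSE, nrow(g), ncol(g))
  nucleus[idx_cell[km$cluster == dark]] <- TRUE
  lab <- label_components(nucleus)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= keep_fraction * max(sizes))
  nucleus <- matrix(lab %in% keep, nrow(g))
  nucleus & cell_mask
}

# logistic pixel-classifier training by full-batch Adam; kept as an explicit
# epoch loop so that zero epochs means "model equals initialization"
train_pixel_logistic <- function(X, y, epochs, lr, init = NULL) {
  w <- init %||% numeric(ncol(X) + 1L)
  opt <- adam_init(length(w), lr = lr)
  loss <- numeric(0)
  n <- length(y)
  for (e in seq_len(epochs)) {
    eta <- w[1] + X %*% w[-1]
    p <- sigmoid(eta)
    loss <- c(loss, -mean(y * log(pmax(p, 1e-12)) +
                            (1 - y) * log(pmax(1 - p, 1e-12))))
    gl <- (p - y) / n
    grad <- c(sum(gl), crossprod(X, gl))
    opt <- adam_step(opt, as.numeric(grad))
    w <- w - opt$delta
  }
  list(w = w, loss = loss)
}

#' Train the WBC pixel segmenter on annotated tiles
#'
#' Pixels are sampled from each annotated tile (balanced between WBC and
#' background); the configured augmentations (dihedral flips/rotations,
#' intensity jitter, Gaussian blur) expand the sample, and a logistic pixel
#' classifier is fitted by full-batch Adam. Deterministic given `seed`.
#'
#' @param tiles List of [tile()] objects (or RGB arrays).
#' @param masks List of logical ground-truth WBC masks, same length.
#' @param epochs Training epochs (0 returns the initialization).
#' @param lr Adam learning rate.
#' @param n_pixels Pixels sampled per tile (before augmentation).
#' @param augment List of augmentation switches: `dihedral`, `jitter`,
#'   `blur`.
#' @param seed Integer seed.
#' @return A `segmenter_model` with a `loss` attribute (per-epoch training
#'   loss).
#' @export
train_segmenter <- function(tiles, masks, epochs = 150, lr = 0.05,
                            n_pixels = 1500,
                            augment = list(dihedral = TRUE, jitter = TRUE,
                                           blur = TRUE),
                            seed = 1L) {
  if (!length(tiles)) stop("no annotated tiles provided", call. = FALSE)
  stopifnot(length(tiles) == length(masks))
  with_seed(seed, {
    Xs <- list(); ys <- list()
    trs <- dihedral_transforms()
    for (i in seq_along(tiles)) {
      px <- if (inherits(tiles[[i]], "cyto_tile")) tiles[[i]]$pixels else
        tiles[[i]]
      m <- masks[[i]] != 0
      variants <- list(list(px = px, m = m))
      if (isTRUE(augment$dihedral)) {
        tr <- trs[[sample.int(8, 1)]]
        variants[[2]] <- list(px = apply_rgb(tr$forward, px),
                              m = tr$forward(m))
      }
      if (isTRUE(augment$jitter)) {
        variants[[length(variants) + 1]] <-
          list(px = pmin(pmax(px * stats::runif(1, 0.9, 1.1) +
                                stats::rnorm(1, 0, 6), 0), 255), m = m)
      }
      if (isTRUE(augment$blur)) {
        b <- px
        for (ch in 1:3) b[, , ch] <- from_eb(EBImage::gblur(to_eb(px[, , ch]),
                                                            1.5))
        variants[[length(variants) + 1]] <- list(px = b, m = m)
      }
      for (v in variants) {
        F <- pixel_features(v$px)
        fg <- which(as.vector(v$m)); bg <- which(!as.vector(v$m))
        take <- c(sample(fg, min(length(fg), n_pixels %/% 2)),
                  sample(bg, min(length(bg), n_pixels %/% 2)))
        Xs[[length(Xs) + 1]] <- F[take, , drop = FALSE]
        ys[[length(ys) + 1]] <- as.integer(as.vector(v$m)[take])
      }
    }
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    mu <- colMeans(X); sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xn <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    fit <- train_pixel_logistic(Xn, y, epochs = epochs, lr = lr)
    model <- init_segmenter(input_size = dim(
      if (inherits(tiles[[1]], "cyto_tile")) tiles[[1]]$pixels else
        tiles[[1]])[1])
    model$w <- as.numeric(fit$w)
    model$center <- mu
    model$scale <- sdev
    attr(model, "loss") <- fit$loss
    model
  })
}
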