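# Tile quality control: keep only informative, monolayer-like tiles (not too
# sparse, not too dense, not blurred) before any cell detection runs.

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonal-only
# neighbors are merged afterwards with a union-find pass.
label_components <- function(mask) {
  lab <- from_eb(EBImage::bwlabel(to_eb(matrix(as.integer(mask != 0),
                                               nrow(mask)))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
    roots <- vapply(seq_len(n), find, integer(1))
    relabel <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- relabel[lab[lab > 0]]
  }
  lab
}

# Engineered tile descriptors: cell-scale blob count (difference-of-Gaussian
# response), foreground fraction, and variance-of-Laplacian sharpness.
# Squared density terms let a linear classifier carve out the mid-density
# band that corresponds to the monolayer.
qc_features <- function(tl) {
  px <- if (inherits(tl, "cyto_tile")) tl$pixels else tl
  g <- rgb_to_gray(px)
  bg <- stats::median(g)
  fg <- abs(g - bg) > 12
  fg_frac <- mean(fg)
  dog <- from_eb(EBImage::gblur(to_eb(g), 6)) -
    from_eb(EBImage::gblur(to_eb(g), 12))
  blobs <- label_components(dog < -3)
  sizes <- tabulate(blobs[blobs > 0])
  blob_count <- sum(sizes >= 40)
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3)
  lapv <- from_eb(EBImage::filter2(to_eb(g), k))
  sharp <- log1p(stats::var(as.vector(lapv)))
  c(fg_frac = fg_frac, fg_frac_sq = fg_frac^2,
    blob_count = blob_count, blob_count_sq = blob_count^2,
    sharpness = sharp, gray_sd = stats::sd(as.vector(g)))
}

#' Train a tile quality-control classifier
#'
#' The default backend computes engineered tile descriptors (cell-scale blob
#' count, foreground fraction, variance-of-Laplacian sharpness plus squared
#' density terms) and fits a ridge-regularized logistic model. Training is
#' deterministic given `seed`.
#'
#' @param tiles List of [tile()] objects (or raw RGB arrays).
#' @param labels Character/factor vector of `"good"` / `"poor"` per tile.
#' @param threshold Probability cut for calling a tile good (default 0.5).
#' @param seed Integer seed.
#' @return Object of class `qc_model`.
#' @export
train_qc <- function(tiles, labels, threshold = 0.5, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("good", "poor")))
  if (length(unique(labels)) < 2) {
    stop("QC training requires both classes", call. = FALSE)
  }
  X <- do.call(rbind, purrr::map(tiles, qc_features))
  y <- as.integer(labels == "good")
  mu <- colMeans(X); sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  fit <- with_seed(seed, suppressWarnings(
    glmnet::glmnet(Xs, y, family = "binomial", alpha = 0, lambda = 0.01)))
  input_size <- if (inherits(tiles[[1]], "cyto_tile")) tiles[[1]]$size[1] else
    dim(tiles[[1]])[1]
  structure(list(backend = "engineered", fit = fit, center = mu,
                 scale = sdev, threshold = threshold,
                 input_size = input_size),
            class = "qc_model")
}

#' Classify one tile as good or poor quality
#'
#' @param model A `qc_model` from [train_qc()].
#' @param tl A [tile()] of the model's input size.
#' @return List with `verdict` (`"good"`/`"poor"`) and `score` in \[0, 1\]
#'   (probability of good quality); `verdict == "good"` iff
#'   `score >= threshold`.
#' @export
classify_tile <- function(model, tl) {
  stopifnot(inherits(model, "qc_model"))
  px <- if (inherits(tl, "cyto_tile")) tl$pixels else tl
  if (dim(px)[1] != model$input_size || dim(px)[2] != model$input_size) {
    stop(sprintf("tile size %dx%d does not match model input %d",
                 dim(px)[1], dim(px)[2], model$input_size), call. = FALSE)
  }
  x <- (qc_features(px) - model$center) / model$scale
  score <- as.numeric(stats::predict(model$fit, matrix(x, 1),
                                     type = "response"))
  list(verdict = if (score >= model$threshold) "good" else "poor",
       score = score)
}

#' Classify many tiles
#'
#' @param model A `qc_model`.
#' @param tiles List of tiles.
#' @return Tibble with `slide_id`, `origin_x`, `origin_y`, `score`,
#'   `verdict`.
#' @export
classify_tiles <- function(model, tiles) {
  purrr::map_dfr(tiles, function(tl) {
    r <- classify_tile(model, tl)
    tibble::tibble(
      slide_id = if (inherits(tl, "cyto_tile")) tl$slide_id else "tile",
      origin_x = if (inherits(tl, "cyto_tile")) tl$origin[1] else NA_integer_,
      origin_y = if (inherits(tl, "cyto_tile")) tl$origin[2] else NA_integer_,
      score = r$score, verdict = r$verdict)
  })
}

#' Fraction of good-quality tiles
#'
#' @param verdicts Character vector of `"good"`/`"poor"` verdicts for one
#'   slide.
#' @return Fraction of good tiles in \[0, 1\].
#' @export
qc_fraction <- function(verdicts) {
  if (!length(verdicts)) stop("no tiles to summarize", call. = FALSE)
  mean(verdicts == "good")
}
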