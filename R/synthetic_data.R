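# Synthetic smear tiles and synthetic per-cell feature bags. The tile
# renderer emulates the objects a smear pipeline must cope with -- pale-
# centered RBC discs, larger WBC with a strictly darker multi-lobed nucleus,
# small dark platelets, optional blur and sensor noise. The bag simulator
# plants a known morphotype mixture per condition so that downstream models
# can be checked for parameter recovery.

#' Describe the content of a synthetic tile
#'
#' @param rbc Tibble/data frame with columns `x`, `y` (centers, 0-based),
#'   `rx`, `ry` (radii px), `rot` (radians), `pallor` (logical central-pallor
#'   flag). May be NULL.
#' @param wbc Tibble with columns `x`, `y`, `r` (cell radius px), `lobes`
#'   (nucleus lobe count >= 1), `nuc_dx`, `nuc_dy` (nucleus offset px).
#' @param platelets Tibble with columns `x`, `y`, `r`.
#' @param blur_sigma Gaussian blur in px (>= 0).
#' @param noise_sd Additive Gaussian pixel noise (8-bit units).
#' @param size Tile side in px.
#' @param background RGB background color (0..255).
#' @return An object of class `tile_scene`.
#' @export
tile_scene <- function(rbc = NULL, wbc = NULL, platelets = NULL,
                       blur_sigma = 0, noise_sd = 0, size = 512L,
                       background = c(236, 228, 232)) {
  stopifnot(blur_sigma >= 0, noise_sd >= 0, size > 0)
  radii <- c(if (!is.null(rbc)) c(rbc$rx, rbc$ry),
             if (!is.null(wbc)) wbc$r,
             if (!is.null(platelets)) platelets$r)
  if (length(radii) && any(radii <= 1)) {
    stop("scene error: object radius must exceed 1 px", call. = FALSE)
  }
  structure(list(rbc = rbc, wbc = wbc, platelets = platelets,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 size = as.integer(size), background = background),
            class = "tile_scene")
}

# masks on the 0-based pixel grid
ellipse_mask <- function(size, x0, y0, rx, ry, rot = 0) {
  xs <- matrix(rep(0:(size - 1), each = size), size)  # [row, col] = col index
  ys <- matrix(rep(0:(size - 1), times = size), size)
  dx <- xs - x0; dy <- ys - y0
  u <- dx * cos(rot) + dy * sin(rot)
  v <- -dx * sin(rot) + dy * cos(rot)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Render a synthetic smear tile with ground truth
#'
#' RBC are drawn as stained ellipses whose central region is rendered paler
#' than the rim (central pallor); WBC as larger cells with a strictly darker,
#' possibly multi-lobed nucleus; platelets as small dark dots. Rendering is
#' deterministic given `seed`.
#'
#' @param scene A [tile_scene()].
#' @param seed Integer seed controlling color jitter and noise.
#' @return List with `tile` (a [tile()]), `labels` (integer matrix, 0 =
#'   background, k = object k), `types` (character vector per object:
#'   RBC/WBC/platelet) and `nucleus` (logical matrix of WBC nucleus pixels).
#' @export
render_tile <- function(scene, seed = 1L) {
  stopifnot(inherits(scene, "tile_scene"))
  with_seed(seed, {
    n <- scene$size
    px <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) px[, , ch] <- scene$background[ch]
    labels <- matrix(0L, n, n)
    nucleus <- matrix(FALSE, n, n)
    types <- character(0)
    paint <- function(mask, color) {
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[mask] <- color[ch]
        px[, , ch] <<- plane
      }
    }
    obj_id <- 0L
    # RBC: rim fully stained, center mixed toward background (pallor)
    if (!is.null(scene$rbc)) {
      for (i in seq_len(nrow(scene$rbc))) {
        s <- scene$rbc[i, ]
        base <- c(208, 138, 148) + stats::rnorm(3, 0, 4)
        m <- ellipse_mask(n, s$x, s$y, s$rx, s$ry, s$rot)
        paint(m, base)
        if (isTRUE(s$pallor)) {
          inner <- ellipse_mask(n, s$x, s$y, 0.55 * s$rx, 0.55 * s$ry, s$rot)
          paint(inner, 0.35 * base + 0.65 * scene$background)
        }
        obj_id <- obj_id + 1L
        labels[m] <- obj_id
        types <- c(types, "RBC")
      }
    }
    if (!is.null(scene$wbc)) {
      for (i in seq_len(nrow(scene$wbc))) {
        s <- scene$wbc[i, ]
        cyt <- c(188, 188, 226) + stats::rnorm(3, 0, 4)
        nuc <- c(88, 58, 128) + stats::rnorm(3, 0, 4)
        m <- ellipse_mask(n, s$x, s$y, s$r, s$r)
        paint(m, cyt)
        lobes <- max(1L, as.integer(s$lobes))
        lobe_r <- s$r * if (lobes == 1) 0.55 else 0.38
        ring_r <- if (lobes == 1) 0 else s$r * 0.34
        nmask <- matrix(FALSE, n, n)
        for (l in seq_len(lobes)) {
          ang <- 2 * pi * (l - 1) / lobes
          cx <- s$x + s$nuc_dx + ring_r * cos(ang)
          cy <- s$y + s$nuc_dy + ring_r * sin(ang)
          nmask <- nmask | (ellipse_mask(n, cx, cy, lobe_r, lobe_r) & m)
        }
        paint(nmask, nuc)
        obj_id <- obj_id + 1L
        labels[m] <- obj_id
        nucleus <- nucleus | nmask
        types <- c(types, "WBC")
      }
    }
    if (!is.null(scene$platelets)) {
      for (i in seq_len(nrow(scene$platelets))) {
        s <- scene$platelets[i, ]
        m <- ellipse_mask(n, s$x, s$y, s$r, s$r)
        paint(m, c(122, 92, 152) + stats::rnorm(3, 0, 4))
        obj_id <- obj_id + 1L
        labels[m] <- obj_id
        types <- c(types, "platelet")
      }
    }
    if (scene$blur_sigma > 0) {
      for (ch in 1:3) {
        px[, , ch] <- from_eb(EBImage::gblur(to_eb(px[, , ch]),
                                             sigma = scene$blur_sigma))
      }
    }
    if (scene$noise_sd > 0) {
      px <- px + array(stats::rnorm(length(px), 0, scene$noise_sd), dim(px))
    }
    px <- pmin(pmax(px, 0), 255)
    list(tile = tile(px, slide_id = "synthetic", origin = c(0L, 0L)),
         labels = labels, types = types, nucleus = nucleus)
  })
}

#' Sample a random smear scene
#'
#' Places the requested number of non-overlapping RBC, WBC and platelets
#' uniformly in the tile, at radii realistic for a 40x scan at 0.25 um/px
#' (RBC ~ 7 um, WBC ~ 12-15 um).
#'
#' @param n_rbc,n_wbc,n_platelets Object counts.
#' @param size Tile side (px).
#' @param blur_sigma,noise_sd Passed to [tile_scene()].
#' @param seed Integer seed.
#' @param margin Minimum gap between object rims, px.
#' @return A [tile_scene()].
#' @export
random_scene <- function(n_rbc = 25, n_wbc = 2, n_platelets = 4, size = 512L,
                         blur_sigma = 0, noise_sd = 2, seed = 1L, margin = 4) {
  with_seed(seed, {
    placed <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    place <- function(r, n_try = 400) {
      for (k in seq_len(n_try)) {
        x <- stats::runif(1, r + 2, size - r - 3)
        y <- stats::runif(1, r + 2, size - r - 3)
        if (!nrow(placed) ||
            all(sqrt((placed$x - x)^2 + (placed$y - y)^2) >
                placed$r + r + margin)) {
          placed[nrow(placed) + 1, ] <<- c(x, y, r)
          return(c(x, y))
        }
      }
      stop("could not place object without overlap; reduce counts",
           call. = FALSE)
    }
    wbc <- NULL
    if (n_wbc > 0) {
      wbc <- purrr::map_dfr(seq_len(n_wbc), function(i) {
        r <- stats::runif(1, 24, 30)
        ctr <- place(r)
        tibble::tibble(x = ctr[1], y = ctr[2], r = r,
                       lobes = sample(1:4, 1),
                       nuc_dx = stats::runif(1, -3, 3),
                       nuc_dy = stats::runif(1, -3, 3))
      })
    }
    rbc <- NULL
    if (n_rbc > 0) {
      rbc <- purrr::map_dfr(seq_len(n_rbc), function(i) {
        rx <- stats::runif(1, 12, 15)
        ry <- rx * stats::runif(1, 0.85, 1)
        ctr <- place(max(rx, ry))
        tibble::tibble(x = ctr[1], y = ctr[2], rx = rx, ry = ry,
                       rot = stats::runif(1, 0, pi), pallor = TRUE)
      })
    }
    platelets <- NULL
    if (n_platelets > 0) {
      platelets <- purrr::map_dfr(seq_len(n_platelets), function(i) {
        r <- stats::runif(1, 2.5, 4.5)
        ctr <- place(r)
        tibble::tibble(x = ctr[1], y = ctr[2], r = r)
      })
    }
    tile_scene(rbc = rbc, wbc = wbc, platelets = platelets,
               blur_sigma = blur_sigma, noise_sd = noise_sd, size = size)
  })
}

# --- feature-bag simulation -------------------------------------------------

default_mixing <- function(K_true) {
  # each condition emphasizes one planted morphotype; the last condition is
  # kept flat so that every task contrast carries signal
  base <- rep(0.45 / max(K_true - 1, 1), K_true)
  mk <- function(k) { v <- base; v[k] <- 0.55; v / sum(v) }
  list(control = mk(1), IDA = mk(2), MA = mk(3),
       MDS_SF3B1 = mk(pmin(4, K_true)), MDS_other = rep(1 / K_true, K_true))
}

# Blood-count means per condition (cells/uL, g/dL, platelets/uL), taken from
# the cohort summary tables; fixed study conditions, not tuning knobs.
default_blood_count_means <- function() {
  list(control   = c(wbcc = 6750, hb = 13.0, plt = 256e3),
       IDA       = c(wbcc = 7000, hb = 7.1,  plt = 382e3),
       MA        = c(wbcc = 3300, hb = 5.3,  plt = 110e3),
       MDS_SF3B1 = c(wbcc = 6253, hb = 10.7, plt = 282e3),
       MDS_other = c(wbcc = 4525, hb = 9.3,  plt = 117e3))
}

#' Design a planted-morphotype bag simulation
#'
#' Each cell type (WBC, RBC) gets `K_true` Gaussian morphotypes in `d`
#' dimensions; a slide of condition `c` draws each cell's morphotype from the
#' condition's mixing vector and its features from the morphotype centroid
#' plus isotropic noise. Centroids are placed at a guaranteed minimum pairwise
#' separation (in units of within-morphotype scatter).
#'
#' @param conditions Named integer vector: slides per condition.
#' @param cells_per_slide Length-2 range; per-slide counts drawn uniformly.
#' @param d Feature dimension per cell type (named `wbc`, `rbc`).
#' @param K_true Planted morphotype count per cell type.
#' @param within_scatter Within-morphotype standard deviation.
#' @param separation Minimum centroid separation in multiples of
#'   `within_scatter`.
#' @param mixing Optional list per cell type: condition -> length-K simplex
#'   vector. Defaults to one dominant morphotype per condition.
#' @param blood_count_means Optional list condition -> c(wbcc, hb, plt).
#' @param blood_count_cv Coefficient of variation for blood counts.
#' @param seed Integer seed.
#' @return An object of class `bag_design`.
#' @export
bag_design <- function(conditions = c(control = 12, IDA = 6, MA = 6,
                                      MDS_SF3B1 = 6, MDS_other = 6),
                       cells_per_slide = c(100, 300),
                       d = c(wbc = 10, rbc = 10),
                       K_true = c(wbc = 4, rbc = 4),
                       within_scatter = 1, separation = 6,
                       mixing = NULL, blood_count_means = NULL,
                       blood_count_cv = 0.15, seed = 1L) {
  stopifnot(all(names(conditions) %in% cyto_conditions),
            within_scatter > 0, separation > 0,
            length(cells_per_slide) == 2)
  centroids <- list()
  with_seed(seed, {
    for (ct in c("wbc", "rbc")) {
      K <- K_true[[ct]]
      M <- matrix(stats::rnorm(K * d[[ct]]), K)
      # rescale so the minimum pairwise distance hits the requested separation
      dmin <- min(stats::dist(M))
      centroids[[ct]] <- M * (separation * within_scatter / dmin)
    }
  })
  if (is.null(mixing)) {
    mixing <- list(wbc = default_mixing(K_true[["wbc"]]),
                   rbc = default_mixing(K_true[["rbc"]]))
  }
  for (ct in c("wbc", "rbc")) {
    for (cn in names(conditions)) {
      v <- mixing[[ct]][[cn]]
      if (is.null(v) || abs(sum(v) - 1) > 1e-8 ||
          length(v) != K_true[[ct]]) {
        stop("mixing vectors must be length-K simplex vectors per condition",
             call. = FALSE)
      }
    }
  }
  structure(list(conditions = conditions, cells_per_slide = cells_per_slide,
                 d = d, K_true = K_true, centroids = centroids,
                 within_scatter = within_scatter, separation = separation,
                 mixing = mixing,
                 blood_count_means = blood_count_means %||%
                   default_blood_count_means(),
                 blood_count_cv = blood_count_cv, seed = seed),
            class = "bag_design")
}

#' Simulate slide bags with planted morphotype structure
#'
#' @param design A [bag_design()].
#' @return List with `bags` (list of [slide_bag()]) and `cells` (tibble of
#'   planted assignments: slide_id, cell_id, cell_type, morphotype,
#'   condition).
#' @export
simulate_bags <- function(design) {
  stopifnot(inherits(design, "bag_design"))
  with_seed(design$seed + 1L, {
    bags <- list()
    cells <- list()
    idx <- 0L
    for (cn in names(design$conditions)) {
      for (s in seq_len(design$conditions[[cn]])) {
        idx <- idx + 1L
        sid <- sprintf("%s_%02d", cn, s)
        n_cells <- sample(design$cells_per_slide[1]:design$cells_per_slide[2], 1)
        feats <- list()
        for (ct in c("wbc", "rbc")) {
          K <- design$K_true[[ct]]
          dd <- design$d[[ct]]
          z <- sample.int(K, n_cells, replace = TRUE,
                          prob = design$mixing[[ct]][[cn]])
          X <- design$centroids[[ct]][z, , drop = FALSE] +
            matrix(stats::rnorm(n_cells * dd, 0, design$within_scatter),
                   n_cells)
          colnames(X) <- sprintf("f%02d", seq_len(dd))
          feats[[ct]] <- X
          cells[[length(cells) + 1]] <- tibble::tibble(
            slide_id = sid,
            cell_id = sprintf("%s_%s_%04d", sid, ct, seq_len(n_cells)),
            cell_type = toupper(ct), morphotype = z, condition = cn)
        }
        mu <- design$blood_count_means[[cn]]
        bc <- stats::setNames(
          pmax(stats::rnorm(3, mu, design$blood_count_cv * mu), 0.05 * mu),
          c("wbcc", "hb", "plt"))
        bags[[idx]] <- slide_bag(sid, feats$wbc, feats$rbc,
                                 blood_counts = bc, condition = cn)
      }
    }
    list(bags = bags, cells = dplyr::bind_rows(cells))
  })
}

#' Benchmark scene of single RBC discs plus confounding objects
#'
#' Grid-places pale-centered single RBC discs together with fused RBC
#' doublets and platelet clumps -- the non-RBC object classes a morphometric
#' candidate filter must reject. Ground truth: objects `1..n_single` in the
#' rendered label image are the true single RBCs.
#'
#' @param seed Integer seed.
#' @param n_single,n_doublet,n_clump Object counts.
#' @return List with `scene` (a [tile_scene()]) and `n_single`.
#' @export
rbc_benchmark_scene <- function(seed, n_single = 30, n_doublet = 5,
                                n_clump = 5) {
  with_seed(seed, {
    slots <- expand.grid(x = seq(40, 472, by = 54), y = seq(40, 472, by = 54))
    slots <- slots[sample(nrow(slots), n_single + n_doublet + n_clump), ]
    jit <- function(n) stats::runif(n, -6, 6)
    singles <- tibble::tibble(
      x = slots$x[seq_len(n_single)] + jit(n_single),
      y = slots$y[seq_len(n_single)] + jit(n_single),
      rx = stats::runif(n_single, 12, 15), ry = stats::runif(n_single, 11, 14),
      rot = stats::runif(n_single, 0, pi), pallor = TRUE)
    i <- n_single
    doub <- purrr::map_dfr(seq_len(n_doublet), function(k) {
      cx <- slots$x[i + k]; cy <- slots$y[i + k]
      ang <- stats::runif(1, 0, pi)
      tibble::tibble(x = cx + c(-1, 1) * 9 * cos(ang),
                     y = cy + c(-1, 1) * 9 * sin(ang),
                     rx = stats::runif(2, 11, 13), ry = stats::runif(2, 10, 12),
                     rot = stats::runif(2, 0, pi), pallor = TRUE)
    })
    i <- n_single + n_doublet
    clump <- purrr::map_dfr(seq_len(n_clump), function(k) {
      m <- sample(4:6, 1)
      ang <- stats::runif(m, 0, 2 * pi)
      tibble::tibble(x = slots$x[i + k] + 5 * cos(ang),
                     y = slots$y[i + k] + 5 * sin(ang),
                     r = stats::runif(m, 3.5, 4.5))
    })
    list(scene = tile_scene(rbc = rbind(singles, doub), platelets = clump,
                            noise_sd = 2),
         n_single = n_single)
  })
}

#' Simulate expert annotations from planted morphotypes
#'
#' Each cell's "expert" type is drawn from the confusion-matrix row of its
#' planted morphotype, emulating imperfect concordance between learned
#' morphotypes and human cell-type calls.
#'
#' @param planted Integer vector of planted morphotype labels (1..K).
#' @param confusion K x T row-stochastic matrix; columns may be named with
#'   annotation type names.
#' @param seed Integer seed.
#' @return Tibble with `morphotype` and `annotation` per cell.
#' @export
simulate_annotations <- function(planted, confusion, seed = 1L) {
  confusion <- as.matrix(confusion)
  if (any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0)) {
    stop("confusion matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (max(planted) > nrow(confusion)) {
    stop("planted label exceeds confusion matrix rows", call. = FALSE)
  }
  types <- colnames(confusion) %||% sprintf("type%d", seq_len(ncol(confusion)))
  with_seed(seed, {
    ann <- vapply(planted, function(k) {
      sample(types, 1, prob = confusion[k, ])
    }, character(1))
    tibble::tibble(morphotype = planted, annotation = ann)
  })
}
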