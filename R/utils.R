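# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Area under the ROC curve by rank statistic
#'
#' Computes the AUC as the normalized Mann-Whitney U statistic, i.e. the
#' probability that a randomly chosen positive receives a higher score than a
#' randomly chosen negative (ties counted 1/2). Invariant under strictly
#' monotone transformations of `scores`.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("auc_rank() requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Moment skewness; 0 for (near-)constant input.
skewness_moment <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= .Machine$double.eps) return(0)
  mean((x - m)^3) / s2^1.5
}

# Optimal one-to-one assignment (Hungarian / shortest augmenting path,
# Jonker-Volgenant style). Minimizes total cost over square matrices.
# Returns the column assigned to each row. No installed package offers LSAP,
# so this is implemented here and cross-checked against brute-force
# enumeration in the tests.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  # arrays carry a dummy slot at index 1 standing for "row/column 0"
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j+1]: row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

# Adam optimizer state over a flat parameter vector.
adam_init <- function(n_par, lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = numeric(n_par), v = numeric(n_par), t = 0L)
}

adam_step <- function(state, grad) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  state$delta <- state$lr * mhat / (sqrt(vhat) + state$eps)
  state
}

# --- image representation bridges ------------------------------------------
# Tiles and masks are stored row-major: matrix/array indexed [row (y), col (x)],
# pixel values 0..255 for RGB, logical/integer for masks. EBImage stores
# images [x, y]; these two helpers are the only place the transpose happens.

to_eb <- function(m) EBImage::Image(t(m))

from_eb <- function(img) t(EBImage::imageData(img))

rgb_to_gray <- function(pixels) {
  # Rec. 601 luma on 0..255 values
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Polygon helpers (0-based pixel frame, x rightward, y downward) -------------

polygon_area_signed <- function(xy) {
  # shoelace; xy is an n x 2 matrix of an open ring (first vertex not repeated)
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

# O(n^2) simple-polygon check used when exporting geometry.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  seg <- cbind(xy, xy[c(2:n, 1), , drop = FALSE])
  intersects <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    for (k in (i + 2):n) {
      if (i == 1 && k == n) next  # adjacent through wrap-around
      if (intersects(seg[i, ], seg[k, ])) return(FALSE)
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
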