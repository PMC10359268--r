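# Shared in-code fixtures for the test suite. Everything is generated at test
# time; nothing binary ships with the package.

# 0-based ellipse mask on an n x n grid (duplicated from the package internals
# so mask fixtures do not depend on the code under test)
fixture_disc <- function(n, x0, y0, rx, ry = rx, rot = 0) {
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), times = n), n)
  dx <- xs - x0; dy <- ys - y0
  u <- dx * cos(rot) + dy * sin(rot)
  v <- -dx * sin(rot) + dy * cos(rot)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# uniform-color RGB array over a mask, different background
fixture_flat_rgb <- function(mask, fg = c(120, 60, 200), bg = c(30, 30, 30)) {
  n <- nrow(mask)
  px <- array(0, c(n, ncol(mask), 3))
  for (ch in 1:3) px[, , ch] <- ifelse(mask, fg[ch], bg[ch])
  px
}

# two-tone WBC: dark inner disc (nucleus) in a lighter cell on white ground
fixture_two_tone_cell <- function(n = 96, cell_r = 30, nuc_r = 15,
                                  nuc_val = 60, cyto_val = 180,
                                  bg_val = 245) {
  c0 <- (n - 1) / 2
  cell <- fixture_disc(n, c0, c0, cell_r)
  nuc <- fixture_disc(n, c0, c0, nuc_r)
  g <- matrix(bg_val, n, n)
  g[cell] <- cyto_val
  g[nuc] <- nuc_val
  px <- array(0, c(n, n, 3))
  for (ch in 1:3) px[, , ch] <- g
  list(pixels = px, cell = cell, nucleus = nuc)
}

# QC fixture: labeled synthetic tiles of the four quality archetypes
fixture_qc_tiles <- function(n_per_class, seed, size = 512L) {
  tiles <- list(); labels <- character(0)
  kinds <- c("good", "blank", "dense", "blur")
  i <- 0
  for (kind in kinds) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1
      sc <- switch(kind,
        good  = random_scene(n_rbc = 25, n_wbc = 2, size = size,
                             seed = seed + i),
        blank = random_scene(n_rbc = 0, n_wbc = 0, n_platelets = 0,
                             size = size, seed = seed + i),
        dense = random_scene(n_rbc = 60, n_wbc = 3, margin = -18,
                             size = size, seed = seed + i),
        blur  = random_scene(n_rbc = 25, n_wbc = 2, blur_sigma = 6,
                             size = size, seed = seed + i))
      tiles[[i]] <- render_tile(sc, seed = seed + i)$tile
      labels <- c(labels, if (kind == "good") "good" else "poor")
    }
  }
  list(tiles = tiles, labels = labels)
}

# planted two-condition bag design with disjoint dominant morphotypes
fixture_recovery_design <- function(n_per_condition = 30, n_cells = 200,
                                    seed = 10) {
  mix <- list(control   = c(0.40, 0.40, 0.10, 0.10),
              MDS_other = c(0.10, 0.10, 0.40, 0.40))
  bag_design(conditions = c(control = n_per_condition,
                            MDS_other = n_per_condition),
             cells_per_slide = c(n_cells, n_cells),
             K_true = c(wbc = 4, rbc = 4), separation = 6,
             mixing = list(wbc = mix, rbc = mix), seed = seed)
}

# permute task labels across bags (slide-label permutation null)
permute_bag_labels <- function(bags, seed) {
  perm <- withr::with_seed(seed, sample(length(bags)))
  purrr::map2(bags, perm, function(b, j) {
    b$labels <- bags[[j]]$labels
    b$condition <- bags[[j]]$condition
    b
  })
}
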