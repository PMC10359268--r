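# Segmenter training fixtures use 256-px tiles: the pixel backend is
# size-agnostic and smaller tiles keep the suite fast.

make_seg_tiles <- function(n, seed, size = 256L) {
  tiles <- list(); masks <- list()
  for (i in seq_len(n)) {
    sc <- random_scene(n_rbc = 8, n_wbc = 2, n_platelets = 2, size = size,
                       seed = seed + i, noise_sd = 2)
    r <- render_tile(sc, seed = seed + i)
    wbc_ids <- which(r$types == "WBC")
    tiles[[i]] <- r$tile
    masks[[i]] <- matrix(r$labels %in% wbc_ids, nrow(r$labels))
  }
  list(tiles = tiles, masks = masks)
}

test_that("a trained pixel segmenter recovers WBC masks on held-out tiles", {
  d <- make_seg_tiles(10, seed = 50)
  model <- train_segmenter(d$tiles[1:8], d$masks[1:8], epochs = 60, seed = 5)
  expect_true(all(diff(attr(model, "loss")[1:10]) < 0))

  ious <- sapply(9:10, function(i) {
    pm <- segment_probabilities(model, d$tiles[[i]], tta = FALSE)
    pred <- pm >= 0.5
    sum(pred & d$masks[[i]]) / sum(pred | d$masks[[i]])
  })
  expect_true(all(ious >= 0.7))
})

test_that("segmenter training is deterministic and zero epochs is identity", {
  d <- make_seg_tiles(2, seed = 70)
  m1 <- train_segmenter(d$tiles, d$masks, epochs = 10, seed = 9)
  m2 <- train_segmenter(d$tiles, d$masks, epochs = 10, seed = 9)
  expect_identical(m1$w, m2$w)

  m0 <- train_segmenter(d$tiles, d$masks, epochs = 0, seed = 9)
  expect_equal(m0$w, numeric(8))  # zero-initialized weights untouched

  expect_error(train_segmenter(list(), list()), "no annotated tiles")
})

test_that("test-time augmentation averages over the dihedral group", {
  d <- make_seg_tiles(2, seed = 80)
  model <- train_segmenter(d$tiles, d$masks, epochs = 30, seed = 2)
  tl <- d$tiles[[1]]

  # identity-only augmentation set equals the plain prediction
  ident <- dihedral_transforms()[1]
  expect_equal(segment_probabilities(model, tl, tta = TRUE, transforms = ident),
               segment_probabilities(model, tl, tta = FALSE))

  # per-pixel pointwise backend is dihedral-equivariant, so full TTA must
  # reproduce the plain prediction up to the smoothing features at borders
  pm1 <- segment_probabilities(model, tl, tta = FALSE)
  pm8 <- segment_probabilities(model, tl, tta = TRUE)
  interior <- 17:240
  expect_equal(pm8[interior, interior], pm1[interior, interior],
               tolerance = 1e-6)
})

test_that("TTA over the full group is idempotent", {
  d <- make_seg_tiles(1, seed = 90)
  model <- train_segmenter(d$tiles, d$masks, epochs = 20, seed = 3)
  tl <- d$tiles[[1]]
  trs <- dihedral_transforms()
  tta_once <- segment_probabilities(model, tl, tta = TRUE)
  # group-average the TTA predictor itself
  tta_twice <- Reduce(`+`, lapply(trs, function(tr) {
    px <- cytomorph:::apply_rgb(tr$forward, tl$pixels)
    inner <- Reduce(`+`, lapply(trs, function(tr2) {
      tr2$inverse(cytomorph:::predict_prob_map(
        model, cytomorph:::apply_rgb(tr2$forward, px)))
    })) / 8
    tr$inverse(inner)
  })) / 8
  expect_equal(tta_twice, tta_once, tolerance = 1e-10)
})

test_that("TTA reduces prediction variance under input noise", {
  sc <- random_scene(n_rbc = 2, n_wbc = 1, n_platelets = 0, size = 96,
                     seed = 95)
  r <- render_tile(sc, seed = 95)
  mask <- matrix(r$labels %in% which(r$types == "WBC"), nrow(r$labels))
  model <- train_segmenter(list(r$tile), list(mask), epochs = 20, seed = 4)
  base <- r$tile$pixels
  set.seed(12)
  single <- list(); averaged <- list()
  for (rep in 1:30) {
    noisy <- pmin(pmax(base + array(rnorm(length(base), 0, 8), dim(base)),
                       0), 255)
    single[[rep]] <- cytomorph:::predict_prob_map(model, noisy)
    averaged[[rep]] <- segment_probabilities(model, tile(noisy), tta = TRUE)
  }
  var_of <- function(lst) {
    m <- Reduce(`+`, lst) / length(lst)
    Reduce(`+`, lapply(lst, function(x) (x - m)^2)) / (length(lst) - 1)
  }
  expect_lte(mean(var_of(averaged)), mean(var_of(single)))
})

test_that("post-processing extracts disjoint, area-gated instances", {
  expect_length(postprocess(matrix(0, 64, 64)), 0)

  disc <- fixture_disc(96, 47, 47, 25.2)  # area ~ 2000 px^2
  inst <- postprocess(disc * 1.0, postprocess_params(min_area = 500,
                                                     max_area = 10000))
  expect_length(inst, 1)
  expect_equal(sum(inst[[1]]), sum(disc))

  # instance area gates are enforced
  small <- fixture_disc(64, 16, 16, 8)
  big <- fixture_disc(64, 46, 46, 14)
  pm <- pmin(small + big, 1)
  inst <- postprocess(pm, postprocess_params(min_area = 300, max_area = 15000))
  areas <- sapply(inst, sum)
  expect_true(all(areas >= 300 & areas <= 15000))
  if (length(inst) > 1) {
    expect_equal(sum(inst[[1]] & inst[[2]]), 0)
  }
})

test_that("watershed splitting separates a two-disc dumbbell", {
  a <- fixture_disc(96, 30, 48, 16)
  b <- fixture_disc(96, 64, 48, 16)
  bridge <- matrix(FALSE, 96, 96)
  bridge[48:49, 31:65] <- TRUE
  pm <- (a | b | bridge) * 1.0
  merged <- postprocess(pm, postprocess_params(min_area = 100,
                                               split_touching = FALSE))
  expect_length(merged, 1)
  split <- postprocess(pm, postprocess_params(min_area = 100,
                                              split_touching = TRUE))
  expect_length(split, 2)
})

test_that("nucleus segmentation recovers a two-tone nucleus within 2%", {
  tt <- fixture_two_tone_cell(96, cell_r = 30, nuc_r = 15)
  nuc <- segment_nucleus(tt$pixels, tt$cell)
  disagree <- sum(xor(nuc, tt$nucleus)) / sum(tt$cell)
  expect_lte(disagree, 0.02)
  expect_true(all(nuc[!tt$cell] == FALSE))  # subset of the cell mask
})

test_that("the darker cluster is always chosen, even under inverted contrast", {
  # inverted: light nucleus, dark cytoplasm -- the method returns the darker
  # cytoplasm region (documented low-contrast failure mode)
  tt <- fixture_two_tone_cell(96, nuc_val = 200, cyto_val = 70)
  nuc <- segment_nucleus(tt$pixels, tt$cell)
  g <- 0.299 * tt$pixels[, , 1] + 0.587 * tt$pixels[, , 2] +
    0.114 * tt$pixels[, , 3]
  rest <- tt$cell & !nuc
  expect_lt(mean(g[nuc]), mean(g[rest]))
  expect_gt(sum(nuc & !tt$nucleus), 0)  # it picked (part of) the cytoplasm

  # noisy random cells: selection rule holds universally
  set.seed(31)
  for (i in 1:5) {
    px <- array(runif(48 * 48 * 3, 0, 255), c(48, 48, 3))
    mask <- fixture_disc(48, 23.5, 23.5, 18)
    nuc <- segment_nucleus(px, mask)
    g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    expect_lt(mean(g[nuc]), mean(g[mask & !nuc]))
  }

  flat <- fixture_flat_rgb(fixture_disc(32, 15.5, 15.5, 10), fg = c(7, 7, 7))
  expect_error(segment_nucleus(flat, fixture_disc(32, 15.5, 15.5, 10)),
               "constant")
})
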