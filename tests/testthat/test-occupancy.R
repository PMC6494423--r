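# small synthetic masks used across registration tests
ribbon_mask <- function(nr = 40, nc = 80, rows = 18:22, cols = 10:70) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

shift_mask <- function(m, dy, dx) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  cs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

test_that("binarization separates a two-level image under every method", {
  img <- matrix(10, 20, 20)
  img[5:15, 5:15] <- 200
  for (m in c("otsu", "percentile")) {
    mask <- binarize(img, m)
    expect_equal(mask, img == 200, ignore_attr = TRUE)
  }
  mask_f <- binarize(img, "fixed", threshold = 100)
  expect_equal(mask_f, img == 200, ignore_attr = TRUE)
  expect_error(binarize(matrix(0, 5, 5), "otsu"), "degenerate")
})

test_that("synthetic ribbon binarization covers the ground-truth ribbon", {
  p <- lattice_params(axon_length_um = 6)
  pair <- simulate_widefield_pair(p, coverage = 1, seed = 2)
  mask <- binarize(pair$tubulin)
  # reconstruct the true ribbon geometry used by the simulator
  margin_nm <- 4 * 250 + 2 * 160
  yc <- (seq_len(nrow(mask)) - 0.5) * 160
  xc <- (seq_len(ncol(mask)) - 0.5) * 160
  truth <- outer(abs(yc - nrow(mask) * 160 / 2) <= 200,
                 xc >= margin_nm & xc < margin_nm + 6000)
  expect_gte(sum(mask & truth) / sum(truth), 0.90)
})

test_that("skeletonization reduces a bar to a line and keeps topology", {
  bar <- ribbon_mask()
  sk <- to_strokes(bar, dilate_px = 0)
  # single thin component spanning the bar's length
  expect_equal(n_components(sk), 1L)
  expect_lte(max(colSums(sk[, 15:65])), 1)
  expect_gte(sum(sk), 40)
  # dilated strokes stay one component
  st <- to_strokes(bar, dilate_px = 2)
  expect_equal(n_components(st), 1L)
  # two disjoint bars stay two components
  two <- ribbon_mask(rows = 5:9)
  two[30:34, 10:70] <- TRUE
  expect_equal(n_components(to_strokes(two)), 2L)
  expect_error(to_strokes(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeleton of a Y-shaped axon keeps its endpoints and junction", {
  m <- matrix(FALSE, 60, 60)
  m[29:31, 5:30] <- TRUE                       # stem
  for (i in 0:20) m[(29 - i):(31 - i) + 0, 30 + i] <- TRUE  # upper branch
  for (i in 0:20) m[(29 + i):(31 + i), 30 + i] <- TRUE      # lower branch
  sk <- to_strokes(m, dilate_px = 0)
  expect_equal(n_components(sk), 1L)
  # neighborhood analysis: endpoints have 1 neighbor, junctions >= 3
  nb <- matrix(0, nrow(sk), ncol(sk))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + shift_mask(sk, dy, dx)
  }
  deg <- nb[sk]
  expect_equal(sum(deg == 1), 3)   # three endpoints
  expect_gte(sum(deg >= 3), 1)     # at least one junction pixel
})

test_that("registration recovers identity and integer shifts", {
  m <- ribbon_mask(rows = 15:25, cols = 20:60)
  m[10:14, 30:35] <- TRUE   # break symmetry
  tf0 <- register_channels(m, m)
  expect_equal(tf0$matrix, matrix(c(1, 0, 0, 1, 0, 0), 2, 3))
  moved <- shift_mask(m, dy = -2, dx = 3)
  tf <- register_channels(m, moved)
  # moving m by (dx, dy) = (3, -2) aligns it with the shifted copy
  expect_equal(unname(tf$matrix[, 3]), c(3, -2))
  # no overlap anywhere in the search radius -> failure status
  a <- matrix(FALSE, 30, 30); a[2, 2] <- TRUE
  b <- matrix(FALSE, 30, 30); b[29, 29] <- TRUE
  expect_equal(register_channels(a, b, search_px = 3)$status, "failed")
})

test_that("affine refinement recovers sub-pixel drift within a quarter pixel", {
  p <- lattice_params(axon_length_um = 5)
  pair <- simulate_widefield_pair(p, coverage = 1, seed = 5)
  # impose a known 0.5 px drift on the continuous channel (a binarized
  # mask quantizes a half-pixel drift to whole pixels, so sub-pixel
  # refinement is exercised on intensities)
  tf_half <- structure(list(matrix = cbind(diag(2), c(0.5, 0.5)),
                            model = "affine", status = "ok", score = 0),
                       class = "mps_transform")
  moved <- apply_transform(pair$tubulin, tf_half)
  tf <- register_channels(moved, pair$tubulin, model = "affine")
  # aligning the moved copy back requires roughly a -0.5 px translation
  expect_lt(abs(tf$matrix[1, 3] + 0.5), 0.25)
  expect_lt(abs(tf$matrix[2, 3] + 0.5), 0.25)
  expect_lt(max(abs(tf$matrix[, 1:2] - diag(2))), 0.05)
})

test_that("occupancy ratio is 1 when spectrin covers the strokes and 0 when absent", {
  p <- lattice_params(axon_length_um = 6)
  pair <- simulate_widefield_pair(p, coverage = 1, seed = 3)
  res <- occupancy_ratio(pair)
  expect_gte(res$ratio, 0.95)
  expect_gt(res$stroke_pixels, 0)
  pair0 <- simulate_widefield_pair(p, coverage = 0, seed = 3)
  res0 <- occupancy_ratio(pair0, occupancy_config(binarize_method = "fixed",
                                                  threshold = 60))
  expect_lte(res0$ratio, 0.05)
  expect_true("empty_spectrin" %in% res0$flags ||
              res0$covered_pixels < 0.05 * res0$stroke_pixels)
})

test_that("spectrin signal outside the strokes never changes the ratio", {
  m <- ribbon_mask(rows = 15:25, cols = 20:60)
  tub <- matrix(10, 40, 80); tub[m] <- 200
  spec <- tub
  pair <- image_pair(spec, tub, pixel_nm = 160)
  cfg <- occupancy_config(binarize_method = "fixed", threshold = 100,
                          register_model = "translation")
  base <- occupancy_ratio(pair, cfg)
  expect_equal(base$ratio, 1.0)
  # paint spectrin far from the axon: ratio invariant
  spec2 <- spec; spec2[1:5, 1:10] <- 200
  res2 <- occupancy_ratio(image_pair(spec2, tub, pixel_nm = 160), cfg)
  expect_equal(res2$ratio, base$ratio)
})

test_that("an integer spectrin drift is absorbed by registration", {
  p <- lattice_params(axon_length_um = 6)
  pair <- simulate_widefield_pair(p, coverage = 1, seed = 8)
  base <- occupancy_ratio(pair)
  # shift the spectrin channel by (3, -2) px
  sh <- matrix(0, nrow(pair$spectrin), ncol(pair$spectrin))
  sh[4:nrow(sh), 1:(ncol(sh) - 2)] <-
    pair$spectrin[1:(nrow(sh) - 3), 3:ncol(sh)]
  res <- occupancy_ratio(image_pair(sh, pair$tubulin,
                                    pixel_nm = pair$pixel_nm))
  expect_lt(abs(res$ratio - base$ratio), 0.02)
})

test_that("generative coverage is recovered within 0.1", {
  p <- lattice_params(axon_length_um = 19)
  ratios <- vapply(1:10, function(s) {
    pair <- simulate_widefield_pair(p, coverage = 0.6, seed = s)
    occupancy_ratio(pair)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.6), 0.1)
  expect_true(all(ratios >= 0 & ratios <= 1))
})
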