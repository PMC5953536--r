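test_that("template is the per-pixel mean of the leading frames", {
  frames <- array(0, c(2, 4, 4))
  frames[2, , ] <- 2
  expect_equal(build_template(movie_stack(frames), 2), matrix(1, 4, 4))

  set.seed(11)
  frames <- array(runif(10 * 6 * 6), c(10, 6, 6))
  mov <- movie_stack(frames)
  expect_equal(build_template(mov, 10), oracle_template(frames, 10))
  expect_equal(build_template(mov, 3), oracle_template(frames, 3))
  expect_error(build_template(mov, 0), "n_frames")
  expect_error(build_template(mov, 11), "exceeds")
})

test_that("registration recovers planted integer shifts exactly", {
  set.seed(21)
  template <- matrix(runif(40 * 40), 40, 40)
  template <- bandpass_filter(template, 1, 6) + 1  # smooth structure
  planted <- rbind(c(0, 0), c(3, -2), c(-4, 4), c(1, 0))
  frames <- array(0, c(4, 40, 40))
  for (i in 1:4)
    frames[i, , ] <- shift_image(template, planted[i, 1], planted[i, 2],
                                 fill = mean(template))
  reg <- register_frames(movie_stack(frames), template, max_shift = 5)
  expect_equal(as.matrix(reg$shifts[, c("dy", "dx")]),
               planted, ignore_attr = TRUE)
  # against the independent exhaustive-search oracle
  for (i in 1:4)
    expect_equal(oracle_best_shift(frames[i, , ], template, 5),
                 planted[i, ])

  # with mild noise: within 1 px of the planted shift
  noisy <- frames
  for (i in 1:4)
    noisy[i, , ] <- noisy[i, , ] + matrix(rnorm(1600, sd = 0.02), 40, 40)
  reg2 <- register_frames(movie_stack(noisy), template, max_shift = 5)
  expect_true(all(abs(reg2$shifts$dy - planted[, 1]) <= 1))
  expect_true(all(abs(reg2$shifts$dx - planted[, 2]) <= 1))
})

test_that("registration is idempotent and flags constant frames", {
  set.seed(22)
  template <- bandpass_filter(matrix(runif(900), 30, 30), 1, 5) + 1
  frames <- array(0, c(2, 30, 30))
  frames[1, , ] <- shift_image(template, 2, -1, fill = mean(template))
  frames[2, , ] <- template
  reg <- register_frames(movie_stack(frames), template, max_shift = 4)
  rereg <- register_frames(reg$movie, template, max_shift = 4)
  expect_true(all(rereg$shifts$dy == 0 & rereg$shifts$dx == 0))

  const <- array(1, c(1, 30, 30))
  expect_warning(r3 <- register_frames(movie_stack(const), template, 4),
                 "constant")
  expect_equal(c(r3$shifts$dy, r3$shifts$dx), c(0, 0))
  expect_error(register_frames(movie_stack(frames), template, max_shift = 20),
               "max_shift")
})

test_that("differential images equal ON mean minus OFF mean", {
  # planted amplitude A over baseline: differential equals A on ROI pixels
  fx <- tiny_movie_fixture(n_stimuli = 3, n_neurons = 3, n_trials = 1,
                           neuropil_level = 0, f0 = 50)
  s <- 2
  d <- differential_image(fx$movie, fx$trial_table, s)
  driven <- which(fx$tuning$strong[s, ])
  A <- 50 * fx$tuning$values[s, driven]
  expect_equal(unname(d[fx$layout$rois[[driven]]]),
               rep(A, length(fx$layout$rois[[driven]])))
  off_px <- setdiff(seq_len(96 * 96), fx$layout$rois[[driven]])
  expect_equal(max(abs(d[off_px])), 0)

  # two trials with amplitudes A and 3A average to 2A
  frames <- array(1, c(8, 10, 10))
  roi <- 23:27
  for (f in 3:4) frames[f, , ][roi] <- 1 + 5      # trial 1 ON: A = 5
  for (f in 7:8) frames[f, , ][roi] <- 1 + 15     # trial 2 ON: 3A
  tt <- data.frame(trial = 1:2, stimulus = 1,
                   off_start = c(0, 4), off_end = c(2, 6),
                   on_start = c(2, 6), on_end = c(4, 8))
  d2 <- differential_image(movie_stack(frames), tt, 1)
  expect_equal(unname(d2[roi]), rep(10, 5))

  expect_error(differential_image(movie_stack(frames), tt, 99),
               "does not occur")
  # ON identical to OFF: zero image
  const <- movie_stack(array(3, c(8, 10, 10)))
  expect_equal(max(abs(differential_image(const, tt, 1))), 0)
})

test_that("band-pass filter matches direct convolution and removes offsets", {
  expect_equal(max(abs(bandpass_filter(matrix(7, 20, 20), 2, 6))), 0)

  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  expect_lt(abs(sum(bandpass_filter(imp, 1, 3))), 1e-10)

  set.seed(31)
  img <- matrix(runif(16 * 16), 16, 16)
  expect_equal(bandpass_filter(img, 2, 6),
               oracle_blur(img, 2) - oracle_blur(img, 6),
               tolerance = 1e-12)
  expect_error(bandpass_filter(img, 0, 6), "positive")
  expect_error(bandpass_filter(img, 6, 2), "smaller")
})

test_that("ROI detection keeps large planted blobs and rejects small ones", {
  set.seed(41)
  mk_blob <- function(px_idx, amp, side = 64, noise = 0.05) {
    img <- matrix(rnorm(side * side, sd = noise), side, side)
    img[px_idx] <- img[px_idx] + amp
    img
  }
  lay <- roi_layout(1, 64, 64, radius = 4)     # 49-px disc
  img <- mk_blob(lay$rois[[1]], 0.5)           # 10 noise-SDs
  rois <- desk_detect(list(img))
  expect_length(rois$rois, 1)
  expect_gt(iou(rois$rois[[1]], lay$rois[[1]]), 0.5)

  # a sub-26-pixel blob fails the > 25 pixel rule even at high contrast
  # (checked on the raw differential image, where the component footprint
  # is exactly the planted pixel set)
  small <- roi_layout(1, 64, 64, radius = 1.6)  # 9-px blob
  expect_lte(length(small$rois[[1]]), 10)
  rois2 <- detect_rois(list(mk_blob(small$rois[[1]], 0.5)),
                       bandpass = FALSE)
  expect_length(rois2$rois, 0)
  # the 49-px disc passes the same raw-image rule
  rois3 <- detect_rois(list(img), bandpass = FALSE)
  expect_length(rois3$rois, 1)
  expect_gt(iou(rois3$rois[[1]], lay$rois[[1]]), 0.9)
})

test_that("ROI detection output is invariant to constant offsets", {
  set.seed(42)
  lay <- roi_layout(2, 64, 64, radius = 4)
  img <- matrix(rnorm(64 * 64, sd = 0.05), 64, 64)
  img[lay$rois[[1]]] <- img[lay$rois[[1]]] + 8
  img[lay$rois[[2]]] <- img[lay$rois[[2]]] + 8
  a <- desk_detect(list(img))
  b <- desk_detect(list(img + 123.4))
  expect_identical(a$rois, b$rois)
  expect_length(a$rois, 2)
})

test_that("pure-noise differential images produce no ROIs", {
  set.seed(43)
  for (i in 1:20) {
    img <- matrix(rnorm(64 * 64), 64, 64)
    expect_length(desk_detect(list(img))$rois, 0)
  }
})

test_that("ROIs from overlapping detections merge; ROI sets stay disjoint", {
  set.seed(44)
  lay <- roi_layout(1, 64, 64, radius = 4)
  base <- matrix(rnorm(64 * 64, sd = 0.05), 64, 64)
  img1 <- base; img1[lay$rois[[1]]] <- img1[lay$rois[[1]]] + 10
  img2 <- matrix(rnorm(64 * 64, sd = 0.05), 64, 64)
  img2[lay$rois[[1]]] <- img2[lay$rois[[1]]] + 10   # same cell, second image
  rois <- desk_detect(list(img1, img2))
  expect_length(rois$rois, 1)                       # merged, not duplicated
  expect_gt(rois$n_candidates, 1)
  px <- unlist(rois$rois)
  expect_identical(anyDuplicated(px), 0L)
  # annuli never include ROI pixels
  expect_length(intersect(unlist(rois$neuropil), px), 0)
  expect_error(detect_rois(list()), "non-empty")
})

test_that("connected components respect the connectivity setting", {
  # two diagonal blobs of > 25 px each touching only at a corner
  img <- matrix(0, 40, 40)
  img[5:10, 5:10] <- 10    # 36 px
  img[11:16, 11:16] <- 10  # diagonal neighbour
  r8 <- detect_rois(list(img), bandpass = FALSE, connectivity = 8)
  r4 <- detect_rois(list(img), bandpass = FALSE, connectivity = 4)
  expect_length(r8$rois, 1)
  expect_length(r4$rois, 2)
})

test_that("roi sets round-trip through TIFF + JSON", {
  set.seed(45)
  lay <- roi_layout(2, 64, 64, radius = 4)
  img <- matrix(rnorm(64 * 64, sd = 0.05), 64, 64)
  img[lay$rois[[1]]] <- img[lay$rois[[1]]] + 8
  img[lay$rois[[2]]] <- img[lay$rois[[2]]] + 8
  rois <- desk_detect(list(img))
  path <- withr::local_tempfile(fileext = ".tif")
  write_roi_set(rois, path)
  back <- read_roi_set(path)
  expect_identical(back$rois, lapply(rois$rois, as.integer))
  expect_identical(back$label_image, rois$label_image)
})
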