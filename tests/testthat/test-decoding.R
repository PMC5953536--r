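test_that("centroid training averages the held-in trials", {
  set.seed(81)
  x <- array(rnorm(3 * 6 * 4), c(3, 6, 4))
  # X2 == X3: C1 equals them
  x[3, , ] <- x[2, , ]
  m <- train_centroids(x, 1)
  expect_equal(m$centroids, x[2, , ])
  # X2 = 0, X3 = 2M: C1 = M
  M <- matrix(rnorm(24), 6, 4)
  x[2, , ] <- 0; x[3, , ] <- 2 * M
  expect_equal(train_centroids(x, 1)$centroids, M)
  # random tensor vs per-entry loop oracle, every fold
  y <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  for (t in 1:4)
    expect_equal(train_centroids(y, t)$centroids, oracle_centroids(y, t))
  expect_error(train_centroids(array(1, c(1, 2, 2)), 1), "single trial")
  expect_error(train_centroids(y, 9), "out of range")
})

test_that("prediction picks the nearest centroid, ties to smallest index", {
  C <- matrix(rnorm(80), 8, 10)
  model <- structure(list(centroids = C, held_out_trial = 1),
                     class = "centroid_model")
  expect_equal(predict_stimulus(C[7, ], model), 7)

  # exact equidistance between rows 2 and 5
  C2 <- matrix(5, 6, 2)
  C2[2, ] <- c(1, 0); C2[5, ] <- c(-1, 0)
  m2 <- structure(list(centroids = C2, held_out_trial = 1),
                  class = "centroid_model")
  expect_equal(predict_stimulus(c(0, 0), m2), 2)

  set.seed(82)
  for (i in 1:20) {
    C3 <- matrix(rnorm(30), 6, 5)
    m3 <- structure(list(centroids = C3, held_out_trial = 1),
                    class = "centroid_model")
    v <- rnorm(5)
    expect_equal(predict_stimulus(v, m3), oracle_predict(v, C3))
  }
  expect_error(predict_stimulus(1:3, model), "length")
})

test_that("cross-validated accuracy matches a second implementation", {
  # identical trials with distinct rows decode perfectly
  set.seed(83)
  base <- matrix(rnorm(12 * 5), 12, 5)
  x <- array(0, c(3, 12, 5))
  for (t in 1:3) x[t, , ] <- base
  expect_equal(as.numeric(cross_validated_accuracy(x)), 1)

  # fixed-seed noisy tensor vs the independent end-to-end loop
  y <- array(rnorm(3 * 10 * 5, mean = 0.2), c(3, 10, 5))
  for (s in 1:10) y[, s, (s %% 5) + 1] <- y[, s, (s %% 5) + 1] + 1.5
  expect_equal(as.numeric(cross_validated_accuracy(y)),
               oracle_cv_accuracy(y))
  expect_error(cross_validated_accuracy(array(1, c(1, 4, 2))), "single trial")
})

test_that("thresholding keeps exactly the top p% with stable tie handling", {
  # 10 distinct pooled values, top 20% -> exactly the 2 largest survive
  x <- array(c(10, 3, 7, 1, 9, 4, 6, 2, 8, 5), c(1, 5, 2))
  kept <- threshold_responses(x, 20, "top_only")
  expect_equal(sort(as.vector(kept)[as.vector(kept) > 0]), c(9, 10))
  excl <- threshold_responses(x, 20, "top_excluded")
  expect_equal(sort(as.vector(excl)[as.vector(excl) > 0]), 1:8)

  # boundary percentages are exact identities
  set.seed(84)
  y <- array(abs(rnorm(2 * 6 * 4)), c(2, 6, 4))
  expect_identical(unclass(threshold_responses(y, 100, "top_only")), y)
  expect_identical(unclass(threshold_responses(y, 0, "top_excluded")), y)
  expect_equal(max(abs(threshold_responses(y, 0, "top_only"))), 0)
  expect_equal(max(abs(threshold_responses(y, 100, "top_excluded"))), 0)
  expect_error(threshold_responses(y, 101, "top_only"), "0, 100")

  # random instances against the sort-and-count oracle, both modes
  for (i in 1:20) {
    z <- array(sample(0:8, 24, replace = TRUE) / 4, c(2, 4, 3))
    p <- sample(c(5, 25, 50, 75), 1)
    for (mode in c("absolute", "relative")) {
      top <- oracle_top_set(z, p, mode)
      got <- threshold_responses(z, p, "top_only", mode)
      expect_equal(which(as.vector(got) != 0),
                   setdiff(top, which(as.vector(z) == 0)))
      gotx <- threshold_responses(z, p, "top_excluded", mode)
      expect_equal(which(as.vector(gotx) != 0),
                   setdiff(which(as.vector(z) != 0), top))
    }
  }
})

test_that("top_only and top_excluded keep complementary entry sets", {
  set.seed(85)
  x <- generate_response_tensor(
    generate_tuning_matrix(30, 20, seed = 12), 3, 0.1, seed = 13)$responses
  for (p in c(0.5, 5, 50, 99)) {
    a <- threshold_responses(x, p, "top_only")
    b <- threshold_responses(x, p, "top_excluded")
    nz <- which(as.vector(x) != 0)
    expect_true(all(xor(as.vector(a)[nz] != 0, as.vector(b)[nz] != 0)))
    z <- which(as.vector(x) == 0)
    expect_true(all(as.vector(a)[z] == 0 & as.vector(b)[z] == 0))
  }
})

test_that("relative mode ranks by peak-normalized response", {
  # neuron 2's responses are 100x smaller but identically tuned;
  # relative mode treats both neurons alike, absolute mode does not
  x <- array(0, c(1, 4, 2))
  x[1, , 1] <- c(1.0, 0.2, 0.1, 0.05)
  x[1, , 2] <- c(1.0, 0.2, 0.1, 0.05) / 100
  rel <- threshold_responses(x, 25, "top_only", "relative")
  expect_equal(which(as.vector(rel) != 0), c(1L, 5L))  # both peaks kept
  abs_ <- threshold_responses(x, 25, "top_only", "absolute")
  expect_equal(which(as.vector(abs_) != 0), c(1L, 2L))  # neuron 1 dominates
})

test_that("decoding curves use the standard grid and reference accuracy", {
  expect_equal(decoding_percentages(),
               c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9,
                 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                 20, 30, 40, 50, 60, 70, 80, 90, 99))
  set.seed(86)
  x <- generate_response_tensor(
    generate_tuning_matrix(20, 15, seed = 14), 3, 0.05, seed = 15)$responses
  full <- as.numeric(cross_validated_accuracy(x))
  cv <- decoding_curve(x, percentages = c(0, 1, 50, 100), keep = "top_only")
  expect_identical(cv$full_accuracy, full)
  expect_identical(cv$curve$accuracy[cv$curve$percentage == 100], full)
  ce <- decoding_curve(x, percentages = c(0, 50), keep = "top_excluded")
  expect_identical(ce$curve$accuracy[ce$curve$percentage == 0], full)
  expect_true(all(cv$curve$accuracy >= 0 & cv$curve$accuracy <= 1))

  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_decoding_curve(cv, csv, json)
  expect_equal(nrow(read.csv(csv)), 4)
  expect_equal(jsonlite::read_json(json)$full_accuracy, full,
               tolerance = 1e-12)
})
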