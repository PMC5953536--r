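test_that("neuron peaks are maxima of trial-mean responses", {
  x <- array(0, c(2, 3, 1))
  x[1, , 1] <- c(0.1, 0.9, 0.4); x[2, , 1] <- c(0.1, 0.9, 0.4)
  expect_equal(as.numeric(neuron_peaks(x)), 0.9)

  set.seed(61)
  x <- array(runif(3 * 8 * 6), c(3, 8, 6))
  m <- apply(x, c(2, 3), mean)
  want <- sapply(1:6, function(j) max(m[, j]))
  expect_equal(as.numeric(neuron_peaks(x)), want)
})

test_that("half-max sparseness counts follow the strict > rule", {
  # population: all peaks 1.0, responses [1.0, 0.6, 0.4, 0.1] -> count 2
  x <- array(0, c(1, 2, 4))
  x[1, 1, ] <- c(1.0, 0.6, 0.4, 0.1)
  x[1, 2, ] <- c(0.2, 1.0, 1.0, 1.0)  # gives every neuron peak 1.0
  pop <- population_sparseness(x)
  expect_equal(pop$counts[1], 2)
  expect_equal(pop$fraction[1], 0.5)
  # stimulus 2: neurons 2..4 at peak, neuron 1 at 0.2 -> count 3
  expect_equal(pop$counts[2], 3)

  # ties at exactly half the peak are excluded
  x[1, 1, ] <- c(1.0, 0.5, 0.4, 0.1)
  expect_equal(population_sparseness(x)$counts[1], 1)

  # lifetime: [1.0, 0.6, 0.4, 0.1] over stimuli -> 2 of 4
  y <- array(0, c(1, 4, 1))
  y[1, , 1] <- c(1.0, 0.6, 0.4, 0.1)
  lt <- lifetime_sparseness(y)
  expect_equal(lt$counts, 2)
  expect_equal(lt$fraction, 0.5)
  # flat tuning: every stimulus above half the peak
  y[1, , 1] <- rep(0.7, 4)
  expect_equal(lifetime_sparseness(y)$fraction, 1)
})

test_that("sparseness matches brute-force oracles on random tensors", {
  set.seed(62)
  for (i in 1:25) {
    S <- sample(3:10, 1); N <- sample(2:8, 1); R <- sample(1:3, 1)
    x <- array(rnorm(R * S * N, mean = 0.3, sd = 0.5), c(R, S, N))
    m <- if (R == 1) x[1, , ] else apply(x, c(2, 3), mean)
    o_pop <- oracle_population_counts(m)
    o_lt <- oracle_lifetime_counts(m)
    pop <- population_sparseness(x)
    lt <- lifetime_sparseness(x)
    expect_equal(unname(pop$counts), o_pop$counts)
    expect_equal(pop$n_neurons, o_pop$n_neurons)
    expect_equal(unname(lt$counts), o_lt)
    # pair-count identity: both sides count the same (stimulus, neuron) pairs
    expect_equal(sum(pop$counts), sum(lt$counts, na.rm = TRUE))
  }
})

test_that("sparseness is invariant to per-neuron positive rescaling", {
  set.seed(63)
  x <- generate_response_tensor(generate_tuning_matrix(30, 20, seed = 1),
                                3, 0.05, seed = 2)$responses
  y <- unclass(x)
  y[, , 7] <- y[, , 7] * 13.7
  y[, , 2] <- y[, , 2] * 0.01
  expect_equal(population_sparseness(y)$counts,
               population_sparseness(x)$counts)
  expect_equal(lifetime_sparseness(y)$counts,
               lifetime_sparseness(x)$counts)
})

test_that("lowering the threshold never decreases counts", {
  set.seed(64)
  x <- array(abs(rnorm(3 * 15 * 10)), c(3, 15, 10))
  for (frac in c(0.7, 0.5, 0.3)) {
    hi <- population_sparseness(x, frac)$counts
    lo <- population_sparseness(x, frac - 0.2)$counts
    expect_true(all(lo >= hi))
  }
})

test_that("neurons with non-positive peaks are excluded and reported", {
  x <- array(0.5, c(2, 4, 3))
  x[, , 2] <- 0  # flat-zero neuron cannot define a half-max threshold
  pop <- population_sparseness(x)
  expect_equal(pop$excluded, 2L)
  expect_equal(pop$n_neurons, 2)
  expect_true(is.na(lifetime_sparseness(x)$counts[2]))
})

test_that("classical sparseness matches the normalized Treves-Rolls form", {
  expect_equal(classic_sparseness(c(1, 0, 0, 0)), 1)
  expect_equal(classic_sparseness(rep(0.3, 5)), 0)
  # direct formula evaluation for [1, 0.5, 0, 0]
  v <- c(1, 0.5, 0, 0)
  a <- mean(v)^2 / mean(v^2)
  expect_equal(classic_sparseness(v), (1 - a) / (1 - 1 / 4))
  expect_true(is.na(classic_sparseness(c(0, 0, 0))))
  expect_message(classic_sparseness(c(1, -0.2, 0)), "flooring")
})

test_that("sparseness summary aggregates and serializes consistently", {
  set.seed(65)
  sim <- generate_response_tensor(
    generate_tuning_matrix(40, 30, k_strong = 2, seed = 3), 3, 0.02,
    seed = 4)
  sp <- sparseness_summary(sim$responses)
  expect_equal(sp$mean_population_sparseness,
               mean(sp$per_stimulus_counts) / sp$n_neurons)
  expect_equal(length(sp$per_neuron_counts), 30)
  json <- withr::local_tempfile(fileext = ".json")
  hist <- withr::local_tempfile(fileext = ".csv")
  write_sparseness_summary(sp, json, hist)
  back <- jsonlite::read_json(json)
  expect_equal(back$mean_population_sparseness,
               sp$mean_population_sparseness, tolerance = 1e-12)
  h <- read.csv(hist)
  expect_equal(sum(h$frequency[h$measure == "population"]), 40)
})
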