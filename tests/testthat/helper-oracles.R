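# Independent brute-force oracles. These deliberately use naive loops and
# direct definitions, not the package's vectorized code paths.

# per-pixel mean of the first n frames
oracle_template <- function(frames, n) {
  H <- dim(frames)[2]; W <- dim(frames)[3]
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W))
    out[y, x] <- mean(frames[seq_len(n), y, x])
  out
}

# exhaustive integer-shift search maximizing overlap correlation
oracle_best_shift <- function(frame, template, max_shift) {
  best <- -Inf; best_s <- c(0L, 0L)
  H <- nrow(frame); W <- ncol(frame)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- max(1, 1 + dy):min(H, H + dy)
    xs <- max(1, 1 + dx):min(W, W + dx)
    a <- as.vector(frame[ys, xs])
    b <- as.vector(template[ys - dy, xs - dx])
    if (sd(a) == 0 || sd(b) == 0) next
    cc <- cor(a, b)
    better <- cc > best + 1e-12
    tie_closer <- abs(cc - best) <= 1e-12 &&
      sum(abs(c(dy, dx))) < sum(abs(best_s))
    if (better || tie_closer) { best <- cc; best_s <- c(dy, dx) }
  }
  best_s
}

# brute-force 2-D convolution with replicate padding
oracle_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  for (y in seq_len(H)) for (x in seq_len(W))
    out[y, x] <- sum(K * img[cl(y + (-r:r), H), cl(x + (-r:r), W)])
  out
}

# double-loop half-max sparseness counts from a trial-mean matrix
oracle_population_counts <- function(m, frac = 0.5) {
  S <- nrow(m); N <- ncol(m)
  peaks <- sapply(seq_len(N), function(j) max(m[, j]))
  keep <- which(peaks > 0)
  counts <- integer(S)
  for (s in seq_len(S)) for (j in keep)
    if (m[s, j] > frac * peaks[j]) counts[s] <- counts[s] + 1L
  list(counts = counts, n_neurons = length(keep))
}

oracle_lifetime_counts <- function(m, frac = 0.5) {
  S <- nrow(m); N <- ncol(m)
  counts <- integer(N)
  for (j in seq_len(N)) {
    pk <- max(m[, j])
    if (pk <= 0) { counts[j] <- NA_integer_; next }
    for (s in seq_len(S)) if (m[s, j] > frac * pk)
      counts[j] <- counts[j] + 1L
  }
  counts
}

# AUC by enumerating all (positive, negative) pairs
oracle_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]; neg <- values[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# per-entry loop centroid of all trials but t
oracle_centroids <- function(x, t) {
  R <- dim(x)[1]; S <- dim(x)[2]; N <- dim(x)[3]
  C <- matrix(0, S, N)
  for (s in seq_len(S)) for (j in seq_len(N))
    C[s, j] <- mean(x[setdiff(seq_len(R), t), s, j])
  C
}

# exhaustive distance loop, first index wins ties
oracle_predict <- function(v, C) {
  d <- sapply(seq_len(nrow(C)), function(s) sqrt(sum((v - C[s, ])^2)))
  which.min(d)
}

# independent end-to-end nearest-centroid cross-validation
oracle_cv_accuracy <- function(x) {
  R <- dim(x)[1]; S <- dim(x)[2]
  accs <- numeric(R)
  for (t in seq_len(R)) {
    C <- oracle_centroids(x, t)
    correct <- 0
    for (s in seq_len(S))
      if (oracle_predict(x[t, s, ], C) == s) correct <- correct + 1
    accs[t] <- correct / S
  }
  mean(accs)
}

# sort-and-count top set; stable tie order: neuron, stimulus, trial
oracle_top_set <- function(x, p, mode = "absolute") {
  n <- length(x)
  m <- ceiling(p / 100 * n)
  idx <- arrayInd(seq_len(n), dim(x))
  vals <- as.vector(x)
  if (mode == "relative") {
    mmat <- if (dim(x)[1] == 1) x[1, , ] else apply(x, c(2, 3), mean)
    peaks <- apply(mmat, 2, max)
    vals <- ifelse(peaks[idx[, 3]] > 0, vals / peaks[idx[, 3]], -Inf)
  }
  ord <- order(-vals, idx[, 3], idx[, 2], idx[, 1])
  sort(ord[seq_len(m)])
}

# intersection-over-union of two pixel sets
iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))
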