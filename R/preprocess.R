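# Movie preprocessing: template, rigid registration by normalized
# cross-correlation, ON-minus-OFF differential images, difference-of-Gaussians
# band-pass, and threshold-based ROI segmentation.

#' Build a registration template
#'
#' The template is the pixel-wise mean of the first `n_frames` frames of the
#' movie.
#'
#' @param movie a [movie_stack()].
#' @param n_frames number of leading frames to average (capped at the movie
#'   length by the caller; the classic choice is 1000).
#' @return An `H x W` matrix.
#' @export
build_template <- function(movie, n_frames = min(1000L, dim(.as_movie(movie)$frames)[1])) {
  movie <- .as_movie(movie)
  T_ <- dim(movie$frames)[1]
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (n_frames > T_) stop("`n_frames` exceeds the number of frames")
  out <- movie$frames[1, , ] * 0
  for (f in seq_len(n_frames)) out <- out + movie$frames[f, , ]
  out / n_frames
}

#' Translate an image by an integer shift
#'
#' Content at `(y, x)` moves to `(y + dy, x + dx)`; vacated pixels are set
#' to `fill` (a scalar or a matrix of the same size, e.g. the template).
#'
#' @param img matrix.
#' @param dy,dx integer shift in rows / columns.
#' @param fill fill value(s) for vacated pixels.
#' @return The shifted matrix.
#' @export
shift_image <- function(img, dy, dx, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- if (is.matrix(fill)) fill else matrix(fill, H, W)
  ys <- seq_len(H); xs <- seq_len(W)
  y_dst <- ys + dy; x_dst <- xs + dx
  ok_y <- y_dst >= 1 & y_dst <= H
  ok_x <- x_dst >= 1 & x_dst <= W
  out[y_dst[ok_y], x_dst[ok_x]] <- img[ys[ok_y], xs[ok_x]]
  out
}

# normalized cross-correlation of frame against template shifted by (dy, dx),
# computed on the overlap region; NA when either patch is constant
.ncc_at <- function(frame, template, dy, dx) {
  H <- nrow(frame); W <- ncol(frame)
  # frame content = template shifted by (dy, dx): compare frame[y, x] with
  # template[y - dy, x - dx] on the valid overlap
  y_f <- max(1, 1 + dy):min(H, H + dy)
  x_f <- max(1, 1 + dx):min(W, W + dx)
  a <- frame[y_f, x_f]
  b <- template[y_f - dy, x_f - dx]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

#' Rigid motion correction by normalized cross-correlation
#'
#' For each frame, searches all integer translations within `± max_shift`
#' for the one maximizing the normalized cross-correlation (Pearson
#' correlation on the overlap) between the frame and the template, then
#' shifts the frame back. Vacated edge pixels are filled with template
#' values so that downstream differential images are unbiased at the
#' borders. Candidate shifts are scanned in order of increasing magnitude
#' and only strictly better correlations replace the incumbent, so an
#' already-registered frame yields `(0, 0)` and registration is idempotent.
#'
#' @param movie a [movie_stack()].
#' @param template `H x W` matrix from [build_template()].
#' @param max_shift search radius in pixels (must be < half the frame size).
#' @return A list with `movie` (registered [movie_stack()]) and `shifts`
#'   (data.frame with columns `frame`, `dy`, `dx`: the detected motion of
#'   each frame relative to the template).
#' @export
register_frames <- function(movie, template, max_shift = 5) {
  movie <- .as_movie(movie)
  H <- dim(movie$frames)[2]; W <- dim(movie$frames)[3]
  if (max_shift >= min(H, W) / 2)
    stop("`max_shift` must be smaller than half the frame size")
  grid <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  grid <- grid[order(abs(grid$dy) + abs(grid$dx), grid$dy, grid$dx), ]
  T_ <- dim(movie$frames)[1]
  out <- movie$frames
  shifts <- matrix(0L, T_, 2)
  warned <- FALSE
  for (f in seq_len(T_)) {
    frame <- movie$frames[f, , ]
    if (stats::sd(frame) == 0) {
      if (!warned) {
        warning("constant frame(s) encountered; assigned shift (0, 0)")
        warned <- TRUE
      }
      next
    }
    best <- -Inf; best_dy <- 0L; best_dx <- 0L
    for (i in seq_len(nrow(grid))) {
      cc <- .ncc_at(frame, template, grid$dy[i], grid$dx[i])
      if (!is.na(cc) && cc > best) {
        best <- cc; best_dy <- grid$dy[i]; best_dx <- grid$dx[i]
      }
    }
    shifts[f, ] <- c(best_dy, best_dx)
    if (best_dy != 0L || best_dx != 0L)
      out[f, , ] <- shift_image(frame, -best_dy, -best_dx, fill = template)
  }
  list(movie = movie_stack(out, frame_rate = movie$frame_rate),
       shifts = data.frame(frame = seq_len(T_), dy = shifts[, 1],
                           dx = shifts[, 2]))
}

#' Per-stimulus differential image
#'
#' Mean of all stimulus-ON frames across every trial of the given stimulus,
#' minus the mean of the corresponding stimulus-OFF (blank) frames.
#'
#' @param movie a registered [movie_stack()].
#' @param trial_table a [make_trial_table()]-format table.
#' @param stimulus stimulus id to condition on.
#' @return An `H x W` matrix.
#' @export
differential_image <- function(movie, trial_table, stimulus) {
  movie <- .as_movie(movie)
  validate_trial_table(trial_table)
  rows <- which(trial_table$stimulus == stimulus)
  if (!length(rows))
    stop(sprintf("stimulus %s does not occur in the trial table", stimulus))
  on_frames <- unlist(lapply(rows, function(r)
    .window_frames(trial_table[r, ], "on")))
  off_frames <- unlist(lapply(rows, function(r)
    .window_frames(trial_table[r, ], "off")))
  if (max(on_frames, off_frames) > dim(movie$frames)[1])
    stop("trial windows extend beyond the movie")
  on_mean <- movie$frames[1, , ] * 0
  for (f in on_frames) on_mean <- on_mean + movie$frames[f, , ]
  on_mean <- on_mean / length(on_frames)
  off_mean <- movie$frames[1, , ] * 0
  for (f in off_frames) off_mean <- off_mean + movie$frames[f, , ]
  off_mean <- off_mean / length(off_frames)
  on_mean - off_mean
}

# 1-D Gaussian kernel, normalized to sum 1, truncated at 3 sigma
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w / sum(w)
}

# separable convolution with replicate (clamped-edge) padding
.gauss_blur <- function(img, sigma) {
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- m * 0
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(img, TRUE), FALSE)
}

#' Difference-of-Gaussians band-pass filter
#'
#' Smooths the image at a small spatial scale and subtracts the same image
#' smoothed at a large scale, removing both pixel noise and slowly varying
#' background. Kernels are normalized Gaussians truncated at three standard
#' deviations; edges use replicate padding. Used only for ROI
#' identification, never for response measurement.
#'
#' @param img matrix (typically a differential image).
#' @param low_size small Gaussian sigma in pixels (default 5).
#' @param high_size large Gaussian sigma in pixels (default 50).
#' @return Filtered matrix of the same size, approximately zero-mean.
#' @export
bandpass_filter <- function(img, low_size = 5, high_size = 50) {
  if (low_size <= 0 || high_size <= 0) stop("filter sizes must be positive")
  if (low_size >= high_size)
    stop("`low_size` must be smaller than `high_size`")
  .gauss_blur(img, low_size) - .gauss_blur(img, high_size)
}

# connected components of a logical mask via igraph; connectivity 4 or 8.
# returns a list of linear-index vectors, ordered by smallest member index
.connected_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) return(list())
  offs <- list(c(1L, 0L), c(0L, 1L))                     # down, right
  if (connectivity == 8)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))          # diagonals
  else if (connectivity != 4)
    stop("`connectivity` must be 4 or 8")
  pos <- arrayInd(fg, c(H, W))
  in_mask <- logical(H * W); in_mask[fg] <- TRUE
  edges <- list()
  for (o in offs) {
    y2 <- pos[, 1] + o[1]; x2 <- pos[, 2] + o[2]
    ok <- y2 >= 1 & y2 <= H & x2 >= 1 & x2 <= W
    nb <- (x2[ok] - 1L) * H + y2[ok]
    keep <- in_mask[nb]
    edges[[length(edges) + 1L]] <- cbind(fg[ok][keep], nb[keep])
  }
  edges <- do.call(rbind, edges)
  id <- match(seq_len(H * W), fg)             # vertex id per pixel
  g <- igraph::graph_from_edgelist(
    cbind(id[edges[, 1]], id[edges[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comps <- split(fg, memb)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 0))]
}

# Chebyshev dilation of a pixel set by `k` steps (8-neighbourhood)
.dilate_px <- function(px, H, W, k) {
  if (k < 1) return(px)
  pos <- arrayInd(px, c(H, W))
  # full Chebyshev ball: offsets in [-k, k]^2
  off <- expand.grid(dy = -k:k, dx = -k:k)
  y <- outer(pos[, 1], off$dy, "+")
  x <- outer(pos[, 2], off$dx, "+")
  ok <- y >= 1 & y <= H & x >= 1 & x <= W
  sort(unique((x[ok] - 1L) * H + y[ok]))
}

#' Segment active-cell ROIs from differential images
#'
#' For each (band-passed) differential image, pixels exceeding
#' `mean + z_thresh * sd` (statistics over that image) are kept, connected
#' components are extracted, and components with more than `min_pixels`
#' pixels whose mean pixel value exceeds the threshold become candidate
#' ROIs. Candidates from different differential images are merged when
#' their overlap exceeds `merge_overlap` of the smaller candidate;
#' non-overlapping candidates become distinct cells. Each kept ROI receives
#' a neuropil annulus (a Chebyshev ring `annulus_gap` px away, of width
#' `annulus_width` px, excluding every ROI's pixels).
#'
#' @param diff_images list of differential images (matrices of equal size).
#' @param z_thresh threshold in standard deviations above the image mean
#'   (default 3).
#' @param min_pixels components must exceed this size to become ROIs
#'   (default 25, i.e. the "> 25 pixels" rule).
#' @param connectivity 8 (default) or 4.
#' @param bandpass apply [bandpass_filter()] before thresholding (default
#'   `TRUE`; the filter is used for detection only).
#' @param low_size,high_size band-pass sigmas, see [bandpass_filter()].
#' @param merge_overlap fraction of the smaller candidate's pixels that must
#'   overlap an existing ROI for the two to be merged (default 0.5).
#' @param annulus_gap,annulus_width neuropil ring geometry in pixels.
#' @return An object of class `roi_set`: list with `rois` (list of linear
#'   pixel-index vectors), `neuropil` (matching list of annulus pixel
#'   vectors), `label_image` (`H x W` integer matrix, 0 = background), and
#'   `n_candidates` (components seen before merging).
#' @export
detect_rois <- function(diff_images, z_thresh = 3, min_pixels = 25,
                        connectivity = 8, bandpass = TRUE, low_size = 5,
                        high_size = 50, merge_overlap = 0.5,
                        annulus_gap = 2, annulus_width = 4) {
  if (!is.list(diff_images) || !length(diff_images))
    stop("`diff_images` must be a non-empty list of images")
  dims <- unique(lapply(diff_images, dim))
  if (length(dims) != 1) stop("differential images differ in shape")
  H <- dims[[1]][1]; W <- dims[[1]][2]
  rois <- list()
  n_candidates <- 0L
  for (img in diff_images) {
    bp <- if (bandpass) bandpass_filter(img, low_size, high_size) else img
    thr <- mean(bp) + z_thresh * stats::sd(bp)
    comps <- .connected_components(bp > thr, connectivity)
    for (comp in comps) {
      if (length(comp) <= min_pixels) next
      if (mean(bp[comp]) <= thr) next
      n_candidates <- n_candidates + 1L
      # merge with every existing ROI sharing > merge_overlap of the smaller
      hit <- which(vapply(rois, function(r) {
        ov <- length(intersect(r, comp))
        ov > merge_overlap * min(length(r), length(comp))
      }, TRUE))
      if (length(hit)) {
        merged <- sort(unique(c(comp, unlist(rois[hit]))))
        rois <- rois[-hit]
        rois[[length(rois) + 1L]] <- merged
      } else {
        rois[[length(rois) + 1L]] <- comp
      }
    }
  }
  rois <- rois[order(vapply(rois, min, 0))]
  # enforce pairwise disjointness: sub-threshold overlaps go to the earlier ROI
  claimed <- integer(0)
  for (i in seq_along(rois)) {
    rois[[i]] <- setdiff(rois[[i]], claimed)
    claimed <- c(claimed, rois[[i]])
  }
  rois <- rois[lengths(rois) > min_pixels]
  neuropil <- neuropil_annuli(rois, H, W, annulus_gap, annulus_width)
  label_image <- matrix(0L, H, W)
  for (i in seq_along(rois)) label_image[rois[[i]]] <- i
  structure(list(rois = rois, neuropil = neuropil,
                 label_image = label_image, n_candidates = n_candidates),
            class = "roi_set")
}

#' Build neuropil annuli around ROIs
#'
#' Each annulus is the Chebyshev ring starting `annulus_gap` pixels outside
#' the ROI, of width `annulus_width` pixels, clipped to the frame and
#' excluding the pixels of every ROI in the set.
#'
#' @param rois list of linear pixel-index vectors (or a `roi_set`).
#' @param height,width frame size.
#' @param annulus_gap,annulus_width ring geometry in pixels.
#' @return List of annulus pixel-index vectors, one per ROI.
#' @export
neuropil_annuli <- function(rois, height, width, annulus_gap = 2,
                            annulus_width = 4) {
  if (inherits(rois, "roi_set")) rois <- rois$rois
  all_roi_px <- unlist(rois)
  lapply(rois, function(r) {
    ring <- setdiff(.dilate_px(r, height, width, annulus_gap + annulus_width),
                    .dilate_px(r, height, width, annulus_gap))
    setdiff(ring, all_roi_px)
  })
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d ROIs (from %d candidate components), sizes %s px\n",
              length(x$rois), x$n_candidates,
              if (length(x$rois))
                paste0(min(lengths(x$rois)), "-", max(lengths(x$rois)))
              else "-"))
  invisible(x)
}

#' Write / read an ROI set
#'
#' The label image is written as 16-bit TIFF; pixel and annulus index lists
#' go to a JSON sidecar.
#'
#' @param rois a `roi_set`.
#' @param path base path for the label TIFF; the sidecar is `<path>.json`.
#' @rdname roi_io
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  tiff::writeTIFF(rois$label_image / 65535, path, bits.per.sample = 16L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(rois = lapply(rois$rois, as.integer),
         neuropil = lapply(rois$neuropil, as.integer),
         dim = dim(rois$label_image)),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname roi_io
#' @export
read_roi_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  d <- as.integer(unlist(meta$dim))
  label_image <- matrix(0L, d[1], d[2])
  rois <- lapply(meta$rois, function(r) as.integer(unlist(r)))
  for (i in seq_along(rois)) label_image[rois[[i]]] <- i
  structure(list(rois = rois,
                 neuropil = lapply(meta$neuropil,
                                   function(r) as.integer(unlist(r))),
                 label_image = label_image,
                 n_candidates = NA_integer_),
            class = "roi_set")
}
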