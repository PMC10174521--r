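#' xy Gaussian blur
#'
#' Convolves every (c,t,z) plane with a normalized, truncated Gaussian kernel
#' applied separably along y and x, with symmetric (reflect) boundary padding
#' so that total plane intensity is conserved. `sigma = 0` returns the input
#' unchanged.
#'
#' @param stack an `ImageStack`.
#' @param sigma kernel standard deviation in pixels (>= 0). The kernel is
#'   truncated at `ceiling(4 * sigma)` pixels.
#' @return A blurred `ImageStack`.
#' @export
blur_xy <- function(stack, sigma) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(stack)
  k <- gaussian_kernel(sigma)
  res <- stack
  res$data <- conv_along(conv_along(stack$data, k, 4L), k, 5L)
  res$name <- paste0(stack$name, "|blur(", sigma, ")")
  res
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 1-D convolution of a 5-D array along one dimension with
# half-sample symmetric padding (edge value repeated), which conserves the
# total intensity exactly for a symmetric normalized kernel
conv_along <- function(a, k, dim) {
  n <- dim(a)[dim]
  r <- (length(k) - 1L) %/% 2L
  reflect <- function(i) {
    i[i < 1L] <- 1L - i[i < 1L]
    i[i > n] <- 2L * n + 1L - i[i > n]
    i
  }
  out <- array(0, dim(a))
  idx <- rep(list(quote(expr = )), 5L)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx[[dim]] <- reflect(seq_len(n) + off)
    out <- out + k[j] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  out
}

#' Histogram-based threshold selection
#'
#' Computes a scalar threshold from a vector of intensities using one of the
#' classical histogram methods. The histogram uses `bins` uniform bins over
#' the observed range; the returned threshold is the centre of the selected
#' bin and masks are formed with a strict `>` comparison.
#'
#' @param x numeric vector of intensities (at least two distinct values).
#' @param method `"otsu"` (maximal between-class variance), `"yen"` (maximal
#'   entropic correlation; more stringent) or `"triangle"` (maximal distance
#'   from the peak-to-tail chord; less stringent).
#' @param bins number of histogram bins.
#' @return The threshold value.
#' @export
find_threshold <- function(x, method = c("yen", "otsu", "triangle"),
                           bins = 4096L) {
  method <- match.arg(method)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant input has no threshold", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  threshold_from_histogram(counts, mids, method)
}

#' Threshold from a precomputed histogram
#' @param counts bin counts.
#' @param mids bin centres (same length, increasing).
#' @param method see [find_threshold()].
#' @return The threshold value (a bin centre).
#' @export
threshold_from_histogram <- function(counts, mids,
                                     method = c("yen", "otsu", "triangle")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  n <- length(counts)
  stopifnot(length(mids) == n, n >= 2L)
  # a flat maximum plateau of the objective (an empty intensity gap between
  # classes) is tie-broken at its midpoint, keeping the threshold clear of
  # both class boundaries; with a unique maximum this is ordinary argmax
  argmax_mid <- function(crit) {
    idx <- which(crit == max(crit))
    idx[(length(idx) + 1L) %/% 2L]
  }
  switch(method,
    otsu = {
      w <- cumsum(counts)
      m <- cumsum(counts * mids)
      wt <- w[n]; mt <- m[n]
      sb <- (mt * w - m * wt)^2 / (w * (wt - w))
      sb[!is.finite(sb)] <- -Inf
      mids[argmax_mid(sb[-n])]
    },
    yen = {
      pmf <- counts / sum(counts)
      P1 <- cumsum(pmf)
      P1sq <- cumsum(pmf^2)
      P2sq <- rev(cumsum(rev(pmf^2)))
      i <- seq_len(n - 1L)
      crit <- log((P1[i] * (1 - P1[i]))^2 / (P1sq[i] * P2sq[i + 1L]))
      crit[!is.finite(crit)] <- -Inf
      mids[argmax_mid(crit)]
    },
    triangle = {
      # chord from the histogram peak to the far end of its longer tail;
      # the threshold maximizes the distance between histogram and chord
      nz <- which(counts > 0)
      lo <- nz[1L]; hi <- nz[length(nz)]
      pk <- which.max(counts)
      h <- counts
      flip <- (pk - lo) < (hi - pk)  # put the longer tail on the left
      if (flip) { h <- rev(h); pk <- n - pk + 1L; lo <- n - hi + 1L }
      if (pk <= lo) return(mids[which.max(counts)])
      xs <- seq.int(0L, pk - lo - 1L)
      ys <- h[lo + xs]
      peak <- h[pk]
      width <- pk - lo
      nrm <- sqrt(peak^2 + width^2)
      dist <- (peak / nrm) * xs - (width / nrm) * ys
      arg <- lo + which.max(dist) - 1L
      if (flip) arg <- n - arg + 1L
      mids[arg]
    })
}

#' Adaptive thresholding of a filtered stack
#'
#' Produces a binary mask, true where the blurred, filtered intensity
#' strictly exceeds the selected threshold. In `"global"` mode one threshold
#' is computed per channel over all (t,z,y,x) voxels; in `"per_frame"` mode
#' one per channel and frame. A unit whose intensities are constant yields an
#' all-false mask with a warning rather than an error.
#'
#' @param stack an `ImageStack` (normally blurred and background-subtracted).
#' @param method `"otsu"`, `"yen"` or `"triangle"`.
#' @param mode `"global"` or `"per_frame"`.
#' @param bins histogram bins for the threshold search.
#' @return A `BinaryMask`: list with logical `data` congruent to the stack,
#'   the `threshold` value(s), `method` and `mode`.
#' @export
threshold_stack <- function(stack, method = c("yen", "otsu", "triangle"),
                            mode = c("global", "per_frame"), bins = 4096L) {
  stopifnot(inherits(stack, "ImageStack"))
  method <- match.arg(method)
  mode <- match.arg(mode)
  d <- dim(stack$data)
  mask <- array(FALSE, d)
  thr_one <- function(vals, label) {
    if (min(vals) == max(vals)) {
      warning("constant intensities in ", label, "; mask set to all-false",
              call. = FALSE)
      return(NA_real_)
    }
    find_threshold(vals, method, bins)
  }
  if (mode == "global") {
    thr <- numeric(d[1])
    for (cc in seq_len(d[1])) {
      v <- stack$data[cc, , , , ]
      thr[cc] <- thr_one(v, paste0("channel ", cc))
      if (!is.na(thr[cc])) mask[cc, , , , ] <- v > thr[cc]
    }
  } else {
    thr <- matrix(NA_real_, d[1], d[2])
    for (cc in seq_len(d[1])) for (t in seq_len(d[2])) {
      v <- stack$data[cc, t, , , ]
      thr[cc, t] <- thr_one(v, paste0("channel ", cc, " frame ", t))
      if (!is.na(thr[cc, t])) mask[cc, t, , , ] <- v > thr[cc, t]
    }
  }
  structure(list(data = mask, threshold = thr, method = method, mode = mode),
            class = "BinaryMask")
}

#' Apply a binary mask to a filtered stack
#'
#' Element-wise (Hadamard) product of the filtered intensities with the
#' 0/1-valued mask: the result is exactly zero off-mask and exactly the
#' filtered value on-mask.
#'
#' @param filtered an `ImageStack`.
#' @param mask a `BinaryMask` of congruent shape.
#' @return A masked `ImageStack`.
#' @export
apply_mask <- function(filtered, mask) {
  stopifnot(inherits(filtered, "ImageStack"), inherits(mask, "BinaryMask"))
  if (!identical(dim(filtered$data), dim(mask$data)))
    stop("shape mismatch: filtered is ", paste(dim(filtered$data), collapse = "x"),
         " but mask is ", paste(dim(mask$data), collapse = "x"), call. = FALSE)
  res <- filtered
  res$data <- filtered$data * mask$data
  res$name <- paste0(filtered$name, "|masked")
  res
}
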