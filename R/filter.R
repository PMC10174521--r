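#' Automatic Savitzky-Golay window length
#'
#' Heuristic used when the signal band of a recording is unknown: the nearest
#' odd integer to T/20, clipped to the range 5 to 31 and never exceeding the
#' largest odd number that fits in T frames. This preserves transients that
#' span at least about 5 percent of the recording while attenuating
#' frame-to-frame noise; when the temporal band of the expected signal is
#' known, a window matched to it should be passed explicitly instead.
#'
#' @param T number of frames (>= 5).
#' @param frame_interval_s optional frame interval; currently unused by the
#'   default rule but accepted so that callers can supply calibrated rates.
#' @return An odd integer window length.
#' @export
auto_window <- function(T, frame_interval_s = NULL) {
  T <- as.integer(T)
  if (T < 5L) stop("too few frames (", T, ") to filter; need at least 5",
                   call. = FALSE)
  w <- 2L * as.integer(round((T / 20 - 1) / 2)) + 1L
  w <- max(5L, min(31L, w))
  wmax <- T - (1L - T %% 2L)  # largest odd <= T
  min(w, wmax)
}

# Dense (T x T) linear operator applying Savitzky-Golay smoothing with
# fit-and-evaluate boundary handling: interior rows hold the central filter,
# the first and last (window-1)/2 rows evaluate the polynomial fitted to the
# first/last window at the boundary positions. Matches signal::sgolayfilt.
sg_smoothing_matrix <- function(T, order, window) {
  F <- signal::sgolay(p = order, n = window)
  k <- (window - 1L) %/% 2L
  S <- matrix(0, T, T)
  for (t in seq_len(T)) {
    if (t <= k) S[t, 1:window] <- F[t, ]
    else if (t > T - k) S[t, (T - window + 1L):T] <- F[window - (T - t), ]
    else S[t, (t - k):(t + k)] <- F[k + 1L, ]
  }
  S
}

#' Per-pixel temporal Savitzky-Golay smoothing
#'
#' Smooths every (c,z,y,x) pixel trace independently along the time axis with
#' a local least-squares polynomial of the given order. Boundary frames are
#' handled by evaluating the polynomial fitted to the first/last full window
#' at the boundary positions (fit-and-extrapolate, not mirror padding), so
#' event onsets near the stack edges are not reflected.
#'
#' @param stack an `ImageStack`.
#' @param order polynomial order (default 3).
#' @param window odd window length, greater than `order` and at most T, or
#'   `"auto"` for [auto_window()].
#' @return A smoothed `ImageStack` of identical shape.
#' @export
smooth_temporal <- function(stack, order = 3L, window = "auto") {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data); T <- d[2]
  if (identical(window, "auto")) window <- auto_window(T)
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd, got ", window, call. = FALSE)
  if (window <= order) stop("window (", window, ") must exceed order (",
                            order, ")", call. = FALSE)
  if (window > T)
    stop("window (", window, ") exceeds the ", T, "-frame time axis; ",
         "use window = \"auto\" to derive a feasible one", call. = FALSE)
  S <- sg_smoothing_matrix(T, order, window)
  m <- matrix(aperm(stack$data, c(2L, 1L, 3L, 4L, 5L)), nrow = T)
  sm <- S %*% m
  out <- aperm(array(sm, c(T, d[1], d[3], d[4], d[5])), c(2L, 1L, 3L, 4L, 5L))
  res <- stack
  res$data <- out
  res$name <- paste0(stack$name, "|sg(", order, ",", window, ")")
  res
}

#' Temporal-minimum background subtraction
#'
#' Subtracts from every pixel trace its minimum over time, so that the
#' per-pixel minimum of the result is exactly zero. Applied after temporal
#' smoothing, this removes the static fluorescence background while keeping
#' transient elevations.
#'
#' @param stack an `ImageStack` (normally the smoothed stack).
#' @return An `ImageStack` with zero per-pixel temporal minimum.
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data); T <- d[2]
  m <- matrix(aperm(stack$data, c(2L, 1L, 3L, 4L, 5L)), nrow = T)
  mins <- .colMins(m)
  m <- sweep(m, 2L, mins, `-`)
  out <- aperm(array(m, c(T, d[1], d[3], d[4], d[5])), c(2L, 1L, 3L, 4L, 5L))
  res <- stack
  res$data <- out
  res$name <- paste0(stack$name, "|bgsub")
  res
}

.colMins <- function(m) {
  if (nrow(m) == 1L) return(as.vector(m))
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}
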