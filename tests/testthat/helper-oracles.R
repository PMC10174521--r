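# Independent brute-force oracles used to verify the implementation.

# Savitzky-Golay by explicit local least-squares: fit a degree-`order`
# polynomial to each centered window by solving the normal equations, and
# evaluate the fit at the window centre; at the boundaries, fit the first or
# last full window and evaluate the polynomial at the boundary positions.
sg_bruteforce <- function(x, order, window) {
  T <- length(x)
  k <- (window - 1) / 2
  fitval <- function(idx, at) {
    # centre the design on the window midpoint for conditioning
    tt <- idx - mean(idx)
    X <- outer(tt, 0:order, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% x[idx])
    drop(outer(at - mean(idx), 0:order, `^`) %*% beta)
  }
  out <- numeric(T)
  for (t in seq_len(T)) {
    if (t <= k) out[t] <- fitval(1:window, t)
    else if (t > T - k) out[t] <- fitval((T - window + 1):T, t)
    else out[t] <- fitval((t - k):(t + k), t)
  }
  out
}

# dense 2-D convolution with a full Gaussian kernel and half-sample
# symmetric padding
blur_bruteforce <- function(img, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(img); W <- ncol(img)
  reflect <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]; i[i > n] <- 2 * n + 1 - i[i > n]; i
  }
  out <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r)
      acc <- acc + K[dy + r + 1, dx + r + 1] *
        img[reflect(y + dy, H), reflect(x + dx, W)]
    out[y, x] <- acc
  }
  out
}

# exhaustive-search threshold oracles on a histogram: evaluate the defining
# objective directly at every cut point. A tied maximum (an empty intensity
# gap between classes) is resolved at the middle cut, mirroring the
# documented tie-break.
mid_of_ties <- function(obj) {
  idx <- which(obj == max(obj, na.rm = TRUE))
  idx[(length(idx) + 1) %/% 2]
}

otsu_oracle <- function(counts, mids) {
  n <- length(counts)
  obj <- rep(-Inf, n - 1)
  for (i in 1:(n - 1)) {
    w0 <- sum(counts[1:i]); w1 <- sum(counts[(i + 1):n])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:i] * mids[1:i]) / w0
    mu1 <- sum(counts[(i + 1):n] * mids[(i + 1):n]) / w1
    obj[i] <- w0 * w1 * (mu0 - mu1)^2
  }
  mids[mid_of_ties(obj)]
}

yen_oracle <- function(counts, mids) {
  p <- counts / sum(counts)
  n <- length(p)
  obj <- rep(-Inf, n - 1)
  for (i in 1:(n - 1)) {
    P1 <- sum(p[1:i])
    if (P1 <= 0 || P1 >= 1) next
    s1 <- sum(p[1:i]^2); s2 <- sum(p[(i + 1):n]^2)
    if (s1 == 0 || s2 == 0) next
    obj[i] <- log(P1^2 * (1 - P1)^2 / (s1 * s2))
  }
  mids[mid_of_ties(obj)]
}

triangle_oracle <- function(counts, mids) {
  n <- length(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  pk <- which.max(counts)
  h <- counts
  flip <- (pk - lo) < (hi - pk)
  if (flip) { h <- rev(h); pk <- n - pk + 1; lo <- n - hi + 1 }
  if (pk <= lo) return(mids[which.max(counts)])
  # perpendicular distance of every histogram point from the chord,
  # computed from the explicit line equation
  x0 <- lo; y0 <- h[lo]; x1 <- pk; y1 <- h[pk]
  best <- -Inf; arg <- lo
  for (i in lo:(pk - 1)) {
    d <- ((y1 - y0) * i - (x1 - x0) * h[i] + x1 * y0 - y1 * x0) /
      sqrt((y1 - y0)^2 + (x1 - x0)^2)
    if (d > best) { best <- d; arg <- i }
  }
  if (flip) arg <- n - arg + 1
  mids[arg]
}

# recursive (stack-based) flood fill over an n-dimensional logical array,
# independent of the igraph-based labelling
floodfill_oracle <- function(mask, connectivity = "face") {
  d <- dim(mask)
  nd <- length(d)
  lin <- which(mask)
  lab <- integer(length(mask))
  offs <- if (connectivity == "face") {
    rbind(diag(1, nd), -diag(1, nd))
  } else {
    g <- as.matrix(expand.grid(rep(list(-1:1), nd)))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  cur <- 0L
  for (start in lin) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      co <- arrayInd(v, d)
      for (i in seq_len(nrow(offs))) {
        nb <- co + offs[i, ]
        if (any(nb < 1) || any(nb > d)) next
        nl <- sum((nb - 1) * cumprod(c(1, d[-nd]))) + 1
        if (mask[nl] && lab[nl] == 0L) { lab[nl] <- cur; stack <- c(stack, nl) }
      }
    }
  }
  lab[lin]
}

# canonical form of a labelling: map membership vectors to the partition of
# indices so that two labellings compare equal iff they induce the same
# partition
partition_of <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort))
}
same_partition <- function(a, b) {
  setequal(lapply(partition_of(a), paste, collapse = ","),
           lapply(partition_of(b), paste, collapse = ","))
}

# small helper: build an ImageStack from a (T,H,W) array
tstack <- function(a, ...) {
  d <- dim(a)
  arr <- array(0, c(1, d[1], 1, d[2], d[3]))
  arr[1, , 1, , ] <- a
  image_stack(arr, "ctzyx", ...)
}

# trace -> 1x1-pixel stack
trace_stack <- function(x) tstack(array(x, c(length(x), 1, 1)))

# Y-shaped convergence fixture: two disjoint bars in frames 1-5 that overlap
# a single merged bar in frames 6-10 (z = 1)
y_mask_stack <- function() {
  arr <- array(FALSE, c(1, 10, 1, 5, 9))
  for (t in 1:5) {
    arr[1, t, 1, 2:3, 2:3] <- TRUE   # branch 1
    arr[1, t, 1, 2:3, 7:8] <- TRUE   # branch 2
  }
  for (t in 6:10) arr[1, t, 1, 2:3, 2:8] <- TRUE  # merged bar
  structure(list(data = arr, threshold = 0.5, method = "yen",
                 mode = "global"), class = "BinaryMask")
}

reverse_time_mask <- function(mask) {
  d <- dim(mask$data)
  mask$data <- mask$data[, rev(seq_len(d[2])), , , , drop = FALSE]
  mask
}
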