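#' Accumulate mask and masked intensity over time
#'
#' Per-voxel sums over the time axis: `v_sum` counts the frames in which each
#' (c,z,y,x) voxel is active; `u_sum` sums the masked intensity. `u_sum` is
#' zero wherever `v_sum` is zero.
#'
#' @param binary a `BinaryMask`.
#' @param masked the masked `ImageStack` of congruent shape.
#' @return A `SummedImages` list with arrays `v_sum` and `u_sum` over
#'   (c,z,y,x).
#' @export
accumulate_masks <- function(binary, masked) {
  stopifnot(inherits(binary, "BinaryMask"), inherits(masked, "ImageStack"))
  if (!identical(dim(binary$data), dim(masked$data)))
    stop("shape mismatch between mask and masked stack", call. = FALSE)
  d <- dim(binary$data)
  v_sum <- colSums(aperm(binary$data, c(2L, 1L, 3L, 4L, 5L)), dims = 1L)
  u_sum <- colSums(aperm(masked$data, c(2L, 1L, 3L, 4L, 5L)), dims = 1L)
  dim(v_sum) <- d[-2]; dim(u_sum) <- d[-2]
  storage.mode(v_sum) <- "integer"
  structure(list(v_sum = v_sum, u_sum = u_sum, T = d[2]),
            class = "SummedImages")
}

# Positive neighbour offsets for connected labelling of coordinate rows.
# face: one step along a single axis; full: all lexicographically positive
# steps in {-1,0,1}^k.
positive_offsets <- function(k, connectivity) {
  if (connectivity == "face") {
    m <- diag(1L, k)
  } else {
    g <- as.matrix(expand.grid(rep(list(-1L:1L), k)))[, k:1, drop = FALSE]
    keep <- apply(g, 1L, function(r) {
      nz <- which(r != 0L)
      length(nz) > 0L && r[nz[1L]] > 0L
    })
    m <- g[keep, , drop = FALSE]
  }
  storage.mode(m) <- "integer"
  m
}

# Connected components of a set of integer coordinate rows (n x k matrix)
# under the given connectivity. Returns an integer membership vector.
label_coords <- function(coords, dims, connectivity = "face") {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  dims <- as.integer(dims)
  mult <- cumprod(c(1L, dims[-length(dims)]))
  key <- as.vector((coords - 1L) %*% mult) + 1
  ord <- order(key)
  skey <- key[ord]
  offs <- positive_offsets(ncol(coords), connectivity)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[i, ], `+`)
    ok <- rep(TRUE, n)
    for (j in seq_len(ncol(coords)))
      ok <- ok & nb[, j] >= 1L & nb[, j] <= dims[j]
    if (!any(ok)) next
    nbkey <- as.vector((nb[ok, , drop = FALSE] - 1L) %*% mult) + 1
    pos <- findInterval(nbkey, skey)
    hit <- pos > 0L & skey[pmax(pos, 1L)] == nbkey
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, ord[pos[hit]])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  as.integer(igraph::components(g)$membership)
}

#' Label 4-D connected signal sites
#'
#' Finds all 4-D connected components ("sites") of active voxels in one
#' channel of a binary mask, discards components smaller than
#' `min_event_voxels` voxels or spanning fewer than `min_event_frames`
#' frames, and assigns ids in order of each component's lexicographically
#' smallest (t,z,y,x) voxel.
#'
#' @param binary a `BinaryMask`.
#' @param channel channel index (1-based).
#' @param connectivity `"face"` (8 neighbours in 4-D) or `"full"` (80).
#' @param min_event_voxels,min_event_frames size filters; 1 disables.
#' @return A list of `Site` objects, each with `id`, `channel`, `voxels`
#'   (n x 4 integer matrix of (t,z,y,x)), `n_voxels` and `bbox`.
#' @export
label_sites <- function(binary, channel = 1L, connectivity = c("face", "full"),
                        min_event_voxels = 1L, min_event_frames = 1L) {
  stopifnot(inherits(binary, "BinaryMask"))
  connectivity <- match.arg(connectivity)
  d <- dim(binary$data)
  m4 <- binary$data[channel, , , , ]
  dim(m4) <- d[2:5]
  lin <- which(m4)
  if (!length(lin)) return(list())
  co <- arrayInd(lin, d[2:5])  # columns: t, z, y, x
  memb <- label_coords(co, d[2:5], connectivity)
  comps <- split(seq_along(lin), memb)
  # order components by lexicographically smallest voxel in (t,z,y,x)
  lexkey <- ((co[, 1] * d[3] + co[, 2]) * d[4] + co[, 3]) * d[5] + co[, 4]
  minkey <- vapply(comps, function(ix) min(lexkey[ix]), 0)
  comps <- comps[order(minkey)]
  sites <- list()
  id <- 0L
  for (ix in comps) {
    v <- co[ix, , drop = FALSE]
    tspan <- diff(range(v[, 1])) + 1L
    if (nrow(v) < min_event_voxels || tspan < min_event_frames) next
    id <- id + 1L
    colnames(v) <- c("t", "z", "y", "x")
    sites[[id]] <- structure(
      list(id = id, channel = as.integer(channel), voxels = v,
           n_voxels = nrow(v),
           bbox = apply(v, 2L, range)),
      class = "Site")
  }
  sites
}

#' @export
print.Site <- function(x, ...) {
  cat("Site", x$id, "(channel", x$channel, "):", x$n_voxels, "voxels, frames",
      x$bbox[1, "t"], "-", x$bbox[2, "t"], "\n")
  invisible(x)
}

#' Extract the dynamic ROI of a site
#'
#' Slices a 4-D site into its per-frame spatial cross-sections and computes
#' the slicewise descriptors: area (voxels and, when calibrated, the xy area
#' of the z-projected cross-section in square micrometres), centroid, and
#' mean filtered intensity.
#'
#' @param site a `Site`.
#' @param filtered the filtered `ImageStack` the mask was derived from.
#' @return A `DynamicROI` with `start_t`, `end_t` and a data frame `frames`
#'   (one row per frame: t, area_vox, area_um2, centroid z/y/x,
#'   mean_intensity, sum_intensity), plus the per-frame voxel sets.
#' @export
extract_dynamic_roi <- function(site, filtered) {
  stopifnot(inherits(site, "Site"), inherits(filtered, "ImageStack"))
  v <- site$voxels
  ts <- sort(unique(v[, "t"]))
  if (!identical(ts, seq(min(ts), max(ts))))
    stop("site ", site$id, " is not temporally contiguous", call. = FALSE)
  px <- filtered$pixel_size_um
  cross <- vector("list", length(ts))
  rows <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    s <- v[v[, "t"] == ts[i], , drop = FALSE]
    cross[[i]] <- s[, c("z", "y", "x"), drop = FALSE]
    vals <- filtered$data[cbind(site$channel, s)]
    xy <- unique(s[, c("y", "x"), drop = FALSE])
    rows[[i]] <- data.frame(
      t = ts[i], area_vox = nrow(s),
      area_um2 = if (is.null(px)) NA_real_ else nrow(xy) * px^2,
      centroid_z = mean(s[, "z"]), centroid_y = mean(s[, "y"]),
      centroid_x = mean(s[, "x"]),
      mean_intensity = mean(vals), sum_intensity = sum(vals))
  }
  structure(list(site_id = site$id, channel = site$channel,
                 start_t = min(ts), end_t = max(ts),
                 frames = do.call(rbind, rows), cross_sections = cross),
            class = "DynamicROI")
}

#' Convergence / divergence topology of a site
#'
#' Computes the spatial components of a site's cross-section in every frame,
#' links components across consecutive frames by voxel overlap, and flags the
#' site as convergent where two or more linked branches merge into one and as
#' divergent where one branch splits into several. Branches are maximal
#' temporally contiguous runs of per-frame components; merges record the
#' incoming branches as parents of the merged branch, splits record the
#' outgoing branches as daughters of the splitting branch.
#'
#' @param site a `Site`.
#' @param connectivity spatial connectivity used within a frame.
#' @return A `TopologyRecord` with per-frame component counts `k`, logical
#'   `convergent`/`divergent` flags, and `parent_links`/`daughter_links` data
#'   frames (`from`, `to`, `frame`).
#' @export
classify_topology <- function(site, connectivity = c("face", "full")) {
  stopifnot(inherits(site, "Site"))
  connectivity <- match.arg(connectivity)
  v <- site$voxels
  ts <- seq(min(v[, "t"]), max(v[, "t"]))
  dims3 <- c(max(v[, "z"]), max(v[, "y"]), max(v[, "x"]))
  comp_by_frame <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    s <- v[v[, "t"] == ts[i], c("z", "y", "x"), drop = FALSE]
    memb <- label_coords(s, dims3, connectivity)
    comp_by_frame[[i]] <- split.data.frame(s, memb)
  }
  k <- lengths(comp_by_frame)
  # node ids per (frame, component); link by spatial voxel overlap
  node_branch <- vector("list", length(ts))
  branch_count <- 0L
  convergent <- FALSE; divergent <- FALSE
  parent_links <- daughter_links <- list()
  key3 <- function(m) (m[, 1] * (dims3[2] + 1) + m[, 2]) * (dims3[3] + 1) + m[, 3]
  for (i in seq_along(ts)) {
    nb <- integer(k[i])
    if (i == 1L) {
      for (j in seq_len(k[i])) { branch_count <- branch_count + 1L; nb[j] <- branch_count }
    } else {
      prev <- comp_by_frame[[i - 1L]]
      prev_keys <- lapply(prev, key3)
      cur_keys <- lapply(comp_by_frame[[i]], key3)
      inc <- lapply(cur_keys, function(ck)
        which(vapply(prev_keys, function(pk) any(ck %in% pk), TRUE)))
      outdeg <- tabulate(unlist(inc), nbins = k[i - 1L])
      for (j in seq_len(k[i])) {
        preds <- inc[[j]]
        if (length(preds) == 1L && outdeg[preds] == 1L) {
          nb[j] <- node_branch[[i - 1L]][preds]
        } else {
          branch_count <- branch_count + 1L
          nb[j] <- branch_count
          if (length(preds) >= 2L) {
            convergent <- TRUE
            for (p in preds)
              parent_links[[length(parent_links) + 1L]] <-
                data.frame(from = node_branch[[i - 1L]][p], to = nb[j],
                           frame = ts[i])
          }
        }
      }
      # splits: a previous component feeding >= 2 current components
      for (p in seq_len(k[i - 1L])) {
        succ <- which(vapply(inc, function(s) p %in% s, TRUE))
        if (length(succ) >= 2L) {
          divergent <- TRUE
          for (s in succ)
            daughter_links[[length(daughter_links) + 1L]] <-
              data.frame(from = node_branch[[i - 1L]][p], to = nb[s],
                         frame = ts[i])
        }
      }
    }
    node_branch[[i]] <- nb
  }
  empty <- data.frame(from = integer(0), to = integer(0), frame = integer(0))
  structure(list(site_id = site$id, k = k,
                 convergent = convergent, divergent = divergent,
                 parent_links = if (length(parent_links))
                   unique(do.call(rbind, parent_links)) else empty,
                 daughter_links = if (length(daughter_links))
                   unique(do.call(rbind, daughter_links)) else empty,
                 n_branches = branch_count),
            class = "TopologyRecord")
}
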