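mk_mask <- function(arr) structure(
  list(data = arr, threshold = 0.5, method = "yen", mode = "global"),
  class = "BinaryMask")

test_that("an isolated blob forms one site with the expected geometry", {
  arr <- array(FALSE, c(1, 30, 1, 12, 12))
  for (t in 10:20) arr[1, t, 1, 4:6, 7] <- TRUE  # 3x1 blob, 11 frames
  sites <- label_sites(mk_mask(arr))
  expect_length(sites, 1)
  expect_identical(sites[[1]]$n_voxels, 33L)
  expect_identical(unname(sites[[1]]$bbox[, "t"]), c(10L, 20L))
})

test_that("spatio-temporally separate blobs form separate sites", {
  arr <- array(FALSE, c(1, 20, 1, 10, 10))
  arr[1, 2:5, 1, 2:3, 2:3] <- TRUE
  arr[1, 12:15, 1, 7:8, 7:8] <- TRUE
  expect_length(label_sites(mk_mask(arr)), 2)
})

test_that("size filters discard small or short components", {
  arr <- array(FALSE, c(1, 10, 1, 8, 8))
  arr[1, 3:6, 1, 2:3, 2:3] <- TRUE   # 16 voxels, 4 frames
  arr[1, 5, 1, 7, 7] <- TRUE         # single voxel, single frame
  expect_length(label_sites(mk_mask(arr)), 2)
  expect_length(label_sites(mk_mask(arr), min_event_voxels = 8), 1)
  expect_length(label_sites(mk_mask(arr), min_event_frames = 2), 1)
})

test_that("labelling matches the flood-fill oracle on random sparse masks", {
  set.seed(12)
  for (i in 1:6) {
    d <- c(6, 1, 7, 8)
    m4 <- array(runif(prod(d)) < 0.18, d)
    arr <- array(m4, c(1, d))
    for (conn in c("face", "full")) {
      sites <- label_sites(mk_mask(arr), connectivity = conn)
      memb_pkg <- integer(sum(m4))
      lin <- which(m4)
      for (s in sites) {
        slin <- (s$voxels[, 4] - 1) * d[1] * d[2] * d[3] +
          (s$voxels[, 3] - 1) * d[1] * d[2] +
          (s$voxels[, 2] - 1) * d[1] + s$voxels[, 1]
        memb_pkg[match(slin, lin)] <- s$id
      }
      memb_oracle <- floodfill_oracle(m4,
        if (conn == "face") "face" else "full")
      expect_true(same_partition(memb_pkg, memb_oracle),
                  label = paste("conn", conn, "rep", i))
    }
  }
})

test_that("sites partition the active voxels and nest face within full", {
  set.seed(13)
  d <- c(8, 1, 9, 9)
  m4 <- array(runif(prod(d)) < 0.2, d)
  arr <- array(m4, c(1, d))
  face <- label_sites(mk_mask(arr), connectivity = "face")
  full <- label_sites(mk_mask(arr), connectivity = "full")
  nvox <- sum(m4)
  expect_identical(sum(vapply(face, function(s) s$n_voxels, 0L)), nvox)
  expect_identical(sum(vapply(full, function(s) s$n_voxels, 0L)), nvox)
  # every face site lies inside exactly one full site
  key <- function(v) paste(v[, 1], v[, 2], v[, 3], v[, 4])
  full_keys <- lapply(full, function(s) key(s$voxels))
  for (s in face) {
    inside <- vapply(full_keys, function(fk) all(key(s$voxels) %in% fk), TRUE)
    expect_identical(sum(inside), 1L)
  }
})

test_that("dynamic ROI cross-sections partition the site and calibrate area", {
  arr <- array(FALSE, c(1, 12, 1, 10, 10))
  for (t in 4:8) arr[1, t, 1, 3:5, 3:(t - 1)] <- TRUE
  sites <- label_sites(mk_mask(arr))
  filt <- tstack(array(1, c(12, 10, 10)))
  filt$pixel_size_um <- 0.5
  roi <- extract_dynamic_roi(sites[[1]], filt)
  expect_identical(sum(roi$frames$area_vox), sites[[1]]$n_voxels)
  expect_equal(roi$frames$area_um2, roi$frames$area_vox * 0.25)
  expect_identical(roi$start_t, 4L)
  expect_identical(roi$end_t, 8L)

  # a single-frame 30-voxel site at 0.5 um/px covers 7.5 um^2
  arr2 <- array(FALSE, c(1, 3, 1, 10, 10))
  arr2[1, 2, 1, 2:7, 2:6] <- TRUE
  s2 <- label_sites(mk_mask(arr2), min_event_frames = 1)
  roi2 <- extract_dynamic_roi(s2[[1]], filt <- {
    f <- tstack(array(1, c(3, 10, 10))); f$pixel_size_um <- 0.5; f
  })
  expect_equal(roi2$frames$area_um2, 7.5)
})

test_that("simple blobs carry no topology flags", {
  arr <- array(FALSE, c(1, 10, 1, 8, 8))
  arr[1, 2:9, 1, 3:5, 3:5] <- TRUE
  s <- label_sites(mk_mask(arr))[[1]]
  tp <- classify_topology(s)
  expect_false(tp$convergent)
  expect_false(tp$divergent)
  expect_identical(nrow(tp$parent_links), 0L)
  expect_identical(nrow(tp$daughter_links), 0L)
  expect_true(all(tp$k == 1))
})

test_that("the Y fixture is convergent with two parents of the merged branch", {
  mask <- y_mask_stack()
  s <- label_sites(mask)[[1]]
  tp <- classify_topology(s)
  expect_true(tp$convergent)
  expect_false(tp$divergent)
  expect_identical(sort(unique(tp$parent_links$from)), c(1L, 2L))
  expect_identical(unique(tp$parent_links$to), 3L)
  expect_identical(unique(tp$parent_links$frame), 6L)
  expect_identical(tp$k, c(rep(2L, 5), rep(1L, 5)))
})

test_that("time reversal swaps convergent and divergent roles", {
  mask <- y_mask_stack()
  rev_mask <- reverse_time_mask(mask)
  s <- label_sites(rev_mask)[[1]]
  tp <- classify_topology(s)
  expect_true(tp$divergent)
  expect_false(tp$convergent)
  expect_identical(nrow(tp$daughter_links), 2L)
  expect_identical(unique(tp$daughter_links$from), 1L)

  # duality on random masks: flags swap under t-reversal
  set.seed(14)
  for (i in 1:5) {
    d <- c(7, 1, 6, 6)
    m4 <- array(runif(prod(d)) < 0.3, d)
    arr <- array(m4, c(1, d))
    fw <- label_sites(mk_mask(arr))
    bw <- label_sites(reverse_time_mask(mk_mask(arr)))
    fw_flags <- sort(vapply(fw, function(s) {
      tp <- classify_topology(s); paste0(as.integer(tp$convergent),
                                         as.integer(tp$divergent))
    }, ""))
    bw_flags <- sort(vapply(bw, function(s) {
      tp <- classify_topology(s); paste0(as.integer(tp$divergent),
                                         as.integer(tp$convergent))
    }, ""))
    expect_identical(fw_flags, bw_flags, label = paste("rep", i))
  }
})

test_that("accumulated images count active frames and masked intensity", {
  arr <- array(FALSE, c(1, 5, 1, 4, 4))
  arr[1, 2:4, 1, 2, 2] <- TRUE   # active in 3 frames
  arr[1, 1, 1, 3, 3] <- TRUE     # active in 1 frame
  mask <- mk_mask(arr)
  filt <- tstack(array(2, c(5, 4, 4)))
  masked <- apply_mask(filt, mask)
  summed <- accumulate_masks(mask, masked)
  expect_identical(summed$v_sum[1, 1, 2, 2], 3L)
  expect_identical(summed$v_sum[1, 1, 3, 3], 1L)
  expect_equal(summed$u_sum[1, 1, 2, 2], 6)
  expect_true(all(summed$u_sum[summed$v_sum == 0] == 0))

  # T = 1: sums equal the single frame
  arr1 <- arr[, 1, , , , drop = FALSE]
  m1 <- mk_mask(arr1)
  s1 <- accumulate_masks(m1, apply_mask(tstack(array(2, c(1, 4, 4))), m1))
  expect_identical(as.vector(s1$v_sum), as.integer(as.vector(arr1[1, 1, , , ])))
})
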