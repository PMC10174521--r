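mk_mask2 <- function(arr) structure(
  list(data = arr, threshold = 0.5, method = "yen", mode = "global"),
  class = "BinaryMask")

# build a ROI whose per-frame cross-section means and areas are prescribed
fixture_roi <- function(means = c(1, 4, 2), areas = c(5, 9, 5)) {
  arr <- array(FALSE, c(1, length(means), 1, 10, 10))
  filt <- array(0, c(1, length(means), 1, 10, 10))
  for (t in seq_along(means)) {
    n <- areas[t]
    px <- cbind(rep(1L, n), 4L + (seq_len(n) - 1L) %/% 3L,
                4L + (seq_len(n) - 1L) %% 3L)
    arr[cbind(1L, t, px)] <- TRUE
    filt[cbind(1L, t, px)] <- means[t]
  }
  fs <- image_stack(filt, "ctzyx")
  sites <- label_sites(mk_mask2(arr))
  list(roi = extract_dynamic_roi(sites[[1]], fs), filt = fs)
}

test_that("delta f, duration and area peaks follow their definitions", {
  fx <- fixture_roi()
  m <- compute_event_metrics(fx$roi, frame_interval_s = 1 / 20)
  expect_equal(m$delta_f, 4)
  expect_equal(m$max_area, 9)
  expect_identical(m$t_peak_area, 2L)
  expect_equal(m$duration, 3 / 20)
  expect_identical(m$duration_unit, "s")

  # 10 frames at 20 frames/s last 0.5 s
  fx10 <- fixture_roi(means = rep(1, 10), areas = rep(4, 10))
  m10 <- compute_event_metrics(fx10$roi, frame_interval_s = 1 / 20)
  expect_equal(m10$duration, 0.5)

  # uncalibrated: duration in frames, tagged
  mf <- compute_event_metrics(fx$roi)
  expect_identical(mf$duration, 3L)
  expect_identical(mf$duration_unit, "frames")
})

test_that("peak-voxel amplitude uses the brightest voxel", {
  fx <- fixture_roi()
  fx$filt$data[1, 2, 1, 4, 4] <- 50
  roi <- extract_dynamic_roi(label_sites(mk_mask2(fx$filt$data > 0))[[1]],
                             fx$filt)
  m <- compute_event_metrics(roi, amplitude_method = "peak_voxel",
                             filtered = fx$filt)
  expect_equal(m$delta_f, 50)
})

test_that("delta f is invariant to a temporally constant intensity offset", {
  set.seed(20)
  base <- array(rnorm(30 * 8 * 8, 2, 0.05), c(30, 8, 8))
  base[10:20, 3:5, 3:5] <- base[10:20, 3:5, 3:5] + 5
  offset <- array(rep(runif(64, 0, 3), each = 30), c(30, 8, 8))
  cfg <- analysis_config(blur_sigma = 0, min_event_voxels = 1,
                         min_event_frames = 1)
  d1 <- detect_events(tstack(base), cfg, topology = FALSE)
  d2 <- detect_events(tstack(base + offset), cfg, topology = FALSE)
  expect_equal(length(d1$sites), length(d2$sites))
  expect_equal(d1$metrics[[1]]$delta_f, d2$metrics[[1]]$delta_f,
               tolerance = 1e-8)
})

test_that("durations and areas scale linearly with calibration", {
  arr <- array(FALSE, c(1, 10, 1, 8, 8))
  arr[1, 3:7, 1, 3:5, 3:5] <- TRUE
  f1 <- tstack(array(1, c(10, 8, 8))); f1$pixel_size_um <- 1
  f2 <- tstack(array(1, c(10, 8, 8))); f2$pixel_size_um <- 3
  r1 <- extract_dynamic_roi(label_sites(mk_mask2(arr))[[1]], f1)
  r2 <- extract_dynamic_roi(label_sites(mk_mask2(arr))[[1]], f2)
  m1 <- compute_event_metrics(r1, frame_interval_s = 1)
  m2 <- compute_event_metrics(r2, frame_interval_s = 4)
  expect_equal(m2$max_area, 9 * m1$max_area)
  expect_equal(m2$duration, 4 * m1$duration)
})

test_that("pearson correlation matches the hand-computed value", {
  z <- c(1, 2, 3, 4); tp <- c(2, 1, 3, 2)
  r_hand <- sum((z - mean(z)) * (tp - mean(tp))) /
    sqrt(sum((z - mean(z))^2) * sum((tp - mean(tp))^2))
  got <- peak_time_depth_correlation(z, tp)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$r, 1 / sqrt(10), tolerance = 1e-9)

  line <- peak_time_depth_correlation(1:5, 2 * (1:5) + 3)
  expect_equal(line$r, 1)
  neg <- peak_time_depth_correlation(z, -tp)
  expect_equal(neg$r, -got$r, tolerance = 1e-12)
  expect_equal(neg$p, got$p, tolerance = 1e-12)
  expect_error(peak_time_depth_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(peak_time_depth_correlation(1:2, 1:2), "at least 3")
})

test_that("site frequency counts events per locale over the recording", {
  arr <- array(FALSE, c(1, 60, 1, 10, 10))
  for (t in c(2:5, 20:23, 40:43)) arr[1, t, 1, 2:3, 2:3] <- TRUE  # 3 events
  for (t in 10:14) arr[1, t, 1, 7:8, 7:8] <- TRUE                 # 1 event
  mask <- mk_mask2(arr)
  filt <- tstack(array(1, c(60, 10, 10)))
  masked <- apply_mask(filt, mask)
  summed <- accumulate_masks(mask, masked)
  sites <- label_sites(mask)
  rois <- lapply(sites, extract_dynamic_roi, filtered = filt)
  mets <- lapply(rois, compute_event_metrics)
  acts <- site_frequency(summed, mets, rois, frame_interval_s = 1)
  expect_length(acts, 2)
  counts <- sort(vapply(acts, function(a) length(a$events), 0L))
  expect_identical(counts, c(1L, 3L))
  # 3 events in a 60 s recording = 0.05 Hz
  expect_equal(sort(vapply(acts, function(a) a$frequency, 0))[2], 0.05)
  expect_identical(site_frequency(summed, list(), list(), 1), list())
})

test_that("the report writes a complete CSV and histogram files", {
  arr <- array(FALSE, c(1, 20, 1, 12, 12))
  arr[1, 3:8, 1, 3:5, 3:5] <- TRUE
  arr[1, 12:17, 1, 8:10, 8:10] <- TRUE
  mask <- mk_mask2(arr)
  filt <- tstack(array(2, c(20, 12, 12)))
  sites <- label_sites(mask)
  rois <- lapply(sites, extract_dynamic_roi, filtered = filt)
  mets <- lapply(rois, compute_event_metrics)
  out <- withr::local_tempdir()
  files <- render_report(mets, rois, out)
  tab <- utils::read.csv(file.path(out, "events.csv"))
  expect_identical(nrow(tab), 2L)
  expect_true(file.exists(file.path(out, "histograms.png")))

  empty <- render_report(list(), NULL, file.path(out, "empty"))
  etab <- utils::read.csv(file.path(out, "empty", "events.csv"))
  expect_identical(nrow(etab), 0L)
  expect_true(any(grepl("REPORT", empty)))
})

test_that("a known injected shift in log max area is recovered", {
  set.seed(21)
  # two synthetic condition groups of event areas, log-normal with a
  # 0.5-log-unit mean shift
  shift <- 0.5
  g1 <- 10^(rnorm(40, 1.2, 0.25))
  g2 <- 10^(rnorm(40, 1.2 + shift, 0.25))
  tt <- t.test(log10(g2), log10(g1), var.equal = TRUE)
  expect_lt(tt$p.value, 1e-6)
  expect_equal(unname(tt$estimate[1] - tt$estimate[2]), shift,
               tolerance = 0.15)
})
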