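test_that("a zero-amplitude pulse stack is pure Normal(1,1) noise", {
  g <- generate_pulse_stack(pulse_params(amplitude = 0), 42)
  v <- as.vector(g$stack$data)
  expect_equal(mean(v), 1, tolerance = 0.01)
  expect_equal(sd(v), 1, tolerance = 0.01)
  expect_identical(g$manifest$n_events, 0L)
})

test_that("the noiseless pulse component peaks at frame 90 over 30 pixels", {
  p <- pulse_params(amplitude = 5, noise_sd = 0, noise_mean = 0)
  g <- generate_pulse_stack(p, 1)
  per_frame <- apply(g$stack$data[1, , 1, , ], 1, sum)
  expect_identical(which.max(per_frame), 90L)
  expect_identical(sum(g$stack$data[1, 90, 1, , ] > 0), 30L)
  expect_identical(g$manifest$events[[1]]$truth_max_area, 30L)
  # footprint is the 6 x 5 centred rectangle
  fp <- g$manifest$events[[1]]$footprint
  expect_identical(nrow(fp), 30L)
  expect_identical(diff(range(fp[, "y"])) + 1L, 6L)
  expect_identical(diff(range(fp[, "x"])) + 1L, 5L)
})

test_that("pulse generation is bit-reproducible for a fixed seed", {
  a <- generate_pulse_stack(pulse_params(amplitude = 3), 99)
  b <- generate_pulse_stack(pulse_params(amplitude = 3), 99)
  expect_identical(a$stack$data, b$stack$data)
  c <- generate_pulse_stack(pulse_params(amplitude = 3), 100)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("percent error follows its definition", {
  expect_equal(percent_error(30, 30), 0)
  expect_equal(percent_error(33, 30), 10)
  expect_equal(percent_error(27, 30), 10)
  expect_error(percent_error(10, 0), "undefined")
})

test_that("the polygonal catalogue has 57 events covering every scenario", {
  poly <- generate_polygonal_dataset(1)
  expect_identical(poly$manifest$n_events, 57L)
  expect_length(poly$stacks, 15)
  classes <- table(vapply(poly$manifest$events, `[[`, "", "scenario_type"))
  expect_true(all(c("growth_decay", "propagation", "periodic", "convergence",
                    "divergence", "static") %in% names(classes)))
  expect_true(all(classes >= 2))
})

test_that("rendered polygonal stacks equal their manifest masks pixelwise", {
  poly <- generate_polygonal_dataset(1)
  for (si in seq_along(poly$stacks)) {
    a <- poly$stacks[[si]]$data
    truth <- array(0, dim(a))
    for (e in poly$manifest$events) {
      if (e$sequence != si) next
      for (f in e$frames)
        truth[cbind(1L, f$t, 1L, f$yx[, "y"], f$yx[, "x"])] <- e$intensity
    }
    expect_identical(a, truth, label = sprintf("sequence %d", si))
  }
})

test_that("polygonal events never overlap and dwell at least two frames", {
  poly <- generate_polygonal_dataset(1)
  for (si in seq_along(poly$stacks)) {
    evs <- Filter(function(e) e$sequence == si, poly$manifest$events)
    keys <- lapply(evs, function(e)
      unlist(lapply(e$frames, function(f)
        paste(f$t, f$yx[, "y"], f$yx[, "x"]))))
    all_keys <- unlist(keys)
    expect_identical(anyDuplicated(all_keys), 0L,
                     label = sprintf("sequence %d overlap", si))
    # per-pixel dwell: every (y,x) of an event appears in >= 2 frames
    for (e in evs) {
      px <- table(unlist(lapply(e$frames, function(f)
        paste(f$yx[, "y"], f$yx[, "x"]))))
      expect_true(all(px >= 2),
                  label = sprintf("seq %d event %d dwell", si, e$event_id))
    }
  }
})

test_that("the growth/decay scenario area is strictly unimodal and matches detection", {
  poly <- generate_polygonal_dataset(1)
  gd <- Filter(function(e) e$scenario_type == "growth_decay",
               poly$manifest$events)[[1]]
  areas <- vapply(gd$frames, function(f) nrow(f$yx), 0L)
  pk <- which.max(areas)
  expect_true(all(diff(areas[1:pk]) > 0))
  expect_true(all(diff(areas[pk:length(areas)]) < 0))

  # end-to-end: detected per-frame areas equal the manifest areas exactly
  si <- gd$sequence
  det <- detect_events(poly$stacks[[si]],
                       analysis_config(blur_sigma = 0,
                                       threshold_method = "otsu",
                                       min_event_voxels = 1,
                                       min_event_frames = 1),
                       topology = FALSE)
  evs <- Filter(function(e) e$sequence == si, poly$manifest$events)
  mm <- match_sites_to_events(det$sites, evs)
  row <- mm$matches[mm$matches$event_id == gd$event_id, ]
  expect_identical(nrow(row), 1L)
  roi <- det$rois[[row$site_id]]
  expect_identical(roi$frames$area_vox, areas)
  expect_identical(roi$frames$t, vapply(gd$frames, `[[`, 0L, "t"))
})

test_that("snr-0 sweeps record no matched detection", {
  tab <- run_snr_sweep(0, reps = 2, seed = 5)
  expect_true(all(!tab$detected))
  expect_true(all(is.na(tab$percent_error)))
})
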