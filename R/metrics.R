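#' Per-event descriptors
#'
#' Computes the descriptor record of one detected event from its dynamic ROI.
#' Because dynamic ROIs have no static baseline region, amplitude is reported
#' as delta f — the maximal change in background-subtracted intensity — rather
#' than a normalized f/f0 ratio. By default delta f is the maximum over frames
#' of the cross-section mean intensity; `amplitude_method = "peak_voxel"`
#' uses the single brightest voxel instead.
#'
#' @param roi a `DynamicROI`.
#' @param topology optional `TopologyRecord` for the same site.
#' @param frame_interval_s optional seconds per frame; when missing, duration
#'   is reported in frames and `duration_unit` says so.
#' @param amplitude_method `"mean"` or `"peak_voxel"`.
#' @param filtered the filtered `ImageStack` (only needed for
#'   `"peak_voxel"`).
#' @return An `EventMetrics` list.
#' @export
compute_event_metrics <- function(roi, topology = NULL,
                                  frame_interval_s = NULL,
                                  amplitude_method = c("mean", "peak_voxel"),
                                  filtered = NULL) {
  stopifnot(inherits(roi, "DynamicROI"))
  amplitude_method <- match.arg(amplitude_method)
  fr <- roi$frames
  n_frames <- nrow(fr)
  delta_f <- if (amplitude_method == "mean") {
    max(fr$mean_intensity)
  } else {
    stopifnot(inherits(filtered, "ImageStack"))
    mx <- -Inf
    for (i in seq_len(n_frames)) {
      s <- roi$cross_sections[[i]]
      idx <- cbind(roi$channel, fr$t[i], s)
      mx <- max(mx, max(filtered$data[idx]))
    }
    mx
  }
  calibrated_area <- !all(is.na(fr$area_um2))
  areas <- if (calibrated_area) fr$area_um2 else fr$area_vox
  ipk_area <- which.max(areas)
  ipk_int <- which.max(fr$sum_intensity)
  dur <- if (is.null(frame_interval_s)) n_frames else n_frames * frame_interval_s
  structure(list(
    site_id = roi$site_id, channel = roi$channel,
    delta_f = delta_f,
    duration = dur,
    duration_unit = if (is.null(frame_interval_s)) "frames" else "s",
    n_frames = n_frames,
    max_area = max(areas),
    area_unit = if (calibrated_area) "um2" else "voxels",
    t_peak_area = fr$t[ipk_area],
    t_peak_intensity = fr$t[ipk_int],
    area_at_peak_intensity = areas[ipk_int],
    start_frame = roi$start_t, end_frame = roi$end_t,
    origination = c(z = fr$centroid_z[1], y = fr$centroid_y[1],
                    x = fr$centroid_x[1]),
    convergent = if (is.null(topology)) NA else topology$convergent,
    divergent = if (is.null(topology)) NA else topology$divergent,
    n_parent_links = if (is.null(topology)) NA_integer_
                     else nrow(topology$parent_links),
    n_daughter_links = if (is.null(topology)) NA_integer_
                       else nrow(topology$daughter_links)),
    class = "EventMetrics")
}

#' Flatten a list of EventMetrics to a data frame
#' @param events list of `EventMetrics`.
#' @return A data frame with one row per event.
#' @export
events_table <- function(events) {
  cols <- c("site_id", "channel", "delta_f", "duration", "duration_unit",
            "n_frames", "max_area", "area_unit", "t_peak_area",
            "t_peak_intensity", "area_at_peak_intensity", "start_frame",
            "end_frame", "convergent", "divergent", "n_parent_links",
            "n_daughter_links")
  if (!length(events)) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols) + 3L),
                                 c(cols, "origination_z", "origination_y",
                                   "origination_x")))
    return(df)
  }
  rows <- lapply(events, function(e) {
    d <- e[cols]
    d$origination_z <- e$origination[["z"]]
    d$origination_y <- e$origination[["y"]]
    d$origination_x <- e$origination[["x"]]
    as.data.frame(d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Site-locale activity and event frequency
#'
#' Connected spatial locales of the accumulated mask footprint (`v_sum > 0`)
#' are associated with the events whose spatial extent overlaps them, and the
#' event frequency of each locale is the event count divided by the recording
#' duration.
#'
#' @param summed a `SummedImages`.
#' @param events list of `EventMetrics`.
#' @param rois list of `DynamicROI` matching `events` (for spatial extents).
#' @param frame_interval_s optional seconds per frame; when missing,
#'   frequency is per frame.
#' @return A list of `SiteActivity` records (locale id, channel, size,
#'   event ids, frequency).
#' @export
site_frequency <- function(summed, events, rois, frame_interval_s = NULL) {
  stopifnot(inherits(summed, "SummedImages"))
  if (!length(events)) return(list())
  d <- dim(summed$v_sum)  # (C,Z,Y,X)
  T <- summed$T
  total_time <- if (is.null(frame_interval_s)) T else T * frame_interval_s
  out <- list()
  for (cc in seq_len(d[1])) {
    fp <- summed$v_sum[cc, , , ]
    dim(fp) <- d[2:4]
    lin <- which(fp > 0)
    if (!length(lin)) next
    co <- arrayInd(lin, d[2:4])
    memb <- label_coords(co, d[2:4], "face")
    key <- (co[, 1] * (d[3] + 1) + co[, 2]) * (d[4] + 1) + co[, 3]
    for (m in sort(unique(memb))) {
      lockey <- key[memb == m]
      ev_ids <- integer(0)
      for (i in seq_along(events)) {
        if (events[[i]]$channel != cc) next
        ext <- unique(do.call(rbind, rois[[i]]$cross_sections))
        ekey <- (ext[, 1] * (d[3] + 1) + ext[, 2]) * (d[4] + 1) + ext[, 3]
        if (any(ekey %in% lockey)) ev_ids <- c(ev_ids, events[[i]]$site_id)
      }
      out[[length(out) + 1L]] <- structure(
        list(locale = m, channel = cc, n_voxels = length(lockey),
             events = ev_ids,
             frequency = length(ev_ids) / total_time,
             frequency_unit = if (is.null(frame_interval_s)) "per frame"
                              else "Hz"),
        class = "SiteActivity")
    }
  }
  out
}

#' Pearson correlation of signal peak time with depth
#'
#' Standard Pearson correlation with its two-sided t-distributed probability,
#' for quantifying depth-dependent delays of signal peaks in volumetric
#' recordings.
#'
#' @param z numeric z positions (>= 3 values, non-constant).
#' @param t_peak numeric peak times, same length.
#' @return A list with `r`, `p`, `n`.
#' @export
peak_time_depth_correlation <- function(z, t_peak) {
  if (length(z) != length(t_peak)) stop("z and t_peak differ in length",
                                        call. = FALSE)
  if (length(z) < 3L) stop("need at least 3 (z, t_peak) pairs", call. = FALSE)
  if (stats::sd(z) == 0 || stats::sd(t_peak) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- stats::cor.test(z, t_peak, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(z))
}

#' Write the graphical and tabular event report
#'
#' Writes (a) the flat per-event CSV table, (b) histograms of delta f, log10
#' duration and log10 maximal area, (c) summed / standard-deviation / maximum
#' projection images when the stacks are supplied, and (d) per-event
#' area-versus-time traces. With zero events a header-only CSV and a note are
#' still produced.
#'
#' @param events list of `EventMetrics`.
#' @param rois matching list of `DynamicROI` (for area traces), or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param summed optional `SummedImages` for projections.
#' @param filtered optional filtered `ImageStack` for the STD projection.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(events, rois = NULL, out_dir, summed = NULL,
                          filtered = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tab <- events_table(events)
  csv <- file.path(out_dir, "events.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  written <- c(written, csv)
  if (!length(events)) {
    note <- file.path(out_dir, "REPORT.txt")
    writeLines("no events detected", note)
    return(invisible(c(written, note)))
  }
  hist_png <- file.path(out_dir, "histograms.png")
  grDevices::png(hist_png, width = 1200, height = 400)
  graphics::par(mfrow = c(1, 3))
  graphics::hist(tab$delta_f, breaks = "Sturges", main = "Amplitude",
                 xlab = "delta f (a.u.)", col = "grey70")
  graphics::hist(log10(tab$duration), breaks = "Sturges", main = "Duration",
                 xlab = paste0("log10 duration (", tab$duration_unit[1], ")"),
                 col = "grey70")
  graphics::hist(log10(tab$max_area), breaks = "Sturges",
                 main = "Maximal area",
                 xlab = paste0("log10 max area (", tab$area_unit[1], ")"),
                 col = "grey70")
  grDevices::dev.off()
  written <- c(written, hist_png)
  if (!is.null(rois)) {
    tr_png <- file.path(out_dir, "area_traces.png")
    grDevices::png(tr_png, width = 900, height = 600)
    xlim <- range(unlist(lapply(rois, function(r) r$frames$t)))
    ylim <- c(0, max(unlist(lapply(rois, function(r) r$frames$area_vox))))
    graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "frame",
                   ylab = "cross-section area (voxels)",
                   main = "Dynamic ROI area over time")
    cols <- grDevices::rainbow(length(rois))
    for (i in seq_along(rois))
      graphics::lines(rois[[i]]$frames$t, rois[[i]]$frames$area_vox,
                      col = cols[i])
    grDevices::dev.off()
    written <- c(written, tr_png)
  }
  if (!is.null(summed)) {
    d <- dim(summed$v_sum)
    proj <- image_stack(array(as.numeric(summed$u_sum), c(d[1], 1, d[2], d[3], d[4])),
                        "ctzyx", name = "u_sum")
    f <- file.path(out_dir, "sum_projection.tif")
    write_stack(proj, f)
    written <- c(written, f)
  }
  if (!is.null(filtered)) {
    d <- dim(filtered$data)
    m <- matrix(aperm(filtered$data, c(2, 1, 3, 4, 5)), nrow = d[2])
    stdproj <- sqrt(pmax(0, colMeans(m^2) - colMeans(m)^2))
    maxproj <- do.call(pmax, lapply(seq_len(d[2]), function(t) m[t, ]))
    std <- array(stdproj, c(d[1], 1, d[3], d[4], d[5]))
    mx <- array(maxproj, c(d[1], 1, d[3], d[4], d[5]))
    f1 <- file.path(out_dir, "std_projection.tif")
    f2 <- file.path(out_dir, "max_projection.tif")
    write_stack(image_stack(std, "ctzyx", name = "std"), f1)
    write_stack(image_stack(mx, "ctzyx", name = "max"), f2)
    written <- c(written, f1, f2)
  }
  invisible(written)
}
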