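#' Results archive
#'
#' Detection results are archived as gzip-compressed JSON lines
#' (`.jsonl.gz`), a self-describing cross-language container. The first line
#' is a header object (`format`, `schema_version`, `n_events`, `config`);
#' every following line is one event record with the site geometry, the
#' per-frame dynamic-ROI measurements and the event metrics. All numbers are
#' serialized at full precision so that [read_results_archive()] inverts the
#' write losslessly.
#'
#' @param result a `DetectionResult` from [detect_events()], or a list with
#'   elements `sites`, `rois`, `metrics`, `topology`.
#' @param path output path (conventionally ending in `.jsonl.gz`).
#' @return `path`, invisibly.
#' @export
write_results_archive <- function(result, path) {
  sites <- result$sites; rois <- result$rois
  metrics <- result$metrics; topology <- result$topology
  n <- length(sites)
  if (length(rois) != n || length(metrics) != n)
    stop("incomplete records: ", n, " sites but ", length(rois), " ROIs and ",
         length(metrics), " metrics", call. = FALSE)
  for (i in seq_len(n)) {
    miss <- setdiff(c("delta_f", "duration", "max_area", "start_frame"),
                    names(metrics[[i]]))
    if (length(miss))
      stop("metrics record ", i, " is missing fields: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  con <- gzfile(path, "wb")
  on.exit(close(con))
  header <- list(format = "dynroi-results", schema_version = 1L,
                 n_events = n,
                 config = if (!is.null(result$config)) unclass(result$config))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17),
                              null = "null"), con)
  for (i in seq_len(n)) {
    s <- sites[[i]]; r <- rois[[i]]; m <- metrics[[i]]; tp <- topology[[i]]
    rec <- list(
      site_id = s$id, channel = s$channel, n_voxels = s$n_voxels,
      bbox = list(t = s$bbox[, "t"], z = s$bbox[, "z"],
                  y = s$bbox[, "y"], x = s$bbox[, "x"]),
      start_t = r$start_t, end_t = r$end_t,
      frames = r$frames,
      metrics = unclass(m),
      topology = if (!is.null(tp)) list(
        convergent = tp$convergent, divergent = tp$divergent,
        k = tp$k, parent_links = tp$parent_links,
        daughter_links = tp$daughter_links))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                dataframe = "columns", null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_results_archive
#' @return `read_results_archive()` returns a list with `header` and
#'   `events` (a list of event records; data frames restored).
#' @export
read_results_archive <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) stop("empty archive: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "dynroi-results"))
    stop("not a dynroi results archive: ", path, call. = FALSE)
  events <- lapply(lines[-1], function(l)
    jsonlite::fromJSON(l, simplifyDataFrame = TRUE))
  if (length(events) != header$n_events)
    stop("archive corrupt: header says ", header$n_events, " events but ",
         length(events), " records found", call. = FALSE)
  list(header = header, events = events)
}
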