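#' Multidimensional image stacks
#'
#' An `ImageStack` holds a five-axis array of fluorescence intensities in the
#' fixed axis order (channel, time, z, y, x), together with optional spatial
#' and temporal calibration. Axes absent from a source file are represented as
#' size-1 axes, so a plain 2-D movie has C = 1 and Z = 1. Intensities are
#' treated as arbitrary units throughout; no photometric rescaling is applied.
#'
#' @param data numeric array with up to five dimensions. Arrays with fewer
#'   than five dimensions are promoted by prepending/appending size-1 axes
#'   according to `axis_order`.
#' @param axis_order character string naming the axes of `data` in order,
#'   using letters from "ctzyx" (e.g. "tyx" for a 2-D movie). Defaults to the
#'   trailing letters of "ctzyx" matching the number of dimensions.
#' @param pixel_size_um optional positive xy pixel size in micrometres.
#' @param z_step_um optional positive z step in micrometres.
#' @param frame_interval_s optional positive frame interval in seconds.
#' @param name text label carried through the pipeline.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, axis_order = NULL, pixel_size_um = NULL,
                        z_step_um = NULL, frame_interval_s = NULL,
                        name = "stack") {
  if (!is.array(data)) {
    if (is.matrix(data)) data <- array(data, dim(data))
    else stop("`data` must be an array", call. = FALSE)
  }
  nd <- length(dim(data))
  if (nd > 5L) stop("more than 5 axes (", nd, ") are not supported", call. = FALSE)
  if (is.null(axis_order)) axis_order <- substring("ctzyx", 6L - nd)
  ax <- strsplit(tolower(axis_order), "")[[1]]
  if (length(ax) != nd || anyDuplicated(ax) || !all(ax %in% c("c", "t", "z", "y", "x")))
    stop("axis_order '", axis_order, "' does not match data with ", nd,
         " dimensions (letters from 'ctzyx', no repeats)", call. = FALSE)
  full <- c("c", "t", "z", "y", "x")
  # promote to 5 axes, missing axes become size 1, then permute to (c,t,z,y,x)
  dims <- rep(1L, 5L)
  dims[match(ax, full)] <- dim(data)
  perm <- order(match(ax, full))
  data <- aperm(array(data, dim(data)), perm)
  dim(data) <- dims
  for (v in c("pixel_size_um", "z_step_um", "frame_interval_s")) {
    val <- get(v)
    if (!is.null(val) && (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0))
      stop(v, " must be a single positive number", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         frame_interval_s = frame_interval_s, name = as.character(name)),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat("ImageStack '", x$name, "': C=", d[1], " T=", d[2], " Z=", d[3],
      " Y=", d[4], " X=", d[5], "\n", sep = "")
  cal <- c(
    if (!is.null(x$pixel_size_um)) paste0(x$pixel_size_um, " um/px"),
    if (!is.null(x$z_step_um)) paste0(x$z_step_um, " um/z"),
    if (!is.null(x$frame_interval_s)) paste0(x$frame_interval_s, " s/frame"))
  if (length(cal)) cat("  calibration:", paste(cal, collapse = ", "), "\n")
  invisible(x)
}

#' Axis sizes of an ImageStack
#' @param stack an `ImageStack`.
#' @return Named integer vector with elements C, T, Z, Y, X.
#' @export
axis_sizes <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  c(C = d[1], T = d[2], Z = d[3], Y = d[4], X = d[5])
}

# Parse an ImageJ-style description string ("key=value" per line) into a list.
parse_imagej_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(list())
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- regmatches(lines, regexec("^([A-Za-z_.]+)=(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  out <- lapply(kv, function(m) m[3])
  names(out) <- vapply(kv, function(m) m[2], "")
  out
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a multidimensional TIFF into an ImageStack
#'
#' Reads single- or multi-page TIFF files. Axis structure is resolved from, in
#' order of precedence: a metadata sidecar written by [write_stack()], an
#' ImageJ-style description tag (`channels=`, `slices=`, `frames=`), the
#' `axis_order_hint`, and finally the default of treating all pages as time
#' points. Calibration is restored from the sidecar or from ImageJ tags
#' (`spacing`, `finterval`) when present.
#'
#' @param path path to a readable TIFF file.
#' @param axis_order_hint optional string such as "tzyx" or "ctyx" describing
#'   how pages are organized when no metadata is available. Page-major order is
#'   assumed to cycle fastest over the last page axis letter given before "yx".
#' @return An `ImageStack`.
#' @export
read_stack <- function(path, axis_order_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  # 8/16-bit integer samples are returned scaled into [0,1]; undo that.
  # 32-bit samples are IEEE floats and arrive as stored.
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  if (bits %in% c(8L, 16L))
    pages <- lapply(pages, function(p) round(p * (2^bits - 1)))
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  n <- length(pages)
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::fromJSON(sc)
  desc <- attr(pages[[1]], "description")
  ij <- parse_imagej_description(desc)

  if (!is.null(meta)) {
    C <- meta$axis_sizes[1]; T <- meta$axis_sizes[2]; Z <- meta$axis_sizes[3]
  } else if (length(ij) && any(c("channels", "slices", "frames") %in% names(ij))) {
    C <- as.integer(ij$channels %||% 1L)
    Z <- as.integer(ij$slices %||% 1L)
    T <- as.integer(ij$frames %||% (n / (C * Z)))
  } else if (!is.null(axis_order_hint)) {
    ax <- strsplit(tolower(axis_order_hint), "")[[1]]
    page_ax <- setdiff(ax, c("y", "x"))
    if (length(page_ax) > 1L)
      stop("ambiguous axis hint '", axis_order_hint,
           "': page counts for axes ", paste(page_ax, collapse = ","),
           " cannot be separated without sizes; use a metadata sidecar",
           call. = FALSE)
    C <- if (identical(page_ax, "c")) n else 1L
    Z <- if (identical(page_ax, "z")) n else 1L
    T <- if (length(page_ax) == 0L) 1L else if (identical(page_ax, "t")) n else 1L
  } else {
    C <- 1L; Z <- 1L; T <- n
  }
  if (C * T * Z != n)
    stop("axis metadata (C=", C, ", T=", T, ", Z=", Z,
         ") does not match page count ", n, call. = FALSE)

  # page order follows the ImageJ hyperstack convention: c fastest, then z, then t
  arr <- array(0, c(C, T, Z, H, W))
  p <- 1L
  for (t in seq_len(T)) for (z in seq_len(Z)) for (cc in seq_len(C)) {
    arr[cc, t, z, , ] <- pages[[p]]
    p <- p + 1L
  }
  if (!is.null(meta)) {
    arr <- arr * meta$scale + meta$offset
    if (isTRUE(meta$integer_data)) arr <- round(arr)
  }
  px <- zs <- fi <- NULL
  if (!is.null(meta)) {
    px <- meta$pixel_size_um; zs <- meta$z_step_um; fi <- meta$frame_interval_s
    if (length(px) == 0) px <- NULL
    if (length(zs) == 0) zs <- NULL
    if (length(fi) == 0) fi <- NULL
  } else if (length(ij)) {
    if (!is.null(ij$spacing)) zs <- as.numeric(ij$spacing)
    if (!is.null(ij$finterval)) fi <- as.numeric(ij$finterval)
  }
  image_stack(arr, "ctzyx", pixel_size_um = px, z_step_um = zs,
              frame_interval_s = fi,
              name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Pages are written in ImageJ hyperstack order (channel fastest, then z, then
#' time) as 32-bit float samples, linearly mapped into the writable range with
#' an exact power-of-two scale. The axis sizes, the scale, and the calibration
#' are stored in a JSON sidecar (`<path>.meta.json`) so that [read_stack()]
#' inverts the write bit-exactly for integer data and to 32-bit float
#' precision for real data.
#'
#' @param stack an `ImageStack`.
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  integer_data <- all(stack$data == round(stack$data))
  offset <- lo
  span <- hi - lo
  scale <- if (span <= 0) 1 else 2^ceiling(log2(span))
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 1L
  for (t in seq_len(d[2])) for (z in seq_len(d[3])) for (cc in seq_len(d[1])) {
    pages[[p]] <- (stack$data[cc, t, z, , ] - offset) / scale
    p <- p + 1L
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  meta <- list(format = "dynroi-stack", schema_version = 1L,
               axis_sizes = unname(d), offset = offset, scale = scale,
               integer_data = integer_data,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               name = stack$name)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
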