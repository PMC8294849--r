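#' Write / read a voxel stack as multi-page TIFF with a YAML sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages (one per z-slice);
#' the voxel size and origin go into a `<path>.yml` sidecar so the
#' physical calibration survives the round trip.
#'
#' @param stack a `voxel_stack`.
#' @param path TIFF file path.
#' @return `read_stack_tiff` returns the `voxel_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!inherits(stack, "voxel_stack")) mito_stop("stack must be a voxel_stack")
  # TIFF sample values live in [0, 1]; physical intensities are restored
  # from the scale factor in the sidecar
  scale <- max(max(stack$data), 1)
  pages <- lapply(seq_len(dim(stack$data)[3]), function(z) {
    m <- stack$data[, , z] / scale
    storage.mode(m) <- "double"
    t(m)  # tiff stores row-major (y, x)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(
    list(voxel_size_um = as.numeric(stack$voxel_size),
         origin_um = as.numeric(stack$origin),
         intensity_scale = as.numeric(scale),
         logical = is.logical(stack$data)),
    paste0(path, ".yml")
  )
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  dims <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  arr <- array(0, dims)
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  arr <- arr * (meta$intensity_scale %||% 1)
  if (isTRUE(meta$logical)) arr <- arr > 0.5 * (meta$intensity_scale %||% 1)
  voxel_stack(arr, meta$voxel_size_um, meta$origin_um)
}

#' Write / read a sampled trace as CSV with a units header
#'
#' Two columns, `t_s` and `value`; the value unit and sample rate are
#' recorded in comment lines so recordings stay self-describing.
#'
#' @param samples numeric vector.
#' @param sample_rate Hz.
#' @param path CSV path.
#' @param unit value unit label (e.g. `"mV"`, `"pA"`).
#' @return `read_trace_csv` returns a list with `samples`, `sample_rate`,
#'   `unit`.
#' @export
write_trace_csv <- function(samples, sample_rate, path, unit = "mV") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# unit: ", unit),
               paste0("# sample_rate_hz: ", sample_rate),
               "t_s,value"), con)
  t <- (seq_along(samples) - 1) / sample_rate
  writeLines(paste(t, samples, sep = ","), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  unit <- sub("# unit: ", "", hdr[1])
  fs <- as.numeric(sub("# sample_rate_hz: ", "", hdr[2]))
  df <- read.csv(path, comment.char = "#")
  list(samples = df$value, sample_rate = fs, unit = unit)
}
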