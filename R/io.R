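#' Image and sinogram file I/O
#'
#' Images and sinograms are exchanged as raw little-endian float32 binaries
#' with a plain-text sidecar header (`<path>.hdr`) carrying the shape, and
#' optionally as 32-bit float TIFF for visualisation. The raw format
#' round-trips float32 values bitwise.
#'
#' @param image,sinogram numeric matrix to write.
#' @param path output path for the binary payload; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param geometry the [ct_geometry()] the sinogram belongs to (its bins,
#'   angles and angular range go into the header).
#' @return `write_*` return `path` invisibly; `read_raw_image` returns a
#'   matrix; `read_raw_sinogram` returns a list with `values` and the
#'   header fields.
#' @name ringrec-io
NULL

#' @rdname ringrec-io
#' @export
write_raw_image <- function(image, path) {
  stopifnot(is.matrix(image))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(image), con, size = 4, endian = "little")
  writeLines(c(sprintf("width %d", nrow(image)),
               sprintf("height %d", ncol(image))),
             paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname ringrec-io
#' @export
read_raw_image <- function(path) {
  hdr <- read_header(paste0(path, ".hdr"))
  w <- as.integer(hdr[["width"]]); h <- as.integer(hdr[["height"]])
  con <- file(path, "rb")
  on.exit(close(con))
  matrix(readBin(con, "numeric", w * h, size = 4, endian = "little"), w, h)
}

#' @rdname ringrec-io
#' @export
write_raw_sinogram <- function(sinogram, path, geometry) {
  check_sinogram(sinogram, geometry)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(sinogram), con, size = 4, endian = "little")
  writeLines(c(sprintf("bins %d", geometry$n_bins),
               sprintf("angles %d", geometry$n_angles),
               sprintf("angular_range %g", geometry$angular_range)),
             paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname ringrec-io
#' @export
read_raw_sinogram <- function(path) {
  hdr <- read_header(paste0(path, ".hdr"))
  R <- as.integer(hdr[["bins"]]); Th <- as.integer(hdr[["angles"]])
  con <- file(path, "rb")
  on.exit(close(con))
  list(values = matrix(readBin(con, "numeric", R * Th, size = 4,
                               endian = "little"), R, Th),
       bins = R, angles = Th,
       angular_range = as.numeric(hdr[["angular_range"]]))
}

read_header <- function(path) {
  if (!file.exists(path)) stop("missing header file: ", path)
  lines <- readLines(path)
  parts <- strsplit(trimws(lines[nzchar(trimws(lines))]), "[[:space:]]+")
  stats::setNames(lapply(parts, function(p) paste(p[-1], collapse = " ")),
                  vapply(parts, `[[`, "", 1))
}

#' @rdname ringrec-io
#' @param normalize rescale to `[0, 1]` before writing (the 32-bit float
#'   TIFF writer only defines values in that range); with
#'   `normalize = FALSE` the values must already lie in `[0, 1]` and then
#'   round-trip exactly at float32 precision. Use the raw format for
#'   arbitrary-range data.
#' @export
write_image_tiff <- function(image, path, normalize = TRUE) {
  stopifnot(is.matrix(image))
  if (normalize) {
    rg <- range(image)
    image <- if (diff(rg) > 0) (image - rg[1]) / diff(rg) else image * 0
  } else if (min(image) < 0 || max(image) > 1)
    stop("values outside [0, 1]; use normalize = TRUE or the raw format")
  # t() so that the first matrix index (x) runs along the TIFF row direction
  tiff::writeTIFF(t(image), path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname ringrec-io
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  t(m)
}

#' Flat key-value configuration files
#'
#' The run configuration is a flat `key value` (or `key = value`) text
#' format, one setting per line, `#` comments allowed. Values are parsed
#' to numeric or logical where possible. Command-line flags override file
#' values.
#'
#' @param path file path.
#' @param config named list to write.
#' @return `read_config` returns a named list.
#' @name ringrec-config
NULL

#' @rdname ringrec-config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("=", " ", ln, fixed = TRUE), "[[:space:]]+")[[1]]
    key <- kv[1]
    val <- paste(kv[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  out
}

#' @rdname ringrec-config
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15),
                            character(1))),
             path)
  invisible(path)
}
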