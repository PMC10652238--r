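# Minimal baseline-TIFF writer for grayscale IEEE float32 pages
# (little-endian, one strip per page, IFD chain for multi-page). Written by
# hand because the installed TIFF writer only stores integer samples;
# reading goes through tiff::readTIFF, which independently validates the
# container.
#' @noRd
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  npix <- vapply(pages, length, integer(1))
  data_off <- integer(length(pages)); ifd_off <- integer(length(pages))
  pos <- 8L
  for (i in seq_along(pages)) {
    data_off[i] <- pos; pos <- pos + 4L * npix[i]
    ifd_off[i] <- pos; pos <- pos + 2L + 10L * 12L + 4L   # 10 tags per IFD
  }
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    writeBin(as.vector(t(m)), con, size = 4, endian = "little")  # row-major
    writeBin(10L, con, size = 2, endian = "little")
    tag(256, 3, 1, ncol(m))          # ImageWidth
    tag(257, 3, 1, nrow(m))          # ImageLength
    tag(258, 3, 1, 32)               # BitsPerSample
    tag(259, 3, 1, 1)                # Compression: none
    tag(262, 3, 1, 1)                # Photometric: BlackIsZero
    tag(273, 4, 1, data_off[i])      # StripOffsets
    tag(277, 3, 1, 1)                # SamplesPerPixel
    tag(278, 3, 1, nrow(m))          # RowsPerStrip
    tag(279, 4, 1, 4L * npix[i])     # StripByteCounts
    tag(339, 3, 1, 3)                # SampleFormat: IEEE float
    writeBin(if (i < length(pages)) ifd_off[i + 1] else 0L,
             con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a hyper-stack as multi-page float TIFF with JSON sidecar
#'
#' Pages are ordered by ascending gate time and stored as 32-bit IEEE float
#' samples, so write/read round-trips reproduce the frames bit-exactly at
#' 32-bit float precision. The sidecar `<path>.json` carries
#' `gate_times_s`, `gate_width_s`, `pixel_size_m`, `seed` and an ISO-8601
#' timestamp.
#'
#' @param stack A [hyper_stack()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @param seed Integer seed recorded in provenance.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, seed = stack$metadata$seed %||% NA_integer_) {
  stopifnot(inherits(stack, "hyper_stack"))
  pages <- lapply(seq_along(stack$gate_times), function(i) stack$frames[, , i])
  write_float_tiff(pages, path)
  meta <- list(gate_times_s = stack$gate_times,
               gate_width_s = stack$gate_width,
               pixel_size_m = stack$pixel_size,
               seed = seed,
               created = utc_stamp())
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @noRd
sidecar_path <- function(path) paste0(path, ".json")

#' Read a hyper-stack written by [write_stack()]
#'
#' Validates that the TIFF page count matches the sidecar's gate-time list
#' and that gate times are strictly increasing.
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A [hyper_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_bad(sprintf("no such stack file: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop_bad(sprintf("missing sidecar metadata: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("gate_times_s", "gate_width_s", "pixel_size_m"))
    if (is.null(meta[[key]])) stop_bad(sprintf("sidecar lacks required key '%s'", key))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  gt <- as.numeric(meta$gate_times_s)
  if (length(pages) != length(gt))
    stop_bad(sprintf("TIFF has %d pages but sidecar lists %d gate times",
                     length(pages), length(gt)))
  if (length(gt) > 1L && any(diff(gt) <= 0))
    stop_bad("sidecar gate times are not strictly increasing")
  frames <- array(NA_real_, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  hyper_stack(frames, gt, meta$pixel_size_m, meta$gate_width_s,
              metadata = list(seed = meta$seed, created = meta$created,
                              source = path))
}

# CSV numbers use %.17g: the shortest decimal representation that
# round-trips IEEE doubles exactly, keeping outputs byte-deterministic.
#' @noRd
fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a single-pixel time trace as CSV
#'
#' Plain CSV with header `time_s,value_mV`.
#'
#' @param trace A [time_trace()].
#' @param path CSV path.
#' @return `write_trace`: `path` invisibly; `read_trace`: a [time_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "time_trace"))
  lines <- c("time_s,value_mV",
             paste(fmt_num(trace$times), fmt_num(trace$values), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_bad(sprintf("no such trace file: %s", path))
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value_mV") %in% names(d)))
    stop_bad("trace CSV must have header time_s,value_mV")
  time_trace(d$time_s, d$value_mV, metadata = list(source = path))
}

#' Export a per-pixel map (CV or tau) as CSV
#'
#' Long-format table `x_px,y_px,value,valid`.
#'
#' @param map A `cv_image`, `tau_map` or plain matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  if (inherits(map, "cv_image")) { v <- map$values; ok <- map$mask }
  else if (inherits(map, "tau_map")) { v <- map$tau; ok <- map$valid }
  else { v <- map; ok <- is.finite(map) }
  idx <- expand.grid(y_px = seq_len(nrow(v)), x_px = seq_len(ncol(v)))
  lines <- c("x_px,y_px,value,valid",
             paste(idx$x_px, idx$y_px,
                   ifelse(ok[cbind(idx$y_px, idx$x_px)],
                          fmt_num(v[cbind(idx$y_px, idx$x_px)]), "NA"),
                   ifelse(ok[cbind(idx$y_px, idx$x_px)], "TRUE", "FALSE"),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a linescan as CSV (`position_m,value_mV`)
#'
#' @param scan A [linescan()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_linescan <- function(scan, path) {
  stopifnot(inherits(scan, "linescan"))
  writeLines(c("position_m,value_mV",
               paste(fmt_num(scan$positions), fmt_num(scan$values), sep = ",")),
             path)
  invisible(path)
}

#' @rdname write_linescan
#' @export
read_linescan <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("position_m", "value_mV") %in% names(d)))
    stop_bad("linescan CSV must have header position_m,value_mV")
  linescan(d$position_m, d$value_mV)
}
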