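#' Write a cine sequence as multi-frame grayscale TIFF with a JSON sidecar
#'
#' Frames are stored as 8-bit grayscale, uncompressed, little-endian
#' baseline TIFF, one IFD per frame. TIFF has no standard tags for pixel
#' pitch in mm or frame timestamps, so those go to `<path>.json`.
#'
#' @param cine A `cine_sequence`.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cine <- function(cine, path) {
  frames <- lapply(cine$frames, function(f) {
    f <- round(pmin(pmax(f, 0), 255))
    storage.mode(f) <- "integer"
    f
  })
  .write_tiff_gray8(frames, path)
  sidecar <- list(pixel_pitch_mm = cine$pixel_pitch,
                  frame_rate_hz = cine$frame_rate,
                  frame_times_s = cine$times)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame grayscale TIFF cine with its JSON sidecar
#'
#' Supports uncompressed 8- and 16-bit grayscale baseline TIFF
#' (little-endian). RGB input is averaged to grayscale with a warning.
#' Pixel pitch and frame times come from the sidecar `<path>.json`;
#' a missing sidecar or missing `pixel_pitch_mm` is an error.
#'
#' @param path TIFF path.
#' @param sidecar Optional explicit sidecar path.
#' @return A `cine_sequence`.
#' @export
read_cine <- function(path, sidecar = paste0(path, ".json")) {
  frames <- .read_tiff_gray(path)
  if (!file.exists(sidecar)) {
    stop("read_cine: sidecar JSON not found (need pixel_pitch_mm): ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("pixel_pitch_mm", "frame_rate_hz")) {
    if (is.null(meta[[field]])) {
      stop("read_cine: sidecar is missing field '", field, "'")
    }
  }
  times <- if (!is.null(meta$frame_times_s)) as.numeric(meta$frame_times_s)
           else (seq_along(frames) - 1) / meta$frame_rate_hz
  structure(list(frames = frames, times = times,
                 pixel_pitch = meta$pixel_pitch_mm,
                 frame_rate = meta$frame_rate_hz),
            class = "cine_sequence")
}

# --- minimal baseline TIFF codec (II byte order, uncompressed) ---------

.tiff_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

.write_tiff_gray8 <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  n <- length(frames)
  sizes <- vapply(frames, length, integer(1))
  # layout: header(8) | frame data blocks | IFD chain
  data_off <- 8L + cumsum(c(0L, sizes[-n]))
  ifd_size <- 2L + 9L * 12L + 4L
  ifd0 <- 8L + sum(sizes)
  writeBin(ifd0, con, size = 4, endian = "little")
  for (f in frames) {
    writeBin(as.raw(as.vector(t(f))), con)
  }
  for (k in seq_len(n)) {
    h <- nrow(frames[[k]]); w <- ncol(frames[[k]])
    writeBin(9L, con, size = 2, endian = "little")
    .tiff_entry(con, 256, 3, 1, w)             # ImageWidth
    .tiff_entry(con, 257, 3, 1, h)             # ImageLength
    .tiff_entry(con, 258, 3, 1, 8)             # BitsPerSample
    .tiff_entry(con, 259, 3, 1, 1)             # Compression: none
    .tiff_entry(con, 262, 3, 1, 1)             # Photometric: BlackIsZero
    .tiff_entry(con, 273, 4, 1, data_off[k])   # StripOffsets
    .tiff_entry(con, 277, 3, 1, 1)             # SamplesPerPixel
    .tiff_entry(con, 278, 3, 1, h)             # RowsPerStrip
    .tiff_entry(con, 279, 4, 1, sizes[k])      # StripByteCounts
    nxt <- if (k < n) ifd0 + k * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(o) as.integer(raw[o + 1]) + 256L * as.integer(raw[o + 2])
  u32 <- function(o) {
    as.integer(raw[o + 1]) + 256 * as.integer(raw[o + 2]) +
      65536 * as.integer(raw[o + 3]) + 16777216 * as.integer(raw[o + 4])
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L) {
    stop("read_cine: not a little-endian TIFF")
  }
  ifd <- u32(4)
  frames <- list()
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_entries)) {
      o <- ifd + 2 + (e - 1) * 12
      tag <- u16(o); type <- u16(o + 2); count <- u32(o + 4)
      val <- if (type == 3L && count == 1L) u16(o + 8) else u32(o + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, off = o + 8)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stop("read_cine: TIFF tag ", tag, " missing")
        return(default)
      }
      t$value
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 8L)
    if (need(259, 1L) != 1L) stop("read_cine: compressed TIFF unsupported")
    spp <- need(277, 1L)
    if (!bits %in% c(8L, 16L)) {
      stop("read_cine: unsupported bit depth ", bits)
    }
    # gather strip offsets/counts (value slot holds the offset when the
    # array does not fit in 4 bytes)
    read_arr <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (t$count == 1L) return(t$value)
      base <- t$value
      if (t$type == 3L) vapply(seq_len(t$count) - 1L,
                               function(i) u16(base + 2 * i), integer(1))
      else vapply(seq_len(t$count) - 1L,
                  function(i) u32(base + 4 * i), numeric(1))
    }
    offs <- read_arr(273)
    cnts <- read_arr(279)
    bytes <- raw[unlist(mapply(function(o, n) (o + 1):(o + n), offs, cnts,
                               SIMPLIFY = FALSE))]
    px <- if (bits == 8L) as.integer(bytes)
          else readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                       signed = FALSE, endian = "little")
    if (spp > 1L) {
      warning("read_cine: multi-sample TIFF averaged to grayscale")
      px <- rowMeans(matrix(px, ncol = spp, byrow = TRUE))
    }
    frames[[length(frames) + 1L]] <- matrix(px, nrow = h, ncol = w,
                                            byrow = TRUE)
    ifd <- u32(ifd + 2 + n_entries * 12)
  }
  if (!length(frames)) stop("read_cine: no frames found")
  frames
}

#' Read a force trace CSV
#'
#' Expects the header `t_s,force_N,pitch_deg,yaw_deg`; the orientation
#' columns are optional metadata (carried through, never used to correct
#' force). Time must be strictly increasing; rows with missing time or
#' force are rejected with their row numbers.
#'
#' @param path CSV path.
#' @return A data.frame of class `force_trace`; attribute `yaw_absent`
#'   when the yaw column is missing.
#' @export
read_force_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_s", "force_N") %in% names(d))) {
    stop("read_force_csv: need columns t_s and force_N")
  }
  bad <- which(!is.finite(d$t_s) | !is.finite(d$force_N))
  if (length(bad)) {
    stop("read_force_csv: non-finite time/force in rows ",
         paste(bad, collapse = ", "))
  }
  nd <- which(diff(d$t_s) <= 0)
  if (length(nd)) {
    stop("read_force_csv: time not strictly increasing at row ", nd[1] + 1)
  }
  yaw_absent <- !"yaw_deg" %in% names(d)
  if (yaw_absent) d$yaw_deg <- NA_real_
  if (!"pitch_deg" %in% names(d)) d$pitch_deg <- NA_real_
  attr(d, "yaw_absent") <- yaw_absent
  class(d) <- c("force_trace", "data.frame")
  d
}

#' Write a force trace CSV
#' @param trace Data.frame with `t_s, force_N, pitch_deg, yaw_deg`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t_s", "force_N", "pitch_deg", "yaw_deg")],
                   path, row.names = FALSE)
  invisible(path)
}
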