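# Frame directory I/O.
#
# Sequences are exchanged as directories of lexicographically ordered
# grayscale PNG or TIFF frames (8-bit on write).  RGB frames are collapsed
# to luminance with the standard luma weights 0.299 R + 0.587 G + 0.114 B.

.luma <- c(0.299, 0.587, 0.114)

.read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    w <- if (nch >= 3) .luma else rep(1 / nch, nch)
    img <- Reduce(`+`, lapply(seq_len(min(nch, 3L)),
                              function(k) w[k] * img[, , k]))
  }
  img
}

#' Load a frame directory as a luminance sequence
#'
#' Reads all PNG/TIFF files in `path` in lexicographic order.
#'
#' @param path Directory of grayscale (or RGB) frames.
#' @param frame_interval Frame interval in seconds (metadata).
#' @return A [luminance_sequence()].
#' @export
load_frames <- function(path, frame_interval = 1 / 30) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no PNG/TIFF frames found in ", path, call. = FALSE)
  }
  imgs <- lapply(files, .read_frame)
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) identical(dim(m), d1), logical(1)))) {
    stop("frames have mixed sizes", call. = FALSE)
  }
  frames <- array(unlist(imgs), dim = c(d1[1], d1[2], length(imgs)))
  luminance_sequence(pmin(pmax(frames, 0), 1), frame_interval)
}

#' Save a luminance sequence as a frame directory
#'
#' Writes zero-padded `frame_0001.png` (or `.tiff`) files; 8-bit grayscale,
#' so a round trip through [load_frames()] reproduces each pixel within
#' 1/255.
#'
#' @param seq A [luminance_sequence()].
#' @param path Output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @param prefix Filename prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
save_frames <- function(seq, path, format = c("png", "tiff"),
                        prefix = "frame_") {
  stopifnot(inherits(seq, "luminance_sequence"))
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Tn <- dim(seq$frames)[3]
  files <- file.path(path, sprintf("%s%04d.%s", prefix, seq_len(Tn), format))
  for (t in seq_len(Tn)) {
    fr <- seq$frames[, , t]
    if (format == "png") {
      png::writePNG(fr, files[t])
    } else {
      tiff::writeTIFF(fr, files[t], bits.per.sample = 8L)
    }
  }
  invisible(files)
}
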