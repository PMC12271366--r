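## Stack containers and TIFF input/output.
##
## Acquisition stores each region of interest as a two-channel, 16-bit,
## multi-page TIFF: pages are interleaved SHG, TPEF, SHG, TPEF, ... in
## depth order.

#' Construct a two-channel image stack
#'
#' @param frames list of frames, each a list with integer matrices `shg`
#'   and `tpef` of a common shape.
#' @param bit_depth integer bit depth of the pixel data (8 or 16).
#' @param pixel_size_um pixel pitch in micrometers.
#' @param provenance free-text provenance note.
#' @return object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(frames, bit_depth = 16L,
                              pixel_size_um = 508 / 512,
                              provenance = "") {
  if (length(frames) == 0) stop2("a stack needs at least one frame")
  dims <- lapply(frames, function(f) c(dim(f$shg), dim(f$tpef)))
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
    stop2("all frames and channels must share the same shape")
  structure(list(frames = frames, bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um, provenance = provenance),
            class = "two_channel_stack")
}

#' @export
length.two_channel_stack <- function(x) length(x$frames)

#' Write a two-channel stack as a multi-page TIFF
#'
#' Pages are interleaved channel-first within each frame, in the order
#' given by `channel_order` (default SHG then TPEF).
#'
#' @param stack a [two_channel_stack()].
#' @param path output path.
#' @param channel_order character vector, page order within a frame.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, channel_order = c("SHG", "TPEF")) {
  maxval <- 2^stack$bit_depth - 1
  pages <- list()
  for (f in stack$frames) {
    for (ch in channel_order) {
      m <- if (ch == "SHG") f$shg else f$tpef
      pages[[length(pages) + 1L]] <- m / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read a two-channel multi-page TIFF stack
#'
#' The page layout (channel order within a frame) and pixel size are
#' resolved from the arguments: the plain-TIFF container carries no
#' reliable channel annotation, so acquisition conventions travel with
#' the configuration, not the file.
#'
#' @param path TIFF file path.
#' @param channel_order page order within a frame.
#' @param pixel_size_um pixel pitch.
#' @return a [two_channel_stack()].
#' @export
read_stack <- function(path, channel_order = c("SHG", "TPEF"),
                       pixel_size_um = 508 / 512) {
  if (!file.exists(path)) stop2("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2, TRUE)))
    stop2("unsupported layout: expected single-channel grayscale pages ",
          "(multi-sample pages found)")
  info <- attributes(pages[[1]])
  bit_depth <- as.integer(info$bits.per.sample %||% 16L)
  if (length(pages) %% 2 != 0)
    stop2("format error: odd page count for an interleaved 2-channel stack")
  if (any(vapply(pages, function(p) any(p != floor(p)), TRUE)))
    stop2("format error: non-integer pixel data")
  n_frames <- length(pages) / 2
  si <- which(channel_order == "SHG")
  ti <- which(channel_order == "TPEF")
  frames <- lapply(seq_len(n_frames), function(i) {
    list(shg = pages[[2 * (i - 1) + si]], tpef = pages[[2 * (i - 1) + ti]])
  })
  two_channel_stack(frames, bit_depth, pixel_size_um,
                    provenance = paste0("read from ", path))
}

#' Rescale a single-channel stack to a target bit depth
#'
#' Linear rescaling between the minimum and maximum of the entire stack
#' (not per frame): `out = round((in - min) / (max - min) * (2^bits - 1))`
#' with rounding half away from zero.  A constant stack maps to all zeros.
#'
#' @param frames list of numeric matrices (one channel).
#' @param target_bits 8 or 16.
#' @return list of integer-valued matrices in `[0, 2^target_bits - 1]`.
#' @export
rescale_stack <- function(frames, target_bits = 8L) {
  if (!target_bits %in% c(8L, 16L)) stop2("target_bits must be 8 or 16")
  if (length(frames) == 0) stop2("empty stack")
  lo <- min(vapply(frames, min, 0))
  hi <- max(vapply(frames, max, 0))
  maxval <- 2^target_bits - 1
  if (hi == lo) return(lapply(frames, function(m) m * 0))
  lapply(frames, function(m) round_half_away((m - lo) / (hi - lo) * maxval))
}
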