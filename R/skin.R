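#' RGB + hue skin-pixel rule
#'
#' Thresholds for the conjunctive skin classifier: a pixel is skin iff
#' `R > r_min & G > g_min & B > b_min & max(R,G,B) - min(R,G,B) >
#' chroma_spread_min & R > G & R > B & h_min <= H <= h_max`, with H the
#' hexcone hue of the RGB->HSV transform in degrees.  Intensity tests are
#' strict inequalities; the hue test is inclusive.
#'
#' @param r_min,g_min,b_min minimum channel intensities (8-bit units).
#' @param chroma_spread_min minimum max-min channel spread (8-bit units).
#' @param h_min,h_max hue range in degrees, within [0, 360).
#' @return a `skin_rule` list.
#' @export
skin_rule <- function(r_min = 95, g_min = 40, b_min = 20,
                      chroma_spread_min = 15, h_min = 0, h_max = 60) {
  for (nm in c("r_min", "g_min", "b_min", "chroma_spread_min",
               "h_min", "h_max"))
    check_scalar(get(nm), nm)
  stop_if(h_min < 0 || h_max >= 360 || h_min > h_max,
          "hue range must satisfy 0 <= h_min <= h_max < 360")
  structure(list(r_min = r_min, g_min = g_min, b_min = b_min,
                 chroma_spread_min = chroma_spread_min,
                 h_min = h_min, h_max = h_max),
            class = "skin_rule")
}

# Hexcone hue in degrees [0, 360); 0 where the chroma is zero (the rule's
# spread test already rejects such pixels, so the convention is inert).
rgb_hue <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  c <- mx - mn
  h <- numeric(length(r))
  i <- c > 0 & mx == r
  h[i] <- 60 * ((g[i] - b[i]) / c[i])
  i <- c > 0 & mx == g & mx != r
  h[i] <- 60 * (2 + (b[i] - r[i]) / c[i])
  i <- c > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * (4 + (r[i] - g[i]) / c[i])
  (h + 360) %% 360
}

#' Classify skin pixels in a frame
#'
#' Applies the conjunctive RGB + hue rule per pixel.  The input is an
#' 8-bit-scale `height x width x 3` array (values 0-255; arrays read with
#' \pkg{png} on the 0-1 scale are accepted and rescaled).
#'
#' @param frame numeric array `h x w x 3`.
#' @param rule a [skin_rule()].
#' @return logical `h x w` matrix; `TRUE` marks skin pixels.
#' @export
skin_mask <- function(frame, rule = skin_rule()) {
  stop_if(!is.array(frame) || length(dim(frame)) != 3 || dim(frame)[3] != 3,
          "'frame' must be a h x w x 3 array")
  stopifnot(inherits(rule, "skin_rule"))
  if (max(frame) <= 1) frame <- frame * 255
  nr <- dim(frame)[1]; nc <- dim(frame)[2]
  r <- matrix(frame[, , 1], nr, nc)
  g <- matrix(frame[, , 2], nr, nc)
  b <- matrix(frame[, , 3], nr, nc)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  h <- matrix(rgb_hue(as.vector(r), as.vector(g), as.vector(b)), nr, nc)
  r > rule$r_min & g > rule$g_min & b > rule$b_min &
    (mx - mn) > rule$chroma_spread_min &
    r > g & r > b &
    h >= rule$h_min & h <= rule$h_max
}

#' Reduce frames to a per-frame averaged channel trace
#'
#' Spatially averages the chosen channel over the mask-true pixels of every
#' frame.  A frame whose mask is empty reuses the previous frame's value
#' (adjacent-frame fallback); an empty mask on the first frame is an error.
#'
#' @param frames list of `h x w x 3` arrays (0-255 scale).
#' @param masks list of logical matrices aligned with `frames`; when NULL,
#'   [skin_mask()] with default thresholds is applied per frame.
#' @param channel one of "G", "R", "B".
#' @param fps frames per second of the video.
#' @param t0 time of the first frame, seconds.
#' @return a [color_trace()].
#' @export
trace_from_frames <- function(frames, masks = NULL, channel = c("G", "R", "B"),
                              fps = 30, t0 = 0) {
  channel <- match.arg(channel)
  stop_if(!is.list(frames) || length(frames) < 2,
          "'frames' must be a list of at least 2 frames")
  if (is.null(masks)) masks <- lapply(frames, skin_mask)
  stop_if(length(masks) != length(frames),
          "'masks' must align with 'frames'")
  ch <- match(channel, c("R", "G", "B"))
  vals <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    stop_if(!is.array(f) || length(dim(f)) != 3 || dim(f)[3] != 3,
            sprintf("frame %d is not a h x w x 3 array", i))
    if (max(f) <= 1) f <- f * 255
    m <- masks[[i]]
    stop_if(!identical(dim(m), dim(f)[1:2]),
            sprintf("mask %d does not match frame %d", i, i))
    if (!any(m)) {
      stop_if(i == 1L, "empty skin mask on frame 1 (no fallback available)")
      vals[i] <- vals[i - 1]
    } else {
      plane <- f[, , ch]
      vals[i] <- mean(plane[m])
    }
  }
  color_trace(vals, fps = fps, t0 = t0, channel = channel)
}

#' Read an image file as a 0-255 RGB array
#'
#' Thin wrapper over \pkg{png} for loading pre-cropped face frames.
#'
#' @param path PNG file path.
#' @return numeric `h x w x 3` array on the 0-255 scale.
#' @export
read_frame_png <- function(path) {
  stop_if(!requireNamespace("png", quietly = TRUE),
          "package 'png' is required to read PNG frames")
  img <- png::readPNG(path)
  stop_if(length(dim(img)) != 3, "PNG must have color channels")
  img[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_frame_png
#' @param frame numeric `h x w x 3` array on the 0-255 scale.
#' @export
write_frame_png <- function(frame, path) {
  stop_if(!requireNamespace("png", quietly = TRUE),
          "package 'png' is required to write PNG frames")
  stop_if(!is.array(frame) || length(dim(frame)) != 3,
          "'frame' must be a h x w x 3 array")
  png::writePNG(frame / 255, path)
  invisible(path)
}
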