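#' Render diffraction-limited spot movies
#'
#' [render_frames()] draws each spot as a 2-D Gaussian of peak amplitude
#' `amplitude` (photons) and width `sigma` (px) on a uniform Poisson
#' background; pixel values are Poisson draws of the noiseless model, so the
#' noise sd on a blank region is `sqrt(background)`.  Pixel coordinates are
#' continuous with the origin at the center of pixel (0,0).
#'
#' [render_movie()] renders one intensity channel of a positions-bearing
#' trace set (see [simulate_traces()] with `positions = TRUE`), using
#' `amplitude = gain * signal`, and returns the stack together with the
#' ground-truth spot table.
#'
#' @param spots Data frame with columns `frame` (0-based), `x`, `y`,
#'   `amplitude`.
#' @param n_frames Number of frames to render.
#' @param field_px Image side, px.
#' @param sigma PSF sd, px.
#' @param background Photon background per pixel.
#' @param seed Integer seed (required; set `NA` to render noiselessly).
#' @return For [render_frames()]: numeric array `field_px x field_px x
#'   n_frames` (photons); `img[i, j, f]` is pixel x = i-1, y = j-1.
#' @examples
#' st <- data.frame(frame = 0, x = 10, y = 12, amplitude = 100)
#' img <- render_frames(st, n_frames = 1, field_px = 32, sigma = 1.3,
#'                      background = 10, seed = 1)
#' @export
render_frames <- function(spots, n_frames, field_px = 128L, sigma = 1.3,
                          background = 10, seed = NULL) {
  if (sigma <= 0) stop("optics error: sigma must be > 0")
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  noiseless <- is.null(seed) || is.na(seed)
  stack <- array(0, dim = c(field_px, field_px, n_frames))
  n_clip <- 0L
  w <- ceiling(5 * sigma)
  for (f in seq_len(n_frames)) {
    img <- matrix(background, field_px, field_px)
    sf <- spots[spots$frame == f - 1L, , drop = FALSE]
    for (k in seq_len(nrow(sf))) {
      x <- sf$x[k]; y <- sf$y[k]; a <- sf$amplitude[k]
      if (a <= 0) next
      if (x < 0 || y < 0 || x > field_px - 1 || y > field_px - 1) n_clip <- n_clip + 1L
      ix <- max(0L, floor(x) - w):min(field_px - 1L, ceiling(x) + w)
      iy <- max(0L, floor(y) - w):min(field_px - 1L, ceiling(y) + w)
      if (!length(ix) || !length(iy)) next
      gx <- exp(-(ix - x)^2 / (2 * sigma^2))
      gy <- exp(-(iy - y)^2 / (2 * sigma^2))
      img[ix + 1L, iy + 1L] <- img[ix + 1L, iy + 1L] + a * outer(gx, gy)
    }
    if (!noiseless) img[] <- rpois(length(img), img)
    stack[, , f] <- img
  }
  if (n_clip > 0) warning(n_clip, " spot(s) outside the field were clipped")
  stack
}

#' @rdname render_frames
#' @param traces Trace data frame with `frame`, `x_px`, `y_px` and the chosen
#'   signal column (e.g. the `traces` element of a [simulate_traces()] run
#'   with `positions = TRUE`).
#' @param channel Name of the signal column to render.
#' @param gain Photons per intensity unit.
#' @return For [render_movie()]: list with `stack` (the rendered array) and
#'   `spots` (ground-truth per-frame positions and amplitudes).
#' @export
render_movie <- function(traces, channel = "ch1_signal", gain = 1,
                         sigma = 1.3, background = 10,
                         field_px = 128L, seed = NULL) {
  if (inherits(traces, "ribotrace_sim")) traces <- traces$traces
  need <- c("frame", "x_px", "y_px", channel)
  miss <- setdiff(need, names(traces))
  if (length(miss)) stop("traces lack column(s): ", paste(miss, collapse = ", "))
  spots <- data.frame(frame = traces$frame,
                      x = traces$x_px, y = traces$y_px,
                      amplitude = gain * pmax(traces[[channel]], 0),
                      cell_id = traces$cell_id, rna_id = traces$rna_id)
  n_frames <- max(traces$frame) + 1L
  stack <- render_frames(spots, n_frames, field_px = field_px, sigma = sigma,
                         background = background, seed = seed)
  list(stack = stack, spots = spots)
}

#' Write a rendered stack as multi-page 16-bit TIFF
#'
#' @param stack Array from [render_frames()].
#' @param path Output file.
#' @param scale Multiplier applied before rounding to 16-bit counts.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF movies")
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(t(stack[, , f]) * scale, 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
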