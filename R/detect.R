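# Spot detection and sub-pixel localization.
#
# detect_spots() runs a band-pass (difference of Gaussians), picks local
# maxima above snr_threshold * robust noise, and refines each candidate by
# least-squares 2-D Gaussian fitting in an 11x11 window, returning sub-pixel
# centers, amplitude, sigma and local background.  Coordinates follow the
# rendering convention: origin at the center of pixel (0,0).

gauss_blur <- function(img, sigma) {
  k <- ceiling(3 * sigma)
  kern <- dnorm(-k:k, sd = sigma)
  kern <- kern / sum(kern)
  n <- nrow(img); m <- ncol(img)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (d in -k:k) {
      idx <- seq_len(n - abs(d))
      K[cbind(idx + max(0, d), idx + max(0, -d))] <- kern[d + k + 1]
    }
    # renormalize at edges so a flat image stays flat
    K / rowSums(K)
  }
  band(n) %*% img %*% t(band(m))
}

#' Detect diffraction-limited spots in one frame
#'
#' @param img Numeric matrix; `img[i, j]` is pixel x = i-1, y = j-1.
#' @param expected_sigma Expected PSF sd, px (in `[0.5, 5]`).
#' @param snr_threshold Local-maximum threshold in units of the robust noise
#'   sd of the band-passed image.
#' @param win Half-width of the fit window (5 gives the 11x11 box used for
#'   intensity integration).
#' @return Data frame with columns `x`, `y`, `amplitude`, `sigma`,
#'   `background` (one row per accepted spot).
#' @examples
#' st <- data.frame(frame = 0, x = 15.3, y = 11.7, amplitude = 200)
#' img <- render_frames(st, 1, field_px = 32, sigma = 1.3,
#'                      background = 10, seed = 1)[, , 1]
#' detect_spots(img, expected_sigma = 1.3)
#' @export
detect_spots <- function(img, expected_sigma = 1.3, snr_threshold = 5, win = 5L) {
  if (!is.matrix(img)) stop("shape error: detect_spots expects a single 2-D frame")
  if (expected_sigma < 0.5 || expected_sigma > 5)
    stop("expected_sigma must be in [0.5, 5] px")
  bp <- gauss_blur(img, expected_sigma) - gauss_blur(img, 3 * expected_sigma)
  noise <- mad(bp)
  if (noise <= 0) noise <- sd(bp) + 1e-12
  thr <- snr_threshold * noise
  n <- nrow(img); m <- ncol(img)
  empty <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      sigma = numeric(0), background = numeric(0))
  # local maxima over the 8-neighborhood, away from the border
  cand <- which(bp > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > win & cand[, 1] <= n - win &
               cand[, 2] > win & cand[, 2] <= m - win, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    bp[i, j] >= max(bp[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  fits <- lapply(seq_len(nrow(cand)), function(k) {
    fit_gaussian_2d(img, cand[k, 1] - 1L, cand[k, 2] - 1L, expected_sigma, win)
  })
  fits <- do.call(rbind, fits)
  fits <- fits[is.finite(fits$x) & fits$amplitude > 0 &
               fits$sigma > expected_sigma / 2 & fits$sigma < expected_sigma * 2, ,
               drop = FALSE]
  # deduplicate fits converging to the same center
  if (nrow(fits) > 1) {
    ord <- order(-fits$amplitude)
    fits <- fits[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(fits))
    for (k in seq_len(nrow(fits))[-1]) {
      d2 <- (fits$x[seq_len(k - 1)] - fits$x[k])^2 + (fits$y[seq_len(k - 1)] - fits$y[k])^2
      if (any(keep[seq_len(k - 1)] & d2 < expected_sigma^2)) keep[k] <- FALSE
    }
    fits <- fits[keep, , drop = FALSE]
  }
  rownames(fits) <- NULL
  fits
}

# least-squares Gaussian refinement around pixel (cx, cy) (0-based)
fit_gaussian_2d <- function(img, cx, cy, sigma0, win = 5L) {
  ix <- (cx - win):(cx + win)
  iy <- (cy - win):(cy + win)
  z <- img[ix + 1L, iy + 1L]
  bg0 <- min(z)
  a0 <- max(z) - bg0
  obj <- function(p) {
    gx <- exp(-(ix - p[1])^2 / (2 * exp(2 * p[4])))
    gy <- exp(-(iy - p[2])^2 / (2 * exp(2 * p[4])))
    sum((z - (p[5] + p[3] * outer(gx, gy)))^2)
  }
  p0 <- c(cx, cy, a0, log(sigma0), bg0)
  pscale <- c(1, 1, max(abs(a0), 1), 0.2, max(abs(bg0), 1))
  fit <- tryCatch(
    optim(p0, obj, method = "BFGS",
          control = list(maxit = 300, reltol = 1e-10, parscale = pscale)),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par)))
    fit <- tryCatch(
      optim(p0, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10, parscale = pscale)),
      error = function(e) NULL)
  bad <- data.frame(x = NA_real_, y = NA_real_, amplitude = NA_real_,
                    sigma = NA_real_, background = NA_real_)
  if (is.null(fit)) return(bad)
  p <- fit$par
  if (abs(p[1] - cx) > win || abs(p[2] - cy) > win) return(bad)
  data.frame(x = p[1], y = p[2], amplitude = p[3],
             sigma = exp(p[4]), background = p[5])
}

#' Detect spots in every frame of a stack
#'
#' @param stack Array from [render_frames()].
#' @inheritParams detect_spots
#' @return Data frame of spots with a 0-based `frame` column.
#' @export
detect_spots_stack <- function(stack, expected_sigma = 1.3, snr_threshold = 5,
                               win = 5L) {
  out <- lapply(seq_len(dim(stack)[3]), function(f) {
    s <- detect_spots(stack[, , f], expected_sigma, snr_threshold, win)
    if (nrow(s)) s$frame <- f - 1L
    s
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      sigma = numeric(0), background = numeric(0),
                      frame = integer(0)))
  do.call(rbind, out)
}
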