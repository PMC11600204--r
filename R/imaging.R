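# Synthetic microscope frames of the sensing-probe tip and recovery of the
# integer-pixel deflection by Harris corner detection. This closes the loop
# between image space and the per-pixel force calibration: the readout the
# bench quantizes is exactly the displacement this stage would report.

#' Synthetic frame specification
#'
#' @param width,height Frame size (px).
#' @param probe_width_px Rendered probe thickness (px).
#' @param probe_intensity Silhouette gray level (0--255; darker than
#'   background).
#' @param background Background gray level.
#' @param noise_sd Additive Gaussian noise SD (gray levels).
#' @param pixel_size Object-plane pixel size (m/px); must match the probe
#'   spec used for force conversion.
#' @param tip_col Reference tip column at zero deflection (defaults to 40%
#'   of width).
#' @param tip_row Row of the probe centerline (defaults to mid-height).
#' @param harris_k Harris sensitivity constant.
#' @param harris_sigma Gaussian window SD (px) for the structure tensor.
#' @param response_threshold Minimum Harris response for a valid detection.
#' @return List of class `frame_spec`.
#' @export
frame_spec <- function(width = 160, height = 120, probe_width_px = 10,
                       probe_intensity = 60, background = 200,
                       noise_sd = 3, pixel_size = 1.1e-6,
                       tip_col = NULL, tip_row = NULL,
                       harris_k = 0.05, harris_sigma = 1.5,
                       response_threshold = 1e5) {
  tip_col <- tip_col %||% round(width * 0.4)
  tip_row <- tip_row %||% round(height / 2)
  if (tip_col < 2 || tip_col > width - 2 || tip_row < 2 || tip_row > height - 2)
    stop("tip reference must be inside the frame")
  structure(list(width = width, height = height,
                 probe_width_px = probe_width_px,
                 probe_intensity = probe_intensity,
                 background = background, noise_sd = noise_sd,
                 pixel_size = pixel_size, tip_col = tip_col,
                 tip_row = tip_row, harris_k = harris_k,
                 harris_sigma = harris_sigma,
                 response_threshold = response_threshold),
            class = "frame_spec")
}

#' Render a probe frame at a given tip deflection
#'
#' Draws the probe as a dark horizontal bar (rows centered on `tip_row`)
#' extending from the left edge to `tip_col + deflection`, with linear
#' edge anti-aliasing for sub-pixel tip positions, plus seeded additive
#' Gaussian noise. Only bending-plane (horizontal) displacement is
#' rendered.
#'
#' @param spec A [frame_spec()].
#' @param deflection Tip deflection (m); positive moves the tip right.
#' @param seed RNG seed for the noise.
#' @return Numeric matrix (`height` x `width`) of gray levels.
#' @export
render_probe_frame <- function(spec, deflection, seed = NULL) {
  shift_px <- deflection / spec$pixel_size
  edge <- spec$tip_col + shift_px
  if (edge < 2 || edge > spec$width - 1)
    stop("deflection places the tip outside the frame")
  with_seed(seed, {
    img <- matrix(spec$background, spec$height, spec$width)
    r0 <- spec$tip_row - floor(spec$probe_width_px / 2)
    rows <- r0:(r0 + spec$probe_width_px - 1)
    full <- seq_len(floor(edge))
    img[rows, full] <- spec$probe_intensity
    frac <- edge - floor(edge)
    if (frac > 0 && floor(edge) + 1 <= spec$width)
      img[rows, floor(edge) + 1] <-
        (1 - frac) * spec$background + frac * spec$probe_intensity
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    img
  })
}

# Separable convolution with edge replication.
conv_sep <- function(mat, kern) {
  half <- (length(kern) - 1) / 2
  pad_apply <- function(m) {
    n <- ncol(m)
    mp <- cbind(m[, rep(1, half), drop = FALSE], m,
                m[, rep(n, half), drop = FALSE])
    out <- matrix(0, nrow(m), n)
    for (j in seq_len(n))
      out[, j] <- mp[, j:(j + 2 * half), drop = FALSE] %*% kern
    out
  }
  t(pad_apply(t(pad_apply(mat))))
}

gauss_kernel <- function(sigma) {
  half <- max(1, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Harris corner response map
#'
#' Structure-tensor corner response `det(M) - k trace(M)^2` with central
#' finite-difference gradients and a Gaussian window.
#'
#' @param img Gray-level matrix.
#' @param sigma Gaussian window SD (px).
#' @param k Harris constant.
#' @return Response matrix of the same size.
#' @export
harris_response <- function(img, sigma = 1.5, k = 0.05) {
  nr <- nrow(img); nc <- ncol(img)
  Ix <- matrix(0, nr, nc); Iy <- matrix(0, nr, nc)
  Ix[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  Iy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  kern <- gauss_kernel(sigma)
  Sxx <- conv_sep(Ix * Ix, kern)
  Syy <- conv_sep(Iy * Iy, kern)
  Sxy <- conv_sep(Ix * Iy, kern)
  (Sxx * Syy - Sxy^2) - k * (Sxx + Syy)^2
}

#' Detect the probe-tip displacement in a frame
#'
#' Finds the strongest Harris corner in a band of rows around the
#' reference tip position, refines the tip-edge column to sub-pixel
#' precision along the probe centerline (coverage integral of the
#' silhouette darkness around the corner), and reports the column
#' displacement rounded to integer pixels -- the "integral multiple of a
#' pixel" the force readout uses.
#'
#' @param img Gray-level matrix from [render_probe_frame()] (or
#'   equivalent).
#' @param spec The [frame_spec()] holding the zero-deflection reference
#'   and detector settings.
#' @return List with `displacement_px` (integer), `corner` (row, col of
#'   the Harris maximum), `edge_col` (sub-pixel column) and `detected`;
#'   when no corner exceeds the response threshold, `detected = FALSE`
#'   and the displacement is `NA`.
#' @export
detect_tip <- function(img, spec) {
  R <- harris_response(img, spec$harris_sigma, spec$harris_k)
  band <- max(1, spec$tip_row - spec$probe_width_px) :
    min(nrow(img), spec$tip_row + spec$probe_width_px)
  Rb <- R[band, , drop = FALSE]
  i <- which.max(Rb)
  if (length(i) == 0 || max(Rb) < spec$response_threshold)
    return(list(displacement_px = NA_integer_, corner = c(NA, NA),
                edge_col = NA_real_, detected = FALSE))
  corner_row <- band[(i - 1) %% nrow(Rb) + 1]
  corner_col <- (i - 1) %/% nrow(Rb) + 1
  # sub-pixel tip edge from the centerline coverage integral in a window
  # around the detected corner: each probe pixel contributes its darkness
  # fraction (unclipped, so zero-mean noise cancels instead of being
  # rectified), and columns left of the window count as fully covered
  prof <- img[spec$tip_row, ]
  cover <- (spec$background - prof) / (spec$background - spec$probe_intensity)
  c_lo <- max(1, corner_col - 10)
  c_hi <- min(length(prof), corner_col + 10)
  edge_col <- (c_lo - 1) + sum(cover[c_lo:c_hi])
  disp <- as.integer(round(edge_col - spec$tip_col))
  list(displacement_px = disp, corner = c(corner_row, corner_col),
       edge_col = edge_col, detected = TRUE)
}

#' Track a sequence of frames into a pixel-displacement series
#'
#' @param frames List of gray-level matrices.
#' @param spec The [frame_spec()].
#' @return Integer vector of per-frame displacements (NA where detection
#'   failed).
#' @export
track_frames <- function(frames, spec) {
  vapply(frames, function(f) detect_tip(f, spec)$displacement_px,
         integer(1))
}
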