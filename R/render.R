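#' Render a synthetic camera frame containing the fiducial marker
#'
#' Draws the dark marker square and its bright contrast circle onto a
#' uniform background, with anti-aliased (area-coverage) edges so that
#' sub-pixel marker positions are faithfully represented, then adds optional
#' Gaussian pixel noise. Serves as the test oracle for the detection stage.
#'
#' The image is a numeric matrix indexed \code{[row = y, col = x]} with gray
#' values in 0..255; pixel centers sit at integer coordinates, so pixel
#' \code{[i, j]} covers \code{x in [j-0.5, j+0.5]}, \code{y in [i-0.5, i+0.5]}.
#' Square coverage is computed exactly (axis-aligned separable overlap);
#' disc coverage by regular supersampling within each boundary pixel.
#'
#' @param center_px numeric length-2, marker center \code{c(x, y)} in px.
#' @param camera a \code{\link{camera_model}}.
#' @param marker a \code{\link{marker_spec}}.
#' @param noise_sd sd of additive Gaussian pixel noise, gray levels.
#' @param seed integer seed for the noise; same seed, same frame.
#' @param supersample subsamples per pixel axis for disc anti-aliasing.
#' @return numeric matrix \code{image_height_px x image_width_px}, values
#'   clipped to [0, 255].
#' @examples
#' fr <- render_frame(c(376, 240), camera_model(), marker_spec())
#' dim(fr)
#' @export
render_frame <- function(center_px, camera = camera_model(),
                         marker = marker_spec(), noise_sd = 0,
                         seed = NULL, supersample = 16L) {
  stopifnot(length(center_px) == 2, is.finite(center_px), noise_sd >= 0)
  W <- camera$image_width_px; H <- camera$image_height_px
  half_sq <- (marker$square_side_mm / 2) / camera$mm_per_px
  r <- expected_radius_px(marker, camera)
  cx <- center_px[1]; cy <- center_px[2]

  if (cx - half_sq < 0.5 || cx + half_sq > W + 0.5)
    stop(sprintf("marker out of bounds: center x = %.2f px (square half-side %.2f px)",
                 cx, half_sq))
  if (cy - half_sq < 0.5 || cy + half_sq > H + 0.5)
    stop(sprintf("marker out of bounds: center y = %.2f px (square half-side %.2f px)",
                 cy, half_sq))

  img <- matrix(marker$background_intensity, nrow = H, ncol = W)

  # exact coverage of an axis-aligned interval [a, b] over pixel centers p
  interval_cov <- function(p, a, b) pmin(p + 0.5, b) - pmax(p - 0.5, a)
  js <- max(1L, floor(cx - half_sq - 1)):min(W, ceiling(cx + half_sq + 1))
  is <- max(1L, floor(cy - half_sq - 1)):min(H, ceiling(cy + half_sq + 1))
  covx <- pmax(0, pmin(1, interval_cov(js, cx - half_sq, cx + half_sq)))
  covy <- pmax(0, pmin(1, interval_cov(is, cy - half_sq, cy + half_sq)))
  cov_sq <- outer(covy, covx)
  img[is, js] <- marker$background_intensity * (1 - cov_sq) +
    marker$square_intensity * cov_sq

  # disc coverage: interior/exterior decided analytically, rim supersampled
  jd <- max(1L, floor(cx - r - 1)):min(W, ceiling(cx + r + 1))
  id <- max(1L, floor(cy - r - 1)):min(H, ceiling(cy + r + 1))
  dx <- outer(rep(1, length(id)), jd - cx)
  dy <- outer(id - cy, rep(1, length(jd)))
  d <- sqrt(dx^2 + dy^2)
  cov <- matrix(0, length(id), length(jd))
  cov[d <= r - 0.75] <- 1
  rim <- which(d > r - 0.75 & d < r + 0.75, arr.ind = TRUE)
  if (nrow(rim) > 0) {
    k <- as.integer(supersample)
    off <- (seq_len(k) - 0.5) / k - 0.5
    sub <- expand.grid(ox = off, oy = off)
    px <- jd[rim[, 2]]; py <- id[rim[, 1]]
    inside <- matrix(0, nrow(rim), nrow(sub))
    for (m in seq_len(nrow(sub))) {
      inside[, m] <- (px + sub$ox[m] - cx)^2 + (py + sub$oy[m] - cy)^2 <= r^2
    }
    cov[rim] <- rowMeans(inside)
  }
  under <- img[id, jd]
  img[id, jd] <- under * (1 - cov) + marker$circle_intensity * cov

  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W))
  }
  pmin(pmax(img, 0), 255)
}
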