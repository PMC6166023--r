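# Shared fixtures. A small camera keeps rendering cheap while preserving the
# reference physical scale (mm_per_px = 183/752), so the expected circle
# radius in pixels is unchanged.
ref_cam <- function() camera_model()
small_cam <- function(width = 320L, height = 240L)
  camera_model(width, height, fov_width_mm = 183 / 752 * width, fps = 30)

# camera with the rounded scale used in worked arithmetic examples
round_cam <- function() camera_model(752L, 480L, fov_width_mm = 0.2434 * 752,
                                     fps = 30)

# build a centroid series from coordinate vectors
make_series <- function(x, y, camera = ref_cam(), valid = TRUE,
                        interpolated = FALSE) {
  n <- length(x)
  centroid_series(camera, data.frame(
    frame = seq_len(n) - 1L, x = x, y = y, radius = 24.7,
    valid = rep_len(valid, n), interpolated = rep_len(interpolated, n)))
}

# one-row segment in the shape extract_segments emits
make_segment <- function(kind, start, end, direction = "rightward",
                         subtask = 1L, missing = FALSE) {
  data.frame(kind = kind, subtask = subtask, subtask_id = "Large1",
             index = 1L, start = start, end = end, direction = direction,
             missing = missing)
}

# Independent dense rasterization of the marker: brute-force supersampling of
# every pixel (no separable shortcut, no rim classification), used as the
# oracle for the render's anti-aliasing and centroid geometry.
oracle_render <- function(center_px, camera, marker, k = 16L) {
  W <- camera$image_width_px; H <- camera$image_height_px
  half_sq <- (marker$square_side_mm / 2) / camera$mm_per_px
  r <- (marker$circle_diameter_mm / 2) / camera$mm_per_px
  off <- (seq_len(k) - 0.5) / k - 0.5
  img <- matrix(0, H, W)
  js <- floor(center_px[1] - half_sq - 1):ceiling(center_px[1] + half_sq + 1)
  is <- floor(center_px[2] - half_sq - 1):ceiling(center_px[2] + half_sq + 1)
  js <- js[js >= 1 & js <= W]; is <- is[is >= 1 & is <= H]
  full <- matrix(marker$background_intensity, H, W)
  for (i in is) for (j in js) {
    sx <- rep(j + off, each = k); sy <- rep(i + off, times = k)
    in_sq <- abs(sx - center_px[1]) <= half_sq & abs(sy - center_px[2]) <= half_sq
    in_c <- (sx - center_px[1])^2 + (sy - center_px[2])^2 <= r^2
    val <- ifelse(in_c, marker$circle_intensity,
                  ifelse(in_sq, marker$square_intensity,
                         marker$background_intensity))
    full[i, j] <- mean(val)
  }
  full
}

# intensity-weighted centroid of above-threshold pixels of a gray image
intensity_centroid <- function(img, threshold) {
  idx <- which(img > threshold, arr.ind = TRUE)
  w <- img[idx]
  c(x = sum(w * idx[, 2]) / sum(w), y = sum(w * idx[, 1]) / sum(w))
}

# draw an axis-aligned bright rectangle (sharp edges) onto an image
add_rect <- function(img, cx, cy, w, h, value) {
  js <- max(1, round(cx - w / 2)):min(ncol(img), round(cx + w / 2))
  is <- max(1, round(cy - h / 2)):min(nrow(img), round(cy + h / 2))
  img[is, js] <- value
  img
}
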