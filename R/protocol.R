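#' Movement-task protocol
#'
#' Geometry and sequencing constants of the two-target repetitive reaching
#' task: six subtasks (four with large 100-px targets, one medium 62-px,
#' one small 50-px), five movements between the horizontally aligned
#' targets per subtask, a 10-s rest on a central 100-px square between
#' subtasks, and a trained movement speed of 25.7 mm/s. The two target
#' centers are 138 mm apart and vertically centered on the display.
#'
#' Pixel coordinates follow the image convention: origin at the top-left
#' pixel, x rightward, y downward, pixel centers at integer coordinates
#' (the first pixel center is (1, 1)).
#'
#' @param camera a \code{\link{camera_model}}; fixes \code{mm_per_px} and
#'   hence the pixel separation of the targets.
#' @param target_side_px named vector of target square sides (px) for the
#'   three size classes.
#' @param subtask_order character vector of size-class labels, one per
#'   subtask.
#' @param movements_per_subtask movements (travel segments) per subtask.
#' @param rest_duration_s rest-screen duration between subtasks, seconds.
#' @param rest_square_px side of the central rest square, px.
#' @param training_speed trained movement speed, mm/s.
#' @param center_to_center_mm physical separation of the target centers.
#' @return An object of class \code{protocol}. Fields include
#'   \code{left_center_px} / \code{right_center_px} (x of the target
#'   centers), \code{center_y_px}, and \code{subtask_ids} (labels
#'   \code{Large1..Large4, Medium, Small}).
#' @export
protocol <- function(camera = camera_model(),
                     target_side_px = c(large = 100, medium = 62, small = 50),
                     subtask_order = c("large", "large", "large", "large",
                                       "medium", "small"),
                     movements_per_subtask = 5L,
                     rest_duration_s = 10,
                     rest_square_px = 100,
                     training_speed = 25.7,
                     center_to_center_mm = 138) {
  stopifnot(all(target_side_px > 0),
            target_side_px["large"] > target_side_px["medium"],
            target_side_px["medium"] > target_side_px["small"],
            all(subtask_order %in% names(target_side_px)),
            movements_per_subtask >= 1, training_speed > 0,
            rest_duration_s >= 0, center_to_center_mm > 0)

  sep_px <- center_to_center_mm / camera$mm_per_px
  cx <- (camera$image_width_px + 1) / 2
  cy <- (camera$image_height_px + 1) / 2
  left_x  <- cx - sep_px / 2
  right_x <- cx + sep_px / 2
  side_max <- max(target_side_px)
  if (left_x - side_max / 2 < 0.5 || right_x + side_max / 2 > camera$image_width_px + 0.5)
    stop("target squares do not fit inside the camera field of view")

  # canonical naming: repeated classes get an index, singletons do not
  counts <- stats::ave(seq_along(subtask_order), subtask_order, FUN = seq_along)
  n_per <- table(subtask_order)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  labels <- mapply(function(cls, i) {
    if (n_per[[cls]] > 1) paste0(cap(cls), i) else cap(cls)
  }, subtask_order, counts)

  structure(list(
    camera = camera,
    target_side_px = target_side_px,
    subtask_order = subtask_order,
    subtask_ids = unname(labels),
    movements_per_subtask = as.integer(movements_per_subtask),
    rest_duration_s = rest_duration_s,
    rest_square_px = rest_square_px,
    training_speed = training_speed,
    center_to_center_mm = center_to_center_mm,
    left_center_px = left_x,
    right_center_px = right_x,
    center_y_px = cy,
    rest_center_px = c(cx, cy)
  ), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf(paste0("<protocol> %d subtasks (%s), %d movements each, ",
                     "%.1f mm/s training speed,\n  targets at x = %.1f / %.1f px ",
                     "(%.0f mm apart), %g s rest\n"),
              length(x$subtask_ids), paste(x$subtask_ids, collapse = ", "),
              x$movements_per_subtask, x$training_speed,
              x$left_center_px, x$right_center_px,
              x$center_to_center_mm, x$rest_duration_s))
  invisible(x)
}

#' Side (px) of the target square used by a subtask
#' @param proto a \code{\link{protocol}}.
#' @param subtask integer subtask index (1-based) or subtask id label.
#' @return side length in pixels.
#' @export
subtask_side_px <- function(proto, subtask) {
  if (is.character(subtask)) subtask <- match(subtask, proto$subtask_ids)
  unname(proto$target_side_px[proto$subtask_order[subtask]])
}

# closed point-in-square test; boundary counts as inside
inside_square <- function(x, y, cx, cy, side) {
  abs(x - cx) <= side / 2 & abs(y - cy) <= side / 2
}

#' Intertarget region of interest for a subtask
#'
#' The rectangular corridor whose height matches the subtask's target side,
#' vertically centered on the targets, spanning from the left square's left
#' edge to the right square's right edge. Both target squares are fully
#' contained. Used by \code{\link{intertarget_path_accuracy}}.
#'
#' @inheritParams subtask_side_px
#' @return list with \code{xmin}, \code{xmax}, \code{ymin}, \code{ymax} (px).
#' @export
region_of_interest <- function(proto, subtask) {
  s <- subtask_side_px(proto, subtask)
  list(xmin = proto$left_center_px - s / 2,
       xmax = proto$right_center_px + s / 2,
       ymin = proto$center_y_px - s / 2,
       ymax = proto$center_y_px + s / 2)
}
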