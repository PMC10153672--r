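#' @title Lesion box tracks
#' @description A box track is a tibble with one row per frame and columns
#'   `case_id`, `frame_index` (0-based, contiguous), `x_min`, `y_min`,
#'   `x_max`, `y_max` (0-based pixel coordinates, inclusive of both
#'   endpoints) and `status` in `observed`, `missing`, `rejected`,
#'   `interpolated`. Cleanup ([reject_outliers()] then
#'   [interpolate_track()]) guarantees one box per frame with no missing
#'   status.
#' @name box_track
NULL

new_box_track <- function(case_id, frame_index, x_min, y_min, x_max, y_max,
                          status) {
  tibble::tibble(case_id = case_id, frame_index = as.integer(frame_index),
                 x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 status = status)
}

#' Intersection-over-union of two pixel-inclusive boxes
#'
#' Boxes are inclusive of both endpoints, so a box from `x_min` to `x_max`
#' spans `x_max - x_min + 1` pixels.
#'
#' @param a,b numeric vectors or lists with `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  ix <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min) + 1
  iy <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min) + 1
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  area <- function(z) (z$x_max - z$x_min + 1) * (z$y_max - z$y_min + 1)
  inter / (area(a) + area(b) - inter)
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  # 0-based: rows -> y, cols -> x
  c(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
    x_max = max(idx[, 2]) - 1, y_max = max(idx[, 1]) - 1)
}

#' Naive per-frame lesion detector
#'
#' A deliberately simple intensity detector standing in for a learned
#' per-frame lesion localiser: each frame is thresholded at `offset` gray
#' levels below (hypoechoic lesions, `polarity = "dark"`) or above
#' (`"bright"`) the frame median, the largest connected component is kept,
#' and its bounding box reported. Frames with no component of at least
#' `min_area` pixels are flagged `missing`. If `masks` is supplied the
#' detector is bypassed and each box is the tight bounding box of the
#' corresponding mask.
#'
#' @param frames list of numeric frame matrices (>= 1 frame).
#' @param masks optional list of per-frame logical masks (bypass mode).
#' @param case_id case identifier carried into the track.
#' @param offset threshold offset from the frame median, in gray levels.
#' @param polarity `"dark"` or `"bright"` lesion polarity.
#' @param min_area minimum component area in pixels.
#' @return a [box_track] tibble (statuses `observed` or `missing`;
#'   coordinates `NA` where missing).
#' @export
detect_boxes_naive <- function(frames, masks = NULL, case_id = "case",
                               offset = 20, polarity = c("dark", "bright"),
                               min_area = 25) {
  if (!is.list(frames) || length(frames) == 0)
    stop("empty frame stack", call. = FALSE)
  polarity <- match.arg(polarity)
  n <- length(frames)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    bb <- NULL
    if (!is.null(masks)) {
      bb <- mask_bbox(masks[[i]])
    } else {
      fr <- frames[[i]]
      med <- stats::median(fr)
      bw <- if (polarity == "dark") fr < med - offset else fr > med + offset
      if (any(bw)) {
        lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
        tab <- tabulate(as.integer(lab))
        if (length(tab) > 0 && max(tab) >= min_area) {
          comp <- which.max(tab)
          bb <- mask_bbox(matrix(as.integer(lab) == comp, nrow(fr), ncol(fr)))
        }
      }
    }
    rows[[i]] <- if (is.null(bb)) {
      new_box_track(case_id, i - 1L, NA_real_, NA_real_, NA_real_, NA_real_,
                    "missing")
    } else {
      new_box_track(case_id, i - 1L, bb["x_min"], bb["y_min"], bb["x_max"],
                    bb["y_max"], "observed")
    }
  }
  dplyr::bind_rows(rows)
}

#' Reject temporally incoherent boxes from a track
#'
#' For each observed box, the element-wise median box over a centered window
#' of `window` frames (missing/rejected neighbours skipped) is computed; a
#' box whose IoU with that median box falls below `iou_min` is re-flagged as
#' `rejected`. All other boxes are left untouched; the window is truncated
#' at the track edges.
#'
#' @param track a [box_track] tibble; tracks shorter than `window` are
#'   handled by the edge truncation.
#' @param window odd window length >= 3.
#' @param iou_min rejection threshold on IoU with the window-median box.
#' @return the track with incoherent boxes re-flagged `rejected`.
#' @export
reject_outliers <- function(track, window = 5, iou_min = 0.3) {
  if (window %% 2 == 0 || window < 3)
    stop("`window` must be an odd count >= 3", call. = FALSE)
  half <- (window - 1) / 2
  n <- nrow(track)
  ok <- track$status == "observed"
  status <- track$status
  coords <- as.matrix(track[, c("x_min", "y_min", "x_max", "y_max")])
  for (i in which(ok)) {
    win <- max(1, i - half):min(n, i + half)
    win <- win[ok[win]]
    med <- apply(coords[win, , drop = FALSE], 2, stats::median)
    if (box_iou(coords[i, ], med) < iou_min) status[i] <- "rejected"
  }
  track$status <- status
  track
}

#' Fill track gaps by linear interpolation
#'
#' Missing or rejected frames receive box coordinates linearly interpolated
#' coordinate-wise between the nearest observed frames; leading and trailing
#' gaps copy the nearest observed box. After interpolation every frame has
#' exactly one box and a non-missing status.
#'
#' @param track a [box_track] tibble with >= 2 observed boxes.
#' @return the cleaned track (filled frames get status `interpolated`).
#' @export
interpolate_track <- function(track) {
  obs <- track$status == "observed"
  if (sum(obs) < 2)
    stop("degenerate track: fewer than 2 observed boxes", call. = FALSE)
  gap <- !obs
  if (any(gap)) {
    for (cc in c("x_min", "y_min", "x_max", "y_max")) {
      track[[cc]][gap] <- stats::approx(track$frame_index[obs],
                                        track[[cc]][obs],
                                        xout = track$frame_index[gap],
                                        rule = 2)$y
    }
    track$status[gap] <- "interpolated"
  }
  track
}

#' Clean a raw track: rejection then interpolation
#'
#' @inheritParams reject_outliers
#' @return cleaned [box_track].
#' @export
clean_track <- function(track, window = 5, iou_min = 0.3) {
  interpolate_track(reject_outliers(track, window = window,
                                    iou_min = iou_min))
}

#' Rasterise a cleaned track into per-frame ROI masks
#'
#' @param track cleaned [box_track] (one box per frame, no missing status).
#' @param frame_shape integer (rows, cols).
#' @return list of logical matrices; ones inside each box, boundary pixels
#'   included. Boxes exceeding the frame are clipped with a warning.
#' @export
track_to_roi_masks <- function(track, frame_shape) {
  if (anyNA(track$x_min))
    stop("track still has missing boxes; run interpolate_track() first",
         call. = FALSE)
  rows <- frame_shape[1]; cols <- frame_shape[2]
  purrr::map(seq_len(nrow(track)), function(i) {
    b <- track[i, ]
    x0 <- round(b$x_min); x1 <- round(b$x_max)
    y0 <- round(b$y_min); y1 <- round(b$y_max)
    if (x0 < 0 || y0 < 0 || x1 > cols - 1 || y1 > rows - 1) {
      warning(sprintf("frame %d: box outside frame, clipped", b$frame_index))
      x0 <- max(x0, 0); y0 <- max(y0, 0)
      x1 <- min(x1, cols - 1); y1 <- min(y1, rows - 1)
    }
    m <- matrix(FALSE, rows, cols)
    m[(y0:y1) + 1L, (x0:x1) + 1L] <- TRUE
    m
  })
}

#' Write / read box tracks as CSV
#'
#' @param track a [box_track] tibble (or several bound together).
#' @param path CSV path.
#' @return `path` (write) or the track tibble (read).
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
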