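# Three-stage vision pipeline: colour mask -> morphological opening ->
# connected components / centroids, plus blob selection, exponential
# smoothing and lost-target holding.

#' Colour range specification
#'
#' Defines the in-range test for the marker colour, in RGB (0-255 per
#' channel) or HSV (hue in degrees 0-360, saturation and value in 0-1).
#' `lower`/`upper` may be length-3 vectors or k x 3 matrices; multiple rows
#' are independent windows combined with OR, which lets a red hue span the
#' 0/360 wrap-around as two windows.
#'
#' @param space `"HSV"` or `"RGB"`.
#' @param lower,upper Per-channel lower/upper bounds (vector or k x 3 matrix).
#' @return A validated `color_spec`.
#' @export
color_spec <- function(space = c("HSV", "RGB"), lower, upper) {
  space <- match.arg(space)
  if (is.null(dim(lower))) lower <- matrix(lower, nrow = 1)
  if (is.null(dim(upper))) upper <- matrix(upper, nrow = 1)
  if (ncol(lower) != 3L || ncol(upper) != 3L || nrow(lower) != nrow(upper) ||
      nrow(lower) < 1L)
    stop_invalid("lower and upper must be matching k x 3 bounds")
  if (any(lower > upper))
    stop_invalid("each lower bound must be <= its upper bound")
  structure(list(space = space, lower = lower, upper = upper),
            class = "color_spec")
}

#' Default HSV specification for a red pen marker
#'
#' Two hue windows around 0/360 degrees capture red across the hue
#' wrap-around; saturation and value floors reject the grey body, the dark
#' floor, and black/white impulse noise.
#'
#' @param hue_halfwidth_deg Half-width of each red hue window, degrees.
#' @param min_saturation,min_value Saturation/value floors in 0-1.
#' @return A [color_spec()].
#' @export
marker_color_spec <- function(hue_halfwidth_deg = 25, min_saturation = 0.35,
                              min_value = 0.15) {
  color_spec("HSV",
             lower = rbind(c(0, min_saturation, min_value),
                           c(360 - hue_halfwidth_deg, min_saturation, min_value)),
             upper = rbind(c(hue_halfwidth_deg, 1, 1),
                           c(360, 1, 1)))
}

#' Per-pixel colour mask
#'
#' Marks a pixel as foreground iff its colour lies inside any window of the
#' specification, after RGB-to-HSV conversion when the spec is in HSV. A
#' pure per-pixel function of the frame.
#'
#' @param frame H x W x 3 array, 8-bit grey levels 0-255.
#' @param spec A [color_spec()].
#' @return Logical H x W matrix.
#' @export
color_mask <- function(frame, spec) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop_invalid("frame must be an H x W x 3 RGB array")
  if (!inherits(spec, "color_spec"))
    stop_invalid("spec must be a color_spec")
  d <- dim(frame)
  .color_mask_cpp(as.numeric(frame), d[1], d[2], spec$lower, spec$upper,
                  spec$space == "HSV")
}

#' Morphological opening with a disk element
#'
#' Erosion followed by dilation with a disk structuring element of the
#' given radius (pixels at Chebyshev offsets with `dx^2 + dy^2 <= r^2`).
#' Radius 0 is the identity. Removes foreground specks smaller than the
#' element while approximately preserving larger shapes; anti-extensive and
#' idempotent.
#'
#' @param mask Logical matrix.
#' @param radius Integer radius >= 0.
#' @return Logical matrix of the same shape.
#' @export
morphological_clean <- function(mask, radius) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_invalid("mask must be a logical matrix")
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop_invalid("radius must be a single integer >= 0")
  radius <- as.integer(radius)
  if (radius == 0L) return(mask)
  .morph_disk(.morph_disk(mask, radius, TRUE), radius, FALSE)
}

#' Connected components of a binary mask
#'
#' 8-connected foreground components. Each blob's centroid is the
#' arithmetic mean of its member pixel coordinates (0-based, `u` = column,
#' `v` = row); the bounding box is inclusive. Blobs are sorted by pixel
#' count descending, ties broken by (centroid_v, centroid_u) ascending so
#' ordering is total and reproducible.
#'
#' @param mask Logical matrix.
#' @return Tibble with columns `pixel_count`, `centroid_u`, `centroid_v`,
#'   `u_min`, `u_max`, `v_min`, `v_max`; zero rows for an empty mask.
#' @export
extract_blobs <- function(mask) {
  empty <- tibble(pixel_count = integer(), centroid_u = numeric(),
                  centroid_v = numeric(), u_min = integer(),
                  u_max = integer(), v_min = integer(), v_max = integer())
  if (!any(mask)) return(empty)
  lab <- .label_components(mask)
  idx <- which(lab > 0L)
  H <- nrow(mask)
  px <- tibble(lab = lab[idx],
               u = (idx - 1L) %/% H,
               v = (idx - 1L) %% H)
  blobs <- px |>
    dplyr::group_by(lab) |>
    dplyr::summarise(pixel_count = dplyr::n(),
                     centroid_u = mean(u), centroid_v = mean(v),
                     u_min = min(u), u_max = max(u),
                     v_min = min(v), v_max = max(v), .groups = "drop") |>
    dplyr::select(-lab) |>
    dplyr::arrange(dplyr::desc(pixel_count), centroid_v, centroid_u)
  blobs
}

#' Tracker parameters
#'
#' @param opening_radius_px Disk radius for morphological cleanup.
#' @param min_blob_px Minimum blob size kept for selection.
#' @param max_jump_px Gate radius for nearest-blob association with the
#'   previous centroid.
#' @param ema_alpha Exponential-moving-average weight on the new centroid,
#'   in (0, 1]; 1 disables smoothing.
#' @param hold_frames Frames the last smoothed position is held after the
#'   target is lost before reporting it absent.
#' @return A validated `tracker_params`.
#' @export
tracker_params <- function(opening_radius_px = 2L, min_blob_px = 10L,
                           max_jump_px = 50, ema_alpha = 0.5,
                           hold_frames = 15L) {
  check_scalar_number(opening_radius_px, "opening_radius_px", 0)
  check_scalar_number(min_blob_px, "min_blob_px", 0)
  check_scalar_number(max_jump_px, "max_jump_px", 0)
  check_scalar_number(ema_alpha, "ema_alpha", 0, 1, strict_lower = TRUE)
  check_scalar_number(hold_frames, "hold_frames", 0)
  structure(list(opening_radius_px = as.integer(opening_radius_px),
                 min_blob_px = as.integer(min_blob_px),
                 max_jump_px = max_jump_px, ema_alpha = ema_alpha,
                 hold_frames = as.integer(hold_frames)),
            class = "tracker_params")
}

# Empty/initial track state.
initial_track_state <- function() {
  structure(list(frame_index = -1L, raw = NULL, smoothed = NULL,
                 found = FALSE, hold_counter = 0L),
            class = "track_state")
}

#' Select the target blob
#'
#' Discards blobs below `min_blob_px`; if the previous state has a
#' centroid, takes the nearest surviving blob within `max_jump_px`
#' (ties: larger blob, then smaller (centroid_v, centroid_u)); otherwise —
#' or when none is in range — the largest surviving blob.
#'
#' @param blobs Tibble from [extract_blobs()].
#' @param prev Previous `track_state` or `NULL`.
#' @param params A [tracker_params()].
#' @return One-row blob tibble, or `NULL` if no blob survives.
#' @export
select_target <- function(blobs, prev, params) {
  keep <- blobs[blobs$pixel_count >= params$min_blob_px, , drop = FALSE]
  if (nrow(keep) == 0L) return(NULL)
  ref <- if (!is.null(prev)) {
    if (!is.null(prev$smoothed)) prev$smoothed else prev$raw
  }
  if (!is.null(ref)) {
    dist <- sqrt((keep$centroid_u - ref[1])^2 + (keep$centroid_v - ref[2])^2)
    inrange <- which(dist <= params$max_jump_px)
    if (length(inrange) > 0L) {
      ord <- inrange[order(dist[inrange], -keep$pixel_count[inrange],
                           keep$centroid_v[inrange],
                           keep$centroid_u[inrange])]
      return(keep[ord[1L], , drop = FALSE])
    }
  }
  keep[order(-keep$pixel_count, keep$centroid_v, keep$centroid_u)[1L], ,
       drop = FALSE]
}

#' Update the track state with a selection
#'
#' With a selected blob: `found = TRUE`, raw centroid recorded, smoothed
#' centroid updated as `alpha * raw + (1 - alpha) * previous` (or raw when
#' there is no previous smoothed position), hold counter reset. Without:
#' `found = FALSE`, the hold counter increments and the last smoothed
#' position is retained while the counter is within `hold_frames`, after
#' which the target is reported absent.
#'
#' @param prev Previous `track_state` or `NULL`.
#' @param selection One-row blob tibble or `NULL`.
#' @param params A [tracker_params()].
#' @param frame_index Index recorded in the new state.
#' @return A `track_state`.
#' @export
update_track <- function(prev, selection, params, frame_index = NA_integer_) {
  if (is.null(prev)) prev <- initial_track_state()
  if (!is.null(selection)) {
    raw <- c(selection$centroid_u[1], selection$centroid_v[1])
    smoothed <- if (is.null(prev$smoothed)) raw
                else params$ema_alpha * raw + (1 - params$ema_alpha) * prev$smoothed
    st <- list(frame_index = as.integer(frame_index), raw = raw,
               smoothed = smoothed, found = TRUE, hold_counter = 0L)
  } else {
    hold <- prev$hold_counter + 1L
    smoothed <- if (!is.null(prev$smoothed) && hold <= params$hold_frames)
      prev$smoothed else NULL
    st <- list(frame_index = as.integer(frame_index), raw = NULL,
               smoothed = smoothed, found = FALSE, hold_counter = hold)
  }
  structure(st, class = "track_state")
}

#' Run the full pipeline on one frame
#'
#' Colour mask, morphological opening, blob extraction, target selection
#' and state update.
#'
#' @param frame H x W x 3 array, grey levels 0-255.
#' @param prev Previous `track_state` or `NULL`.
#' @param spec A [color_spec()].
#' @param params A [tracker_params()].
#' @param frame_index Index recorded in the new state.
#' @return A `track_state`.
#' @export
track_step <- function(frame, prev, spec, params, frame_index = NA_integer_) {
  mask <- color_mask(frame, spec)
  mask <- morphological_clean(mask, params$opening_radius_px)
  blobs <- extract_blobs(mask)
  sel <- select_target(blobs, prev, params)
  update_track(prev, sel, params, frame_index)
}

track_state_row <- function(st, time_s) {
  tibble(frame_index = st$frame_index, time_s = time_s, found = st$found,
         raw_u_px = if (is.null(st$raw)) NA_real_ else st$raw[1],
         raw_v_px = if (is.null(st$raw)) NA_real_ else st$raw[2],
         smooth_u_px = if (is.null(st$smoothed)) NA_real_ else st$smoothed[1],
         smooth_v_px = if (is.null(st$smoothed)) NA_real_ else st$smoothed[2],
         hold_counter = st$hold_counter)
}

#' Track a frame sequence
#'
#' Applies [track_step()] to every frame in order. Frames may be given as
#' a directory of `frame_*.png` files or as a list of in-memory arrays.
#'
#' @param frames Directory path or list of H x W x 3 arrays.
#' @param spec A [color_spec()].
#' @param params A [tracker_params()].
#' @param fps Frames per second used to fill `time_s`.
#' @return Tibble with one row per frame: `frame_index`, `time_s`, `found`,
#'   `raw_u_px`, `raw_v_px`, `smooth_u_px`, `smooth_v_px`, `hold_counter`.
#' @export
track_sequence <- function(frames, spec = marker_color_spec(),
                           params = tracker_params(), fps = 20) {
  if (is.character(frames)) {
    paths <- sort(list.files(frames, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (length(paths) == 0L)
      stop_invalid("no frame_*.png files found in ", frames)
    getter <- function(i) {
      tryCatch(read_frame(paths[i]),
               error = function(e)
                 stop_invalid("cannot read frame index ", i - 1L, ": ",
                              conditionMessage(e)))
    }
    n <- length(paths)
  } else if (is.list(frames) && length(frames) > 0L) {
    getter <- function(i) frames[[i]]
    n <- length(frames)
  } else {
    stop_invalid("frames must be a directory path or a non-empty list")
  }
  st <- NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- track_step(getter(i), st, spec, params, frame_index = i - 1L)
    rows[[i]] <- track_state_row(st, time_s = (i - 1L) / fps)
  }
  dplyr::bind_rows(rows)
}

#' Write a trajectory CSV
#'
#' Writes the [track_sequence()] tibble atomically with the canonical
#' header `frame_index,time_s,found,raw_u_px,raw_v_px,smooth_u_px,
#' smooth_v_px,hold_counter`.
#'
#' @param trajectory Tibble from [track_sequence()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("frame_index", "time_s", "found", "raw_u_px", "raw_v_px",
            "smooth_u_px", "smooth_v_px", "hold_counter")
  write_csv_atomic(trajectory[, cols], path)
  invisible(path)
}
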