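#' Track tables
#'
#' A track table is the atom of all migration statistics: one row per cell
#' per frame, with positions in micrometres (x rightward, y upward, the
#' mathematical convention) and time in hours. It is stored as a plain
#' data.frame of class \code{etx_tracks} with columns \code{cell_id},
#' \code{frame}, \code{time_h}, \code{x}, \code{y} and optional
#' \code{viewfield} and \code{condition} labels.
#'
#' @param df A data.frame with at least cell_id, frame, x, y columns
#'   (time_h computed from frame if absent).
#' @param frame_interval Minutes between frames, used when time_h is absent.
#' @return An \code{etx_tracks} data.frame, rows ordered by cell then frame.
#' @export
tracks <- function(df, frame_interval = 10) {
  need <- c("cell_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$frame) || !is.numeric(df$x) || !is.numeric(df$y))
    stop("track table format error: frame, x, y must be numeric",
         call. = FALSE)
  if (anyNA(df$x) || anyNA(df$y) || any(!is.finite(df$x)) ||
      any(!is.finite(df$y)))
    stop("track table format error: non-finite coordinates", call. = FALSE)
  if (is.null(df$time_h)) df$time_h <- df$frame * frame_interval / 60
  if (is.null(df$viewfield)) df$viewfield <- "vf1"
  if (is.null(df$condition)) df$condition <- "default"
  key <- paste(df$viewfield, df$cell_id, df$frame, sep = "\r")
  if (anyDuplicated(key))
    stop("track table format error: duplicate (cell_id, frame) rows",
         call. = FALSE)
  df <- df[order(df$viewfield, df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("etx_tracks", "data.frame")
  df
}

#' Split a track table into per-cell trajectories
#'
#' Each trajectory is validated: at least two time points, strictly
#' increasing finite times, finite positions.
#'
#' @param tk An \code{etx_tracks} table.
#' @param validate Check the trajectory invariants (default TRUE).
#' @return Named list of data.frames, one per (viewfield, cell_id).
#' @export
split_tracks <- function(tk, validate = TRUE) {
  key <- interaction(tk$viewfield, tk$cell_id, drop = TRUE, sep = "/")
  out <- split(as.data.frame(tk), key)
  if (validate) {
    for (nm in names(out)) {
      tr <- out[[nm]]
      if (nrow(tr) < 2)
        stop("trajectory ", nm, " has fewer than 2 time points", call. = FALSE)
      if (any(diff(tr$time_h) <= 0) || any(!is.finite(tr$time_h)))
        stop("trajectory ", nm, " times not strictly increasing/finite",
             call. = FALSE)
    }
  }
  out
}

#' Per-cell net (first-to-last) displacement
#'
#' The Euclidean displacement vector from the first to the last observed
#' frame of each trajectory, together with the elapsed time. This endpoint
#' vector underlies directedness, migration speed and displacement angles.
#'
#' @param tk An \code{etx_tracks} table.
#' @return A data.frame with cell_id, viewfield, condition, dx, dy,
#'   net_distance (um), elapsed_h, n_frames.
#' @export
net_displacement <- function(tk) {
  trs <- split_tracks(tk)
  rows <- lapply(trs, function(tr) {
    n <- nrow(tr)
    data.frame(cell_id = tr$cell_id[1], viewfield = tr$viewfield[1],
               condition = tr$condition[1],
               dx = tr$x[n] - tr$x[1], dy = tr$y[n] - tr$y[1],
               elapsed_h = tr$time_h[n] - tr$time_h[1], n_frames = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$net_distance <- sqrt(out$dx^2 + out$dy^2)
  out
}

#' Read a track table from CSV
#'
#' Reads the comma-separated, headered track-table dialect emitted by
#' segmentation/tracking tools and by \code{\link{simulate_walks}}:
#' columns \code{cell_id, frame, x, y} (0-based frames) plus optional
#' \code{viewfield, condition, area, axis_angle}. Coordinates may be in
#' pixels (converted using the calibration) or already in micrometres.
#'
#' @param path CSV file path.
#' @param cal An \code{etx_calibration}; supplies the pixel size and the
#'   frame interval.
#' @param unit_mode "pixel" or "um": the units of the x/y columns on disk.
#' @return An \code{etx_tracks} table in micrometres and hours.
#' @export
read_tracks <- function(path, cal, unit_mode = c("um", "pixel")) {
  unit_mode <- match.arg(unit_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track table format error: missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("empty track table: ", path, call. = FALSE)
    df$time_h <- numeric(0)
    df$viewfield <- character(0)
    df$condition <- character(0)
    class(df) <- c("etx_tracks", "data.frame")
    return(df)
  }
  for (cc in c("frame", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("track table format error: non-numeric values in column ", cc,
           call. = FALSE)
    df[[cc]] <- v
  }
  if (unit_mode == "pixel") {
    px <- effective_pixel_size(cal)
    df$x <- df$x * px
    df$y <- df$y * px
    if (!is.null(df$area)) df$area <- df$area * px^2
  }
  tracks(df, frame_interval = cal$frame_interval)
}

#' Write a track table to CSV
#'
#' Inverse of \code{\link{read_tracks}} (in micrometre mode): coordinates
#' round-trip to at least six significant digits.
#'
#' @param tk An \code{etx_tracks} table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(tk, path) {
  df <- as.data.frame(tk)
  for (cc in c("x", "y", "time_h"))
    df[[cc]] <- formatC(df[[cc]], digits = 10, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
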