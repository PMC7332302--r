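#' Applied electric field vector
#'
#' The reference frame for directedness and orientation: the unit
#' direction from anode to cathode, plus the field strength. Cathodal
#' migration (along the field vector) has directedness +1, anodal -1.
#'
#' @param direction 2D vector, anode to cathode (normalized internally).
#' @param strength Field strength, V/m (>= 0).
#' @param on_time Hours of field application (metadata).
#' @return An \code{etx_field} object with unit-norm direction.
#' @export
field_vector <- function(direction = c(1, 0), strength = 0, on_time = NA_real_) {
  direction <- as.numeric(direction)
  if (length(direction) != 2 || any(!is.finite(direction)))
    stop("field direction must be a finite 2D vector", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("field direction must be nonzero", call. = FALSE)
  if (strength < 0) stop("field strength must be >= 0", call. = FALSE)
  structure(list(direction = direction / nrm, strength = strength,
                 on_time = on_time), class = "etx_field")
}

#' Field direction as an angle
#' @param field An \code{etx_field}.
#' @return Angle of the anode-to-cathode direction, radians.
#' @export
field_angle <- function(field) atan2(field$direction[2], field$direction[1])

#' Electrotaxis directedness
#'
#' The group directedness is the average cosine of the angle between each
#' cell's net (first-to-last frame) Euclidean displacement vector and the
#' anode-to-cathode field vector: sum(cos Phi_i)/N. A cohort moving
#' cathodally scores +1, anodally -1, and randomly 0. Cells with zero net
#' displacement have an undefined angle and are excluded with a warning.
#'
#' @param tk An \code{etx_tracks} table.
#' @param field An \code{etx_field}.
#' @return List: \code{value} (group mean), \code{n}, \code{n_excluded},
#'   \code{per_cell} data.frame with cos_phi per cell.
#' @export
directedness <- function(tk, field) {
  nd <- net_displacement(tk)
  if (nrow(nd) == 0) stop("empty group: no trajectories", call. = FALSE)
  zero <- nd$net_distance == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero net displacement excluded from ",
            "directedness", call. = FALSE)
  keep <- nd[!zero, , drop = FALSE]
  if (nrow(keep) == 0) stop("empty group: all net displacements zero",
                            call. = FALSE)
  fx <- field$direction[1]; fy <- field$direction[2]
  cos_phi <- (keep$dx * fx + keep$dy * fy) / keep$net_distance
  cos_phi <- pmin(1, pmax(-1, cos_phi))
  per <- data.frame(cell_id = keep$cell_id, viewfield = keep$viewfield,
                    condition = keep$condition, cos_phi = cos_phi,
                    stringsAsFactors = FALSE)
  list(value = mean(cos_phi), n = nrow(per), n_excluded = sum(zero),
       per_cell = per)
}

#' Migration speed from net displacement
#'
#' Per-cell speed is the Euclidean (net) distance travelled divided by the
#' elapsed time, in um/h; the group value is the mean over cells. The
#' total path length and the derived "motility" speed (path/time) are
#' emitted as auxiliary columns.
#'
#' @param tk An \code{etx_tracks} table.
#' @return List: \code{value} (mean speed um/h), \code{n},
#'   \code{per_cell} data.frame (speed, net_distance, path_length,
#'   path_speed, elapsed_h).
#' @export
speeds <- function(tk) {
  trs <- split_tracks(tk)
  if (!length(trs)) stop("empty group: no trajectories", call. = FALSE)
  rows <- lapply(trs, function(tr) {
    n <- nrow(tr)
    el <- tr$time_h[n] - tr$time_h[1]
    if (el <= 0) stop("undefined speed: zero elapsed time for cell ",
                      tr$cell_id[1], call. = FALSE)
    net <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
    path <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
    data.frame(cell_id = tr$cell_id[1], viewfield = tr$viewfield[1],
               condition = tr$condition[1], speed = net / el,
               net_distance = net, path_length = path,
               path_speed = path / el, elapsed_h = el,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(value = mean(per$speed), n = nrow(per), per_cell = per)
}

#' Speed of a single trajectory
#'
#' @param tr A single-trajectory data.frame (time_h, x, y).
#' @return Net speed in um/h.
#' @export
trajectory_speed <- function(tr) {
  n <- nrow(tr)
  if (n < 2) stop("undefined speed: single-frame trajectory", call. = FALSE)
  el <- tr$time_h[n] - tr$time_h[1]
  if (el <= 0) stop("undefined speed: zero elapsed time", call. = FALSE)
  sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2) / el
}

#' Orientation index of cell long axes
#'
#' The mean of cos(2*theta_i), where theta_i is the angle between a
#' cell's long axis and the field vector. Doubling the angle makes the
#' index insensitive to the head/tail ambiguity of an axis: +1 for a
#' cohort aligned parallel to the field, -1 perpendicular, 0 for random
#' orientations. Undefined axis angles (near-circular cells) are
#' excluded, not imputed.
#'
#' @param axis_angles Numeric axial angles in [0, pi) measured from +x
#'   (NA = undefined), or an axial \code{etx_angles} set.
#' @param field An \code{etx_field}.
#' @return List: \code{value}, \code{n}, \code{n_excluded},
#'   \code{per_cell} (cos_2theta).
#' @export
orientation_index <- function(axis_angles, field) {
  ang <- if (inherits(axis_angles, "etx_angles")) {
    if (!axis_angles$axial)
      stop("orientation_index expects axial angles", call. = FALSE)
    axis_angles$angles
  } else as.numeric(axis_angles)
  bad <- is.na(ang)
  ang <- ang[!bad]
  if (!length(ang)) stop("empty group: no defined axis angles", call. = FALSE)
  theta <- ang - field_angle(field)
  cos2 <- cos(2 * theta)
  list(value = mean(cos2), n = length(cos2), n_excluded = sum(bad),
       per_cell = data.frame(cos_2theta = cos2))
}

#' Mean cell area
#'
#' Group mean of per-cell mask areas, sum(A_i)/N in um^2.
#'
#' @param region_measures A numeric vector of areas or a data.frame with
#'   an \code{area} column (e.g. from \code{measure_labelmask_stack}).
#' @return List: \code{value} (um^2), \code{n}.
#' @export
mean_area <- function(region_measures) {
  a <- if (is.data.frame(region_measures)) region_measures$area
       else as.numeric(region_measures)
  if (!length(a)) stop("empty group: no regions", call. = FALSE)
  list(value = mean(a), n = length(a))
}

#' Time-resolved group metrics
#'
#' Per-frame group values over the acquisition. Directedness at frame t
#' uses the cumulative displacement from frame 0 to frame t (so frame 0,
#' with zero displacement, is undefined and omitted). Orientation at
#' frame t averages cos(2*theta) over the regions measured in that frame.
#' Trajectories must share a common frame grid (apply
#' \code{\link{filter_complete_tracks}} first).
#'
#' @param x An \code{etx_tracks} table (directedness) or a region-measure
#'   data.frame with frame_index and axis_angle (orientation).
#' @param field An \code{etx_field}.
#' @param metric "directedness" or "orientation".
#' @return Data.frame with frame, time_h (tracks only), value, n.
#' @export
time_series <- function(x, field, metric = c("directedness", "orientation")) {
  metric <- match.arg(metric)
  if (metric == "directedness") {
    trs <- split_tracks(x)
    if (!length(trs)) stop("empty group: no trajectories", call. = FALSE)
    frames <- trs[[1]]$frame
    for (tr in trs)
      if (!identical(tr$frame, frames))
        stop("alignment error: trajectories have inconsistent frame grids",
             call. = FALSE)
    fx <- field$direction[1]; fy <- field$direction[2]
    out <- lapply(seq_along(frames)[-1], function(k) {
      dx <- vapply(trs, function(tr) tr$x[k] - tr$x[1], numeric(1))
      dy <- vapply(trs, function(tr) tr$y[k] - tr$y[1], numeric(1))
      d <- sqrt(dx^2 + dy^2)
      ok <- d > 0
      data.frame(frame = frames[k], time_h = trs[[1]]$time_h[k],
                 value = if (any(ok))
                   mean((dx[ok] * fx + dy[ok] * fy) / d[ok]) else NA_real_,
                 n = sum(ok))
    })
    do.call(rbind, out)
  } else {
    if (!is.data.frame(x) || is.null(x$frame_index) || is.null(x$axis_angle))
      stop("orientation series needs region measures with frame_index and ",
           "axis_angle", call. = FALSE)
    keep <- x[!is.na(x$axis_angle), , drop = FALSE]
    if (!nrow(keep)) stop("empty group: no defined axis angles", call. = FALSE)
    fa <- field_angle(field)
    agg <- lapply(split(keep, keep$frame_index), function(d)
      data.frame(frame = d$frame_index[1],
                 value = mean(cos(2 * (d$axis_angle - fa))), n = nrow(d)))
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out[order(out$frame), , drop = FALSE]
  }
}
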