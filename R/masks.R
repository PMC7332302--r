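#' Measure labelled regions in a mask stack
#'
#' Computes per-frame, per-label region properties from integer label
#' masks (background = 0), as produced by segmentation/tracking tools:
#' pixel count, area in um^2, centroid in um, and the long-axis
#' orientation from the principal eigenvector of the second central
#' moment matrix of the pixel coordinates.
#'
#' Coordinates use the mathematical convention: x increases with image
#' column, y increases upward, so the image row axis is negated. The pixel
#' at (row r, col c) has its centre at \code{x = (c - 0.5) * px},
#' \code{y = (nrow - r + 0.5) * px}. \code{axis_angle} is axial
#' (undirected) and reported in [0, pi) from the +x axis.
#'
#' Regions of fewer than 3 pixels have no meaningful axis: their area is
#' still reported but \code{axis_angle} is NA and \code{degenerate_axis}
#' is TRUE, excluding them from orientation statistics. Isotropic regions
#' (equal principal moments) report angle 0 with the flag set.
#'
#' @param stack A list of integer matrices (one per frame), or a single
#'   matrix.
#' @param cal An \code{etx_calibration} (or a single number, the pixel
#'   size in um).
#' @return A data.frame with frame_index (0-based), label, n_pixels,
#'   area (um^2), cx, cy (um), axis_angle (radians in [0, pi) or NA),
#'   degenerate_axis.
#' @export
measure_labelmask_stack <- function(stack, cal) {
  px <- if (inherits(cal, "etx_calibration")) effective_pixel_size(cal)
        else as.numeric(cal)
  if (is.matrix(stack)) stack <- list(stack)
  out <- list()
  for (f in seq_along(stack)) {
    img <- stack[[f]]
    if (!is.matrix(img) || any(img != round(img), na.rm = TRUE))
      stop("label mask format error: frame ", f - 1,
           " is not an integer matrix", call. = FALSE)
    labs <- sort(unique(as.vector(img)))
    labs <- labs[labs > 0]
    for (lab in labs) {
      idx <- which(img == lab, arr.ind = TRUE)
      n <- nrow(idx)
      # pixel centres in math (y-up) convention
      xs <- (idx[, 2] - 0.5) * px
      ys <- (nrow(img) - idx[, 1] + 0.5) * px
      cx <- mean(xs); cy <- mean(ys)
      if (n < 3) {
        ang <- NA_real_; degen <- TRUE
      } else {
        mu20 <- mean((xs - cx)^2)
        mu02 <- mean((ys - cy)^2)
        mu11 <- mean((xs - cx) * (ys - cy))
        if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) {
          ang <- 0; degen <- TRUE   # isotropic tie: deterministic 0, flagged
        } else {
          ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
          ang <- ang %% pi
          degen <- FALSE
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        frame_index = f - 1L, label = lab, n_pixels = n,
        area = n * px^2, cx = cx, cy = cy,
        axis_angle = ang, degenerate_axis = degen)
    }
  }
  if (!length(out))
    return(data.frame(frame_index = integer(0), label = integer(0),
                      n_pixels = integer(0), area = numeric(0),
                      cx = numeric(0), cy = numeric(0),
                      axis_angle = numeric(0), degenerate_axis = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a label-mask stack from TIFF files
#'
#' Accepts a multi-page TIFF or a directory of numbered single-page TIFF
#' frames holding 8/16-bit integer labels.
#'
#' @param path A TIFF file or a directory of TIFF frames.
#' @return A list of integer matrices, one per frame.
#' @export
read_labelmask_stack <- function(path) {
  to_labels <- function(m) {
    if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
    # readTIFF scales to [0,1]; recover integer labels from the bit depth
    depth <- attr(m, "bits.per.sample")
    if (is.null(depth)) depth <- 16L
    round(m * (2^depth - 1))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF frames found in ", path, call. = FALSE)
    lapply(files, function(f) to_labels(tiff::readTIFF(f, info = TRUE)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    lapply(pages, to_labels)
  }
}

#' Write a label-mask stack as a multi-page 16-bit TIFF
#'
#' @param stack List of integer matrices (labels < 65536).
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_labelmask_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  norm <- lapply(stack, function(m) m / 65535)
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  invisible(path)
}
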