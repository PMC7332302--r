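#' Configuration for the elliptical-mask generator
#'
#' Cells are modelled as filled ellipses with gamma-distributed areas,
#' gamma-distributed aspect ratios (>= 1) and axial orientations drawn so
#' that twice the axis angle follows a von Mises distribution centred on
#' twice \code{preferred_axis} with concentration \code{kappa_axial}
#' (\code{kappa_axial = 0} gives uniform axial orientations; large values
#' align all long axes with the preferred axis, e.g. perpendicular to an
#' applied field).
#'
#' @param n_cells Number of ellipses.
#' @param mean_area Mean cell area, um^2.
#' @param area_cv Coefficient of variation of areas.
#' @param aspect_mean Mean long/short axis ratio (>= 1).
#' @param kappa_axial Axial concentration (>= 0).
#' @param preferred_axis Preferred long-axis direction, radians in [0, pi).
#' @param image_shape Integer c(rows, cols) of each mask frame, pixels.
#' @param n_frames Number of frames; cells are spread evenly across
#'   frames (labels stay globally unique).
#' @param pixel_size Effective pixel size, um/pixel.
#' @param seed Seed.
#' @param max_tries Placement attempts per cell before a placement error.
#' @return A validated \code{etx_shape_config} list.
#' @export
shape_config <- function(n_cells, mean_area = 400, area_cv = 0.3,
                         aspect_mean = 3, kappa_axial = 0,
                         preferred_axis = pi / 2,
                         image_shape = c(512L, 512L), n_frames = 1L,
                         pixel_size = 0.87,
                         seed = 1L, max_tries = 200L) {
  bad <- function(msg) stop("shape config error: ", msg, call. = FALSE)
  if (n_cells < 1) bad("n_cells must be >= 1")
  if (mean_area <= 0 || area_cv < 0) bad("area parameters invalid")
  if (aspect_mean < 1) bad("aspect_mean must be >= 1")
  if (kappa_axial < 0) bad("kappa_axial must be >= 0")
  if (preferred_axis < 0 || preferred_axis >= pi)
    bad("preferred_axis must lie in [0, pi)")
  if (pixel_size <= 0) bad("pixel_size must be > 0")
  if (n_frames < 1) bad("n_frames must be >= 1")
  structure(list(n_cells = as.integer(n_cells), mean_area = mean_area,
                 area_cv = area_cv, aspect_mean = aspect_mean,
                 kappa_axial = kappa_axial, preferred_axis = preferred_axis,
                 image_shape = as.integer(image_shape),
                 n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, seed = as.integer(seed),
                 max_tries = as.integer(max_tries)),
            class = "etx_shape_config")
}

#' Simulate a labelled ellipse mask with ground truth
#'
#' Rasterizes non-overlapping filled ellipses into an integer label mask
#' (background 0, labels 1..n) using the same y-up pixel-centre convention
#' that \code{\link{measure_labelmask_stack}} assumes, and returns the
#' analytic ground truth for each cell. Overlaps are avoided by rejecting
#' candidate centres whose bounding circles intersect an accepted cell.
#'
#' @param cfg An \code{etx_shape_config}.
#' @return A list with \code{stack} (list of one integer matrix) and
#'   \code{truth} (data.frame: label, area um^2, cx, cy um, axis_angle
#'   radians in [0, pi), aspect).
#' @export
simulate_shape_stack <- function(cfg) {
  if (!inherits(cfg, "etx_shape_config"))
    stop("shape config error: not an etx_shape_config", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]; px <- cfg$pixel_size
  n <- cfg$n_cells
  # per-cell geometry draws
  if (cfg$area_cv > 0) {
    sh <- 1 / cfg$area_cv^2
    areas <- stats::rgamma(n, shape = sh, scale = cfg$mean_area / sh)
  } else areas <- rep(cfg$mean_area, n)
  if (cfg$aspect_mean > 1) {
    aspects <- 1 + stats::rgamma(n, shape = 4,
                                 scale = (cfg$aspect_mean - 1) / 4)
  } else aspects <- rep(1, n)
  thetas <- (rvonmises(n, 2 * cfg$preferred_axis, cfg$kappa_axial) / 2) %% pi
  b_um <- sqrt(areas / (pi * aspects))
  a_um <- aspects * b_um
  a_px <- a_um / px; b_px <- b_um / px
  if (any(2 * a_px > min(nr, nc) - 2))
    stop("shape config error: ellipse larger than the image", call. = FALSE)
  frame_of <- rep(seq_len(cfg$n_frames), length.out = n)
  # rejection-sampled placement on bounding circles, per frame
  cxs <- numeric(n); cys <- numeric(n)
  for (fr in seq_len(cfg$n_frames)) {
    members <- which(frame_of == fr)
    done <- integer(0)
    for (i in members) {
      placed <- FALSE
      for (try in seq_len(cfg$max_tries)) {
        cx <- stats::runif(1, a_px[i] + 1, nc - a_px[i] - 1)
        cy <- stats::runif(1, a_px[i] + 1, nr - a_px[i] - 1)
        if (!length(done) ||
            all(sqrt((cxs[done] - cx)^2 + (cys[done] - cy)^2) >
                a_px[done] + a_px[i] + 1)) {
          cxs[i] <- cx; cys[i] <- cy; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("placement error: could not place non-overlapping cells ",
             "after ", cfg$max_tries, " tries (cell ", i, ", frame ", fr,
             ")", call. = FALSE)
      done <- c(done, i)
    }
  }
  stack <- vector("list", cfg$n_frames)
  for (fr in seq_len(cfg$n_frames)) {
    img <- matrix(0L, nr, nc)
    for (i in which(frame_of == fr)) {
      r0 <- max(1L, floor(nr - cys[i] + 0.5 - a_px[i] - 1))
      r1 <- min(nr, ceiling(nr - cys[i] + 0.5 + a_px[i] + 1))
      c0 <- max(1L, floor(cxs[i] + 0.5 - a_px[i] - 1))
      c1 <- min(nc, ceiling(cxs[i] + 0.5 + a_px[i] + 1))
      rr <- r0:r1; cc <- c0:c1
      # pixel centres, y-up
      xs <- matrix(cc - 0.5, length(rr), length(cc), byrow = TRUE) - cxs[i]
      ys <- matrix(nr - rr + 0.5, length(rr), length(cc)) - cys[i]
      u <- xs * cos(thetas[i]) + ys * sin(thetas[i])
      v <- -xs * sin(thetas[i]) + ys * cos(thetas[i])
      inside <- (u / a_px[i])^2 + (v / b_px[i])^2 <= 1
      sub <- img[rr, cc]
      sub[inside] <- i
      img[rr, cc] <- sub
    }
    stack[[fr]] <- img
  }
  truth <- data.frame(label = seq_len(n), frame_index = frame_of - 1L,
                      area = areas, cx = cxs * px, cy = cys * px,
                      axis_angle = thetas, aspect = aspects)
  list(stack = stack, truth = truth)
}
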