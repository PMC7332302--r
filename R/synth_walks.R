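#' Configuration for the biased persistent random-walk simulator
#'
#' Each simulated cell takes \code{n_steps} steps of duration \code{dt}
#' hours. The heading of step t is a single von Mises draw centred on the
#' circular weighted mean of the field direction (\code{target_angle},
#' weight \code{mix_weight}, concentration \code{kappa_bias}) and the
#' previous heading (weight \code{1 - mix_weight}, concentration
#' \code{kappa_persist}); the two weighted concentration vectors are added
#' vectorially, so with \code{mix_weight = 1} headings are i.i.d.
#' von Mises(\code{target_angle}, \code{kappa_bias}). Per-step speeds are
#' independent gamma draws with mean \code{speed_mean} and shape
#' \code{speed_shape}.
#'
#' Defaults mirror a typical 6-h time-lapse electrotaxis acquisition at
#' 10-min frame intervals: 36 steps of dt = 1/6 h, per-step speeds around
#' 15 um/h (net speeds of persistent biased walks then fall in the
#' 2-20 um/h range seen in glioblastoma electrotaxis).
#'
#' @param n_cells Number of cells (>= 1).
#' @param n_steps Steps per cell (>= 1); positions have n_steps + 1 frames.
#' @param dt Step duration, hours.
#' @param speed_mean Mean per-step speed, um/h (> 0).
#' @param speed_shape Gamma shape of per-step speeds (> 0).
#' @param kappa_bias von Mises concentration toward \code{target_angle} (>= 0).
#' @param kappa_persist Concentration about the previous heading (>= 0).
#' @param target_angle Preferred absolute direction, radians
#'   (anode-to-cathode field direction = 0 by convention).
#' @param mix_weight Weight of bias vs persistence, in [0, 1].
#' @param condition Condition label stamped on the output table.
#' @param seed Root seed; per-cell substreams are derived from it.
#' @return A validated \code{etx_walk_config} list.
#' @export
walk_config <- function(n_cells, n_steps = 36L, dt = 1 / 6,
                        speed_mean = 15, speed_shape = 2,
                        kappa_bias = 0, kappa_persist = 0,
                        target_angle = 0, mix_weight = 0.5,
                        condition = "sim", seed = 1L) {
  bad <- function(msg) stop("walk config error: ", msg, call. = FALSE)
  if (n_cells < 1 || n_cells != round(n_cells)) bad("n_cells must be int >= 1")
  if (n_steps < 1 || n_steps != round(n_steps)) bad("n_steps must be int >= 1")
  if (dt <= 0) bad("dt must be > 0")
  if (speed_mean <= 0 || speed_shape <= 0) bad("speed params must be > 0")
  if (kappa_bias < 0 || kappa_persist < 0) bad("concentrations must be >= 0")
  if (mix_weight < 0 || mix_weight > 1) bad("mix_weight must be in [0, 1]")
  structure(list(n_cells = as.integer(n_cells), n_steps = as.integer(n_steps),
                 dt = dt, speed_mean = speed_mean, speed_shape = speed_shape,
                 kappa_bias = kappa_bias, kappa_persist = kappa_persist,
                 target_angle = target_angle, mix_weight = mix_weight,
                 condition = condition, seed = as.integer(seed)),
            class = "etx_walk_config")
}

#' Simulate biased persistent random-walk trajectories
#'
#' Generates a track table with the statistical structure electrotaxis
#' analysis assumes: directional bias toward a target angle, persistence
#' of heading, gamma-distributed step speeds. Cells start at the origin;
#' the initial reference heading is the target angle plus a uniform
#' deviate, so with zero bias the ensemble is isotropic while rotating
#' \code{target_angle} rotates the whole process exactly (matched seeds).
#'
#' @param cfg An \code{etx_walk_config}.
#' @return An \code{etx_tracks} table (frames 0..n_steps, times in hours,
#'   positions in um).
#' @export
simulate_walks <- function(cfg) {
  if (!inherits(cfg, "etx_walk_config"))
    stop("walk config error: not an etx_walk_config", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_cells)
  ns <- cfg$n_steps
  res <- vector("list", cfg$n_cells)
  wp <- (1 - cfg$mix_weight) * cfg$kappa_persist   # persistence weight-conc.
  for (i in seq_len(cfg$n_cells)) {
    set.seed(cell_seeds[i])
    speeds <- stats::rgamma(ns, shape = cfg$speed_shape,
                            scale = cfg$speed_mean / cfg$speed_shape)
    prev <- wrap_angle(cfg$target_angle + stats::runif(1, -pi, pi))
    if (wp < 1e-12) {
      # no persistence: headings are i.i.d. von Mises, draw vectorized
      head <- rvonmises(ns, cfg$target_angle,
                        cfg$mix_weight * cfg$kappa_bias)
      step <- speeds * cfg$dt
      res[[i]] <- data.frame(
        cell_id = sprintf("cell%05d", i), frame = 0:ns,
        time_h = (0:ns) * cfg$dt,
        x = c(0, cumsum(step * cos(head))),
        y = c(0, cumsum(step * sin(head))),
        viewfield = "sim", condition = cfg$condition,
        stringsAsFactors = FALSE)
      next
    }
    head <- numeric(ns)
    for (t in seq_len(ns)) {
      C <- cfg$mix_weight * cfg$kappa_bias * cos(cfg$target_angle) +
        (1 - cfg$mix_weight) * cfg$kappa_persist * cos(prev)
      S <- cfg$mix_weight * cfg$kappa_bias * sin(cfg$target_angle) +
        (1 - cfg$mix_weight) * cfg$kappa_persist * sin(prev)
      k_eff <- sqrt(C^2 + S^2)
      mu <- if (k_eff > 1e-12) atan2(S, C) else 0
      head[t] <- rvonmises(1L, mu, k_eff)
      prev <- head[t]
    }
    step <- speeds * cfg$dt
    x <- c(0, cumsum(step * cos(head)))
    y <- c(0, cumsum(step * sin(head)))
    res[[i]] <- data.frame(
      cell_id = sprintf("cell%05d", i), frame = 0:ns,
      time_h = (0:ns) * cfg$dt, x = x, y = y,
      viewfield = "sim", condition = cfg$condition,
      stringsAsFactors = FALSE)
  }
  tracks(do.call(rbind, res), frame_interval = cfg$dt * 60)
}

#' Per-step headings of simulated walks
#'
#' Utility for simulator diagnostics: the heading angle of every step of
#' every trajectory in a track table.
#'
#' @param tk An \code{etx_tracks} table.
#' @return Numeric vector of step headings in (-pi, pi].
#' @export
step_headings <- function(tk) {
  trs <- split_tracks(tk)
  unlist(lapply(trs, function(tr) {
    atan2(diff(tr$y), diff(tr$x))
  }), use.names = FALSE)
}

#' Two independent uniform circular samples
#'
#' Null-model fixture for two-sample directional tests: both samples are
#' drawn from the same uniform distribution on the circle.
#'
#' @param n1,n2 Sample sizes (>= 2).
#' @param seed Seed for reproducibility.
#' @return List of two \code{etx_angles} sets, \code{a} and \code{b}.
#' @export
make_null_pair <- function(n1, n2, seed = 1L) {
  if (n1 < 2 || n2 < 2) stop("sample sizes must be >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  list(a = angle_set(stats::runif(n1, -pi, pi)),
       b = angle_set(stats::runif(n2, -pi, pi)))
}
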