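#' A set of angles for circular statistics
#'
#' Directional angles live on (-pi, pi]; axial angles (undirected lines,
#' e.g. cell long axes) live on [0, pi) and are doubled before any
#' circular operation. Axial and directional sets are never mixed.
#'
#' @param angles Numeric, radians.
#' @param axial Logical: axial (undirected) data?
#' @return An \code{etx_angles} object.
#' @export
angle_set <- function(angles, axial = FALSE) {
  angles <- as.numeric(angles)
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("angles must be finite", call. = FALSE)
  angles <- if (axial) angles %% pi else wrap_angle(angles)
  structure(list(angles = angles, axial = axial, n = length(angles)),
            class = "etx_angles")
}

#' @export
print.etx_angles <- function(x, ...) {
  cat(sprintf("%s angle set, n = %d\n",
              if (x$axial) "Axial" else "Directional", x$n))
  invisible(x)
}

#' Displacement angles relative to the field vector
#'
#' Converts each cell's net (first-to-last) X-Y displacement into an angle
#' relative to the anode-to-cathode field direction via the two-argument
#' arctangent: 0 means movement along the field (cathodal), pi against it.
#' Cells with zero net displacement carry no direction and are excluded
#' with a warning.
#'
#' @param tk An \code{etx_tracks} table (or the data.frame from
#'   \code{\link{net_displacement}}).
#' @param field An \code{etx_field} vector.
#' @return A directional \code{etx_angles} set, with attribute
#'   \code{n_excluded}.
#' @export
displacement_angles <- function(tk, field) {
  nd <- if (inherits(tk, "etx_tracks")) net_displacement(tk) else tk
  zero <- nd$net_distance == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero net displacement excluded",
            call. = FALSE)
  nd <- nd[!zero, , drop = FALSE]
  if (nrow(nd) == 0) {
    warning("all displacements zero: empty angle set", call. = FALSE)
    out <- angle_set(numeric(0))
  } else {
    fx <- field$direction[1]; fy <- field$direction[2]
    ang <- atan2(fx * nd$dy - fy * nd$dx, fx * nd$dx + fy * nd$dy)
    out <- angle_set(ang)
  }
  attr(out, "n_excluded") <- sum(zero)
  out
}

#' Mean resultant vector
#'
#' The vector average of unit direction vectors: its length r in [0, 1]
#' measures directional concentration and its argument is the mean
#' direction. Axial sets are doubled first and the mean angle halved back
#' onto [0, pi). If r = 0 the mean angle is undefined (NA, flagged).
#'
#' @param a An \code{etx_angles} set with n >= 1.
#' @return List with \code{r}, \code{mean_angle}, \code{n},
#'   \code{defined}.
#' @export
resultant_vector <- function(a) {
  stopifnot(inherits(a, "etx_angles"))
  if (a$n < 1) stop("empty angle set", call. = FALSE)
  th <- if (a$axial) 2 * a$angles else a$angles
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  if (r < 1e-12) {
    list(r = 0, mean_angle = NA_real_, n = a$n, defined = FALSE)
  } else {
    mu <- atan2(S, C)
    if (a$axial) mu <- (mu / 2) %% pi else mu <- wrap_angle(mu)
    list(r = r, mean_angle = mu, n = a$n, defined = TRUE)
  }
}

#' Rose histogram of directions
#'
#' Frequency counts of angles in equal circular bins, the first bin
#' centred on 0 rad (the field direction). Bins are half-open
#' [centre - w/2, centre + w/2) with w = 2*pi/n_bins; counts always sum
#' to n.
#'
#' @param a An \code{etx_angles} set (directional).
#' @param n_bins Number of bins (integer >= 2).
#' @return Data.frame with bin_center, lower, upper (radians), count.
#' @export
rose_histogram <- function(a, n_bins = 12L) {
  stopifnot(inherits(a, "etx_angles"))
  if (length(n_bins) != 1 || n_bins < 2 || n_bins != round(n_bins))
    stop("config error: n_bins must be an integer >= 2", call. = FALSE)
  w <- 2 * pi / n_bins
  centers <- (seq_len(n_bins) - 1) * w
  counts <- integer(n_bins)
  if (a$n > 0) {
    shifted <- (a$angles + w / 2) %% (2 * pi)
    idx <- floor(shifted / w) + 1L
    idx[idx > n_bins] <- 1L          # guard against %% rounding at 2*pi
    tab <- tabulate(idx, nbins = n_bins)
    counts <- tab
  }
  data.frame(bin_center = wrap_angle(centers),
             lower = wrap_angle(centers - w / 2),
             upper = wrap_angle(centers + w / 2),
             count = counts)
}

#' Mardia-Watson-Wheeler two-sample test
#'
#' Non-parametric uniform-scores test of whether two samples of
#' directions come from the same circular distribution (equal migration
#' tendency). The pooled sample is ranked around the circle, each angle
#' replaced by its uniform score beta = 2*pi*rank/N, and the statistic
#'
#'   W = 2 * sum_j (C_j^2 + S_j^2) / n_j,
#'
#' with C_j, S_j the resultant components of sample j's scores, is
#' asymptotically chi-square with 2 degrees of freedom under the null
#' (survival function exp(-W/2)). The asymptotic p-value is flagged
#' unreliable when min(n1, n2) < 10; a permutation p-value from random
#' relabellings is available and reported as (b + 1)/(B + 1). Ties are
#' broken by infinitesimal random jitter under \code{seed}.
#'
#' @param a,b Directional \code{etx_angles} sets with n >= 2.
#' @param n_permutations Number of random relabellings (0 = asymptotic
#'   only; default 10000 when requested via \code{permutation = TRUE}).
#' @param seed Seed for jitter and permutations.
#' @return An \code{etx_mww} list: W, p_asymptotic, p_permutation (or NA),
#'   n1, n2, n_permutations, asymptotic_reliable.
#' @export
mww_test <- function(a, b, n_permutations = 0L, seed = 1L) {
  stopifnot(inherits(a, "etx_angles"), inherits(b, "etx_angles"))
  if (a$axial || b$axial)
    stop("mww_test expects directional sets; double axial data upstream",
         call. = FALSE)
  n1 <- a$n; n2 <- b$n; N <- n1 + n2
  if (n1 < 2 || n2 < 2)
    stop("sample-size error: both samples need n >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pooled <- c(a$angles, b$angles) %% (2 * pi)
  while (anyDuplicated(pooled))
    pooled <- (pooled + stats::runif(N, 0, 1e-9)) %% (2 * pi)
  beta <- 2 * pi * rank(pooled) / N
  cb <- cos(beta); sb <- sin(beta)
  stat <- function(idx1) {
    C1 <- sum(cb[idx1]); S1 <- sum(sb[idx1])
    C2 <- sum(cb) - C1;  S2 <- sum(sb) - S1
    2 * ((C1^2 + S1^2) / n1 + (C2^2 + S2^2) / n2)
  }
  W <- stat(seq_len(n1))
  p_asym <- stats::pchisq(W, df = 2, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_permutations > 0) {
    Wp <- vapply(seq_len(n_permutations),
                 function(i) stat(sample.int(N, n1)), numeric(1))
    p_perm <- (sum(Wp >= W - 1e-12) + 1) / (n_permutations + 1)
  }
  structure(list(W = W, p_asymptotic = p_asym, p_permutation = p_perm,
                 n1 = n1, n2 = n2, n_permutations = as.integer(n_permutations),
                 asymptotic_reliable = min(n1, n2) >= 10),
            class = "etx_mww")
}

#' Asymptotic p-value for a Mardia-Watson-Wheeler statistic
#'
#' Chi-square (2 df) survival function, which for this statistic reduces
#' to the closed form exp(-W/2).
#'
#' @param W Test statistic (>= 0).
#' @return P-value in [0, 1].
#' @export
mww_asymptotic_p <- function(W) stats::pchisq(W, df = 2, lower.tail = FALSE)

#' @export
print.etx_mww <- function(x, ...) {
  cat(sprintf("Mardia-Watson-Wheeler test: W = %.4f (n1 = %d, n2 = %d)\n",
              x$W, x$n1, x$n2))
  cat(sprintf("  asymptotic p (chi-sq, 2 df) = %.4g%s\n", x$p_asymptotic,
              if (!x$asymptotic_reliable) " [unreliable: min n < 10]" else ""))
  if (!is.na(x$p_permutation))
    cat(sprintf("  permutation p (%d relabellings) = %.4g\n",
                x$n_permutations, x$p_permutation))
  invisible(x)
}

#' Rose plot of a directional sample
#'
#' Base-graphics angle histogram (frequencies, matching the convention of
#' electrotaxis figures) with the mean resultant vector drawn as an
#' arrow when defined.
#'
#' @param a Directional \code{etx_angles} set.
#' @param n_bins Number of bins.
#' @param main Plot title.
#' @return The rose histogram data.frame, invisibly.
#' @export
plot_rose <- function(a, n_bins = 12L, main = "") {
  h <- rose_histogram(a, n_bins)
  maxc <- max(h$count, 1)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  w <- 2 * pi / n_bins
  for (i in seq_len(nrow(h))) {
    if (h$count[i] == 0) next
    rad <- h$count[i] / maxc
    th <- seq(h$bin_center[i] - w / 2, h$bin_center[i] + w / 2,
              length.out = 20)
    graphics::polygon(c(0, rad * cos(th)), c(0, rad * sin(th)),
                      col = "grey40", border = "white")
  }
  rv <- resultant_vector(a)
  if (rv$defined)
    graphics::arrows(0, 0, rv$r * cos(rv$mean_angle),
                     rv$r * sin(rv$mean_angle),
                     col = "red", lwd = 2, length = 0.1)
  invisible(h)
}
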