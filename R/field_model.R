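#' A rectangular microchannel segment
#'
#' Geometry and material properties of one medium-filled channel segment,
#' in SI units. Defaults are those of MEMalpha + 10% FBS culture medium
#' (conductivity 1.536 S/m, dynamic viscosity 0.946 mPa s). By convention
#' height <= width (the shallow dimension is the height), which the
#' hydraulic formula assumes.
#'
#' @param length,width,height Segment dimensions, metres (> 0).
#' @param conductivity Electrical conductivity, S/m.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return An \code{etx_segment}.
#' @export
channel_segment <- function(length, width, height,
                            conductivity = 1.536, viscosity = 0.946e-3) {
  v <- c(length, width, height, conductivity, viscosity)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("invalid segment: all dimensions/properties must be > 0",
         call. = FALSE)
  structure(list(length = length, width = width, height = height,
                 conductivity = conductivity, viscosity = viscosity),
            class = "etx_segment")
}

#' Electrical resistance of a channel segment
#'
#' Uniform conduction through the medium: R = L / (sigma * w * h).
#'
#' @param seg An \code{etx_segment}.
#' @return Resistance in ohms.
#' @export
electrical_resistance <- function(seg) {
  stopifnot(inherits(seg, "etx_segment"))
  seg$length / (seg$conductivity * seg$width * seg$height)
}

#' Hydraulic resistance of a rectangular channel
#'
#' Wide-rectangular-duct approximation for creeping flow:
#' R_h = 12 * mu * L / (w * h^3 * (1 - 0.63 * h / w)), valid for
#' h <= w. Shallow interconnecting channels therefore present orders of
#' magnitude more hydraulic resistance than tall main channels, which is
#' what confines convective cross-talk in multi-field chips.
#'
#' @param seg An \code{etx_segment} with height <= width.
#' @return Hydraulic resistance in Pa s / m^3.
#' @export
hydraulic_resistance <- function(seg) {
  stopifnot(inherits(seg, "etx_segment"))
  if (seg$height > seg$width)
    stop("convention error: height > width; swap the two dimensions",
         call. = FALSE)
  12 * seg$viscosity * seg$length /
    (seg$width * seg$height^3 * (1 - 0.63 * seg$height / seg$width))
}

#' A resistive channel network
#'
#' Lumped model of a microfluidic chip's electrical pathways: nodes
#' joined by resistive edges (direct ohms or channel segments), driven by
#' a current or voltage source between two terminals, with one node
#' grounded.
#'
#' @param edges Data.frame with columns from, to and either resistance
#'   (ohms) or segment (list of \code{etx_segment}).
#' @param source List: \code{type} ("current" or "voltage"),
#'   \code{value} (A or V), \code{pos} node (injection/high terminal).
#' @param ground Name of the reference node (0 V; the source's return
#'   terminal).
#' @return An \code{etx_network}.
#' @export
channel_network <- function(edges, source = list(type = "current", value = 1e-3,
                                                 pos = NULL),
                            ground = NULL) {
  if (is.null(edges$resistance)) {
    if (is.null(edges$segment))
      stop("edges need a resistance or segment column", call. = FALSE)
    edges$resistance <- vapply(edges$segment, electrical_resistance,
                               numeric(1))
  }
  if (any(!is.finite(edges$resistance)) || any(edges$resistance <= 0))
    stop("all resistances must be finite and > 0", call. = FALSE)
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(source$pos)) source$pos <- nodes[1]
  if (is.null(ground)) ground <- nodes[length(nodes)]
  if (!source$pos %in% nodes || !ground %in% nodes)
    stop("source/ground must name existing nodes", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, source = source,
                 ground = ground), class = "etx_network")
}

# breadth-first reachability on the undirected edge list
.reachable <- function(net, start) {
  seen <- start
  repeat {
    nb <- unique(c(net$edges$to[net$edges$from %in% seen],
                   net$edges$from[net$edges$to %in% seen]))
    new <- setdiff(nb, seen)
    if (!length(new)) return(seen)
    seen <- c(seen, new)
  }
}

#' Solve a channel network by nodal analysis
#'
#' Assembles the conductance Laplacian and solves Kirchhoff's equations
#' for the node potentials; edge currents follow from Ohm's law. For a
#' current source, \code{value} amperes enter at \code{pos} and leave at
#' ground; for a voltage source, \code{pos} is held at \code{value}
#' volts against ground and the delivered current is reported.
#'
#' @param net An \code{etx_network}.
#' @return List: \code{potentials} (named V), \code{currents} data.frame
#'   (from, to, resistance, current A, positive from -> to),
#'   \code{source_current} (A), \code{kcl_residual} (max relative
#'   current imbalance over non-terminal nodes).
#' @export
solve_network <- function(net) {
  stopifnot(inherits(net, "etx_network"))
  if (!net$ground %in% .reachable(net, net$source$pos))
    stop("singular-network error: source and ground are not connected",
         call. = FALSE)
  nodes <- net$nodes
  n <- length(nodes)
  G <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$from[k]; j <- net$edges$to[k]
    g <- 1 / net$edges$resistance[k]
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
  }
  V <- stats::setNames(numeric(n), nodes)
  if (net$source$type == "current") {
    b <- stats::setNames(numeric(n), nodes)
    b[net$source$pos] <- net$source$value
    b[net$ground] <- -net$source$value
    free <- setdiff(nodes, net$ground)
    V[free] <- solve(G[free, free, drop = FALSE], b[free])
    src_I <- net$source$value
  } else if (net$source$type == "voltage") {
    fixed <- c(net$source$pos, net$ground)
    V[net$source$pos] <- net$source$value
    free <- setdiff(nodes, fixed)
    if (length(free))
      V[free] <- solve(G[free, free, drop = FALSE],
                       -G[free, fixed, drop = FALSE] %*% V[fixed])
    src_I <- sum((V[net$source$pos] - V[net$edges$to[net$edges$from ==
                    net$source$pos]]) /
                   net$edges$resistance[net$edges$from == net$source$pos]) +
      sum((V[net$source$pos] - V[net$edges$from[net$edges$to ==
             net$source$pos]]) /
            net$edges$resistance[net$edges$to == net$source$pos])
  } else stop("unknown source type", call. = FALSE)
  cur <- data.frame(from = net$edges$from, to = net$edges$to,
                    resistance = net$edges$resistance,
                    current = (V[net$edges$from] - V[net$edges$to]) /
                      net$edges$resistance,
                    stringsAsFactors = FALSE)
  rownames(cur) <- NULL
  # KCL residual at every non-terminal node, relative to the network's
  # dominant current (local scales collapse on dangling zero-current limbs)
  scale <- max(abs(cur$current), abs(src_I), 1e-300)
  resid <- 0
  for (nd in setdiff(nodes, c(net$source$pos, net$ground))) {
    inn <- sum(cur$current[cur$to == nd]) - sum(cur$current[cur$from == nd])
    resid <- max(resid, abs(inn) / scale)
  }
  list(potentials = V, currents = cur, source_current = src_I,
       kcl_residual = resid)
}

#' Build an n-rung R-2R-style ladder network
#'
#' Generic helper for multi-field chip topologies: a rail of series
#' resistances whose junctions are tied through shunt rungs to a return
#' conductor, driven from one rail end. With series arms R, rungs 2R, a
#' 2R termination and an ideal (bus) return this is the classic R-2R
#' ladder whose successive rung currents halve exactly, producing the
#' graded field strengths multi-field chips exploit. A resistive return
#' rail (\code{r_return > 0}) models real chips, where the grading
#' deviates from exact powers of two.
#'
#' @param n_rungs Number of rungs (>= 1).
#' @param r_series Series arm resistance between junctions, ohms.
#' @param r_shunt Rung resistance, ohms (default 2 * r_series).
#' @param r_return Return-rail series resistance per span (0 = ideal bus).
#' @param terminate Add the terminating r_shunt at the junction farthest
#'   from the source (required for the exact powers-of-two grading).
#' @return An \code{etx_network}; junctions T1 (far end) .. Tn (source),
#'   return/ground node REF (B1..Bn when \code{r_return > 0}).
#' @export
r2r_ladder <- function(n_rungs, r_series, r_shunt = 2 * r_series,
                       r_return = 0, terminate = TRUE) {
  stopifnot(n_rungs >= 1, r_series > 0, r_shunt > 0, r_return >= 0)
  bus <- r_return == 0
  bnode <- function(k) if (bus) "REF" else sprintf("B%d", k)
  e <- list()
  for (k in seq_len(n_rungs)) {
    e[[length(e) + 1]] <- data.frame(from = sprintf("T%d", k),
                                     to = bnode(k), resistance = r_shunt)
    if (k > 1) {
      e[[length(e) + 1]] <- data.frame(from = sprintf("T%d", k - 1),
                                       to = sprintf("T%d", k),
                                       resistance = r_series)
      if (!bus)
        e[[length(e) + 1]] <- data.frame(from = bnode(k - 1), to = bnode(k),
                                         resistance = r_return)
    }
  }
  if (terminate)
    e[[length(e) + 1]] <- data.frame(from = "T1", to = bnode(1),
                                     resistance = r_shunt)
  channel_network(do.call(rbind, e),
                  source = list(type = "current", value = 1e-3,
                                pos = sprintf("T%d", n_rungs)),
                  ground = bnode(n_rungs))
}

#' Electric field strength in channel sections
#'
#' Converts the current through each section's channel into a field
#' strength: EFS = I / (sigma * w * h), the current density divided by
#' the conductivity.
#'
#' @param currents Numeric currents (A), one per section, or the
#'   \code{currents} data.frame from \code{\link{solve_network}}.
#' @param segments List of \code{etx_segment}, one per section.
#' @param section_ids Optional section labels (default I, II, ...).
#' @return Data.frame: section_id, current, efs (V/m, magnitude).
#' @export
section_efs <- function(currents, segments, section_ids = NULL) {
  I <- if (is.data.frame(currents)) currents$current else as.numeric(currents)
  if (length(segments) != length(I))
    stop("one segment per section current required", call. = FALSE)
  area <- vapply(segments, function(s) {
    stopifnot(inherits(s, "etx_segment"))
    a <- s$width * s$height
    if (a <= 0) stop("invalid segment: zero cross-section", call. = FALSE)
    a
  }, numeric(1))
  sig <- vapply(segments, function(s) s$conductivity, numeric(1))
  if (is.null(section_ids))
    section_ids <- as.character(utils::as.roman(seq_along(I)))
  data.frame(section_id = section_ids, current = I,
             efs = abs(I) / (sig * area), stringsAsFactors = FALSE)
}

#' Scale a field-strength ratio to a maximum value
#'
#' Multi-field chips are characterised by the ratio of section field
#' strengths (e.g. 5.25 : 2.5 : 1 : 0); the absolute values follow from
#' scaling the largest section to the intended maximum EFS. Ratios are
#' preserved exactly.
#'
#' @param ratio Non-negative numeric ratio vector.
#' @param max_efs The field strength of the largest section, V/m (>= 0).
#' @return Absolute field strengths, V/m.
#' @export
scale_to_max <- function(ratio, max_efs) {
  if (any(ratio < 0) || max_efs < 0)
    stop("ratio and max_efs must be >= 0", call. = FALSE)
  top <- max(ratio)
  if (top == 0) return(rep(0, length(ratio)))
  ratio / top * max_efs
}
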