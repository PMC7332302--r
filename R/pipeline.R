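#' Mean with a 95% confidence half-width
#'
#' The reporting convention of electrotaxis studies: mean plus/minus
#' multiplier times the standard error of the mean, with multiplier 1.96
#' for a normal-approximation 95% interval (used at every n, not a
#' t-quantile).
#'
#' @param values Numeric vector, n >= 2.
#' @param multiplier SEM multiplier (default 1.96).
#' @return List: \code{mean}, \code{half_width}, \code{n}.
#' @export
ci95 <- function(values, multiplier = 1.96) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("undefined CI: need at least 2 values", call. = FALSE)
  list(mean = mean(values),
       half_width = multiplier * stats::sd(values) / sqrt(n), n = n)
}

#' Keep only cells tracked through every frame
#'
#' A trajectory is retained iff it has an observation at every frame
#' index of its viewfield's frame range (by default the [min, max] of
#' frames present in that viewfield). This removes cells that enter,
#' leave, divide or die during the acquisition, which would otherwise
#' bias endpoint statistics.
#'
#' @param tk An \code{etx_tracks} table.
#' @param frame_range Optional integer c(first, last) applied to every
#'   viewfield, or a named list per viewfield.
#' @return List: \code{tracks} (retained \code{etx_tracks}),
#'   \code{excluded} data.frame (viewfield, cell_id, n_missing),
#'   \code{n_in}, \code{n_out}.
#' @export
filter_complete_tracks <- function(tk, frame_range = NULL) {
  if (nrow(tk) == 0)
    return(list(tracks = tk,
                excluded = data.frame(viewfield = character(0),
                                      cell_id = character(0),
                                      n_missing = integer(0)),
                n_in = 0L, n_out = 0L))
  keep_rows <- logical(nrow(tk))
  excl <- list()
  n_in <- 0L
  for (vf in unique(tk$viewfield)) {
    sel <- tk$viewfield == vf
    rng <- if (is.list(frame_range)) frame_range[[vf]] else frame_range
    if (is.null(rng)) rng <- range(tk$frame[sel])
    wanted <- seq(rng[1], rng[2])
    for (cid in unique(tk$cell_id[sel])) {
      csel <- sel & tk$cell_id == cid
      n_in <- n_in + 1L
      missing <- setdiff(wanted, tk$frame[csel])
      if (length(missing) == 0) {
        keep_rows <- keep_rows | csel
      } else {
        excl[[length(excl) + 1]] <- data.frame(
          viewfield = vf, cell_id = cid, n_missing = length(missing),
          stringsAsFactors = FALSE)
      }
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl)
              else data.frame(viewfield = character(0),
                              cell_id = character(0), n_missing = integer(0))
  out <- tk[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tk)
  list(tracks = out, excluded = excluded, n_in = n_in,
       n_out = n_in - nrow(excluded))
}

#' Compare a metric (or angle sets) between two groups
#'
#' Scalar metrics are compared with a two-tailed Welch t-test; angle sets
#' with the Mardia-Watson-Wheeler test. Degenerate (zero-variance) scalar
#' input is handled by an exact-equality fast path rather than a failing
#' t-test.
#'
#' @param a,b Numeric vectors or directional \code{etx_angles} sets.
#' @param n_permutations Permutations for the MWW branch.
#' @param seed Seed for the MWW branch.
#' @return For scalars: list(statistic, p_value, df, method); for angles:
#'   an \code{etx_mww}.
#' @export
compare_groups <- function(a, b, n_permutations = 0L, seed = 1L) {
  if (inherits(a, "etx_angles") && inherits(b, "etx_angles"))
    return(mww_test(a, b, n_permutations = n_permutations, seed = seed))
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("need n >= 2 per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df = NA_real_, method = "degenerate-variance exact equality"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = "Welch two-sample t-test")
}

#' One-way ANOVA with Tukey post-hoc across several groups
#'
#' Routine multi-group comparison, delegated to \code{stats::aov} and
#' \code{stats::TukeyHSD}.
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @return List: \code{anova} (df, F, p), \code{tukey} (pairwise table).
#' @export
compare_many <- function(groups) {
  if (length(groups) < 3) stop("use compare_groups for two groups",
                               call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  list(anova = list(df_between = an$Df[1], df_within = an$Df[2],
                    F = an$`F value`[1], p_value = an$`Pr(>F)`[1]),
       tukey = as.data.frame(stats::TukeyHSD(fit)$group))
}

#' Load an experiment configuration
#'
#' Reads a YAML experiment description: a list of conditions (each with a
#' label, a track source — a CSV path or a \code{simulate} block of
#' \code{\link{walk_config}} fields — field direction and strength),
#' calibration keys, filter settings and statistics settings.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return Validated config list of class \code{etx_experiment_config}.
#' @export
experiment_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("config error: no conditions", call. = FALSE)
  labels <- vapply(cfg$conditions, function(cd) as.character(cd$label),
                   character(1))
  if (anyDuplicated(labels))
    stop("config error: condition labels must be unique", call. = FALSE)
  cfg$frame_interval <- cfg$frame_interval %||% 10
  cfg$filters <- cfg$filters %||% list()
  cfg$filters$completeness <- cfg$filters$completeness %||% TRUE
  cfg$filters$min_cells <- cfg$filters$min_cells %||% 100L
  if (cfg$filters$min_cells < 1)
    stop("config error: min_cells must be >= 1", call. = FALSE)
  cfg$statistics <- cfg$statistics %||% list()
  cfg$statistics$ci_multiplier <- cfg$statistics$ci_multiplier %||% 1.96
  cfg$statistics$mww_permutations <- cfg$statistics$mww_permutations %||% 0L
  cfg$statistics$seed <- cfg$statistics$seed %||% 1L
  class(cfg) <- "etx_experiment_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.condition_tracks <- function(cd, frame_interval, seed) {
  if (!is.null(cd$simulate)) {
    args <- cd$simulate
    args$condition <- cd$label
    if (is.null(args$seed)) args$seed <- seed
    simulate_walks(do.call(walk_config, args))
  } else if (!is.null(cd$tracks)) {
    if (!file.exists(cd$tracks))
      stop("missing source for condition '", cd$label, "': ", cd$tracks,
           call. = FALSE)
    cal <- calibration(pixel_pitch = 1, frame_interval = frame_interval)
    read_tracks(cd$tracks, cal, unit_mode = cd$unit_mode %||% "um")
  } else stop("condition '", cd$label, "' has neither tracks nor simulate",
              call. = FALSE)
}

#' Run a full electrotaxis analysis
#'
#' Orchestrates one experiment from a config: load or simulate each
#' condition's tracks, apply the complete-track filter, compute per-cell
#' metrics, summarise each group as mean +/- CI with its resultant
#' vector, run pairwise Mardia-Watson-Wheeler comparisons of displacement
#' angles, and (optionally) write per-cell CSVs, a group-summary CSV,
#' rose-histogram CSVs and a JSON report with provenance (config hash,
#' seed, package version). Deterministic given config + seed.
#'
#' @param cfg An \code{etx_experiment_config} (or path / list accepted by
#'   \code{\link{experiment_config}}).
#' @param out_dir Output directory (NULL = return results only).
#' @return List: \code{summary} data.frame (one row per condition),
#'   \code{comparisons} data.frame (pairwise MWW), \code{per_cell} list,
#'   \code{rose} list, \code{filter_log} list, \code{provenance}.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "etx_experiment_config")) cfg <- experiment_config(cfg)
  seed <- cfg$statistics$seed
  mult <- cfg$statistics$ci_multiplier
  labels <- vapply(cfg$conditions, function(cd) as.character(cd$label),
                   character(1))
  per_cell <- list(); angles <- list(); rose <- list(); flog <- list()
  summary_rows <- list()
  for (k in seq_along(cfg$conditions)) {
    cd <- cfg$conditions[[k]]
    fld <- field_vector(unlist(cd$field$direction %||% c(1, 0)),
                        cd$field$strength %||% 0)
    tk <- .condition_tracks(cd, cfg$frame_interval, seed + k)
    if (isTRUE(cfg$filters$completeness)) {
      fl <- filter_complete_tracks(tk)
      tk <- fl$tracks
      flog[[cd$label]] <- list(n_in = fl$n_in, n_out = fl$n_out,
                               n_excluded = nrow(fl$excluded))
    }
    dd <- directedness(tk, fld)
    sp <- speeds(tk)
    ang <- displacement_angles(tk, fld)
    rv <- resultant_vector(ang)
    pc <- merge(dd$per_cell, sp$per_cell,
                by = c("cell_id", "viewfield", "condition"))
    per_cell[[cd$label]] <- pc
    angles[[cd$label]] <- ang
    rose[[cd$label]] <- rose_histogram(ang, cfg$statistics$rose_bins %||% 12L)
    cd_ci <- ci95(dd$per_cell$cos_phi, mult)
    sp_ci <- ci95(sp$per_cell$speed, mult)
    summary_rows[[k]] <- data.frame(
      label = cd$label, n_cells = dd$n, efs = fld$strength,
      directedness = cd_ci$mean, directedness_ci = cd_ci$half_width,
      speed = sp_ci$mean, speed_ci = sp_ci$half_width,
      r = rv$r, mean_angle = rv$mean_angle,
      low_n = dd$n < cfg$filters$min_cells,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  comps <- list()
  if (length(labels) > 1) {
    pairs <- utils::combn(labels, 2)
    for (j in seq_len(ncol(pairs))) {
      la <- pairs[1, j]; lb <- pairs[2, j]
      mw <- mww_test(angles[[la]], angles[[lb]],
                     n_permutations = cfg$statistics$mww_permutations,
                     seed = seed)
      tt <- compare_groups(per_cell[[la]]$cos_phi, per_cell[[lb]]$cos_phi)
      comps[[j]] <- data.frame(
        group_a = la, group_b = lb, mww_W = mw$W,
        mww_p = mw$p_asymptotic, mww_p_perm = mw$p_permutation,
        directedness_t_p = tt$p_value, stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    data.frame(group_a = character(0), group_b = character(0))
  prov <- list(package = "etaxis",
               version = as.character(utils::packageVersion("etaxis")),
               seed = seed, config_hash = .config_hash(cfg))
  res <- list(summary = summary, comparisons = comparisons,
              per_cell = per_cell, rose = rose, filter_log = flog,
              provenance = prov)
  if (!is.null(out_dir)) .write_report(res, out_dir)
  res
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (cc in names(df))
      if (is.numeric(df[[cc]]))
        df[[cc]] <- formatC(df[[cc]], digits = 10, format = "g")
    df
  }
  utils::write.csv(fmt(res$summary), file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(res$comparisons),
                   file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE, quote = FALSE)
  for (lab in names(res$per_cell)) {
    utils::write.csv(fmt(res$per_cell[[lab]]),
                     file.path(out_dir, paste0("per_cell_", lab, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(fmt(res$rose[[lab]]),
                     file.path(out_dir, paste0("rose_", lab, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(provenance = res$provenance, filter_log = res$filter_log,
         summary = res$summary, comparisons = res$comparisons),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
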