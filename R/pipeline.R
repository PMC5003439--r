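# End-to-end pipeline: read -> QC metrics -> degradation -> normalization/
# PCA -> flags -> circular plot + Circos export, plus the run configuration
# and the machine-readable per-array report.

#' Assemble the per-array QC report
#'
#' Runs every QC stage on an in-memory batch: zonal background/noise,
#' control signals, degradation profile and slope, quantile-normalized
#' median-polish expression with mean-centred PCA, outlier flags,
#' degradation colors and the display order.
#'
#' @param batch An [intensity_batch()].
#' @param annotation The matching [probe_annotation()].
#' @param geometry A [chip_geometry()].
#' @param manifest A [control_manifest()].
#' @param thresholds A [qc_thresholds()] list.
#' @return A `QCReport` list: `array_names`, `metrics` (one data-frame row
#'   per array), `bg_noise`, `signals`, `profile`, `degradation`, `pca`,
#'   `variance_explained`, `flags`, `colors`, `order`, `thresholds`.
#' @export
qc_report <- function(batch, annotation, geometry, manifest,
                      thresholds = qc_thresholds()) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      e$message <- sprintf("[stage %s] %s", what, conditionMessage(e))
      stop(e)
    })
    message(sprintf("qccircos: %-18s %6.2fs (%d arrays)", what,
                    proc.time()[["elapsed"]] - t1, n_arrays(batch)))
    res
  }

  bgn <- stage("background/noise", batch_background_noise(
    batch, annotation, geometry,
    grid_k = thresholds$grid_k, low_fraction = thresholds$low_fraction))
  signals <- stage("control signals", control_signals(
    batch, annotation, manifest,
    tau = thresholds$tau, alpha1 = thresholds$alpha1, alpha2 = thresholds$alpha2))
  profile <- stage("degradation", degradation_profile(
    batch, annotation, k = thresholds$degradation_k))
  deg <- degradation_slope(profile)
  expr <- stage("normalization", normalize_expression(batch, annotation))
  pca <- stage("PCA", pca_scores(expr, n_components = 2L))
  flags <- flag_arrays(bgn, signals, deg, thresholds)
  colors <- degradation_colors(stats::setNames(deg$slope, deg$array))
  ord <- display_order(deg$slope, batch$array_names)

  metrics <- data.frame(
    array = batch$array_names,
    avg_background = bgn$avg_background,
    avg_noise = bgn$avg_noise,
    hk_ratio_actin = signals$hk_ratios[, "actin"],
    hk_ratio_gapdh = signals$hk_ratios[, "gapdh"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (s in 1:3) metrics[[paste0("spike_", s, "_call")]] <- signals$spike_calls[, s]
  for (i in seq_along(POLYA_NAMES))
    metrics[[paste0("polya_", POLYA_NAMES[i], "_log2")]] <- signals$polya_signals[, i]
  metrics$deg_slope <- deg$slope
  metrics$deg_t <- deg$t_stat
  metrics$pc1 <- pca$scores[, 1]
  metrics$pc2 <- pca$scores[, 2]
  metrics$flag_background <- flags$bg_noise[, "background"]
  metrics$flag_noise <- flags$bg_noise[, "noise"]
  metrics$flag_actin <- flags$hk[, "actin"]
  metrics$flag_gapdh <- flags$hk[, "gapdh"]
  for (s in 1:3) metrics[[paste0("flag_spike_", s)]] <- flags$spike[, s]
  for (i in seq_along(POLYA_NAMES))
    metrics[[paste0("flag_polya_", POLYA_NAMES[i])]] <- flags$polya[, i]
  metrics$flag_degradation <- flags$degradation
  metrics$degradation_color <- rgb_hex(colors)

  message(sprintf("qccircos: report ready in %.2fs",
                  proc.time()[["elapsed"]] - t0))
  structure(list(array_names = batch$array_names, metrics = metrics,
                 bg_noise = bgn, signals = signals, profile = profile,
                 degradation = deg, pca = pca,
                 variance_explained = pca$variance_explained,
                 flags = flags, colors = colors, order = ord,
                 thresholds = thresholds),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  n <- length(x$array_names)
  any_flag <- apply(cbind(x$flags$bg_noise, x$flags$hk, x$flags$spike,
                          x$flags$polya, x$flags$degradation), 1,
                    function(r) any(r, na.rm = TRUE))
  nfl <- sum(any_flag)
  cat(sprintf("QCReport: %d arrays, %d with >= 1 outlier flag\n", n, nfl))
  cat(sprintf("PC1 %.1f%% / PC2 %.1f%% variance explained\n",
              100 * x$variance_explained[1], 100 * x$variance_explained[2]))
  invisible(x)
}

#' Run configuration
#'
#' @param annotation,intensities,manifest Input file paths.
#' @param out_svg,out_circos,out_report Output paths (SVG file, Circos
#'   directory, report TSV); at least one must be requested.
#' @param thresholds A [qc_thresholds()] list.
#' @param gap_deg Sector gap in degrees.
#' @param canvas_px SVG canvas edge in pixels.
#' @param seed Seed for any stochastic step (none in the core pipeline;
#'   recorded for provenance).
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(annotation, intensities, manifest,
                       out_svg = NULL, out_circos = NULL, out_report = NULL,
                       thresholds = qc_thresholds(),
                       gap_deg = 1, canvas_px = 800, seed = 1L) {
  if (is.null(out_svg) && is.null(out_circos) && is.null(out_report))
    stop_validation("at least one output (out_svg, out_circos, out_report) is required")
  if (gap_deg < 0) stop_config("gap_deg must be >= 0")
  if (canvas_px < 100) stop_config("canvas_px must be >= 100")
  structure(list(annotation = annotation, intensities = intensities,
                 manifest = manifest, out_svg = out_svg,
                 out_circos = out_circos, out_report = out_report,
                 thresholds = thresholds, gap_deg = gap_deg,
                 canvas_px = canvas_px, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration file (YAML)
#'
#' Top-level keys mirror the [run_config()] arguments; threshold keys live
#' under `thresholds:`.
#'
#' @param path Path to a YAML config file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  thr <- do.call(qc_thresholds, as.list(y$thresholds))
  args <- y[setdiff(names(y), "thresholds")]
  known <- setdiff(names(formals(run_config)), "thresholds")
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, c(args, list(thresholds = thr)))
}

#' Write the per-array report TSV
#'
#' One row per array with every metric, flag, PC score and the degradation
#' color; the first line is a `#`-prefixed JSON metadata header recording
#' the thresholds and configuration for provenance.
#'
#' @param report A [qc_report()].
#' @param path Output path.
#' @param config Optional `RunConfig` echoed into the header.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path, config = NULL) {
  meta <- list(tool = "qccircos",
               version = as.character(utils::packageVersion("qccircos")),
               n_arrays = length(report$array_names),
               variance_explained = round(report$variance_explained, 6),
               thresholds = report$thresholds)
  if (!is.null(config))
    meta$config <- config[c("gap_deg", "canvas_px", "seed")]
  header <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  m <- report$metrics
  for (col in names(m)) {
    if (is.numeric(m[[col]])) m[[col]] <- sprintf("%.17g", m[[col]])
    else m[[col]] <- as.character(m[[col]])
  }
  lines <- c(header,
             paste(names(m), collapse = "\t"),
             apply(m, 1, paste, collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write report to '%s'", path)
  invisible(path)
}

#' Read a report TSV back into a minimal `QCReport`
#'
#' Restores the fields the renderer needs (names, PC scores, flags,
#' colors, slopes and display order), e.g. to re-plot a saved or
#' hand-edited report.
#'
#' @param path Report TSV written by [write_qc_report()].
#' @return A `QCReport` sufficient for [render_svg()] and
#'   [write_circos_files()].
#' @export
read_qc_report <- function(path) {
  parsed <- read_tsv_lines(path)
  m <- as.data.frame(do.call(rbind, parsed$rows), stringsAsFactors = FALSE)
  names(m) <- parsed$header
  num_cols <- setdiff(names(m), c("array", grep("call$|^flag_|color$",
                                                names(m), value = TRUE)))
  for (col in num_cols) m[[col]] <- as.numeric(m[[col]])
  for (col in grep("^flag_", names(m), value = TRUE))
    m[[col]] <- ifelse(m[[col]] == "NA", NA, m[[col]] == "TRUE")
  n <- nrow(m)
  colors <- t(vapply(m$degradation_color, function(h)
    as.integer(c(strtoi(substr(h, 2, 3), 16L), strtoi(substr(h, 4, 5), 16L),
                 strtoi(substr(h, 6, 7), 16L))), integer(3)))
  rownames(colors) <- m$array; colnames(colors) <- c("r", "g", "b")
  flags <- structure(list(
    bg_noise = cbind(background = m$flag_background, noise = m$flag_noise),
    hk = cbind(actin = m$flag_actin, gapdh = m$flag_gapdh),
    spike = as.matrix(m[paste0("flag_spike_", 1:3)]),
    polya = as.matrix(m[paste0("flag_polya_", POLYA_NAMES)]),
    degradation = m$flag_degradation), class = "QCFlags")
  rownames(flags$spike) <- rownames(flags$polya) <- m$array
  scores <- cbind(PC1 = m$pc1, PC2 = m$pc2)
  rownames(scores) <- m$array
  structure(list(array_names = m$array, metrics = m,
                 degradation = data.frame(array = m$array, slope = m$deg_slope,
                                          t_stat = m$deg_t,
                                          stringsAsFactors = FALSE),
                 pca = list(scores = scores),
                 variance_explained = c(NA_real_, NA_real_),
                 flags = flags, colors = colors,
                 order = display_order(m$deg_slope, m$array)),
            class = "QCReport")
}

#' Run the full QC pipeline
#'
#' Reads the three input files, computes the [qc_report()] and writes the
#' requested outputs. Any stage error propagates with the stage name and
#' partially written outputs are removed.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @return The `QCReport`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (p in c(config$annotation, config$intensities, config$manifest))
    if (!file.exists(p)) stop_io("input file not found: %s", p)

  ann <- read_probe_annotation(config$annotation)
  manifest <- read_control_manifest(config$manifest)
  batch <- read_intensity_table(config$intensities, ann$annotation)

  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written, recursive = TRUE))

  report <- qc_report(batch, ann$annotation, ann$geometry, manifest,
                      thresholds = config$thresholds)

  if (!is.null(config$out_report)) {
    written <- c(written, config$out_report)
    write_qc_report(report, config$out_report, config)
  }
  if (!is.null(config$out_svg)) {
    written <- c(written, config$out_svg)
    layout <- build_layout(length(report$array_names), report$order,
                           gap_deg = config$gap_deg)
    render_svg(report, layout, plot_style(canvas_px = config$canvas_px),
               config$out_svg)
  }
  if (!is.null(config$out_circos)) {
    written <- c(written, config$out_circos)
    write_circos_files(report, config$out_circos)
  }
  ok <- TRUE
  invisible(report)
}
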