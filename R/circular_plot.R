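# Six-rim circular layout, native SVG renderer, and Circos-format export.
# Rim order (outer -> inner): 1 PC1 scores, 2 degradation tiles,
# 3 background/noise, 4 housekeeping genes, 5 spike-ins, 6 poly-A controls.

RIM_RADII <- data.frame(
  rim = 1:6,
  inner = c(0.74, 0.62, 0.53, 0.44, 0.35, 0.26),
  outer = c(0.97, 0.72, 0.60, 0.51, 0.42, 0.33)
)

#' Circular sector layout
#'
#' Equal-width sectors of `(360 - n * gap_deg) / n` degrees, one per array,
#' laid out clockwise from 12 o'clock in display order.
#'
#' @param n_arrays Number of arrays (>= 1).
#' @param order Display permutation of array indices (e.g. from
#'   [display_order()]).
#' @param gap_deg Angular gap between sectors, `0 <= gap_deg < 360/n`.
#' @return A `CircularLayout` with per-array `sector_start_deg` /
#'   `sector_end_deg` (degrees clockwise from 12 o'clock, indexed by
#'   original array position), the `order`, `gap_deg` and the `rims` radius
#'   table (fractions of the plot radius).
#' @export
build_layout <- function(n_arrays, order = seq_len(n_arrays), gap_deg = 1) {
  if (n_arrays < 1L) stop_validation("n_arrays must be >= 1")
  if (!identical(sort(as.integer(order)), seq_len(n_arrays)))
    stop_validation("order must be a permutation of 1..n_arrays")
  if (gap_deg < 0 || gap_deg >= 360 / n_arrays)
    stop_validation("gap_deg must satisfy 0 <= gap_deg < 360/n_arrays")
  width <- (360 - n_arrays * gap_deg) / n_arrays
  start <- numeric(n_arrays); end <- numeric(n_arrays)
  for (pos in seq_len(n_arrays)) {
    a <- order[pos]
    start[a] <- (pos - 1) * (width + gap_deg)
    end[a] <- start[a] + width
  }
  structure(list(sector_start_deg = start, sector_end_deg = end,
                 sector_width_deg = width, order = as.integer(order),
                 gap_deg = gap_deg, rims = RIM_RADII),
            class = "CircularLayout")
}

#' Plot style parameters
#'
#' @param canvas_px Square canvas edge in pixels.
#' @param col_actual,col_other Dot colors for the sector's own array (red,
#'   drawn slightly bigger) and the remaining arrays in rim 1.
#' @param col_flag,col_ok,col_na Dot colors for flagged / clean /
#'   unavailable sub-metrics in rims 3-6.
#' @param r_actual,r_other,r_dot Dot radii in pixels.
#' @param font_px Label font size in pixels.
#' @return A `PlotStyle` list.
#' @export
plot_style <- function(canvas_px = 800,
                       col_actual = "#FF0000", col_other = "#0000FF",
                       col_flag = "#FF0000", col_ok = "#0000FF",
                       col_na = "#BBBBBB",
                       r_actual = 5, r_other = 3.5, r_dot = 4,
                       font_px = 10) {
  if (r_actual <= r_other)
    stop_validation("the actual-array dot must be bigger than the others")
  structure(list(canvas_px = canvas_px, col_actual = col_actual,
                 col_other = col_other, col_flag = col_flag, col_ok = col_ok,
                 col_na = col_na, r_actual = r_actual, r_other = r_other,
                 r_dot = r_dot, font_px = font_px),
            class = "PlotStyle")
}

# Polar -> canvas coordinates; theta in degrees clockwise from 12 o'clock,
# r as a fraction of the drawable radius.
polar_xy <- function(theta_deg, r_frac, cx, cy, radius) {
  th <- theta_deg * pi / 180
  c(x = cx + radius * r_frac * sin(th), y = cy - radius * r_frac * cos(th))
}

fmt_px <- function(x) sprintf("%.2f", x)

# SVG path for an annular wedge between angles a1 < a2 and radii r0 < r1.
wedge_path <- function(a1, a2, r0, r1, cx, cy, radius) {
  large <- if ((a2 - a1) > 180) 1L else 0L
  p1 <- polar_xy(a1, r1, cx, cy, radius)
  p2 <- polar_xy(a2, r1, cx, cy, radius)
  p3 <- polar_xy(a2, r0, cx, cy, radius)
  p4 <- polar_xy(a1, r0, cx, cy, radius)
  ro <- radius * r1; ri <- radius * r0
  sprintf(paste0("M %s %s A %s %s 0 %d 1 %s %s L %s %s ",
                 "A %s %s 0 %d 0 %s %s Z"),
          fmt_px(p1["x"]), fmt_px(p1["y"]), fmt_px(ro), fmt_px(ro), large,
          fmt_px(p2["x"]), fmt_px(p2["y"]), fmt_px(p3["x"]), fmt_px(p3["y"]),
          fmt_px(ri), fmt_px(ri), large, fmt_px(p4["x"]), fmt_px(p4["y"]))
}

svg_circle <- function(theta, r_frac, cx, cy, radius, r_px, fill, class) {
  p <- polar_xy(theta, r_frac, cx, cy, radius)
  sprintf('<circle class="%s" cx="%s" cy="%s" r="%s" fill="%s"/>',
          class, fmt_px(p["x"]), fmt_px(p["y"]), fmt_px(r_px), fill)
}

# min-max scale to [0,1]; constant input maps to 0.5
minmax01 <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Render the circular QC plot to SVG
#'
#' Rim 1 repeats the PC1 scores of all arrays inside every sector (dots
#' placed radially by min-max-scaled score), drawing the sector's own
#' array as a bigger red dot; rim 2 is one tile per array in its
#' degradation color; rims 3-6 draw one red dot per flagged and one blue
#' dot per clean sub-metric (grey when the metric is unavailable). Output
#' is deterministic: the same report yields a byte-identical file.
#'
#' @param report A [qc_report()].
#' @param layout A [build_layout()] (defaults to the report's display
#'   order with a 1-degree gap).
#' @param style A [plot_style()].
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
render_svg <- function(report, layout = NULL, style = plot_style(), path) {
  n <- length(report$array_names)
  if (is.null(layout)) layout <- build_layout(n, report$order, gap_deg = 1)
  S <- style$canvas_px
  cx <- S / 2; cy <- S / 2
  radius <- S / 2 - 45  # margin for sector labels
  rims <- layout$rims
  el <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">'), S, S, S, S),
    sprintf('<rect width="%d" height="%d" fill="#FFFFFF"/>', S, S)
  )

  scaled_pc1 <- minmax01(report$pca$scores[, 1])
  hex <- rgb_hex(report$colors)
  pos_of <- match(seq_len(n), layout$order)  # display position per array

  for (a in seq_len(n)) {
    a1 <- layout$sector_start_deg[a]
    a2 <- layout$sector_end_deg[a]
    width <- a2 - a1
    mid <- (a1 + a2) / 2

    # rim 2: degradation tile
    el <- c(el, sprintf(
      '<path class="rim2 tile" d="%s" fill="%s" stroke="#FFFFFF" stroke-width="0.5"/>',
      wedge_path(a1, a2, rims$inner[2], rims$outer[2], cx, cy, radius), hex[a]))

    # rim 1: all arrays' PC1 scores inside this sector, own array on top
    r0 <- rims$inner[1]; band <- rims$outer[1] - rims$inner[1]
    others <- setdiff(seq_len(n), a)
    for (b in c(others[order(pos_of[others])], a)) {
      theta <- a1 + width * (pos_of[b] - 0.5) / n
      rr <- r0 + band * scaled_pc1[b]
      if (b == a) {
        el <- c(el, svg_circle(theta, rr, cx, cy, radius, style$r_actual,
                               style$col_actual, "rim1 self"))
      } else {
        el <- c(el, svg_circle(theta, rr, cx, cy, radius, style$r_other,
                               style$col_other, "rim1 other"))
      }
    }

    # rims 3-6: sub-metric dots
    dot_rim <- function(rim, flags) {
      m <- length(flags)
      rmid <- (rims$inner[rim] + rims$outer[rim]) / 2
      unlist(lapply(seq_len(m), function(i) {
        theta <- a1 + width * (i - 0.5) / m
        f <- flags[i]
        fill <- if (is.na(f)) style$col_na else if (f) style$col_flag else style$col_ok
        state <- if (is.na(f)) "na" else if (f) "flag" else "ok"
        svg_circle(theta, rmid, cx, cy, radius, style$r_dot, fill,
                   sprintf("rim%d %s", rim, state))
      }))
    }
    el <- c(el,
            dot_rim(3, report$flags$bg_noise[a, ]),
            dot_rim(4, report$flags$hk[a, ]),
            dot_rim(5, report$flags$spike[a, ]),
            dot_rim(6, report$flags$polya[a, ]))

    # sector label
    lp <- polar_xy(mid, 1.06, cx, cy, radius)
    el <- c(el, sprintf(
      '<text class="label" x="%s" y="%s" font-size="%d" font-family="sans-serif" text-anchor="middle">%s</text>',
      fmt_px(lp["x"]), fmt_px(lp["y"]), style$font_px, report$array_names[a]))
  }

  # rim index numerals at 12 o'clock
  for (rim in 1:6) {
    rp <- polar_xy(0, (rims$inner[rim] + rims$outer[rim]) / 2, cx, cy, radius)
    el <- c(el, sprintf(
      '<text class="rim-index" x="%s" y="%s" font-size="%d" font-family="sans-serif" text-anchor="middle" fill="#888888">%d</text>',
      fmt_px(rp["x"]), fmt_px(rp["y"]), style$font_px, rim))
  }

  ve <- report$variance_explained
  el <- c(el, sprintf(
    '<text class="center" x="%s" y="%s" font-size="%d" font-family="sans-serif" text-anchor="middle">PC1 %s%% / PC2 %s%%</text>',
    fmt_px(cx), fmt_px(cy), style$font_px,
    fmt_px(100 * ve[1]), fmt_px(100 * ve[2])),
    "</svg>")
  ok <- tryCatch({ writeLines(el, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write SVG to '%s'", path)
  invisible(path)
}

#' Emit Circos-compatible input files
#'
#' Writes, into `outdir`: a karyotype file with one `chr` segment of
#' `segment_length` units per array (in display order); one data file per
#' rim (scatter values for rim 1 with every array's score in every sector,
#' a colored tile per array for rim 2, red/blue highlight dots for rims
#' 3-6); and a master configuration `circosQCconfig.txt` referencing the
#' data files by relative path. Coordinates are 0-based, end-exclusive.
#'
#' @param report A [qc_report()].
#' @param outdir Output directory (created if needed).
#' @param segment_length Units per array segment (default 1000).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_circos_files <- function(report, outdir, segment_length = 1000L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  n <- length(report$array_names)
  L <- as.integer(segment_length)
  ord <- report$order
  seg_id <- sprintf("qc%d", seq_len(n))          # by display position
  seg_of_array <- seg_id[match(seq_len(n), ord)] # original index -> segment

  files <- c(karyotype = "karyotype.txt",
             rim1 = "rim1_pc1.txt", rim2 = "rim2_degradation.txt",
             rim3 = "rim3_bgnoise.txt", rim4 = "rim4_housekeeping.txt",
             rim5 = "rim5_spikein.txt", rim6 = "rim6_polya.txt",
             config = "circosQCconfig.txt")
  paths <- stats::setNames(file.path(outdir, files), names(files))

  writeLines(sprintf("chr - %s %s 0 %d grey", seg_id,
                     report$array_names[ord], L), paths["karyotype"])

  # rim 1: every array's PC1 score in every sector -> n^2 rows
  slot <- function(pos) c(floor(L * (pos - 1) / n), floor(L * pos / n))
  rim1 <- character(0)
  for (s in seq_len(n)) {
    for (pos in seq_len(n)) {
      b <- ord[pos]
      sl <- slot(pos)
      rim1 <- c(rim1, sprintf("%s %d %d %.6f", seg_of_array[s], sl[1], sl[2],
                              report$pca$scores[b, 1]))
    }
  }
  writeLines(rim1, paths["rim1"])

  writeLines(sprintf("%s 0 %d fill_color=%d,%d,%d", seg_of_array, L,
                     report$colors[, 1], report$colors[, 2], report$colors[, 3]),
             paths["rim2"])

  highlight_lines <- function(flag_mat) {
    out <- character(0)
    m <- ncol(flag_mat)
    for (a in seq_len(n)) {
      for (i in seq_len(m)) {
        f <- flag_mat[a, i]
        if (is.na(f)) next
        s0 <- floor(L * (i - 1) / m); s1 <- floor(L * i / m)
        out <- c(out, sprintf("%s %d %d fill_color=%s", seg_of_array[a],
                              s0, s1, if (f) "red" else "blue"))
      }
    }
    out
  }
  writeLines(highlight_lines(report$flags$bg_noise), paths["rim3"])
  writeLines(highlight_lines(report$flags$hk), paths["rim4"])
  writeLines(highlight_lines(report$flags$spike), paths["rim5"])
  writeLines(highlight_lines(report$flags$polya), paths["rim6"])

  rims <- RIM_RADII
  plot_block <- function(type, file, rim) {
    c("<plot>",
      sprintf("type = %s", type),
      sprintf("file = %s", file),
      sprintf("r0 = %.2fr", rims$inner[rim]),
      sprintf("r1 = %.2fr", rims$outer[rim]),
      "</plot>")
  }
  cfg <- c(
    "# Circos master configuration for the circular array-QC plot",
    "karyotype = karyotype.txt",
    "chromosomes_units = 100",
    "<ideogram>",
    "<spacing>",
    "default = 0.005r",
    "</spacing>",
    "radius = 0.90r",
    "thickness = 20p",
    "fill = yes",
    "show_label = yes",
    "label_radius = 1.05r",
    "label_size = 30",
    "</ideogram>",
    "<plots>",
    plot_block("scatter", files["rim1"], 1),
    plot_block("highlight", files["rim2"], 2),
    plot_block("highlight", files["rim3"], 3),
    plot_block("highlight", files["rim4"], 4),
    plot_block("highlight", files["rim5"], 5),
    plot_block("highlight", files["rim6"], 6),
    "</plots>",
    "<image>",
    "dir = .",
    "file = circosQCplot.png",
    "radius = 1500p",
    "svg = yes",
    "</image>",
    "<<include etc/colors_fonts_patterns.conf>>",
    "<<include etc/housekeeping.conf>>"
  )
  writeLines(cfg, paths["config"])
  invisible(paths)
}
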