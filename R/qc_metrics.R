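# Per-array QC measurements: zonal average background and noise,
# MAS5-style Wilcoxon detection calls, housekeeping 3'/5' ratios, and
# signals/calls for the spike-in and poly-A control probe sets.

#' Zonal average background and noise of one array
#'
#' The chip is partitioned into `grid_k` x `grid_k` equal rectangular zones
#' by probe coordinates. In each zone the lowest
#' `ceiling(low_fraction * n_zone)` intensities are taken; the zone
#' background is their mean and the zone noise their standard deviation
#' (0 for a single value). The array values are the unweighted means over
#' zones.
#'
#' @param intensities Per-probe intensity vector.
#' @param coords Two-column matrix/data.frame of 0-based `(x, y)` probe
#'   coordinates.
#' @param geometry A [chip_geometry()].
#' @param grid_k Zones per chip edge (default 4).
#' @param low_fraction Fraction of lowest intensities per zone (default 0.02).
#' @return A list with `avg_background` and `avg_noise`.
#' @export
zonal_background_noise <- function(intensities, coords, geometry,
                                   grid_k = 4L, low_fraction = 0.02) {
  if (grid_k < 1L) stop_config("grid_k must be >= 1")
  if (low_fraction <= 0 || low_fraction > 1)
    stop_config("low_fraction must be in (0, 1]")
  coords <- as.matrix(coords)
  if (nrow(coords) != length(intensities))
    stop_validation("coords and intensities lengths differ")
  zx <- pmin(floor(coords[, 1] * grid_k / geometry$n_cols), grid_k - 1L)
  zy <- pmin(floor(coords[, 2] * grid_k / geometry$n_rows), grid_k - 1L)
  zone <- factor(zx * grid_k + zy, levels = 0:(grid_k * grid_k - 1L))
  counts <- table(zone)
  if (any(counts == 0L))
    stop_config("grid_k = %d leaves %d empty zone(s); use a smaller grid_k",
                grid_k, sum(counts == 0L))
  per_zone <- tapply(intensities, zone, function(v) {
    m <- max(1L, as.integer(ceiling(low_fraction * length(v))))
    low <- sort(v, partial = seq_len(m))[seq_len(m)]
    c(mean(low), if (m > 1L) stats::sd(low) else 0)
  })
  bg <- vapply(per_zone, `[`, numeric(1), 1L)
  nz <- vapply(per_zone, `[`, numeric(1), 2L)
  list(avg_background = mean(bg), avg_noise = mean(nz))
}

#' Background and noise for every array of a batch
#'
#' Applies [zonal_background_noise()] to each array.
#'
#' @param batch An [intensity_batch()].
#' @param annotation The matching [probe_annotation()].
#' @param geometry A [chip_geometry()].
#' @inheritParams zonal_background_noise
#' @return Data frame with columns `array`, `avg_background`, `avg_noise`.
#' @export
batch_background_noise <- function(batch, annotation, geometry,
                                   grid_k = 4L, low_fraction = 0.02) {
  coords <- cbind(annotation$x, annotation$y)
  res <- apply(batch$intensities, 2, zonal_background_noise, coords = coords,
               geometry = geometry, grid_k = grid_k, low_fraction = low_fraction)
  data.frame(
    array = batch$array_names,
    avg_background = vapply(res, `[[`, numeric(1), "avg_background"),
    avg_noise = vapply(res, `[[`, numeric(1), "avg_noise"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Exact null distribution of the signed-rank statistic: dynamic programme
# over doubled (integer) midranks. Returns P(W* >= W) under random signs.
signed_rank_exact_p <- function(ranks, W) {
  w2 <- as.integer(round(2 * ranks))
  total <- sum(w2)
  counts <- numeric(total + 1L)  # counts[s+1] = #assignments with 2*W = s
  counts[1L] <- 1
  for (wi in w2) {
    shifted <- c(numeric(wi), counts[seq_len(total + 1L - wi)])
    counts <- counts + shifted
  }
  tail_from <- as.integer(round(2 * W)) + 1L
  sum(counts[tail_from:(total + 1L)]) / 2^length(w2)
}

#' MAS5-style detection call for one probe set
#'
#' Discrimination scores `R_i = (PM_i - MM_i) / (PM_i + MM_i)` are tested
#' against the threshold `tau` with a one-sided Wilcoxon signed-rank test
#' (alternative: median R > tau). The p-value is exact (enumeration of the
#' sign-flip null) for up to 12 informative pairs, and a tie-corrected,
#' continuity-corrected normal approximation beyond. Zero differences are
#' dropped; tied absolute differences receive midranks.
#'
#' @param pm,mm Numeric vectors of PM and MM intensities (k >= 3 pairs).
#' @param tau Discrimination threshold (default 0.015).
#' @param alpha1,alpha2 Call thresholds: Present if p < alpha1, Marginal if
#'   alpha1 <= p < alpha2, else Absent. Require alpha1 < alpha2 < 0.5.
#' @return A list with `p_value` and `call` (factor with levels
#'   Present/Marginal/Absent).
#' @export
detection_call <- function(pm, mm, tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (length(pm) != length(mm)) stop_validation("pm and mm lengths differ")
  if (!(alpha1 < alpha2 && alpha2 < 0.5))
    stop_config("need alpha1 < alpha2 < 0.5")
  denom <- pm + mm
  keep <- denom > 0
  if (sum(keep) < 3L)
    stop_validation("fewer than 3 usable PM/MM pairs (k = %d)", sum(keep))
  r_score <- (pm[keep] - mm[keep]) / denom[keep]
  d <- r_score - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    p <- 0.5
  } else {
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    if (n <= 12L) {
      p <- signed_rank_exact_p(rk, W)
    } else {
      ties <- table(rk)
      mu <- n * (n + 1) / 4
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
      z <- (W - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  call <- if (p < alpha1) "Present" else if (p < alpha2) "Marginal" else "Absent"
  list(p_value = p,
       call = factor(call, levels = c("Present", "Marginal", "Absent")))
}

#' Housekeeping 3'/5' ratio per array
#'
#' `median(PM of the 3' probe set) / median(PM of the 5' probe set)` on the
#' raw scale (QC precedes normalization). Ratios above 3 indicate RNA
#' degradation or inefficient reverse transcription.
#'
#' @param batch An [intensity_batch()].
#' @param annotation The matching [probe_annotation()].
#' @param manifest A [control_manifest()] providing the `<gene>_3` and
#'   `<gene>_5` classes.
#' @param gene `"actin"` or `"gapdh"`.
#' @return Named numeric vector, one ratio per array.
#' @export
three_prime_ratio <- function(batch, annotation, manifest,
                              gene = c("actin", "gapdh")) {
  gene <- match.arg(gene)
  ps3 <- manifest_probeset(manifest, paste0(gene, "_3"))
  ps5 <- manifest_probeset(manifest, paste0(gene, "_5"))
  if (is.na(ps3) || is.na(ps5))
    stop_config("manifest lacks the %s_3/%s_5 classes needed for the ratio",
                gene, gene)
  rows3 <- pm_rows(annotation, ps3)
  rows5 <- pm_rows(annotation, ps5)
  if (!length(rows3) || !length(rows5))
    stop_config("probe set '%s' from the manifest is absent from the annotation",
                if (!length(rows3)) ps3 else ps5)
  m3 <- apply(batch$intensities[rows3, , drop = FALSE], 2, stats::median)
  m5 <- apply(batch$intensities[rows5, , drop = FALSE], 2, stats::median)
  if (any(m5 == 0))
    stop_validation("5' median is 0 for array '%s'; ratio undefined",
                    batch$array_names[which(m5 == 0)[1]])
  stats::setNames(m3 / m5, batch$array_names)
}

POLYA_NAMES <- c("dap", "lys", "phe", "thr")

#' Control signals and calls for every array
#'
#' Housekeeping 3'/5' ratios (when both end probe sets are present in the
#' manifest), detection calls for the three spike-in probe sets, and
#' `log2(median PM)` signals plus calls for the (up to four) poly-A
#' controls. Missing manifest classes yield `NA` entries.
#'
#' @param batch An [intensity_batch()].
#' @param annotation The matching [probe_annotation()].
#' @param manifest A [control_manifest()].
#' @param tau,alpha1,alpha2 Detection-call parameters, see [detection_call()].
#' @return A `ControlSignals` list with `hk_ratios` (arrays x 2),
#'   `spike_p`/`spike_calls` (arrays x 3), `polya_signals`/`polya_p`/
#'   `polya_calls` (arrays x 4).
#' @export
control_signals <- function(batch, annotation, manifest,
                            tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  n <- n_arrays(batch)
  anames <- batch$array_names
  present <- manifest$control_class
  missing_ps <- setdiff(manifest$probeset_id, annotation$probeset_id)
  if (length(missing_ps))
    stop_config("manifest probe set(s) absent from annotation: %s",
                paste(missing_ps, collapse = ", "))

  hk <- matrix(NA_real_, n, 2, dimnames = list(anames, c("actin", "gapdh")))
  for (gene in c("actin", "gapdh")) {
    if (all(paste0(gene, c("_3", "_5")) %in% present))
      hk[, gene] <- three_prime_ratio(batch, annotation, manifest, gene)
  }

  call_for <- function(class_name) {
    ps <- manifest_probeset(manifest, class_name)
    if (is.na(ps)) return(NULL)
    rows_pm <- pm_rows(annotation, ps)
    rows_mm <- mm_rows(annotation, ps)
    mm_pair <- rows_mm[match(annotation$pair_index[rows_pm],
                             annotation$pair_index[rows_mm])]
    lapply(seq_len(n), function(a)
      detection_call(batch$intensities[rows_pm, a],
                     batch$intensities[mm_pair, a], tau, alpha1, alpha2))
  }

  spike_p <- matrix(NA_real_, n, 3, dimnames = list(anames, paste0("spike_", 1:3)))
  spike_calls <- matrix(NA_character_, n, 3,
                        dimnames = dimnames(spike_p))
  for (s in 1:3) {
    res <- call_for(paste0("spike_", s))
    if (!is.null(res)) {
      spike_p[, s] <- vapply(res, `[[`, numeric(1), "p_value")
      spike_calls[, s] <- vapply(res, function(r) as.character(r$call), "")
    }
  }

  polya_signals <- matrix(NA_real_, n, 4, dimnames = list(anames, POLYA_NAMES))
  polya_p <- polya_signals
  polya_calls <- matrix(NA_character_, n, 4, dimnames = dimnames(polya_signals))
  for (i in seq_along(POLYA_NAMES)) {
    cls <- paste0("polya_", POLYA_NAMES[i])
    ps <- manifest_probeset(manifest, cls)
    if (is.na(ps)) next
    rows_pm <- pm_rows(annotation, ps)
    med <- apply(batch$intensities[rows_pm, , drop = FALSE], 2, stats::median)
    polya_signals[, i] <- log2(pmax(med, 2^-20))
    res <- call_for(cls)
    polya_p[, i] <- vapply(res, `[[`, numeric(1), "p_value")
    polya_calls[, i] <- vapply(res, function(r) as.character(r$call), "")
  }

  structure(list(hk_ratios = hk, spike_p = spike_p, spike_calls = spike_calls,
                 polya_signals = polya_signals, polya_p = polya_p,
                 polya_calls = polya_calls,
                 classes_present = present),
            class = "ControlSignals")
}
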