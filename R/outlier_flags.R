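# Condense per-array metrics into the per-rim outlier flags and the
# blue-white-red degradation gradient of the circular plot.

#' Robust dataset-relative outlier rule
#'
#' Flags value v iff `|v - median| > k * 1.4826 * MAD`. If the MAD is 0 the
#' rule falls back to `|v - median| > k * IQR / 1.349` with inverse-ECDF
#' (type-1) quantiles; if both spreads are 0 nothing is flagged.
#'
#' @param values Per-array numeric vector (>= 3 values for any flagging).
#' @param k Multiplier on the robust SD (default 2).
#' @return Logical vector, TRUE = outlier.
#' @export
robust_outliers <- function(values, k = 2) {
  n <- length(values)
  if (n < 3L) {
    warning("fewer than 3 values: no outliers flagged")
    return(rep(FALSE, n))
  }
  med <- stats::median(values)
  s <- stats::mad(values)  # 1.4826 * MAD
  if (s == 0) {
    iqr <- diff(stats::quantile(values, c(0.25, 0.75), type = 1, names = FALSE))
    s <- iqr / 1.349
  }
  if (s == 0) return(rep(FALSE, n))
  abs(values - med) > k * s
}

#' Default QC thresholds
#'
#' @param grid_k,low_fraction Zonal background parameters
#'   ([zonal_background_noise()]).
#' @param tau,alpha1,alpha2 Detection-call parameters ([detection_call()]).
#' @param hk_threshold Housekeeping 3'/5' ratio flag threshold (strict
#'   "more than threefold", default 3).
#' @param robust_k Multiplier for [robust_outliers()] (default 2).
#' @param degradation_k Probe count of the degradation profile (default 11).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(grid_k = 4L, low_fraction = 0.02,
                          tau = 0.015, alpha1 = 0.04, alpha2 = 0.06,
                          hk_threshold = 3, robust_k = 2,
                          degradation_k = 11L) {
  if (!(alpha1 < alpha2 && alpha2 < 0.5)) stop_config("need alpha1 < alpha2 < 0.5")
  if (hk_threshold <= 0) stop_config("hk_threshold must be > 0")
  if (robust_k <= 0) stop_config("robust_k must be > 0")
  list(grid_k = as.integer(grid_k), low_fraction = low_fraction, tau = tau,
       alpha1 = alpha1, alpha2 = alpha2, hk_threshold = hk_threshold,
       robust_k = robust_k, degradation_k = as.integer(degradation_k))
}

#' Per-array, per-rim outlier flags
#'
#' Background and noise are flagged by [robust_outliers()]; housekeeping
#' genes iff the 3'/5' ratio exceeds `hk_threshold` (strictly more than
#' threefold by default); spike-ins iff the detection call is not Present
#' (Marginal counts as failure); poly-A controls by a robust signal
#' outlier OR an Absent call; degradation iff the slope is a robust
#' outlier.
#'
#' @param bg_noise Data frame from [batch_background_noise()].
#' @param signals A [control_signals()] result.
#' @param deg_stats A [degradation_slope()] result.
#' @param thresholds A [qc_thresholds()] list.
#' @return A `QCFlags` list of logical matrices/vectors: `bg_noise`
#'   (arrays x 2: background, noise), `hk` (arrays x 2), `spike`
#'   (arrays x 3), `polya` (arrays x 4, NA where the manifest lacks the
#'   class) and `degradation` (per array).
#' @export
flag_arrays <- function(bg_noise, signals, deg_stats,
                        thresholds = qc_thresholds()) {
  k <- thresholds$robust_k
  anames <- bg_noise$array
  bg <- cbind(background = robust_outliers(bg_noise$avg_background, k),
              noise = robust_outliers(bg_noise$avg_noise, k))
  rownames(bg) <- anames

  hk <- signals$hk_ratios > thresholds$hk_threshold

  spike <- !is.na(signals$spike_calls) & signals$spike_calls != "Present"
  spike[is.na(signals$spike_calls)] <- NA

  polya <- matrix(NA, nrow(signals$polya_signals), 4,
                  dimnames = dimnames(signals$polya_signals))
  for (i in seq_len(4)) {
    sig <- signals$polya_signals[, i]
    if (all(is.na(sig))) next
    polya[, i] <- robust_outliers(sig, k) | signals$polya_calls[, i] == "Absent"
  }

  if (!identical(deg_stats$array, anames))
    stop_config("degradation stats and background table list different arrays")
  degradation <- robust_outliers(deg_stats$slope, k)
  names(degradation) <- anames

  structure(list(bg_noise = bg, hk = hk, spike = spike, polya = polya,
                 degradation = degradation),
            class = "QCFlags")
}

#' Diverging blue-white-red degradation colors
#'
#' Piecewise-linear map anchored at the minimum slope (blue, #0000FF), the
#' median slope (white, #FFFFFF) and the maximum slope (red, #FF0000).
#' Zero-range (or single-array) input maps to white.
#'
#' @param slopes Per-array numeric slopes.
#' @return Integer matrix arrays x 3 (columns r, g, b) in 0..255.
#' @export
degradation_colors <- function(slopes) {
  n <- length(slopes)
  if (n < 1L) stop_validation("need at least one slope")
  out <- matrix(255L, n, 3, dimnames = list(names(slopes), c("r", "g", "b")))
  lo <- min(slopes); hi <- max(slopes); med <- stats::median(slopes)
  if (n == 1L || hi == lo) return(out)
  for (i in seq_len(n)) {
    v <- slopes[i]
    if (v <= med) {
      t <- if (med > lo) (v - lo) / (med - lo) else 1
      out[i, ] <- as.integer(round(c(255 * t, 255 * t, 255)))
    } else {
      t <- (v - med) / (hi - med)
      out[i, ] <- as.integer(round(c(255, 255 * (1 - t), 255 * (1 - t))))
    }
  }
  out
}

rgb_hex <- function(colors) {
  apply(colors, 1, function(ch) sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3]))
}

#' Array display order by degradation
#'
#' Ascending degradation slope; ties broken by array name, so arrays of
#' similar RNA quality sit side by side in the circular plot.
#'
#' @param slopes Per-array numeric slopes.
#' @param names Array names used for tie-breaking (defaults to
#'   `names(slopes)`).
#' @return Integer permutation of `seq_along(slopes)`.
#' @export
display_order <- function(slopes, names = base::names(slopes)) {
  if (is.null(names)) names <- as.character(seq_along(slopes))
  order(slopes, names)
}
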