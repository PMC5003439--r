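# Synthetic probe-level batches with known, controllable QC defects.
# Every defect axis the QC pipeline measures (degradation slope, additive
# background, housekeeping 3'/5' ratio, spike-in presence, poly-A level,
# cluster structure) is injected with an analytically known truth value.

#' Specify a synthetic probe-level batch
#'
#' The PM signal model on the log2 scale is
#' `baseline + probeset_effect + probe_effect + cluster_signature +
#'  slope * (probe_index - (k+1)/2) + N(0, noise_sd_log2)`;
#' MM probes carry half the PM signal (or ~equal signal for absent
#' spike-ins, which flips the detection call). On the raw scale an additive
#' optical background `N(bg, (bg_noise_frac*bg)^2)` is added per probe.
#' Housekeeping, spike-in and poly-A control probe sets carry no probe
#' affinity effects and no degradation trend so their injected parameters
#' are exactly recoverable in the noiseless limit.
#'
#' @param n_arrays Number of arrays (>= 2).
#' @param n_probesets Number of regular probe sets (>= 20).
#' @param probes_per_set PM/MM pairs per regular probe set (>= 3, default 11).
#' @param baseline_log2 Mean log2 PM intensity of regular probes.
#' @param noise_sd_log2 Per-measurement log2 noise SD (>= 0).
#' @param probe_sd_log2 SD of fixed per-probe affinity effects (log2).
#' @param probeset_sd_log2 SD of per-probe-set expression levels (log2).
#' @param degradation_slopes Per-array linear 5'->3' trend, log2 units per
#'   probe position.
#' @param background_levels Per-array additive raw-scale background (>= 0).
#' @param bg_noise_frac Optical background fluctuation as a fraction of the
#'   background level (so average noise co-varies with background).
#' @param hk_ratios n_arrays x 2 matrix (columns `actin`, `gapdh`) of target
#'   3'/5' median ratios (> 0).
#' @param hk_level_log2 log2 level of the housekeeping 5' probe sets.
#' @param spike_present n_arrays x 3 logical matrix; FALSE makes the spike
#'   probe set read as Absent.
#' @param spike_level_log2 log2 PM level of spike-in probe sets.
#' @param polya_levels n_arrays x 4 matrix of log2 levels for the poly-A
#'   controls (columns `dap`, `lys`, `phe`, `thr`).
#' @param cluster_assignment Per-array integer cluster labels (drives PCA
#'   separation).
#' @param cluster_offset_log2 Magnitude of the per-cluster expression
#'   signature (log2).
#' @param signature_fraction Fraction of regular probe sets carrying the
#'   cluster signature.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return A validated `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_arrays = 6L,
                           n_probesets = 200L,
                           probes_per_set = 11L,
                           baseline_log2 = 8,
                           noise_sd_log2 = 0.2,
                           probe_sd_log2 = 0.25,
                           probeset_sd_log2 = 1,
                           degradation_slopes = rep(0.1, n_arrays),
                           background_levels = rep(50, n_arrays),
                           bg_noise_frac = 0.1,
                           hk_ratios = cbind(actin = rep(1.5, n_arrays),
                                             gapdh = rep(1.2, n_arrays)),
                           hk_level_log2 = baseline_log2 + 2,
                           spike_present = matrix(TRUE, n_arrays, 3),
                           spike_level_log2 = baseline_log2 + 2,
                           polya_levels = matrix(rep(c(11.5, 7, 8.5, 10),
                                                     each = n_arrays),
                                                 n_arrays, 4,
                                                 dimnames = list(NULL,
                                                   c("dap", "lys", "phe", "thr"))),
                           cluster_assignment = rep(1L, n_arrays),
                           cluster_offset_log2 = 1,
                           signature_fraction = 0.2,
                           seed = 1L) {
  n_arrays <- as.integer(n_arrays)
  if (is.na(n_arrays) || n_arrays < 2L)
    stop_validation("n_arrays must be an integer >= 2")
  if (n_probesets < 20L) stop_validation("n_probesets must be >= 20")
  if (probes_per_set < 3L)
    stop_validation("probes_per_set must be >= 3 (a slope needs >= 3 positions)")
  if (noise_sd_log2 < 0 || probe_sd_log2 < 0 || probeset_sd_log2 < 0)
    stop_validation("noise/effect SDs must be >= 0")
  hk_ratios <- as.matrix(hk_ratios)
  spike_present <- as.matrix(spike_present)
  polya_levels <- as.matrix(polya_levels)
  chk_len <- function(x, nc, what) {
    if (nrow(x) != n_arrays || ncol(x) != nc)
      stop_validation("%s must be an n_arrays x %d matrix", what, nc)
  }
  if (length(degradation_slopes) != n_arrays)
    stop_validation("degradation_slopes must have length n_arrays")
  if (length(background_levels) != n_arrays)
    stop_validation("background_levels must have length n_arrays")
  if (any(background_levels < 0)) stop_validation("background_levels must be >= 0")
  chk_len(hk_ratios, 2L, "hk_ratios")
  if (any(hk_ratios <= 0)) stop_validation("hk_ratios must be > 0")
  chk_len(spike_present, 3L, "spike_present")
  chk_len(polya_levels, 4L, "polya_levels")
  if (length(cluster_assignment) != n_arrays)
    stop_validation("cluster_assignment must have length n_arrays")
  if (signature_fraction <= 0 || signature_fraction > 1)
    stop_validation("signature_fraction must be in (0, 1]")
  structure(list(
    n_arrays = n_arrays, n_probesets = as.integer(n_probesets),
    probes_per_set = as.integer(probes_per_set),
    baseline_log2 = baseline_log2, noise_sd_log2 = noise_sd_log2,
    probe_sd_log2 = probe_sd_log2, probeset_sd_log2 = probeset_sd_log2,
    degradation_slopes = as.numeric(degradation_slopes),
    background_levels = as.numeric(background_levels),
    bg_noise_frac = bg_noise_frac,
    hk_ratios = hk_ratios, hk_level_log2 = hk_level_log2,
    spike_present = spike_present, spike_level_log2 = spike_level_log2,
    polya_levels = polya_levels,
    cluster_assignment = as.integer(cluster_assignment),
    cluster_offset_log2 = cluster_offset_log2,
    signature_fraction = signature_fraction,
    seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

# Control probe sets get a pair count different from the regular sets so
# that they never enter the k-probe degradation profile.
control_pair_count <- function(probes_per_set) {
  if (probes_per_set == 10L) 11L else 10L
}

CONTROL_PROBESET_IDS <- stats::setNames(
  c("AFFX-ACTIN-3", "AFFX-ACTIN-M", "AFFX-ACTIN-5",
    "AFFX-GAPDH-3", "AFFX-GAPDH-M", "AFFX-GAPDH-5",
    "AFFX-SPIKE-1", "AFFX-SPIKE-2", "AFFX-SPIKE-3",
    "AFFX-POLYA-DAP", "AFFX-POLYA-LYS", "AFFX-POLYA-PHE", "AFFX-POLYA-THR"),
  CONTROL_CLASSES)

# Run `expr` under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a synthetic probe-level batch
#'
#' Deterministic given the spec (one RNG stream seeded from `spec$seed`;
#' draw order: cluster signature, probe-set levels, probe affinities, per
#' array PM noise, MM noise, absent-spike MM multipliers, background).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `annotation`, `geometry`, `batch`, `manifest` and
#'   `truth` (a `SyntheticTruth`: per-array outlier labels derived from the
#'   injected parameters by the documented flag rules, plus the parameters
#'   themselves).
#' @export
generate_batch <- function(spec) {
  if (!inherits(spec, "SyntheticSpec")) spec <- do.call(synthetic_spec, spec)
  n <- spec$n_arrays
  pps <- spec$probes_per_set
  cpp <- control_pair_count(pps)

  reg_ids <- sprintf("PS%04d", seq_len(spec$n_probesets))
  sets <- data.frame(
    probeset_id = c(rep(reg_ids, each = pps),
                    rep(unname(CONTROL_PROBESET_IDS), each = cpp)),
    probe_index = c(rep(seq_len(pps), spec$n_probesets),
                    rep(seq_len(cpp), length(CONTROL_PROBESET_IDS))),
    stringsAsFactors = FALSE
  )
  n_pairs <- nrow(sets)
  total_probes <- 2L * n_pairs
  n_cols <- as.integer(ceiling(sqrt(total_probes)))
  n_rows <- as.integer(ceiling(total_probes / n_cols))
  cell <- seq_len(total_probes) - 1L
  ann <- data.frame(
    probe_id = c(paste0(sets$probeset_id, "_pm", sets$probe_index),
                 paste0(sets$probeset_id, "_mm", sets$probe_index)),
    probeset_id = rep(sets$probeset_id, 2L),
    probe_index = rep(sets$probe_index, 2L),
    pair_index = rep(sets$probe_index, 2L),
    role = rep(c("PM", "MM"), each = n_pairs),
    x = cell %% n_cols,
    y = cell %/% n_cols,
    stringsAsFactors = FALSE
  )
  annotation <- probe_annotation(ann)
  geometry <- chip_geometry(n_rows, n_cols)
  manifest <- control_manifest(unname(CONTROL_PROBESET_IDS), CONTROL_CLASSES)

  pm_mu <- matrix(0, n_pairs, n)   # log2 PM signal, noise-free
  mm_mu <- matrix(NA_real_, n_pairs, n)  # log2 MM signal (NA = tied to PM draw)
  is_reg <- seq_len(n_pairs) <= spec$n_probesets * pps
  reg_set_of_pair <- rep(seq_len(spec$n_probesets), each = pps)

  out <- with_seed(spec$seed, {
    n_sig <- max(1L, as.integer(ceiling(spec$signature_fraction * spec$n_probesets)))
    clusters <- sort(unique(spec$cluster_assignment))
    signature <- matrix(sample(c(-1, 1), n_sig * length(clusters), replace = TRUE),
                        n_sig, length(clusters))
    ps_level <- stats::rnorm(spec$n_probesets, 0, spec$probeset_sd_log2)
    probe_eff <- stats::rnorm(spec$n_probesets * pps, 0, spec$probe_sd_log2)

    centre <- (pps + 1) / 2
    j <- sets$probe_index[is_reg]
    base_reg <- spec$baseline_log2 + ps_level[reg_set_of_pair] + probe_eff
    for (a in seq_len(n)) {
      mu <- base_reg + spec$degradation_slopes[a] * (j - centre)
      cl <- match(spec$cluster_assignment[a], clusters)
      sig_sets <- seq_len(n_sig)
      add <- numeric(spec$n_probesets)
      add[sig_sets] <- spec$cluster_offset_log2 * signature[, cl]
      pm_mu[is_reg, a] <- mu + add[reg_set_of_pair]
    }

    ctrl_mu_for <- function(class, a) {
      switch(class,
        actin_5 = spec$hk_level_log2,
        actin_M = spec$hk_level_log2 + log2(spec$hk_ratios[a, 1]) / 2,
        actin_3 = spec$hk_level_log2 + log2(spec$hk_ratios[a, 1]),
        gapdh_5 = spec$hk_level_log2,
        gapdh_M = spec$hk_level_log2 + log2(spec$hk_ratios[a, 2]) / 2,
        gapdh_3 = spec$hk_level_log2 + log2(spec$hk_ratios[a, 2]),
        spike_1 = , spike_2 = , spike_3 = spec$spike_level_log2,
        polya_dap = spec$polya_levels[a, 1],
        polya_lys = spec$polya_levels[a, 2],
        polya_phe = spec$polya_levels[a, 3],
        polya_thr = spec$polya_levels[a, 4])
    }
    for (cc in CONTROL_CLASSES) {
      rows <- which(sets$probeset_id == CONTROL_PROBESET_IDS[[cc]])
      for (a in seq_len(n)) pm_mu[rows, a] <- ctrl_mu_for(cc, a)
    }

    pm_noise <- matrix(stats::rnorm(n_pairs * n, 0, spec$noise_sd_log2), n_pairs, n)
    mm_noise <- matrix(stats::rnorm(n_pairs * n, 0, spec$noise_sd_log2), n_pairs, n)
    pm_log2 <- pm_mu + pm_noise

    # MM: half the PM signal; for absent spike-ins, MM tracks PM to within
    # a U(0.9, 1.1) factor so the detection call reads Absent.
    mm_raw <- 0.5 * 2^(pm_mu + mm_noise)
    for (s in 1:3) {
      rows <- which(sets$probeset_id == CONTROL_PROBESET_IDS[[paste0("spike_", s)]])
      for (a in seq_len(n)) {
        if (!spec$spike_present[a, s]) {
          u <- stats::runif(length(rows), 0.9, 1.1)
          mm_raw[rows, a] <- u * 2^(pm_log2[rows, a])
        }
      }
    }

    pm_raw <- 2^pm_log2
    raw <- rbind(pm_raw, mm_raw)
    for (a in seq_len(n)) {
      bg <- spec$background_levels[a]
      if (bg > 0) {
        raw[, a] <- raw[, a] +
          stats::rnorm(nrow(raw), bg, spec$bg_noise_frac * bg)
      }
    }
    pmax(raw, 0)
  })

  rownames(out) <- annotation$probe_id
  batch <- intensity_batch(out, sprintf("array%02d", seq_len(n)))

  truth <- structure(list(
    is_degradation_outlier = suppressWarnings(
      robust_outliers(spec$degradation_slopes, k = 2)),
    is_background_outlier = suppressWarnings(
      robust_outliers(spec$background_levels, k = 2)),
    is_hk_outlier = cbind(actin = spec$hk_ratios[, 1] > 3,
                          gapdh = spec$hk_ratios[, 2] > 3),
    is_spike_outlier = !spec$spike_present,
    is_polya_outlier = apply(spec$polya_levels, 2, function(v)
      suppressWarnings(robust_outliers(v, k = 2))),
    spec = spec
  ), class = "SyntheticTruth")

  list(annotation = annotation, geometry = geometry, batch = batch,
       manifest = manifest, truth = truth)
}

#' Write a generated dataset to disk
#'
#' Emits the three TSV interchange files plus a JSON ground-truth file.
#'
#' @param gen Result of [generate_batch()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic_dataset <- function(gen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.tsv"),
    intensities = file.path(dir, "intensities.tsv"),
    manifest = file.path(dir, "controls.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_probe_annotation(gen$annotation, paths["annotation"], gen$geometry)
  write_intensity_table(gen$batch, gen$annotation, paths["intensities"])
  write_control_manifest(gen$manifest, paths["manifest"])
  truth <- gen$truth
  truth$spec <- lapply(unclass(truth$spec), function(x) {
    if (is.matrix(x)) apply(x, 2, identity, simplify = FALSE) else x
  })
  jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Built-in validation scenarios
#'
#' `defect_scenario_spec()` builds a ten-array batch with one all-defect
#' array (elevated background, steep 5'->3' degradation trend, fivefold
#' housekeeping ratios, absent spike-ins, depressed poly-A controls) among
#' clean arrays whose parameters spread over bounded, evenly spaced ranges
#' so that every injected defect sits at five or more robust SD of the
#' clean spread. `cluster_scenario_spec()` builds a six-array batch with
#' two expression clusters plus one array carrying its own signature and
#' every defect, emulating a small study with a single failed array.
#'
#' @param seed Integer seed (also shuffles the clean-array parameter
#'   spreads).
#' @return A [synthetic_spec()].
#' @export
defect_scenario_spec <- function(seed = 1L) {
  n <- 10L
  spread <- function(lo, hi) {
    v <- seq(lo, hi, length.out = n - 1L)
    v[sample.int(n - 1L)]
  }
  with_seed(seed, {
    bg <- c(500, 100 + spread(-50, 50))
    slopes <- c(1.5, spread(0.05, 0.25))
    hk <- cbind(actin = c(5, 1.5 + spread(-0.3, 0.3)),
                gapdh = c(5, 1.2 + spread(-0.2, 0.2)))
    spike <- matrix(TRUE, n, 3); spike[1, ] <- FALSE
    base <- c(13, 10.5, 11.5, 12.5)
    polya <- matrix(rep(base, each = n), n, 4,
                    dimnames = list(NULL, c("dap", "lys", "phe", "thr")))
    for (j in 1:4) polya[2:n, j] <- polya[2:n, j] + spread(-0.4, 0.4)
    polya[1, ] <- polya[1, ] - 3
    synthetic_spec(n_arrays = n, n_probesets = 500L, noise_sd_log2 = 0.1,
                   degradation_slopes = slopes, background_levels = bg,
                   hk_ratios = hk, spike_present = spike,
                   polya_levels = polya, seed = seed)
  })
}

#' @rdname defect_scenario_spec
#' @export
cluster_scenario_spec <- function(seed = 1L) {
  n <- 6L
  bad <- 6L  # the failed array: separate cluster and every defect
  bg <- c(90, 100, 110, 95, 105, 400)
  slopes <- c(0.08, 0.10, 0.12, 0.09, 0.11, 1.2)
  hk <- cbind(actin = c(1.4, 1.5, 1.6, 1.45, 1.55, 5),
              gapdh = c(1.1, 1.2, 1.3, 1.15, 1.25, 4))
  spike <- matrix(TRUE, n, 3); spike[bad, ] <- FALSE
  polya <- matrix(rep(c(13, 10.5, 11.5, 12.5), each = n), n, 4,
                  dimnames = list(NULL, c("dap", "lys", "phe", "thr")))
  polya[1:5, ] <- polya[1:5, ] + c(-0.2, -0.1, 0, 0.1, 0.2)
  polya[bad, ] <- polya[bad, ] - 3
  synthetic_spec(n_arrays = n, degradation_slopes = slopes,
                 background_levels = bg, hk_ratios = hk,
                 spike_present = spike, polya_levels = polya,
                 cluster_assignment = c(1L, 1L, 1L, 2L, 2L, 3L),
                 cluster_offset_log2 = 1.5, seed = seed)
}
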