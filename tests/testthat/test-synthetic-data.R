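test_that("generation is deterministic under a fixed seed", {
  spec <- quick_spec(seed = 11L)
  g1 <- generate_batch(spec)
  g2 <- generate_batch(spec)
  expect_identical(g1$batch$intensities, g2$batch$intensities)
  expect_identical(g1$truth, g2$truth)
  # a different seed changes the data
  g3 <- generate_batch(quick_spec(seed = 12L))
  expect_false(identical(g1$batch$intensities, g3$batch$intensities))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_batch(quick_spec()))
  expect_identical(before, .Random.seed)
})

test_that("noiseless generation makes slope and ratio estimators exact", {
  slopes <- c(0, 0.12, 0.3, -0.05)
  spec <- quick_spec(
    n_arrays = 4L, noise_sd_log2 = 0, probe_sd_log2 = 0,
    degradation_slopes = slopes,
    background_levels = rep(0, 4),
    hk_ratios = cbind(actin = c(4, 1, 2, 1.5), gapdh = rep(1, 4)))
  gen <- generate_batch(spec)

  prof <- degradation_profile(gen$batch, gen$annotation, k = 11L)
  # noiseless profiles are exactly linear, so the +Inf t-stat sentinel fires
  fit <- suppressWarnings(degradation_slope(prof))
  expect_equal(fit$slope, slopes, tolerance = 1e-10)

  ratio <- three_prime_ratio(gen$batch, gen$annotation, gen$manifest, "actin")
  expect_equal(unname(ratio), c(4, 1, 2, 1.5), tolerance = 1e-10)

  lvl <- matrix(rep(c(11.5, 7, 8.5, 10), each = 4), 4, 4)
  sig <- control_signals(gen$batch, gen$annotation, gen$manifest)
  expect_equal(unname(sig$polya_signals), lvl, tolerance = 1e-10)
})

test_that("injected spike absence flips the detection call", {
  spec <- quick_spec(n_arrays = 3L,
                     spike_present = rbind(c(TRUE, TRUE, FALSE),
                                           c(TRUE, TRUE, TRUE),
                                           c(FALSE, FALSE, FALSE)))
  gen <- generate_batch(spec)
  sig <- control_signals(gen$batch, gen$annotation, gen$manifest)
  expect_equal(unname(sig$spike_calls[1, ]), c("Present", "Present", "Absent"))
  expect_equal(unname(sig$spike_calls[2, ]), rep("Present", 3))
  expect_equal(unname(sig$spike_calls[3, ]), rep("Absent", 3))
  expect_identical(unname(gen$truth$is_spike_outlier),
                   unname(!spec$spike_present))
})

test_that("raising one array's background shifts its measured background by that amount", {
  base <- quick_spec(bg_noise_frac = 0, noise_sd_log2 = 0.1,
                     background_levels = rep(40, 4))
  up <- quick_spec(bg_noise_frac = 0, noise_sd_log2 = 0.1,
                   background_levels = c(40, 40, 65, 40))
  g1 <- generate_batch(base); g2 <- generate_batch(up)
  b1 <- zonal_background_noise(g1$batch$intensities[, 3],
                               cbind(g1$annotation$x, g1$annotation$y),
                               g1$geometry)
  b2 <- zonal_background_noise(g2$batch$intensities[, 3],
                               cbind(g2$annotation$x, g2$annotation$y),
                               g2$geometry)
  expect_equal(b2$avg_background - b1$avg_background, 25, tolerance = 1e-9)
  expect_equal(b2$avg_noise, b1$avg_noise, tolerance = 1e-9)
})

test_that("truth labels follow the documented rules on injected parameters", {
  bg <- c(50, 52, 48, 51, 49, 200)
  hk <- cbind(actin = c(1.5, 1.4, 1.6, 1.5, 1.5, 5),
              gapdh = rep(1.2, 6))
  spec <- quick_spec(n_arrays = 6L, background_levels = bg, hk_ratios = hk)
  gen <- generate_batch(spec)
  expect_identical(unname(gen$truth$is_background_outlier),
                   c(rep(FALSE, 5), TRUE))
  expect_identical(unname(gen$truth$is_hk_outlier[, "actin"]),
                   c(rep(FALSE, 5), TRUE))
  expect_false(any(gen$truth$is_hk_outlier[, "gapdh"]))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_arrays = 1L), class = "qc_validation_error")
  expect_error(synthetic_spec(probes_per_set = 2L), class = "qc_validation_error")
  expect_error(synthetic_spec(degradation_slopes = c(0, 0)),
               class = "qc_validation_error")
  expect_error(synthetic_spec(background_levels = rep(-1, 6)),
               class = "qc_validation_error")
})

test_that("written datasets round-trip through the readers", {
  gen <- generate_batch(quick_spec(seed = 5L))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(gen, dir)
  expect_true(all(file.exists(paths)))
  ann <- read_probe_annotation(paths["annotation"])
  expect_equal(as.data.frame(ann$annotation), as.data.frame(gen$annotation))
  batch <- read_intensity_table(paths["intensities"], ann$annotation)
  expect_identical(batch$intensities, gen$batch$intensities)
  man <- read_control_manifest(paths["manifest"])
  expect_equal(as.data.frame(man), as.data.frame(gen$manifest))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(unlist(truth$is_background_outlier),
               unname(gen$truth$is_background_outlier))
})

test_that("arrays sharing a cluster sit closer on PC1 than arrays across clusters", {
  worse <- 0L
  for (seed in 1:20) {
    spec <- synthetic_spec(n_arrays = 6L, n_probesets = 60L,
                           cluster_assignment = c(1L, 1L, 1L, 2L, 2L, 2L),
                           cluster_offset_log2 = 1, seed = 1000L + seed)
    gen <- generate_batch(spec)
    expr <- normalize_expression(gen$batch, gen$annotation)
    pc1 <- pca_scores(expr)$scores[, 1]
    d <- abs(outer(pc1, pc1, "-"))
    same <- outer(spec$cluster_assignment, spec$cluster_assignment, "==")
    diag(same) <- NA
    within <- mean(d[same & !is.na(same)])
    between <- mean(d[!same & !is.na(same)])
    if (within >= between) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})
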