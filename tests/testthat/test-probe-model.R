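test_that("annotation validates structure and reports offending lines", {
  ann <- tiny_annotation(nset = 1L, k = 2L)
  expect_s3_class(ann, "ProbeAnnotation")
  expect_equal(length(unique(ann$probeset_id)), 1L)
  expect_equal(sort(ann$probe_index[ann$role == "PM"]), 1:2)

  # duplicate coordinates
  bad <- as.data.frame(ann)
  bad$x[2] <- bad$x[1]; bad$y[2] <- bad$y[1]
  expect_error(probe_annotation(bad), class = "qc_validation_error")

  # MM without a PM partner
  orphan <- as.data.frame(tiny_annotation(1L, 3L))
  orphan <- orphan[!(orphan$role == "PM" & orphan$pair_index == 2L), ]
  expect_error(probe_annotation(orphan), class = "qc_validation_error")

  # PM probe_index must run 1..k
  gap <- as.data.frame(tiny_annotation(1L, 3L))
  gap$probe_index[gap$role == "PM" & gap$probe_index == 2L] <- 5L
  expect_error(probe_annotation(gap), "1\\.\\.k")
})

test_that("annotation file round-trips and line numbers appear in errors", {
  ann <- tiny_annotation(2L, 11L)
  geom <- chip_geometry(max(ann$y) + 1L, max(ann$x) + 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(ann, f, geom)
  rt <- read_probe_annotation(f)
  expect_equal(as.data.frame(rt$annotation), as.data.frame(ann))
  expect_equal(rt$geometry$n_rows, geom$n_rows)
  # 22 PM + 22 MM over 2 sets of 11: probe_index runs 1..11 per set
  for (ps in unique(rt$annotation$probeset_id)) {
    pm <- rt$annotation[rt$annotation$probeset_id == ps &
                          rt$annotation$role == "PM", ]
    expect_equal(sort(pm$probe_index), 1:11)
  }

  # duplicated probe_id must name the line
  lines <- readLines(f)
  writeLines(c(lines, lines[length(lines)]), f)
  err <- tryCatch(read_probe_annotation(f), error = identity)
  expect_s3_class(err, "qc_format_error")
  expect_match(conditionMessage(err), "line \\d+")
})

test_that("geometry pragma overrides the bounding-box default", {
  ann <- tiny_annotation(1L, 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(ann, f, chip_geometry(12L, 9L))
  rt <- read_probe_annotation(f)
  expect_equal(c(rt$geometry$n_rows, rt$geometry$n_cols), c(12L, 9L))
  # too-small declared geometry is rejected
  write_probe_annotation(ann, f, chip_geometry(1L, 2L))
  expect_error(read_probe_annotation(f), class = "qc_validation_error")
})

test_that("intensity tables round-trip exactly and ignore row order", {
  ann <- tiny_annotation(2L, 11L)
  set.seed(1)
  vals <- matrix(stats::rexp(nrow(ann) * 3) * 100, nrow(ann), 3)
  rownames(vals) <- ann$probe_id
  batch <- intensity_batch(vals, c("x", "y", "z"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(batch, ann, f)
  rt <- read_intensity_table(f, ann)
  expect_identical(rt$intensities, batch$intensities)
  expect_equal(dim(rt$intensities), c(44L, 3L))

  # shuffle the body rows: identical batch
  lines <- readLines(f)
  body <- lines[-1]
  set.seed(2)
  writeLines(c(lines[1], sample(body)), f)
  rt2 <- read_intensity_table(f, ann)
  expect_identical(rt2$intensities, batch$intensities)
})

test_that("intensity reader rejects malformed input with line numbers", {
  ann <- tiny_annotation(1L, 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ta1",
               paste0(ann$probe_id[1], "\t-5"),
               paste(ann$probe_id[-1], 1, sep = "\t")), f)
  err <- tryCatch(read_intensity_table(f, ann), error = identity)
  expect_s3_class(err, "qc_validation_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c("probe_id\ta1",
               "no_such_probe\t5",
               paste(ann$probe_id[-1], 1, sep = "\t")), f)
  expect_error(read_intensity_table(f, ann), "unknown probe_id",
               class = "qc_validation_error")

  writeLines(c("probe_id\ta1\ta2",
               paste(ann$probe_id[1], 1, sep = "\t"),  # missing cell
               paste(ann$probe_id[-1], 1, 2, sep = "\t")), f)
  expect_error(read_intensity_table(f, ann), "line 2")
})

test_that("degenerate batches cannot be written", {
  ann <- tiny_annotation(1L, 2L)
  m <- matrix(1, nrow(ann), 1, dimnames = list(ann$probe_id, NULL))
  b <- intensity_batch(m, "a1")
  b$intensities[1, 1] <- Inf
  expect_error(write_intensity_table(b, ann, tempfile()),
               class = "qc_validation_error")
  b0 <- b; b0$intensities <- b$intensities[, 0, drop = FALSE]
  b0$array_names <- character(0)
  expect_error(write_intensity_table(b0, ann, tempfile()),
               class = "qc_validation_error")
  expect_error(intensity_batch(matrix(-1, 2, 1,
                                      dimnames = list(c("p", "q"), "a")), "a"),
               class = "qc_validation_error")
})

test_that("control manifest validates classes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probeset_id\tcontrol_class",
               paste(sprintf("CTL%02d", seq_along(CONTROL_CLASSES)),
                     CONTROL_CLASSES, sep = "\t")), f)
  man <- read_control_manifest(f)
  expect_s3_class(man, "ControlManifest")
  expect_equal(nrow(man), 13L)

  writeLines(c("probeset_id\tcontrol_class", "X\tspike_4"), f)
  expect_error(read_control_manifest(f), "spike_4", class = "qc_format_error")

  writeLines(c("probeset_id\tcontrol_class", "X\tspike_1", "Y\tspike_1"), f)
  expect_error(read_control_manifest(f), class = "qc_validation_error")
})

test_that("a manifest without gapdh_5 loads but the ratio then errors", {
  gen <- generate_batch(quick_spec())
  man <- gen$manifest[gen$manifest$control_class != "gapdh_5", ]
  class(man) <- class(gen$manifest)
  expect_error(three_prime_ratio(gen$batch, gen$annotation, man, "gapdh"),
               class = "qc_config_error")
  # actin is still fine
  expect_length(three_prime_ratio(gen$batch, gen$annotation, man, "actin"), 4L)
})
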