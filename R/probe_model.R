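# Domain types for probe-level data and the tab-separated interchange
# formats: probe annotation, intensity table and control-probe manifest.
# All files are UTF-8, tab-separated, one header row, '#' comment lines.

#' Recognised control-probe classes
#'
#' Housekeeping 3'/M/5' probe sets for beta-actin and GAPDH, three spike-in
#' probe sets and up to four poly-A control probe sets.
#'
#' @format Character vector of the 13 valid `control_class` tokens.
#' @export
CONTROL_CLASSES <- c(
  "actin_3", "actin_M", "actin_5",
  "gapdh_3", "gapdh_M", "gapdh_5",
  "spike_1", "spike_2", "spike_3",
  "polya_dap", "polya_lys", "polya_phe", "polya_thr"
)

#' Chip geometry
#'
#' @param n_rows,n_cols Positive integers giving the probe grid dimensions.
#' @return A `ChipGeometry` object.
#' @export
chip_geometry <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop_validation("chip geometry must have n_rows >= 1 and n_cols >= 1")
  structure(list(n_rows = n_rows, n_cols = n_cols), class = "ChipGeometry")
}

#' @export
print.ChipGeometry <- function(x, ...) {
  cat(sprintf("ChipGeometry: %d rows x %d cols\n", x$n_rows, x$n_cols))
  invisible(x)
}

ANNOTATION_COLUMNS <- c("probe_id", "probeset_id", "probe_index",
                        "pair_index", "role", "x", "y")

#' Construct a probe annotation table
#'
#' Each probe maps to a probe set, a 5'->3' position index within the set
#' (`probe_index`), a PM/MM pair number and 0-based chip coordinates.
#'
#' @param df A data.frame with columns
#'   `probe_id, probeset_id, probe_index, pair_index, role, x, y`.
#' @param line_numbers Optional per-row source line numbers used in error
#'   messages when validating a parsed file.
#' @return A validated `ProbeAnnotation` (a data.frame subclass).
#' @export
probe_annotation <- function(df, line_numbers = NULL) {
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop_format("probe annotation is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  df <- df[ANNOTATION_COLUMNS]
  if (is.null(line_numbers)) line_numbers <- seq_len(nrow(df))
  ln <- function(i) line_numbers[i]

  df$probe_id    <- as.character(df$probe_id)
  df$probeset_id <- as.character(df$probeset_id)
  df$role        <- as.character(df$role)
  for (col in c("probe_index", "pair_index", "x", "y")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_format("line %d: field '%s' is not an integer", ln(bad[1]), col)
    df[[col]] <- v
  }

  dup <- which(duplicated(df$probe_id))
  if (length(dup))
    stop_format("line %d: duplicate probe_id '%s'", ln(dup[1]), df$probe_id[dup[1]])
  bad_role <- which(!df$role %in% c("PM", "MM"))
  if (length(bad_role))
    stop_format("line %d: field 'role' must be PM or MM, got '%s'",
                ln(bad_role[1]), df$role[bad_role[1]])
  neg <- which(df$x < 0L | df$y < 0L | df$probe_index < 1L | df$pair_index < 1L)
  if (length(neg))
    stop_validation("line %d: field 'x'/'y' must be >= 0 and indices >= 1 (probe '%s')",
                    ln(neg[1]), df$probe_id[neg[1]])
  xy <- paste(df$x, df$y)
  dup_xy <- which(duplicated(xy))
  if (length(dup_xy))
    stop_validation("line %d: field 'x,y' coordinate (%d,%d) already used",
                    ln(dup_xy[1]), df$x[dup_xy[1]], df$y[dup_xy[1]])

  # within each probe set PM probe_index must run 1..k; each MM needs a PM
  # partner with the same pair_index
  for (ps in unique(df$probeset_id)) {
    rows <- df[df$probeset_id == ps, ]
    pm <- rows[rows$role == "PM", ]
    if (nrow(pm) == 0L)
      stop_validation("probe set '%s' has no PM probes", ps)
    idx <- sort(pm$probe_index)
    if (!identical(idx, seq_len(nrow(pm))))
      stop_validation("probe set '%s': PM probe_index values must form 1..k, got {%s}",
                      ps, paste(idx, collapse = ","))
    mm <- rows[rows$role == "MM", ]
    orphan <- setdiff(mm$pair_index, pm$pair_index)
    if (length(orphan))
      stop_validation("probe set '%s': MM pair_index %d has no PM partner",
                      ps, orphan[1])
  }
  rownames(df) <- NULL
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

# Parse a tab-separated body keeping track of original line numbers.
# Returns list(header = character, rows = list of character vectors,
#              line_numbers = integer, pragmas = named character).
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pragmas <- character(0)
  prg <- grep("^#\\s*([A-Za-z_]+)\\s*:", lines, value = TRUE)
  if (length(prg)) {
    keys <- sub("^#\\s*([A-Za-z_]+)\\s*:.*$", "\\1", prg)
    vals <- trimws(sub("^#\\s*[A-Za-z_]+\\s*:", "", prg))
    pragmas <- stats::setNames(vals, keys)
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop_format("%s: no header row found", path)
  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  body_idx <- idx[-1]
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  list(header = header, rows = rows, line_numbers = body_idx, pragmas = pragmas)
}

#' Read a probe annotation file
#'
#' Tab-separated with header
#' `probe_id probeset_id probe_index pair_index role x y`. Chip geometry is
#' inferred as the coordinate bounding box `(max x + 1, max y + 1)` unless a
#' `# geometry: <n_rows> <n_cols>` pragma is present.
#'
#' @param path Path to the annotation TSV.
#' @return A list with elements `annotation` (a [probe_annotation()]) and
#'   `geometry` (a [chip_geometry()]).
#' @export
read_probe_annotation <- function(path) {
  parsed <- read_tsv_lines(path)
  if (!identical(parsed$header, ANNOTATION_COLUMNS))
    stop_format("%s: header must be '%s'", path,
                paste(ANNOTATION_COLUMNS, collapse = "\t"))
  nf <- lengths(parsed$rows)
  bad <- which(nf != length(ANNOTATION_COLUMNS))
  if (length(bad))
    stop_format("line %d: expected %d fields, found %d",
                parsed$line_numbers[bad[1]], length(ANNOTATION_COLUMNS), nf[bad[1]])
  df <- as.data.frame(do.call(rbind, parsed$rows), stringsAsFactors = FALSE)
  names(df) <- ANNOTATION_COLUMNS
  ann <- probe_annotation(df, line_numbers = parsed$line_numbers)
  if (!is.na(pr <- parsed$pragmas["geometry"]) && length(pr)) {
    dims <- suppressWarnings(as.integer(strsplit(trimws(pr), "\\s+")[[1]]))
    if (length(dims) != 2L || anyNA(dims))
      stop_format("%s: geometry pragma must be '# geometry: <n_rows> <n_cols>'", path)
    geom <- chip_geometry(dims[1], dims[2])
  } else {
    geom <- chip_geometry(max(ann$y) + 1L, max(ann$x) + 1L)
  }
  if (geom$n_rows * geom$n_cols < nrow(ann))
    stop_validation("geometry %dx%d too small for %d probes",
                    geom$n_rows, geom$n_cols, nrow(ann))
  if (any(ann$x >= geom$n_cols) || any(ann$y >= geom$n_rows))
    stop_validation("probe coordinates exceed declared geometry %dx%d",
                    geom$n_rows, geom$n_cols)
  list(annotation = ann, geometry = geom)
}

#' Construct an intensity batch
#'
#' @param intensities Numeric matrix, rows = probes (in annotation order,
#'   rownames = probe ids), columns = arrays; non-negative fluorescence.
#' @param array_names Optional character vector of array names (defaults to
#'   the matrix column names).
#' @return An `IntensityBatch` object.
#' @export
intensity_batch <- function(intensities, array_names = colnames(intensities)) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_validation("intensities must be a numeric matrix")
  if (is.null(array_names) || length(array_names) != ncol(intensities))
    stop_validation("array_names must match the number of intensity columns")
  array_names <- as.character(array_names)
  if (anyDuplicated(array_names))
    stop_validation("array names must be unique")
  if (is.null(rownames(intensities)))
    stop_validation("intensity matrix needs probe_id rownames")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop_validation("intensities must be finite and non-missing")
  if (any(intensities < 0))
    stop_validation("intensities must be non-negative")
  colnames(intensities) <- array_names
  structure(list(intensities = intensities, array_names = array_names),
            class = "IntensityBatch")
}

#' @export
print.IntensityBatch <- function(x, ...) {
  cat(sprintf("IntensityBatch: %d probes x %d arrays (%s%s)\n",
              nrow(x$intensities), length(x$array_names),
              paste(utils::head(x$array_names, 3), collapse = ", "),
              if (length(x$array_names) > 3) ", ..." else ""))
  invisible(x)
}

n_arrays <- function(batch) length(batch$array_names)

#' Read an intensity table
#'
#' Tab-separated with a `probe_id` column followed by one column per array.
#' Rows may be in any order; the result is aligned to annotation order.
#'
#' @param path Path to the intensity TSV.
#' @param annotation A [probe_annotation()] the probes must match exactly.
#' @return An [intensity_batch()].
#' @export
read_intensity_table <- function(path, annotation) {
  parsed <- read_tsv_lines(path)
  if (parsed$header[1] != "probe_id" || length(parsed$header) < 2L)
    stop_format("%s: header must start with 'probe_id' plus one column per array", path)
  arrays <- parsed$header[-1]
  if (anyDuplicated(arrays))
    stop_format("%s: duplicate array name '%s'", path, arrays[duplicated(arrays)][1])
  nf <- lengths(parsed$rows)
  bad <- which(nf != length(parsed$header))
  if (length(bad))
    stop_validation("line %d: expected %d cells, found %d (missing cell?)",
                    parsed$line_numbers[bad[1]], length(parsed$header), nf[bad[1]])
  mat <- do.call(rbind, parsed$rows)
  ids <- mat[, 1]
  unknown <- which(!ids %in% annotation$probe_id)
  if (length(unknown))
    stop_validation("line %d: unknown probe_id '%s'",
                    parsed$line_numbers[unknown[1]], ids[unknown[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop_validation("line %d: duplicate probe_id '%s'",
                    parsed$line_numbers[dup[1]], ids[dup[1]])
  if (length(ids) != nrow(annotation))
    stop_validation("%s: %d probes present but annotation has %d",
                    path, length(ids), nrow(annotation))
  vals <- suppressWarnings(matrix(as.numeric(mat[, -1, drop = FALSE]),
                                  nrow = nrow(mat)))
  bad_num <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad_num) > 0L)
    stop_validation("line %d: field '%s' is not numeric",
                    parsed$line_numbers[bad_num[1, 1]], arrays[bad_num[1, 2]])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_validation("line %d: field '%s' has a negative intensity",
                    parsed$line_numbers[neg[1, 1]], arrays[neg[1, 2]])
  rownames(vals) <- ids
  vals <- vals[annotation$probe_id, , drop = FALSE]
  intensity_batch(vals, arrays)
}

#' Write an intensity table
#'
#' Values are serialized with 17 significant digits so a read/write
#' round-trip reproduces the matrix bit for bit.
#'
#' @param batch An [intensity_batch()] aligned to `annotation`.
#' @param annotation The matching [probe_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(batch, annotation, path) {
  if (n_arrays(batch) == 0L)
    stop_validation("batch has no arrays; nothing to write")
  if (!identical(rownames(batch$intensities), annotation$probe_id))
    stop_validation("batch is not aligned to the annotation probe order")
  if (any(!is.finite(batch$intensities)))
    stop_validation("batch contains non-finite intensities")
  body <- apply(batch$intensities, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = 1L)
  lines <- c(
    paste(c("probe_id", batch$array_names), collapse = "\t"),
    apply(cbind(annotation$probe_id, body), 1, paste, collapse = "\t")
  )
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write intensity table to '%s'", path)
  invisible(path)
}

#' Write a probe annotation file
#'
#' @param annotation A [probe_annotation()].
#' @param geometry Optional [chip_geometry()]; written as a header pragma.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path, geometry = NULL) {
  lines <- character(0)
  if (!is.null(geometry))
    lines <- sprintf("# geometry: %d %d", geometry$n_rows, geometry$n_cols)
  lines <- c(lines, paste(ANNOTATION_COLUMNS, collapse = "\t"),
             apply(annotation, 1, function(r) paste(trimws(r), collapse = "\t")))
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write annotation to '%s'", path)
  invisible(path)
}

#' Construct a control-probe manifest
#'
#' @param probeset_id Character vector of probe-set identifiers.
#' @param control_class Character vector of classes from [CONTROL_CLASSES].
#' @param line_numbers Optional source line numbers for error messages.
#' @return A `ControlManifest` (a data.frame subclass).
#' @export
control_manifest <- function(probeset_id, control_class, line_numbers = NULL) {
  probeset_id <- as.character(probeset_id)
  control_class <- as.character(control_class)
  if (length(probeset_id) != length(control_class))
    stop_validation("probeset_id and control_class must have equal length")
  if (is.null(line_numbers)) line_numbers <- seq_along(probeset_id)
  unknown <- which(!control_class %in% CONTROL_CLASSES)
  if (length(unknown))
    stop_format("line %d: unknown control_class '%s'",
                line_numbers[unknown[1]], control_class[unknown[1]])
  dup <- which(duplicated(control_class))
  if (length(dup))
    stop_validation("line %d: duplicate control_class '%s'",
                    line_numbers[dup[1]], control_class[dup[1]])
  df <- data.frame(probeset_id = probeset_id, control_class = control_class,
                   stringsAsFactors = FALSE)
  class(df) <- c("ControlManifest", "data.frame")
  df
}

#' Read a control-probe manifest
#'
#' Two tab-separated columns: `probeset_id  control_class`.
#'
#' @param path Path to the manifest TSV.
#' @return A [control_manifest()].
#' @export
read_control_manifest <- function(path) {
  parsed <- read_tsv_lines(path)
  if (!identical(parsed$header, c("probeset_id", "control_class")))
    stop_format("%s: header must be 'probeset_id\tcontrol_class'", path)
  nf <- lengths(parsed$rows)
  bad <- which(nf != 2L)
  if (length(bad))
    stop_format("line %d: expected 2 fields, found %d",
                parsed$line_numbers[bad[1]], nf[bad[1]])
  mat <- do.call(rbind, parsed$rows)
  control_manifest(mat[, 1], mat[, 2], line_numbers = parsed$line_numbers)
}

#' Write a control-probe manifest
#'
#' @param manifest A [control_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_control_manifest <- function(manifest, path) {
  lines <- c("probeset_id\tcontrol_class",
             paste(manifest$probeset_id, manifest$control_class, sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write manifest to '%s'", path)
  invisible(path)
}

# Look up the probe set mapped to a control class; NA if absent.
manifest_probeset <- function(manifest, class_name) {
  i <- match(class_name, manifest$control_class)
  if (is.na(i)) NA_character_ else manifest$probeset_id[i]
}

# Row indices (into annotation/batch) of PM probes of one probe set.
pm_rows <- function(annotation, probeset_id) {
  which(annotation$probeset_id == probeset_id & annotation$role == "PM")
}

mm_rows <- function(annotation, probeset_id) {
  which(annotation$probeset_id == probeset_id & annotation$role == "MM")
}
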