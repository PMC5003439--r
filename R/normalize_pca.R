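# Quantile normalization (no background adjustment), median-polish
# summarization to probe-set expression, and mean-centred PCA.

#' Quantile normalization
#'
#' Forces all columns (arrays) to share one distribution: the reference is
#' the row-wise mean of the column-sorted matrix, and each column's values
#' are replaced by the reference values at their ranks. Ties within a
#' column receive the mean of the reference values at their tied ranks.
#'
#' @param m Numeric matrix, probes x arrays, no missing values.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_validation("m must be a numeric matrix")
  if (anyNA(m)) stop_validation("m must not contain missing values")
  if (ncol(m) < 2L) {
    warning("single array: quantile normalization is the identity")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    # average the reference over blocks of tied input values
    out[o, j] <- stats::ave(ref, match(m[o, j], unique(m[o, j])), FUN = mean)
  }
  out
}

# Two-way median polish of one probes x arrays matrix. Absolute stopping
# rule: iterate until the summed absolute row+column adjustments fall
# below tol, or max_iter sweeps. Returns list(overall, row, col, residuals).
median_polish_fit <- function(x, max_iter = 10L, tol = 0.01) {
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  res <- x
  for (it in seq_len(max_iter)) {
    rdelta <- apply(res, 1, stats::median)
    res <- sweep(res, 1, rdelta)
    row_eff <- row_eff + rdelta
    cdelta <- apply(res, 2, stats::median)
    res <- sweep(res, 2, cdelta)
    col_eff <- col_eff + cdelta
    shift <- stats::median(row_eff)
    row_eff <- row_eff - shift
    overall <- overall + shift
    shift <- stats::median(col_eff)
    col_eff <- col_eff - shift
    overall <- overall + shift
    if (sum(abs(rdelta)) + sum(abs(cdelta)) < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = res)
}

#' Median-polish summarization to probe-set expression
#'
#' Per probe set, a two-way median polish of the probes x arrays log2
#' matrix; the expression of array j is `overall effect + column effect j`
#' (row/probe effects are excluded, as in RMA summarization).
#'
#' @param log2_pm Numeric matrix of log2 PM intensities (probes x arrays).
#' @param probeset Character/factor of probe-set ids, one per row.
#' @param max_iter Maximum polish sweeps (default 10).
#' @param tol Absolute convergence tolerance on the log2 scale (default 0.01).
#' @return An `ExpressionMatrix`: probe sets x arrays numeric matrix with
#'   probe-set rownames.
#' @export
median_polish_summarize <- function(log2_pm, probeset, max_iter = 10L, tol = 0.01) {
  if (any(!is.finite(log2_pm))) stop_validation("log2_pm must be finite")
  if (length(probeset) != nrow(log2_pm))
    stop_validation("probeset must have one entry per row of log2_pm")
  probeset <- as.character(probeset)
  ids <- unique(probeset)
  out <- matrix(NA_real_, length(ids), ncol(log2_pm),
                dimnames = list(ids, colnames(log2_pm)))
  for (ps in ids) {
    x <- log2_pm[probeset == ps, , drop = FALSE]
    if (nrow(x) == 1L) {
      out[ps, ] <- x[1, ]
    } else {
      fit <- median_polish_fit(x, max_iter = max_iter, tol = tol)
      out[ps, ] <- fit$overall + fit$col
    }
  }
  structure(out, class = c("ExpressionMatrix", class(out)))
}

#' Normalize a batch to probe-set expression
#'
#' PM probes only: quantile normalization of the raw intensities (no
#' background adjustment), log2 transform, then median-polish
#' summarization per probe set.
#'
#' @param batch An [intensity_batch()].
#' @param annotation The matching [probe_annotation()].
#' @inheritParams median_polish_summarize
#' @return An `ExpressionMatrix` (probe sets x arrays, log2 scale).
#' @export
normalize_expression <- function(batch, annotation, max_iter = 10L, tol = 0.01) {
  pm <- annotation$role == "PM"
  m <- batch$intensities[pm, , drop = FALSE]
  qn <- quantile_normalize(m)
  median_polish_summarize(log2(pmax(qn, 2^-20)), annotation$probeset_id[pm],
                          max_iter = max_iter, tol = tol)
}

#' Mean-centred principal component scores
#'
#' Each probe-set row is centred to mean 0 across arrays; the centred
#' matrix is decomposed by SVD. Scores are the array-side projections
#' (`V %*% diag(d)`), and `variance_explained[i] = d_i^2 / sum(d^2)`. Sign
#' convention: the largest-magnitude element of each probe-side loading
#' vector is positive.
#'
#' @param expr An [median_polish_summarize()] expression matrix
#'   (probe sets x arrays).
#' @param n_components Number of components to keep (default 2; clipped to
#'   the matrix rank bound with a warning).
#' @return A `PcaResult` with `scores` (arrays x components, array
#'   rownames) and `variance_explained`.
#' @export
pca_scores <- function(expr, n_components = 2L) {
  if (ncol(expr) < 2L) stop_validation("PCA needs >= 2 arrays")
  if (any(!is.finite(expr))) stop_validation("expression matrix must be finite")
  maxc <- min(dim(expr))
  if (n_components > maxc) {
    warning(sprintf("n_components clipped from %d to %d", n_components, maxc))
    n_components <- maxc
  }
  xc <- expr - rowMeans(expr)
  s <- svd(xc)
  for (i in seq_along(s$d)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  total <- sum(s$d^2)
  ve <- if (total > 0) s$d^2 / total else rep(0, length(s$d))
  scores <- s$v %*% diag(s$d, nrow = length(s$d))
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_along(s$d))
  structure(list(scores = scores[, seq_len(n_components), drop = FALSE],
                 variance_explained = ve[seq_len(n_components)],
                 all_variance_explained = ve),
            class = "PcaResult")
}
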