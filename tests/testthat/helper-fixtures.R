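# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# A minimal hand-written annotation: `nset` probe sets of `k` PM/MM pairs.
tiny_annotation <- function(nset = 2L, k = 2L) {
  ps <- sprintf("PS%02d", seq_len(nset))
  n_pairs <- nset * k
  df <- data.frame(
    probe_id = c(sprintf("%s_pm%d", rep(ps, each = k), rep(seq_len(k), nset)),
                 sprintf("%s_mm%d", rep(ps, each = k), rep(seq_len(k), nset))),
    probeset_id = rep(rep(ps, each = k), 2),
    probe_index = rep(rep(seq_len(k), nset), 2),
    pair_index = rep(rep(seq_len(k), nset), 2),
    role = rep(c("PM", "MM"), each = n_pairs),
    x = 0:(2 * n_pairs - 1) %% (2 * k),
    y = 0:(2 * n_pairs - 1) %/% (2 * k),
    stringsAsFactors = FALSE
  )
  probe_annotation(df)
}

tiny_batch <- function(annotation, values, arrays = c("a1", "a2", "a3")) {
  m <- matrix(values, nrow = nrow(annotation), ncol = length(arrays))
  rownames(m) <- annotation$probe_id
  intensity_batch(m, arrays)
}

# A clean small synthetic spec for fast end-to-end tests.
quick_spec <- function(n_arrays = 4L, n_probesets = 30L, seed = 42L, ...) {
  synthetic_spec(n_arrays = n_arrays, n_probesets = n_probesets,
                 seed = seed, ...)
}

# Exact one-sided signed-rank p-value by explicit enumeration of all 2^n
# sign assignments (independent oracle for detection_call).
brute_force_signed_rank_p <- function(pm, mm, tau) {
  r_score <- (pm - mm) / (pm + mm)
  d <- r_score - tau
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% rk
  mean(Ws >= W)
}

# A minimal QCReport-shaped object for the rendering tests.
fake_report <- function(flag_pattern) {
  n <- nrow(flag_pattern$hk)
  anames <- sprintf("arr%d", seq_len(n))
  slopes <- seq(0.1, 0.3, length.out = n)
  structure(list(
    array_names = anames,
    pca = list(scores = cbind(PC1 = seq(-1, 1, length.out = n),
                              PC2 = rep(0, n))),
    variance_explained = c(0.7, 0.2),
    degradation = data.frame(array = anames, slope = slopes),
    colors = degradation_colors(stats::setNames(slopes, anames)),
    flags = structure(flag_pattern, class = "QCFlags"),
    order = display_order(slopes, anames)
  ), class = "QCReport")
}

clean_flags <- function(n) {
  list(bg_noise = matrix(FALSE, n, 2, dimnames = list(NULL, c("background", "noise"))),
       hk = matrix(FALSE, n, 2, dimnames = list(NULL, c("actin", "gapdh"))),
       spike = matrix(FALSE, n, 3),
       polya = matrix(FALSE, n, 4),
       degradation = rep(FALSE, n))
}
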