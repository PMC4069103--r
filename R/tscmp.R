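#' Configuration for RMSD time-series comparison
#'
#' Holds the knobs of the trajectory-comparison protocol: moving-average
#' smoothing window, the set of DTW warping windows to examine, the window
#' used for reported statistics, and the expected series length (the
#' trailing number of frames each series is truncated to before
#' comparison). Defaults follow the published protocol: 10-frame smoothing,
#' warping windows {0, 100, 250, 500, 750, 900, 1000}, statistics reported
#' at window 500, series of 2000 frames (the last 10 ns at 5 ps/frame).
#'
#' @param ma_window Moving-average window, frames (>= 1).
#' @param dtw_windows Integer vector of warping windows; 0 means no DTW
#'   (frame-by-frame pairing, equal lengths required).
#' @param report_window The warping window used by [compare_models()]; must
#'   be one of `dtw_windows`.
#' @param expected_length Trailing frames analysed per series.
#' @param significance_f f at or below which a comparison is flagged
#'   significant (default 0.05).
#' @return List of class `phstab_tscfg`.
#' @export
ts_compare_config <- function(ma_window = 10,
                              dtw_windows = c(0, 100, 250, 500, 750, 900, 1000),
                              report_window = 500,
                              expected_length = 2000,
                              significance_f = 0.05) {
  stopifnot(
    ma_window >= 1, all(dtw_windows >= 0),
    report_window %in% dtw_windows, expected_length >= 1
  )
  structure(
    list(
      ma_window = as.integer(ma_window),
      dtw_windows = as.integer(dtw_windows),
      report_window = as.integer(report_window),
      expected_length = as.integer(expected_length),
      significance_f = significance_f
    ),
    class = "phstab_tscfg"
  )
}

#' Centered moving-average smoothing
#'
#' Same-length smoothing: element k is the mean of a centered window of
#' `window` frames, truncated at the series edges (so output length equals
#' input length and constant series pass through unchanged).
#'
#' @param series Numeric vector.
#' @param window Window size in frames (>= 1); even windows extend one
#'   frame further to the right.
#' @return Smoothed numeric vector of the same length.
#' @export
#' @examples
#' smooth_moving_average(c(1, 2, 3, 4, 5), 3) # 1.5 2 3 4 4.5
smooth_moving_average <- function(series, window = 10) {
  if (length(series) == 0) abort("empty series")
  stopifnot(window >= 1)
  n <- length(series)
  left <- floor((window - 1) / 2)
  right <- floor(window / 2)
  vapply(seq_len(n), function(k) {
    mean(series[max(1, k - left):min(n, k + right)])
  }, numeric(1))
}

#' Dynamic time warping alignment of two scalar series
#'
#' Minimal-total-cost monotone alignment under local cost `|a_i - b_j|`,
#' symmetric unit-weight steps and a warping-window (band) constraint
#' `|i - j| <= window`. `window = 0` means no warping: the identity pairing
#' of equal-length series. Traceback ties break deterministically (diagonal
#' preferred, then advancing along `a`).
#'
#' @param series_a,series_b Numeric vectors (non-empty).
#' @param window Band half-width in frames; 0 disables DTW.
#' @return Tibble with columns `i`, `j` (1-based indices into the two
#'   series) and attributes `cost` (total alignment cost) and `window`.
#' @export
dtw_align <- function(series_a, series_b, window) {
  n <- length(series_a)
  m <- length(series_b)
  if (n == 0 || m == 0) abort("empty series")
  if (window == 0) {
    if (n != m) abort("window 0 (no DTW) requires equal-length series")
    path <- tibble::tibble(i = seq_len(n), j = seq_len(n))
    attr(path, "cost") <- sum(abs(series_a - series_b))
    attr(path, "window") <- 0L
    return(path)
  }
  if (window < abs(n - m)) {
    abort("band narrower than the length difference: no admissible path")
  }
  res <- .dtw_core(as.numeric(series_a), as.numeric(series_b), as.integer(window))
  path <- tibble::tibble(i = res$path[, 1], j = res$path[, 2])
  attr(path, "cost") <- res$cost
  attr(path, "window") <- as.integer(window)
  path
}

#' Alignment cost of a DTW path
#' @param path Result of [dtw_align()].
#' @return Total alignment cost.
#' @export
dtw_cost <- function(path) attr(path, "cost")

#' Delta-RMSD and overlap frequency f along an alignment
#'
#' For an alignment of two RMSD series (series 1 = MD1, series 2 = MD2),
#' `delta_rmsd` is the mean of `b_j - a_i` over path elements (signed:
#' positive when the second series runs higher) and `f` is the fraction of
#' path elements with `a_i >= b_j` (non-strict, so self-comparison gives
#' f = 1). Low f flags a significant difference in conformational mobility
#' between the two trajectories.
#'
#' @param series_a,series_b The two series the path refers to.
#' @param path Alignment from [dtw_align()].
#' @return One-row tibble: `delta_rmsd`, `f`, `n_pairs`.
#' @export
delta_and_f <- function(series_a, series_b, path) {
  if (nrow(path) == 0) abort("empty path")
  a <- series_a[path$i]
  b <- series_b[path$j]
  tibble::tibble(
    delta_rmsd = mean(b - a),
    f = mean(a >= b),
    n_pairs = nrow(path)
  )
}

# truncate to trailing expected_length frames, then smooth
prep_series <- function(x, config) {
  if (is.data.frame(x)) x <- x$rmsd
  x <- as.numeric(x)
  if (length(x) > config$expected_length) {
    x <- tail(x, config$expected_length)
  }
  smooth_moving_average(x, config$ma_window)
}

compare_pair <- function(a, b, window, config) {
  path <- dtw_align(a, b, window)
  delta_and_f(a, b, path)
}

#' Compare two replicate sets of RMSD series
#'
#' The full comparison protocol for two models (e.g. two pH conditions or
#' wild type vs mutant), each represented by one or more replicate RMSD
#' series: every series is truncated to the trailing `expected_length`
#' frames and smoothed, then every ordered pair (set 1 series as MD1,
#' set 2 series as MD2) is DTW-aligned at `report_window` and its
#' delta-RMSD and f computed. Reported are the mean and sample SD of
#' delta-RMSD and the mean f over all pairwise comparisons.
#'
#' @param series_set_1,series_set_2 Lists of numeric vectors (or of
#'   [rmsd_series()] tibbles, whose `rmsd` column is used). A single vector
#'   or tibble is promoted to a one-element list.
#' @param config [ts_compare_config()].
#' @param detail Also return the per-pair table (attribute `"pairs"`).
#' @return One-row tibble: `delta_rmsd`, `delta_sd`, `f`, `window`,
#'   `n_pairs`.
#' @export
compare_models <- function(series_set_1, series_set_2,
                           config = ts_compare_config(), detail = FALSE) {
  as_set <- function(s) {
    if (is.data.frame(s) || is.numeric(s)) list(s) else s
  }
  s1 <- lapply(as_set(series_set_1), prep_series, config = config)
  s2 <- lapply(as_set(series_set_2), prep_series, config = config)
  if (length(s1) == 0 || length(s2) == 0) abort("each set needs >= 1 series")
  grid <- expand.grid(p = seq_along(s1), q = seq_along(s2))
  pairs <- purrr::map2_dfr(grid$p, grid$q, function(p, q) {
    dplyr::mutate(
      compare_pair(s1[[p]], s2[[q]], config$report_window, config),
      series_1 = p, series_2 = q
    )
  })
  out <- tibble::tibble(
    delta_rmsd = mean(pairs$delta_rmsd),
    delta_sd = if (nrow(pairs) > 1) stats::sd(pairs$delta_rmsd) else 0,
    f = mean(pairs$f),
    window = config$report_window,
    n_pairs = nrow(pairs)
  )
  if (detail) attr(out, "pairs") <- pairs
  out
}

#' Sensitivity of delta-RMSD and f to the warping window
#'
#' Recomputes the pair comparison at every configured warping window. Used
#' to verify that conclusions do not hinge on the band width (and that the
#' window-0, no-DTW delta is the largest in magnitude, as frame-by-frame
#' pairing reduces the comparison to a difference of series means).
#'
#' @param series_a,series_b Numeric vectors or [rmsd_series()] tibbles.
#' @param config [ts_compare_config()].
#' @return Tibble with one row per window: `window`, `delta_rmsd`, `f`.
#' @export
window_sensitivity <- function(series_a, series_b,
                               config = ts_compare_config()) {
  a <- prep_series(series_a, config)
  b <- prep_series(series_b, config)
  purrr::map_dfr(config$dtw_windows, function(w) {
    if (w == 0 && length(a) != length(b)) {
      return(NULL)
    }
    res <- compare_pair(a, b, w, config)
    tibble::tibble(window = w, delta_rmsd = res$delta_rmsd, f = res$f)
  })
}
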