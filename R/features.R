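#' Time-series features for one variable
#'
#' Computes the eight summary features used to characterise each sensor
#' variable before variable selection: mean, standard deviation, curvature,
#' excess kurtosis, linearity, Shannon entropy, skewness and trend
#' strength.
#'
#' Conventions (each configurable where a parameter exists):
#' \itemize{
#'   \item `sd`: sample standard deviation (denominator n - 1).
#'   \item `skewness`, `kurtosis`: bias-corrected sample moments
#'     ([e1071::skewness()] / [e1071::kurtosis()], type 2); kurtosis is
#'     excess (a normal sample is near 0).
#'   \item `shannon_entropy`: histogram entropy over `n_bins` equal-width
#'     bins spanning `[min, max]`, natural log, with `0 log 0 := 0`; lies
#'     in `[0, log(n_bins)]` and is invariant under positive affine maps
#'     of the data (bins follow the data range).
#'   \item `trend`: strength of trend `max(0, 1 - Var(remainder) /
#'     Var(series))` from a centred moving-average decomposition with an
#'     odd `window` (default `min(7, ...)` shrunk for short series); in
#'     `[0, 1]`, 1 for a noiseless trend.
#'   \item `linearity`, `curvature`: the degree-1 and degree-2
#'     coefficients of an orthogonal-polynomial regression of the trend
#'     component on time; unbounded, sign reflects direction of the
#'     (curved) trend.
#' }
#' A constant series returns `sd = 0`, `entropy = 0`, `skewness = 0`,
#' `kurtosis = 0`, `trend = 0`, `linearity = 0`, `curvature = 0` by
#' convention.
#'
#' @param series numeric vector, length >= 4, all values finite.
#' @param n_bins number of histogram bins for the entropy, default 10.
#' @param window odd moving-average window for the trend decomposition;
#'   `NULL` picks `min(7, 2 * floor(length/3) + 1)`.
#' @return A one-row data frame of class `feature_vector` with columns
#'   `mean`, `sd`, `curvature`, `kurtosis`, `linearity`,
#'   `shannon_entropy`, `skewness`, `trend`.
#' @examples
#' compute_features(sin(seq(0, 4 * pi, length.out = 100)))
#' @export
compute_features <- function(series, n_bins = 10, window = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4) stop("series must have length >= 4")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  if (n_bins < 2) stop("n_bins must be >= 2")

  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    out <- data.frame(mean = m, sd = 0, curvature = 0, kurtosis = 0,
                      linearity = 0, shannon_entropy = 0, skewness = 0,
                      trend = 0)
    class(out) <- c("feature_vector", "data.frame")
    return(out)
  }

  skew <- e1071::skewness(x, type = 2)
  kurt <- e1071::kurtosis(x, type = 2)

  # histogram entropy: equal-width bins over the observed range
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts / n
  p <- p[p > 0]
  entropy <- -sum(p * log(p))

  dec <- trend_decompose(x, window)
  var_rem <- stats::var(dec$remainder)
  trend_strength <- max(0, 1 - var_rem / stats::var(dec$series))
  tt <- seq_along(dec$trend)
  co <- stats::coef(stats::lm(dec$trend ~ stats::poly(tt, 2)))
  out <- data.frame(mean = m, sd = s,
                    curvature = unname(co[3]), kurtosis = kurt,
                    linearity = unname(co[2]), shannon_entropy = entropy,
                    skewness = skew, trend = trend_strength)
  class(out) <- c("feature_vector", "data.frame")
  out
}

# centred moving-average trend; trend and remainder restricted to the
# interior where the full window fits
trend_decompose <- function(x, window = NULL) {
  n <- length(x)
  if (is.null(window)) {
    window <- min(7, 2 * (n %/% 3) + 1)
  }
  if (window %% 2 == 0) window <- window + 1
  window <- max(3, min(window, if (n %% 2 == 0) n - 1 else n))
  half <- (window - 1) / 2
  tr <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  keep <- (half + 1):(n - half)
  list(trend = tr[keep], remainder = x[keep] - tr[keep], series = x[keep])
}

#' Feature table for every variable of an activity table
#'
#' Applies [compute_features()] column-wise to the nine variables of an
#' activity table (or to every column of a plain numeric data frame),
#' returning one feature row per variable.
#'
#' @param table an `activity_table`, or any data frame of numeric columns.
#' @param n_bins,window passed to [compute_features()].
#' @return A data frame of class `feature_table`: one row per variable,
#'   rownames are the variable names, columns the eight features.
#' @examples
#' tab <- read_activity_table(cattlemc_example("activity"))
#' build_feature_table(tab)
#' @export
build_feature_table <- function(table, n_bins = 10, window = NULL) {
  if (inherits(table, "activity_table")) {
    ss <- attr(table, "state_space")
    cols <- ss$labels
    df <- as.data.frame(table)[, cols, drop = FALSE]
  } else {
    df <- as.data.frame(table)
    df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  }
  if (nrow(df) < 4) stop("need at least 4 records to compute features")
  rows <- lapply(names(df), function(v) {
    compute_features(df[[v]], n_bins = n_bins, window = window)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(df)
  class(out) <- c("feature_table", "data.frame")
  out
}
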