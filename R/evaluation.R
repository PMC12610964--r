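#' Error metrics between observed and predicted vectors
#'
#' Computes the three accuracy measures used throughout the package to
#' compare an observed vector `X` against a prediction `X^` of the same
#' length N:
#' \deqn{AAE = \frac{1}{N} \sum_i |X_i - \hat X_i|}
#' \deqn{AES = \frac{1}{N} \sum_i (X_i - \hat X_i)^2}
#' \deqn{RMSE = \sqrt{AES}}
#' AAE is the mean absolute error, AES the mean squared error, and RMSE
#' its square root, so `rmse == sqrt(aes)` holds identically and
#' `aae <= rmse` for every input (quadratic mean dominates arithmetic
#' mean). All three are symmetric in their arguments and translation
#' invariant.
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return An object of class `error_report`: list with `aae`, `aes`,
#'   `rmse`, `n_components`, and the two input vectors.
#' @examples
#' error_metrics(c(0.1, 0.2, 0.7), c(0.2, 0.2, 0.6))
#' @export
error_metrics <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < 1) stop("vectors must be non-empty")
  d <- observed - predicted
  aes <- mean(d^2)
  structure(list(aae = mean(abs(d)),
                 aes = aes,
                 rmse = sqrt(aes),
                 n_components = length(observed),
                 observed = observed,
                 predicted = predicted),
            class = "error_report")
}

#' @export
print.error_report <- function(x, digits = 6, ...) {
  cat("Error report (N =", x$n_components, ")\n")
  cat(sprintf("  AAE  = %.*f\n  AES  = %.*f\n  RMSE = %.*f\n",
              digits, x$aae, digits, x$aes, digits, x$rmse))
  invisible(x)
}

# round half away from zero (the convention used by the accuracy row,
# where base R's round() would round to even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pooled cohort accuracy table
#'
#' Aggregates per-cow AAE/AES/RMSE values measured at several iteration
#' counts into the standard cohort layout: one column per iteration count,
#' a pooled `Average` row (the arithmetic mean of all 3 x n_cows error
#' values in the column) and an `Accuracy` row, `1 - Average` rounded
#' half-up to two decimals.
#'
#' @param errors a long-format data frame with columns `cow_id`,
#'   `n_iterations`, `aae`, `aes`, `rmse` -- one row per cow per iteration
#'   count. The same set of cows must appear at every iteration count.
#' @return A `cohort_report`: list with `per_cow` (the input, ordered),
#'   `pooled_mean` (named by iteration count), `accuracy` (fraction) and
#'   `accuracy_percent`.
#' @examples
#' errs <- utils::read.csv(cattlemc_example("errors"))
#' cohort_table(errs)$pooled_mean
#' @export
cohort_table <- function(errors) {
  errors <- as.data.frame(errors)
  need <- c("cow_id", "n_iterations", "aae", "aes", "rmse")
  if (!all(need %in% names(errors))) {
    stop("errors must have columns: ", paste(need, collapse = ", "))
  }
  split_by_n <- split(errors, errors$n_iterations)
  cows <- lapply(split_by_n, function(d) sort(unique(d$cow_id)))
  if (length(unique(vapply(cows, paste, collapse = ",", ""))) != 1) {
    stop("ragged input: every iteration count needs the same cow set")
  }
  pooled <- vapply(split_by_n, function(d) {
    mean(c(d$aae, d$aes, d$rmse))
  }, numeric(1))
  acc <- round_half_up(1 - pooled, 2)
  structure(list(per_cow = errors[order(errors$n_iterations, errors$cow_id), ],
                 pooled_mean = pooled,
                 accuracy = acc,
                 accuracy_percent = 100 * acc),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort accuracy report\n")
  print(data.frame(n_iterations = names(x$pooled_mean),
                   pooled_mean = round(unname(x$pooled_mean), 6),
                   accuracy = unname(x$accuracy),
                   row.names = NULL))
  invisible(x)
}

#' Similarity of two stationary distributions
#'
#' Applies [error_metrics()] to a pair of probability vectors (for example
#' an analytic stationary distribution versus the empirical frequencies of
#' a simulated chain). Small AAE/RMSE indicate that the two long-run
#' activity budgets agree.
#'
#' @param pi_a,pi_b probability vectors of equal length, each summing to 1
#'   within `tol`.
#' @param tol tolerance on the normalisation check, default 1e-9.
#' @return An `error_report` with `n_components` equal to the number of
#'   states.
#' @export
stationary_similarity <- function(pi_a, pi_b, tol = 1e-9) {
  pi_a <- as.numeric(pi_a)
  pi_b <- as.numeric(pi_b)
  if (length(pi_a) != length(pi_b)) stop("distributions must have equal length")
  if (abs(sum(pi_a) - 1) > tol || abs(sum(pi_b) - 1) > tol) {
    stop("inputs must be normalised probability vectors (sum to 1)")
  }
  error_metrics(pi_a, pi_b)
}
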