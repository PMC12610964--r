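#' Principal component analysis with explained-variance selection
#'
#' Standardises every column to mean 0, sd 1, eigendecomposes the
#' covariance of the standardised data (equivalently, the correlation
#' matrix) and selects the smallest number of leading components whose
#' cumulative explained variance reaches `threshold`. Wraps
#' [stats::prcomp()]; component signs are fixed by making each loading
#' vector's largest-magnitude entry positive.
#'
#' The input may be observations x variables in either orientation the
#' analysis calls for (sensor variables over time, or features over
#' variables); the caller chooses what the rows and columns mean.
#'
#' @param x numeric matrix or data frame, >= 2 rows, >= 2 columns, no
#'   missing values; constant columns are rejected (not standardisable).
#' @param threshold cumulative explained-variance fraction in (0, 1],
#'   default 0.95 (0.90 is a common, slightly more aggressive choice).
#' @return An object of class `pca_result`: list with `eigenvalues`
#'   (non-increasing), `components` (orthonormal loading matrix, one
#'   column per component), `explained_ratio`, `cumulative_ratio`,
#'   `n_selected`, `contributions` (per-variable score, see
#'   [rank_variable_contributions()]), `threshold` and `scores` (the
#'   rotated data).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' fit_pca(x, threshold = 0.9)$n_selected
#' @export
fit_pca <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 rows and 2 columns")
  if (anyNA(x)) stop("input contains missing values")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) cannot be standardised, remove: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- p$sdev^2
  rot <- p$rotation
  scores <- p$x
  # sign convention: dominant loading of each component is positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ratio <- eig / sum(eig)
  cumr <- cumsum(ratio)
  n_sel <- which(cumr >= threshold - 1e-12)[1]
  sel <- seq_len(n_sel)
  contrib <- as.numeric(abs(rot[, sel, drop = FALSE]) %*% ratio[sel])
  names(contrib) <- colnames(x)
  structure(list(eigenvalues = eig,
                 components = rot,
                 explained_ratio = ratio,
                 cumulative_ratio = cumr,
                 n_selected = n_sel,
                 contributions = contrib,
                 threshold = threshold,
                 scores = scores),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, digits = 4, ...) {
  cat("PCA: ", length(x$eigenvalues), " components, ", x$n_selected,
      " selected at threshold ", x$threshold, "\n", sep = "")
  print(round(data.frame(eigenvalue = x$eigenvalues,
                         explained = x$explained_ratio,
                         cumulative = x$cumulative_ratio), digits))
  invisible(x)
}

#' Rank variables by their contribution to the selected components
#'
#' Each variable's score is the sum over the selected components of the
#' absolute loading weighted by the component's explained-variance ratio,
#' so variables loading on high-variance components rank higher. Ties are
#' broken by original variable order.
#'
#' @param result a `pca_result` from [fit_pca()].
#' @return A data frame with columns `variable`, `score` and `rank`,
#'   ordered by decreasing score.
#' @export
rank_variable_contributions <- function(result) {
  if (!inherits(result, "pca_result")) stop("expected a pca_result")
  sc <- result$contributions
  ord <- order(-sc, seq_along(sc))
  data.frame(variable = names(sc)[ord],
             score = unname(sc[ord]),
             rank = seq_along(sc),
             stringsAsFactors = FALSE)
}
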