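#' Construct a transition matrix object
#'
#' A row-stochastic matrix over the states of a [state_space()]. Entry
#' (i, j) is the probability of moving from state i to state j in one step.
#'
#' @param probs numeric square matrix; rows must sum to 1 within `tol`.
#' @param state_space a [state_space()] whose labels name the rows and
#'   columns; defaults to a space built from existing dimnames (or
#'   `S1..Sk`) when not the standard nine-state space.
#' @param source provenance tag: `"printed"`, `"sequence-mle"`,
#'   `"composition"` or `"manual"`.
#' @param tol tolerance on row sums, default 1e-12.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(probs, state_space = NULL, source = "manual",
                              tol = 1e-12) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("transition matrix must be square")
  if (is.null(state_space)) {
    labels <- rownames(probs)
    if (is.null(labels)) labels <- paste0("S", seq_len(nrow(probs)))
    state_space <- generic_state_space(labels)
  }
  if (length(state_space$labels) != nrow(probs)) {
    stop("state space size does not match matrix dimension")
  }
  dimnames(probs) <- list(state_space$labels, state_space$labels)
  if (any(probs < 0)) stop("transition probabilities must be non-negative")
  bad <- which(abs(rowSums(probs) - 1) > tol)
  if (length(bad)) {
    stop("row(s) not summing to 1: ",
         paste(state_space$labels[bad], collapse = ", "),
         " (use renormalize_rows())")
  }
  structure(probs, class = "transition_matrix", state_space = state_space,
            source = source)
}

# state space for matrices that are not the standard 9-state chain: all
# labels are treated as behavioural, there is no environmental subset
generic_state_space <- function(labels) {
  state_space(labels = labels, behavioral = labels,
              environmental = character(0))
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Transition matrix (", nrow(x), " states, source: ",
      attr(x, "source"), ")\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Renormalise the rows of a non-negative matrix
#'
#' Divides each row by its sum so the result is row-stochastic. Intended
#' for matrices whose entries were rounded for printing (three-decimal
#' tables have row sums around 0.994-0.997) and for raw count matrices.
#' The pre-normalisation row sums are stored in the `row_sums_original`
#' attribute.
#'
#' @param matrix non-negative square matrix; no row may sum to zero.
#' @inheritParams transition_matrix
#' @return A `transition_matrix`.
#' @examples
#' renormalize_rows(matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE))
#' @export
renormalize_rows <- function(matrix, state_space = NULL, source = "manual") {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (any(m < 0)) stop("matrix entries must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("absorbing-defective row: row(s) ",
         paste(which(rs == 0), collapse = ", "), " sum to zero")
  }
  out <- transition_matrix(m / rs, state_space = state_space, source = source)
  attr(out, "row_sums_original") <- stats::setNames(rs, rownames(out))
  out
}

#' Estimate a transition matrix from an observed state sequence
#'
#' Maximum-likelihood estimate from one-step transition counts, with an
#' optional additive pseudo-count. `P[i, j] = (n_ij + a) / (n_i. + k * a)`
#' where `a` is the smoothing constant and `k` the number of states. A
#' state that never appears in the sequence gets a uniform row (tagged in
#' the `source` attribute as `"sequence-mle"`); a *visited* state with no
#' outgoing transition is an error unless smoothing is positive.
#'
#' @param seq a [state_sequence()] (or character vector of labels).
#' @param state_space a [state_space()]; defaults to the sequence's own.
#' @param smoothing pseudo-count added to every cell, default 0 (exact MLE).
#' @return A `transition_matrix` with `source = "sequence-mle"`.
#' @examples
#' ss <- state_space(c("A", "B"), c("A", "B"), character(0))
#' estimate_from_sequence(state_sequence(c("A","B","A","B","A"), ss))
#' @export
estimate_from_sequence <- function(seq, state_space = NULL, smoothing = 0) {
  if (is.null(state_space)) {
    state_space <- attr(seq, "state_space")
    if (is.null(state_space)) {
      state_space <- generic_state_space(sort(unique(as.character(seq))))
    }
  }
  if (smoothing < 0) stop("smoothing must be non-negative")
  x <- as.character(seq)
  if (length(x) < 2) stop("need a sequence of length >= 2 to count transitions")
  labels <- state_space$labels
  k <- length(labels)
  f <- factor(x, levels = labels)
  if (anyNA(f)) stop("sequence contains labels outside the state space")
  counts <- table(from = f[-length(f)], to = f[-1])
  counts <- matrix(as.numeric(counts), k, k, dimnames = list(labels, labels))
  out_deg <- rowSums(counts)
  visited <- labels %in% x
  if (smoothing == 0 && any(visited & out_deg == 0)) {
    stop("visited state(s) with no outgoing transition: ",
         paste(labels[visited & out_deg == 0], collapse = ", "),
         "; use smoothing > 0")
  }
  probs <- (counts + smoothing) / (out_deg + k * smoothing)
  if (any(!visited)) {
    probs[!visited, ] <- 1 / k  # never-observed states: uniform by convention
  }
  transition_matrix(probs, state_space = state_space, source = "sequence-mle",
                    tol = 1e-9)
}

#' Derive a transition matrix from interval composition vectors
#'
#' Builds a nine-state matrix from aggregated activity rows rather than a
#' step-by-step sequence. Each record's nine values are normalised to a
#' composition vector `q(d)`; the matrix is the row-normalised sum of
#' outer products, either between consecutive intervals (`mode =
#' "lagged"`, `sum_d q(d) q(d+1)'`) or within intervals (`mode =
#' "co-occurrence"`, `sum_d q(d) q(d)'`). Either construction yields a
#' valid row-stochastic matrix; neither is a maximum-likelihood chain
#' estimate, and the two agree only when compositions are constant in time.
#'
#' @param table an `activity_table`.
#' @param mode `"lagged"` (default) or `"co-occurrence"`.
#' @return A `transition_matrix` with `source = "composition"`.
#' @export
estimate_from_compositions <- function(table,
                                       mode = c("lagged", "co-occurrence")) {
  mode <- match.arg(mode)
  ss <- attr(table, "state_space")
  if (is.null(ss)) ss <- state_space()
  q <- as.matrix(as.data.frame(table)[, ss$labels, drop = FALSE])
  if (nrow(q) < 2) stop("need at least 2 records")
  rs <- rowSums(q)
  if (any(rs == 0)) {
    stop("record(s) with all-zero values: row ",
         paste(which(rs == 0), collapse = ", "))
  }
  q <- q / rs
  n <- nrow(q)
  if (mode == "lagged") {
    acc <- crossprod(q[-n, , drop = FALSE], q[-1, , drop = FALSE])
  } else {
    acc <- crossprod(q, q)
  }
  renormalize_rows(acc, state_space = ss, source = "composition")
}

# strong connectivity of the positive-entry digraph via boolean reachability
is_irreducible <- function(P) {
  A <- unclass(P) > 0
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  for (i in seq_len(ceiling(log2(max(n, 2))))) {
    R <- (R %*% R) > 0
  }
  all(R) && all(t(R))
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi P = pi`, `sum(pi) = 1` for an irreducible chain. The default
#' `"eigen"` method takes the left eigenvector of eigenvalue 1 (robust to
#' periodic chains). The `"power"` method iterates the damped map
#' `pi <- pi (P + I)/2`, whose fixed point is the same stationary vector;
#' the damping makes the iteration converge even when the chain itself is
#' periodic.
#'
#' @param matrix a `transition_matrix`.
#' @param method `"eigen"` (default) or `"power"`.
#' @param tol convergence tolerance on `max |pi P - pi|`, default 1e-12.
#' @param max_iter iteration cap for the power method.
#' @return An object of class `stationary_distribution`: a named
#'   probability vector with attribute `cumulative` (running partial sums
#'   `C1..Ck`, final element forced to exactly 1).
#' @examples
#' P <- transition_matrix(matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE))
#' stationary_distribution(P)  # (5/6, 1/6)
#' @export
stationary_distribution <- function(matrix, method = c("eigen", "power"),
                                    tol = 1e-12, max_iter = 100000) {
  method <- match.arg(method)
  P <- unclass(matrix)
  if (!is_irreducible(matrix)) {
    stop("stationary distribution not unique: chain is reducible")
  }
  n <- nrow(P)
  if (method == "eigen") {
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    if (sum(v) < 0) v <- -v
    v[v < 0 & v > -1e-12] <- 0
    pi <- v / sum(v)
  } else {
    Q <- (P + diag(n)) / 2  # damped chain: same stationary vector, aperiodic
    pi <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      nxt <- as.numeric(pi %*% Q)
      if (max(abs(nxt - pi)) < tol / 2) {
        pi <- nxt
        break
      }
      pi <- nxt
    }
    pi <- pi / sum(pi)
  }
  if (max(abs(as.numeric(pi %*% P) - pi)) > max(tol, 1e-10)) {
    stop("stationary solve failed to reach tolerance")
  }
  names(pi) <- rownames(P)
  cum <- cumsum(pi)
  cum[n] <- 1
  structure(pi, class = "stationary_distribution", cumulative = cum)
}

#' @export
print.stationary_distribution <- function(x, digits = 4, ...) {
  cat("Stationary distribution\n")
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  cat("cumulative:\n")
  print(round(attr(x, "cumulative"), digits))
  invisible(x)
}

#' n-step transition probabilities
#'
#' Matrix power `P^n` by repeated squaring; entry (i, j) is the
#' probability of being in state j exactly n steps after leaving state i.
#'
#' @param matrix a `transition_matrix`.
#' @param n positive integer number of steps.
#' @return A `transition_matrix` for the n-step chain.
#' @export
n_step_matrix <- function(matrix, n) {
  if (length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  P <- unclass(matrix)
  out <- diag(nrow(P))
  base <- P
  k <- as.integer(n)
  while (k > 0) {
    if (k %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2L
  }
  out <- out / rowSums(out)  # remove accumulated round-off
  transition_matrix(out, state_space = attr(matrix, "state_space"),
                    source = attr(matrix, "source"))
}
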