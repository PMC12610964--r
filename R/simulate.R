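#' Simulation configuration
#'
#' Settings shared by the two samplers. The retained sequence has exactly
#' `n_iterations` states; `burn_in` additional initial steps are generated
#' and discarded so the chain can forget its starting state. Burn-in counts
#' proposals (steps), not acceptances.
#'
#' @param n_iterations number of retained samples (typical runs use 3000,
#'   4000 or 5000).
#' @param burn_in number of initial discarded steps, default 1000.
#' @param seed integer RNG seed; identical configurations reproduce
#'   identical sequences bit for bit.
#' @param initial_state a state label, or `"stationary-draw"` to draw the
#'   start from the stationary distribution (one inverse-CDF draw). The
#'   default uses the first state in the state space.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_iterations, burn_in = 1000, seed = 1,
                       initial_state = NULL) {
  if (n_iterations < 1) stop("n_iterations must be positive")
  if (burn_in < 0) stop("burn_in must be non-negative")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed),
                 initial_state = initial_state),
            class = "sim_config")
}

new_sim_result <- function(states, state_space, config, sampler,
                           acceptance_rate = NA_real_, step_seconds = 60) {
  seq <- state_sequence(states, state_space, step_seconds)
  emp <- table(factor(states, levels = state_space$labels))
  emp <- as.numeric(emp) / length(states)
  names(emp) <- state_space$labels
  structure(list(sequence = seq,
                 empirical = emp,
                 config = config,
                 sampler = sampler,
                 acceptance_rate = acceptance_rate),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, digits = 4, ...) {
  cat("Simulation result (", x$sampler, ", n = ", x$config$n_iterations,
      ", burn-in = ", x$config$burn_in, ", seed = ", x$config$seed, ")\n",
      sep = "")
  cat("empirical state frequencies:\n")
  print(round(x$empirical, digits))
  if (!is.na(x$acceptance_rate)) {
    cat("acceptance rate:", round(x$acceptance_rate, digits), "\n")
  }
  invisible(x)
}

resolve_initial <- function(initial, labels, cumulative) {
  if (is.null(initial)) return(1L)
  if (identical(initial, "stationary-draw")) {
    if (is.null(cumulative)) {
      stop("'stationary-draw' initialisation needs a stationary distribution")
    }
    return(findInterval(stats::runif(1), cumulative) + 1L)
  }
  i <- match(initial, labels)
  if (is.na(i)) stop("unknown initial state: ", initial)
  i
}

#' Direct Markov chain simulation by inverse-CDF sampling
#'
#' Simulates the chain step by step: from state i the next state is drawn
#' by inverting the cumulative probabilities of row i (`C1..Ck`) at a
#' uniform variate. The first `burn_in` states are discarded.
#'
#' @param matrix a `transition_matrix`.
#' @param config a [sim_config()].
#' @return A `sim_result`: retained `sequence` of length `n_iterations`,
#'   `empirical` state frequencies (summing to 1), and the config.
#' @examples
#' P <- load_transition_matrix(cattlemc_example("matrix"))
#' r <- simulate_direct(P, sim_config(5000, burn_in = 1000, seed = 7))
#' round(r$empirical, 3)
#' @export
simulate_direct <- function(matrix, config) {
  ss <- attr(matrix, "state_space")
  P <- unclass(matrix)
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  cum[, k] <- 1
  total <- config$burn_in + config$n_iterations
  set.seed(config$seed)
  start_cum <- if (identical(config$initial_state, "stationary-draw")) {
    attr(stationary_distribution(matrix), "cumulative")
  } else NULL
  state <- resolve_initial(config$initial_state, ss$labels, start_cum)
  u <- stats::runif(total)
  out <- integer(total)
  for (t in seq_len(total)) {
    state <- findInterval(u[t], cum[state, ]) + 1L
    out[t] <- state
  }
  kept <- out[(config$burn_in + 1L):total]
  new_sim_result(ss$labels[kept], ss, config, sampler = "direct")
}

#' Metropolis-Hastings sampling of a stationary target
#'
#' Samples a discrete target distribution `pi` with a uniform independence
#' proposal over all states (including the current one -- a lazy,
#' symmetric proposal). A proposed move from i to j is accepted with
#' probability `min(1, pi_j / pi_i)`; on rejection the current state is
#' repeated. All target masses must be strictly positive.
#'
#' @param target a `stationary_distribution` (or positive probability
#'   vector summing to 1).
#' @param config a [sim_config()].
#' @param state_space optional [state_space()]; defaults to the target's
#'   names (or the standard nine-state space for unnamed length-9 input).
#' @return A `sim_result` including the realised `acceptance_rate`.
#' @examples
#' pi <- stationary_distribution(load_transition_matrix(cattlemc_example("matrix")))
#' r <- simulate_metropolis_hastings(pi, sim_config(5000, seed = 7))
#' r$empirical["L"]
#' @export
simulate_metropolis_hastings <- function(target, config, state_space = NULL) {
  pi <- as.numeric(target)
  if (is.null(state_space)) {
    if (!is.null(names(target))) {
      state_space <- if (identical(names(target),
                                   cattlemc::state_space()$labels)) {
        cattlemc::state_space()
      } else {
        generic_state_space(names(target))
      }
    } else if (length(pi) == 9) {
      state_space <- cattlemc::state_space()
    } else {
      state_space <- generic_state_space(paste0("S", seq_along(pi)))
    }
  }
  if (length(pi) != length(state_space$labels)) {
    stop("target length does not match state space")
  }
  if (abs(sum(pi) - 1) > 1e-9) stop("target must sum to 1")
  if (any(pi <= 0)) {
    stop("target must be strictly positive in every state")
  }
  k <- length(pi)
  total <- config$burn_in + config$n_iterations
  set.seed(config$seed)
  state <- resolve_initial(config$initial_state, state_space$labels,
                           cumsum(pi))
  props <- sample.int(k, total, replace = TRUE)
  u <- stats::runif(total)
  out <- integer(total)
  accepted <- 0L
  for (t in seq_len(total)) {
    j <- props[t]
    if (u[t] < pi[j] / pi[state]) {
      state <- j
      accepted <- accepted + 1L
    }
    out[t] <- state
  }
  kept <- out[(config$burn_in + 1L):total]
  new_sim_result(state_space$labels[kept], state_space, config,
                 sampler = "metropolis-hastings",
                 acceptance_rate = accepted / total)
}
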