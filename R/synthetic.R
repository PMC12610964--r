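#' Specification of a synthetic herd
#'
#' Describes the generator's study conditions: herd size, observation
#' length, sampling step, the ground-truth transition matrix the
#' behavioural sequences are drawn from, and the climate of the barn. The
#' defaults emulate the bundled reference herd: 5 cows observed for 30
#' days at 1-minute resolution during a hot, humid month (daily mean
#' temperature around 31.5 degrees C, relative humidity near 78%, so THI
#' sits in the heat-stress band of the mid 80s).
#'
#' Behavioural sequences are drawn from the 6x6 behavioural sub-chain of
#' `ground_truth` (rows and columns F, M, L, S, RS, RL, renormalised): a
#' cow occupies exactly one behavioural state per step, while temperature
#' and humidity evolve as parallel continuous series.
#'
#' @param n_cows number of cows, default 5.
#' @param days observation days per cow, default 30.
#' @param step_seconds sampling step of the behavioural sequence, default
#'   60 (1-minute aggregation).
#' @param ground_truth a `transition_matrix` over the standard nine-state
#'   space; default is the bundled reference matrix.
#' @param temp_mean,temp_sd daily temperature mean and marginal sd, deg C.
#' @param hum_mean,hum_sd daily relative humidity mean and marginal sd, %;
#'   generated values are clipped to [0, 100].
#' @param ar_rho day-to-day AR(1) autocorrelation of the environmental
#'   series, default 0.5.
#' @param seed base RNG seed; cow `i` uses `seed + i`.
#' @return A `herd_spec` list.
#' @export
herd_spec <- function(n_cows = 5, days = 30, step_seconds = 60,
                      ground_truth = NULL,
                      temp_mean = 31.5, temp_sd = 0.95,
                      hum_mean = 77.7, hum_sd = 4.1,
                      ar_rho = 0.5, seed = 1) {
  if (n_cows < 1 || days < 1 || step_seconds < 1) {
    stop("n_cows, days and step_seconds must be positive")
  }
  if (is.null(ground_truth)) {
    ground_truth <- load_transition_matrix(cattlemc_example("matrix"))
  }
  structure(list(n_cows = as.integer(n_cows), days = as.integer(days),
                 step_seconds = step_seconds, ground_truth = ground_truth,
                 temp_mean = temp_mean, temp_sd = temp_sd,
                 hum_mean = hum_mean, hum_sd = hum_sd,
                 ar_rho = ar_rho, seed = as.integer(seed)),
            class = "herd_spec")
}

#' Behavioural sub-chain of a nine-state matrix
#'
#' Restricts a transition matrix to the behavioural states (F, M, L, S,
#' RS, RL) and renormalises the rows; used as the generating chain for
#' synthetic cow sequences.
#'
#' @param matrix a `transition_matrix` over a state space with a
#'   behavioural subset.
#' @return A `transition_matrix` over the behavioural states only.
#' @export
behavioral_subchain <- function(matrix) {
  ss <- attr(matrix, "state_space")
  beh <- ss$behavioral
  if (length(beh) < 2) stop("state space has no behavioural subset to extract")
  sub <- unclass(matrix)[beh, beh, drop = FALSE]
  sub_ss <- state_space(labels = beh, behavioral = beh,
                        environmental = character(0))
  renormalize_rows(sub, state_space = sub_ss,
                   source = attr(matrix, "source"))
}

#' Generate one cow's behavioural state sequence
#'
#' Simulates `days * 86400 / step_seconds` steps from the behavioural
#' sub-chain of the spec's ground-truth matrix, seeded per cow
#' (`spec$seed + cow_index`) so herds are reproducible and cows mutually
#' independent.
#'
#' @param spec a [herd_spec()].
#' @param cow_index 1-based cow number within the herd.
#' @return A `state_sequence` over the six behavioural states.
#' @examples
#' seq1 <- generate_cow_sequence(herd_spec(days = 1), 1)
#' length(seq1)  # 1440 one-minute states
#' @export
generate_cow_sequence <- function(spec, cow_index = 1) {
  steps_per_day <- 86400 / spec$step_seconds
  if (steps_per_day != round(steps_per_day)) {
    stop("step_seconds must divide a day")
  }
  n_steps <- spec$days * steps_per_day
  sub <- behavioral_subchain(spec$ground_truth)
  res <- simulate_direct(sub, sim_config(n_iterations = n_steps, burn_in = 0,
                                         seed = spec$seed + cow_index))
  seq <- res$sequence
  attr(seq, "step_seconds") <- spec$step_seconds
  seq
}

#' Aggregate a behavioural sequence into an activity table
#'
#' Counts minutes spent in each behavioural state per aggregation interval
#' (15-minute or daily rows), mirroring the sensor system's aggregated
#' export. Each row's durations sum to the interval length by
#' construction.
#'
#' @param seq a `state_sequence` over behavioural states.
#' @param interval_minutes aggregation interval, typically 15 or 1440; the
#'   sequence length must divide evenly into intervals.
#' @param environment optional per-interval data frame with columns `T`,
#'   `H`, `THI` (e.g. from [generate_environment()]); when `NULL`,
#'   environmental columns are filled with `NA`.
#' @param cow_id stored with the result.
#' @return An `activity_table` with one row per interval.
#' @export
aggregate_sequence <- function(seq, interval_minutes = 1440,
                               environment = NULL, cow_id = NA_character_) {
  ss <- attr(seq, "state_space")
  if (is.null(ss)) stop("sequence must carry a state space")
  step_seconds <- attr(seq, "step_seconds")
  steps_per_interval <- interval_minutes * 60 / step_seconds
  if (steps_per_interval != round(steps_per_interval)) {
    stop("interval is not a whole number of steps")
  }
  n <- length(seq)
  if (n %% steps_per_interval != 0) {
    stop("sequence length ", n, " is not divisible into ",
         interval_minutes, "-minute intervals")
  }
  n_int <- n / steps_per_interval
  idx <- rep(seq_len(n_int), each = steps_per_interval)
  beh <- ss$labels
  counts <- table(interval = idx, state = factor(as.character(seq), levels = beh))
  mins <- matrix(as.numeric(counts), n_int, length(beh),
                 dimnames = list(NULL, beh)) * step_seconds / 60
  env <- if (is.null(environment)) {
    data.frame(T = rep(NA_real_, n_int), H = NA_real_, THI = NA_real_)
  } else {
    if (nrow(environment) != n_int) {
      stop("environment must have one row per interval")
    }
    environment[, c("T", "H", "THI")]
  }
  out <- data.frame(No = seq_len(n_int), env, mins,
                    TOTAL_MIN = rowSums(mins), check.names = FALSE)
  full_ss <- state_space()
  ord <- intersect(c("No", full_ss$labels, "TOTAL_MIN"), names(out))
  out <- out[, ord]
  structure(out, class = c("activity_table", "data.frame"),
            state_space = full_ss, interval_minutes = interval_minutes,
            cow_id = cow_id)
}

#' Generate correlated daily environmental series
#'
#' Draws daily temperature and humidity as AR(1) series with the spec's
#' marginal mean and sd (innovation variance scaled so the marginal sd is
#' respected), clips humidity to [0, 100], and derives THI with [thi()].
#'
#' @param spec a [herd_spec()].
#' @param days number of days; defaults to `spec$days`.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A data frame with columns `T`, `H`, `THI`, one row per day.
#' @export
generate_environment <- function(spec, days = spec$days, seed = spec$seed) {
  set.seed(seed)
  ar1 <- function(n, mean, sd, rho) {
    if (sd == 0) return(rep(mean, n))
    innov_sd <- sd * sqrt(1 - rho^2)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd)
    for (t in seq_len(n)[-1]) {
      x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, innov_sd)
    }
    mean + x
  }
  T <- ar1(days, spec$temp_mean, spec$temp_sd, spec$ar_rho)
  H <- pmin(100, pmax(0, ar1(days, spec$hum_mean, spec$hum_sd, spec$ar_rho)))
  data.frame(T = T, H = H, THI = thi(T, H))
}

#' Temperature-humidity index
#'
#' The standard livestock heat-stress index
#' `THI = 0.8 T + (H / 100) (T - 14.4) + 46.4` with `T` in degrees
#' Celsius and `H` in percent relative humidity. Values above ~72 indicate
#' the onset of heat stress in dairy cattle; the high 80s indicate severe
#' stress.
#'
#' @param T temperature, degrees Celsius.
#' @param H relative humidity, percent, in [0, 100].
#' @return The THI value(s).
#' @examples
#' thi(31.2, 88.7)
#' @export
thi <- function(T, H) {
  if (any(H < 0 | H > 100)) stop("humidity must be in [0, 100]")
  0.8 * T + (H / 100) * (T - 14.4) + 46.4
}

#' Generate a complete synthetic herd
#'
#' Runs the full generator: one behavioural sequence per cow, one shared
#' daily environmental series, and one daily-aggregated activity table per
#' cow. Everything is determined by the spec's seed.
#'
#' @param spec a [herd_spec()].
#' @return A list with elements `sequences` (list of `state_sequence`),
#'   `tables` (list of daily `activity_table`), `environment` (data
#'   frame) and `spec`.
#' @examples
#' herd <- generate_herd(herd_spec(n_cows = 2, days = 2))
#' sapply(herd$tables, nrow)
#' @export
generate_herd <- function(spec) {
  env <- generate_environment(spec)
  sequences <- lapply(seq_len(spec$n_cows), function(i) {
    generate_cow_sequence(spec, i)
  })
  tables <- lapply(seq_len(spec$n_cows), function(i) {
    aggregate_sequence(sequences[[i]], interval_minutes = 1440,
                       environment = env, cow_id = sprintf("cow%02d", i))
  })
  names(sequences) <- names(tables) <- sprintf("cow%02d", seq_len(spec$n_cows))
  list(sequences = sequences, tables = tables, environment = env, spec = spec)
}
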