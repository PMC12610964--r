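# shared builders for the test suite

two_state_space <- function() {
  state_space(labels = c("A", "B"), behavioral = c("A", "B"),
              environmental = character(0))
}

reference_matrix <- function() {
  load_transition_matrix(cattlemc_example("matrix"))
}

reference_pi_rounded <- function() {
  d <- read.csv(cattlemc_example("stationary"))
  stats::setNames(d$pi, d$state)
}

# random irreducible row-stochastic matrix: strictly positive entries
random_stochastic <- function(k, seed) {
  set.seed(seed)
  m <- matrix(runif(k * k, 0.01, 1), k, k)
  transition_matrix(m / rowSums(m), source = "manual", tol = 1e-9)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
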