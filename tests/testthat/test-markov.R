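test_that("sequence MLE reproduces hand-counted transition probabilities", {
  ss <- two_state_space()
  P <- estimate_from_sequence(state_sequence(c("A", "B", "A", "B", "A"), ss))
  expect_equal(unclass(P), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
                                  dimnames = list(c("A", "B"), c("A", "B"))),
               ignore_attr = TRUE)

  aaab <- state_sequence(c("A", "A", "A", "B"), ss)
  expect_error(estimate_from_sequence(aaab), "no outgoing transition")
  Ps <- estimate_from_sequence(aaab, smoothing = 1)
  expect_equal(unclass(Ps)["A", ], c(A = 3 / 5, B = 2 / 5))  # (2+1, 1+1)/(3+2)
  expect_equal(unclass(Ps)["B", ], c(A = 0.5, B = 0.5))

  # a state never visited gets a uniform row
  three <- state_space(c("A", "B", "C"), c("A", "B", "C"), character(0))
  Pu <- estimate_from_sequence(state_sequence(c("A", "B", "A", "B"), three),
                               smoothing = 0)
  expect_equal(unname(unclass(Pu)["C", ]), rep(1 / 3, 3))
})

test_that("sequence MLE recovers the generating matrix and is consistent", {
  P <- reference_matrix()
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    seq <- simulate_direct(P, sim_config(n, burn_in = 0, seed = 11))$sequence
    max(abs(unclass(estimate_from_sequence(seq)) - unclass(P)))
  }, numeric(1))
  expect_lte(errs[3], 0.01)
  expect_false(is.unsorted(rev(errs)))  # error shrinks with 10x more data
})

test_that("composition estimates honour the outer-product algebra", {
  ss <- state_space()
  mk_table <- function(rows) {
    df <- as.data.frame(rows)
    names(df) <- ss$labels
    df <- cbind(No = seq_len(nrow(df)), df, TOTAL_MIN = rowSums(df))
    structure(df, class = c("activity_table", "data.frame"),
              state_space = ss, interval_minutes = 1440)
  }
  unif <- mk_table(matrix(160, 3, 9))
  for (mode in c("lagged", "co-occurrence")) {
    expect_equal(unname(unclass(estimate_from_compositions(unif, mode))),
                 matrix(1 / 9, 9, 9), ignore_attr = TRUE)
  }
  v <- c(0.05, 0.05, 0.1, 0.1, 0.2, 0.3, 0.05, 0.05, 0.1)
  fixed <- mk_table(matrix(rep(v * 1440, 4), 4, 9, byrow = TRUE))
  for (mode in c("lagged", "co-occurrence")) {
    Pf <- estimate_from_compositions(fixed, mode)
    for (i in 1:9) expect_equal(unname(unclass(Pf)[i, ]), v,
                                ignore_attr = TRUE)
  }
  # real table: any mode yields a valid stochastic matrix
  tab <- read_activity_table(cattlemc_example("activity"))
  Pt <- estimate_from_compositions(tab, "lagged")
  expect_equal(unname(rowSums(unclass(Pt))), rep(1, 9), tolerance = 1e-12)
  expect_true(all(unclass(Pt) >= 0))
  zero <- mk_table(rbind(rep(0, 9), rep(160, 9)))
  expect_error(estimate_from_compositions(zero), "all-zero")
})

test_that("row renormalisation is exact and records original sums", {
  m <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE)
  r <- renormalize_rows(m)
  expect_equal(unname(unclass(r)), matrix(c(0.5, 0.5, 0.25, 0.75), 2, 2,
                                          byrow = TRUE), ignore_attr = TRUE)
  already <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE)
  expect_equal(unname(unclass(renormalize_rows(already))), already,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(renormalize_rows(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)),
               "absorbing-defective")
  expect_error(renormalize_rows(matrix(c(-1, 2, 1, 1), 2, 2)), "non-negative")
})

test_that("stationary distribution matches analytic and reference values", {
  # 2x2 balance equation: pi = (5/6, 1/6)
  P2 <- transition_matrix(matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE))
  expect_equal(unname(as.numeric(stationary_distribution(P2))), c(5 / 6, 1 / 6),
               tolerance = 1e-10)
  # periodic two-cycle still has the uniform stationary vector
  flip <- transition_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  for (method in c("eigen", "power")) {
    expect_equal(unname(as.numeric(stationary_distribution(flip, method))),
                 c(0.5, 0.5), tolerance = 1e-9)
  }
  # reference nine-state chain: within rounding of the published vector
  pi <- stationary_distribution(reference_matrix())
  ref <- reference_pi_rounded()
  expect_lte(abs(unname(pi["T"]) - ref[["T"]]), 0.005)
  expect_lte(abs(unname(pi["L"]) - ref[["L"]]), 0.005)
  expect_lte(mean(abs(as.numeric(pi) - unname(ref))), 0.003)
  # reducible chain has no unique stationary distribution
  expect_error(stationary_distribution(transition_matrix(diag(2))),
               "not unique")
})

test_that("cumulative probabilities are monotone partial sums ending at 1", {
  pi <- stationary_distribution(reference_matrix())
  cum <- attr(pi, "cumulative")
  expect_equal(unname(cum), unname(cumsum(as.numeric(pi))), tolerance = 1e-12)
  expect_false(is.unsorted(cum))
  expect_identical(unname(cum[9]), 1)
})

test_that("eigen and power solvers agree on random irreducible chains", {
  for (s in 1:20) {
    P <- random_stochastic(sample(2:9, 1), seed = s)
    pe <- as.numeric(stationary_distribution(P, "eigen"))
    pp <- as.numeric(stationary_distribution(P, "power"))
    expect_lt(max(abs(pe - pp)), 1e-9)
  }
})

test_that("n-step powers stay stochastic and converge to stationarity", {
  P <- reference_matrix()
  expect_equal(unclass(n_step_matrix(P, 1)), unclass(P), tolerance = 1e-15,
               ignore_attr = TRUE)
  flip <- transition_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(unclass(n_step_matrix(flip, 2))), diag(2),
               ignore_attr = TRUE)
  for (n in c(2, 5, 17)) {
    expect_equal(unname(rowSums(unclass(n_step_matrix(P, n)))), rep(1, 9),
                 tolerance = 1e-12)
  }
  pi <- as.numeric(stationary_distribution(P))
  P64 <- unclass(n_step_matrix(P, 64))
  for (i in 1:9) expect_equal(unname(P64[i, ]), pi, tolerance = 1e-6)
  expect_error(n_step_matrix(P, 0), "positive integer")
})
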