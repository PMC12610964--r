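test_that("an absorbing lying state produces an all-lying sequence", {
  ss <- state_space()
  m <- matrix(0, 9, 9, dimnames = list(ss$labels, ss$labels))
  m[, "L"] <- 1  # every state, behavioural or not, moves to L
  spec <- herd_spec(n_cows = 1, days = 1,
                    ground_truth = transition_matrix(m, ss))
  seq <- generate_cow_sequence(spec, 1)
  expect_equal(length(seq), 1440)
  expect_true(all(as.character(seq) == "L"))
})

test_that("sequence length follows days and sampling step", {
  expect_equal(length(generate_cow_sequence(herd_spec(days = 1), 1)), 1440)
  expect_equal(length(generate_cow_sequence(herd_spec(days = 2,
                                                      step_seconds = 120), 1)),
               1440)
  expect_error(generate_cow_sequence(herd_spec(step_seconds = 7), 1),
               "divide a day")
})

test_that("the behavioural sub-chain is recovered from a month of data", {
  spec <- herd_spec(n_cows = 1, days = 30, seed = 20)
  sub <- behavioral_subchain(spec$ground_truth)
  seq <- generate_cow_sequence(spec, 1)
  est <- estimate_from_sequence(seq)
  expect_lte(max(abs(unclass(est) - unclass(sub))), 0.02)
})

test_that("aggregation counts minutes per behaviour exactly", {
  beh <- state_space()$behavioral
  bss <- state_space(beh, beh, character(0))
  all_l <- state_sequence(rep("L", 1440), bss, step_seconds = 60)
  tab <- aggregate_sequence(all_l, 1440)
  expect_equal(as.numeric(tab[1, beh]), c(0, 0, 1440, 0, 0, 0))
  expect_equal(tab$TOTAL_MIN, 1440)

  fm <- state_sequence(rep(c("F", "M"), 720), bss, step_seconds = 60)
  tab2 <- aggregate_sequence(fm, 1440)
  expect_equal(as.numeric(tab2[1, beh]), c(720, 720, 0, 0, 0, 0))

  quarter <- aggregate_sequence(fm, 15)
  expect_equal(nrow(quarter), 96)
  expect_true(all(quarter$TOTAL_MIN == 15))

  odd <- state_sequence(rep("L", 100), bss, step_seconds = 60)
  expect_error(aggregate_sequence(odd, 1440), "not divisible")
})

test_that("generated aggregates always validate", {
  for (s in 1:20) {
    set.seed(s)
    spec <- herd_spec(n_cows = 1, days = sample(1:3, 1),
                      step_seconds = sample(c(60, 120), 1), seed = s)
    tab <- aggregate_sequence(generate_cow_sequence(spec, 1), 1440,
                              environment = generate_environment(spec,
                                                                 spec$days))
    expect_true(all(validate_activity_table(tab)$pass))
  }
})

test_that("environmental series respect the spec and derive THI", {
  flat <- herd_spec(temp_sd = 0, hum_sd = 0, days = 10)
  env0 <- generate_environment(flat)
  expect_equal(env0$T, rep(31.5, 10))
  expect_equal(env0$H, rep(77.7, 10))
  expect_equal(env0$THI, thi(env0$T, env0$H))

  env <- generate_environment(herd_spec(days = 1000, seed = 7))
  expect_equal(env$THI, thi(env$T, env$H))
  # defaults emulate a hot humid month: typical days within observed bands
  expect_gte(mean(env$T >= 29 & env$T <= 33), 0.85)
  expect_gte(mean(env$H >= 70 & env$H <= 89), 0.85)
  expect_true(all(env$H >= 0 & env$H <= 100))
})

test_that("the heat-stress index matches its closed form", {
  expect_equal(thi(14.4, 0), 57.92)    # humidity term vanishes
  expect_equal(thi(14.4, 63), 57.92)
  expect_equal(thi(0, 0), 46.4)
  expect_equal(thi(31.2, 88.7), 86.2616, tolerance = 1e-10)
  expect_error(thi(30, 101), "humidity")
})

test_that("generate -> aggregate -> estimate -> stationary closes the loop", {
  spec <- herd_spec(n_cows = 1, days = 30, seed = 30)
  sub <- behavioral_subchain(spec$ground_truth)
  pi_true <- stationary_distribution(sub)
  seq <- generate_cow_sequence(spec, 1)
  tab <- aggregate_sequence(seq, 1440)
  expect_true(all(validate_activity_table(tab)$pass))
  pi_hat <- stationary_distribution(estimate_from_sequence(seq))
  expect_lte(mean(abs(as.numeric(pi_hat) - as.numeric(pi_true))), 0.02)
  # the long-run activity budget also shows up in the aggregated minutes
  budget <- colSums(as.data.frame(tab)[, attr(sub, "state_space")$labels])
  expect_lte(mean(abs(budget / sum(budget) - as.numeric(pi_true))), 0.02)
})

test_that("the whole generator is seed deterministic", {
  spec <- herd_spec(n_cows = 2, days = 1, seed = 5)
  h1 <- generate_herd(spec)
  h2 <- generate_herd(spec)
  expect_identical(lapply(h1$sequences, as.character),
                   lapply(h2$sequences, as.character))
  expect_identical(h1$environment, h2$environment)
  expect_identical(lapply(h1$tables, as.data.frame),
                   lapply(h2$tables, as.data.frame))
  # cows within a herd are distinct
  expect_false(identical(as.character(h1$sequences[[1]]),
                         as.character(h1$sequences[[2]])))
})
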