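test_that("offspring draw honours the no-event and certain-event edges", {
  p <- tiny_params(u = 0, v = 0)
  set.seed(1)
  for (i in 1:20) expect_equal(offspring_draw(2L, 1L, p), c(2L, 1L))

  # v = 1 with a self-circle kernel never moves the offspring
  p <- model_params(N = 3, M = 3, S = 3, u = 0, v = 1,
                    kernel = migration_kernel(3, c(1, 0, 0)))
  set.seed(1)
  for (i in 1:20) expect_equal(offspring_draw(1L, 2L, p)[2], 2L)

  # u = 1: strategy marginally uniform regardless of the parent
  p <- tiny_params(u = 1, v = 0, S = 3)
  set.seed(42)
  draws <- replicate(6000, offspring_draw(1L, 1L, p)[1])
  freq <- tabulate(draws, 3) / 6000
  expect_true(all(abs(freq - 1/3) < 3 * sqrt(1/3 * 2/3 / 6000)))
})

test_that("moran step replaces exactly one slot and conserves N", {
  p <- tiny_params(N = 12, M = 3, S = 3, u = 0.3, v = 0.4)
  st <- fixture_random_state(12, 3, 3, seed = 5)
  set.seed(9)
  for (i in 1:50) {
    nxt <- moran_step(st, p)
    expect_length(nxt$s, 12)
    changed <- sum(nxt$s != st$s | nxt$g != st$g)
    expect_lte(changed, 1)
    st <- nxt
  }
})

test_that("wright-fisher step replaces the whole population", {
  # u = 1: next generation is N i.i.d. uniform strategies
  p <- model_params(N = 2000, M = 1, S = 4, u = 1, v = 0)
  st <- population_state(rep(1L, 2000), rep(1L, 2000), S = 4, M = 1)
  set.seed(3)
  nxt <- wf_step(st, p)
  freq <- tabulate(nxt$s, 4) / 2000
  expect_true(all(abs(freq - 1/4) < 3 * sqrt(1/4 * 3/4 / 2000)))
})

test_that("run_chain bookkeeping: observer count and seed determinism", {
  p <- tiny_params(N = 5, M = 2, S = 3, u = 0.5, v = 0.5)
  cfg <- chain_config(n_steps = 100, burn_in = 20, seed = 11, record_every = 4)
  calls <- 0
  res <- run_chain(params = p, config = cfg,
                   observer = function(state, step) { calls <<- calls + 1; step })
  expect_equal(calls, 20)                     # (100 - 20) / 4
  expect_length(res$observations, 20)

  res2 <- run_chain(params = p, config = cfg, observer = function(s, i) s)
  res3 <- run_chain(params = p, config = cfg, observer = function(s, i) s)
  expect_identical(res2$final, res3$final)

  expect_error(
    run_chain(params = p, config = chain_config(50, 0, seed = 1),
              observer = function(s, i) if (i == 7) stop("boom") else NULL),
    "step 7")
})

test_that("neutral long-run strategy frequencies converge to 1/S", {
  # compiled driver, neutral: time-average frequency of each strategy ~ 1/S
  p <- model_params(N = 20, M = 3, S = 3, u = 0.2, v = 0.3, r = 1)
  sim <- simulate_mean_frequencies(p, payoff_spec(matrix(0, 3, 3)),
                                   chain_config(n_steps = 4e5, burn_in = 2e4,
                                                seed = 17))
  expect_true(all(abs(sim$mean_freq - 1/3) < 3 * sim$se))
})

test_that("moran without migration reaches and keeps a single occupied group", {
  p <- model_params(N = 8, M = 4, S = 2, u = 0.5, v = 0)
  st <- population_state(rep(1L, 8), rep(1:4, 2), S = 2, M = 4)
  cfg <- chain_config(n_steps = 4000, burn_in = 0, seed = 23)
  occ <- run_chain(st, p, cfg, observer = function(s, i) length(unique(s$g)))
  occ <- unlist(occ$observations)
  expect_equal(occ[length(occ)], 1)            # absorbed into one group
  # once a group empties it is never recolonised: occupancy never increases
  expect_true(all(diff(occ) <= 0))
})
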