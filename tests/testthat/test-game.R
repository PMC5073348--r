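test_that("gradients sum to zero and are shift-invariant", {
  set.seed(1)
  for (i in 1:50) {
    S <- sample(2:6, 1)
    A <- matrix(rnorm(S * S), S)
    s1 <- runif(1, 0, 3); s2 <- runif(1, 0, 20)
    grads <- vapply(seq_len(S), selection_gradient, numeric(1),
                    A = A, sigma1 = s1, sigma2 = s2)
    expect_lt(abs(sum(grads)), 1e-10)
    shifted <- vapply(seq_len(S), selection_gradient, numeric(1),
                      A = A + 17.3, sigma1 = s1, sigma2 = s2)
    expect_equal(grads, shifted, tolerance = 1e-9)
  }
})

test_that("degenerate games favour nobody", {
  A <- matrix(5, 4, 4)                    # constant matrix: every contest ties
  for (k in 1:4) {
    expect_equal(pairwise_competition_term(A, k, sigma1 = 1.7), 0)
    expect_equal(equal_frequency_term(A, k), 0)
    expect_false(favored(A, k, 1.7, 4.2))
  }
  # cyclic rock-paper-scissors: perfect symmetry, all gradients zero
  rps <- matrix(c(0, -1, 1, 1, 0, -1, -1, 1, 0), 3)
  for (k in 1:3) expect_equal(selection_gradient(rps, k, 0.8, 3), 0)
})

test_that("two-strategy games reduce to the single-sigma condition", {
  # closed-form check of the reduction identities
  expect_equal(two_strategy_sigma(0.7, 0), 0.7)
  for (s2 in c(0, 1, 10, 100)) expect_equal(two_strategy_sigma(1, s2), 1)

  set.seed(2)
  for (i in 1:200) {
    A <- matrix(rnorm(4), 2)
    s1 <- runif(1, 0, 3); s2 <- runif(1, 0, 20)
    sig <- two_strategy_sigma(s1, s2)
    eq1 <- sig * A[1, 1] + A[1, 2] - A[2, 1] - sig * A[2, 2]
    eq2 <- selection_gradient(A, 1, s1, s2)
    expect_equal(sign(eq1), sign(eq2))
    # and the magnitudes are proportional: same linear form up to scale
    expect_equal(eq2, (1 + s2 / 2) * eq1, tolerance = 1e-9)
  }
})

test_that("repeated-game payoffs come out of the automaton simulation", {
  A <- reciprocity_payoffs(b = 3, c = 1, m = 5)
  expect_equal(rownames(A), c("ALLC", "ALLD", "TFT"))
  # diagonal: mutual cooperation for ALLC and TFT, nothing for ALLD
  expect_equal(unname(diag(A)), c(5 * 2, 0, 5 * 2))
  # TFT cooperates only in round 1 against ALLD
  expect_equal(A["ALLD", "TFT"], 3)
  expect_equal(A["TFT", "ALLD"], -1)
  expect_equal(A["ALLC", "ALLD"], -5)
  expect_equal(A["ALLD", "ALLC"], 15)
  # one round: TFT is indistinguishable from ALLC
  A1 <- reciprocity_payoffs(b = 2, c = 0.5, m = 1)
  expect_equal(A1["ALLC", ], A1["TFT", ], ignore_attr = TRUE)
  expect_equal(A1[, "ALLC"], A1[, "TFT"], ignore_attr = TRUE)
  expect_error(reciprocity_payoffs(b = 1, c = 2, m = 3), "b > c")
})

test_that("critical cost-benefit ratio behaves as the theory demands", {
  # one-shot game: cooperation is never strictly favoured
  expect_equal(critical_cost_benefit(1, 0.5, m = 1), 0)
  expect_equal(critical_cost_benefit(1, 8, m = 1), 0)

  # non-decreasing in the number of rounds
  for (pars in list(c(1, 1), c(0.5, 3), c(2, 10))) {
    cb <- vapply(1:20, function(m)
      critical_cost_benefit(pars[1], pars[2], m), numeric(1))
    expect_true(all(diff(cb) >= -1e-12))
  }

  # high-mutation regime: sigma2 dominates and (c/b)* -> 2(m-1)/(5m+1)
  for (m in c(1, 2, 5, 20)) {
    cb <- critical_cost_benefit(1, 1e8, m)
    expect_equal(cb, 2 * (m - 1) / (5 * m + 1), tolerance = 1e-6)
  }

  # the root really is the sign change of ALLD's gradient
  s1 <- 1.3; s2 <- 4; m <- 6
  cb <- critical_cost_benefit(s1, s2, m)
  g_lo <- selection_gradient(reciprocity_payoffs(1, 0.9 * cb, m), 2, s1, s2)
  g_hi <- selection_gradient(reciprocity_payoffs(1, 1.1 * cb, m), 2, s1, s2)
  expect_lt(g_lo, 0)   # ALLD disfavoured below the critical ratio
  expect_gt(g_hi, 0)

  expect_error(critical_cost_benefit(0, 0, 3), "not both zero")
})

test_that("selection report flags the favoured strategies consistently", {
  A <- reciprocity_payoffs(b = 1, c = 0.1, m = 5)
  rep <- selection_report(A, sigma1 = 1, sigma2 = 2)
  expect_equal(rep$strategy, c("ALLC", "ALLD", "TFT"))
  expect_lt(abs(sum(rep$gradient)), 1e-10)
  expect_identical(rep$favored, rep$gradient > 0)
  expect_false(rep$favored[2])   # cheap cooperation: ALLD disfavoured
})

test_that("gradient sign predicts simulated abundance for a dominant strategy", {
  # strategy 1 strictly dominates: its weak-selection abundance must exceed
  # 1/S, and the gradient must say so
  A <- matrix(c(2, 2, 2,
                0, 0, 0,
                0, 0, 0), 3, 3, byrow = TRUE)
  p <- model_params(N = 20, M = 3, S = 3, u = 0.1, v = 0.2, r = 1, delta = 0.02)
  cf <- sigma_closed_form(p)
  expect_true(favored(A, 1, cf$sigma1, cf$sigma2))
  expect_false(favored(A, 2, cf$sigma1, cf$sigma2))
  sim <- simulate_mean_frequencies(p, payoff_spec(A, 0.02),
                                   chain_config(n_steps = 2e6, burn_in = 1e5,
                                                seed = 404))
  expect_gt(sim$mean_freq[1] - 1/3, 3 * sim$se[1])
})
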