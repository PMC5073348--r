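# Central correctness property: the closed-form coefficients agree with the
# exact stationary computation on every enumerable instance (a subset here;
# the full acceptance grid lives in test-acceptance.R).

test_that("closed form equals the exact oracle on tiny instances", {
  for (proc in c("moran", "wright_fisher")) {
    for (v in c(0.3, 1.0)) {
      p <- model_params(N = 3, M = 2, S = 3, u = 0.3, v = v, r = 1, process = proc)
      cf <- sigma_closed_form(p)
      ex <- sigma_exact(p)
      expect_lt(abs(cf$sigma1 - ex$sigma1), 1e-10)
      expect_lt(abs(cf$sigma2 - ex$sigma2), 1e-10)
    }
  }
  # a random isotropic kernel, not from the range family
  kern <- fixture_random_kernel(3, seed = 99)
  for (proc in c("moran", "wright_fisher")) {
    p <- model_params(N = 3, M = 3, S = 2 + 1, u = 0.2, v = 0.7,
                      kernel = kern, process = proc)
    cf <- sigma_closed_form(p)
    ex <- sigma_exact(p, limit = 1e6)
    expect_lt(abs(cf$sigma1 - ex$sigma1), 1e-10)
    expect_lt(abs(cf$sigma2 - ex$sigma2), 1e-10)
  }
})

test_that("u = 0 is rejected; u -> 0 limit matches a small-u evaluation", {
  p <- model_params(N = 6, M = 3, S = 3, u = 0, v = 0.4, r = 1)
  expect_error(sigma_closed_form(p), "u > 0")
  expect_error(sigma_exact(p), "u > 0")

  for (proc in c("moran", "wright_fisher")) {
    p <- model_params(N = 6, M = 3, S = 3, u = 1e-9, v = 0.4, r = 1, process = proc)
    lim <- sigma_limit_small_u(p)
    at <- sigma_closed_form(p)
    expect_equal(lim$sigma1, at$sigma1, tolerance = 1e-5)
    expect_equal(lim$sigma2, 0)
    expect_lt(at$sigma2, 1e-6)
  }
})

test_that("u = 1 kills the pairwise coefficient", {
  for (proc in c("moran", "wright_fisher")) {
    est <- sigma_limit_u1(model_params(N = 50, M = 5, S = 3, u = 0.5, v = 0.3,
                                       r = 2, process = proc))
    expect_equal(est$sigma1, 0)
    expect_gt(est$sigma2, 0)
  }
})

test_that("v = 0 equals the well-mixed population for any M and kernel", {
  for (proc in c("moran", "wright_fisher")) {
    a <- sigma_closed_form(model_params(N = 37, M = 9, S = 3, u = 0.13, v = 0,
                                        r = 4, process = proc))
    b <- sigma_wellmixed(37, 0.13, process = proc)
    expect_equal(a$sigma1, b$sigma1, tolerance = 1e-14)
    expect_equal(a$sigma2, b$sigma2, tolerance = 1e-14)
  }
})

test_that("well-mixed moran recovers the classic finite-N results", {
  # u -> 0: sigma1 -> (N - 2)/N, the known low-mutation two-strategy value
  for (N in c(4, 10, 50)) {
    lim <- sigma_limit_small_u(model_params(N = N, M = 1, S = 3, u = 0.5, v = 0))
    expect_equal(lim$sigma1, (N - 2) / N, tolerance = 1e-10)
  }
  # the two-strategy reduction sigma = (2 s1 + s2)/(2 + s2) is (N - 2)/N
  # for EVERY mutation probability (arbitrary-mutation-rate result),
  # for both update rules
  for (proc in c("moran", "wright_fisher")) {
    for (u in c(0.05, 0.3, 0.8, 1)) {
      est <- sigma_wellmixed(12, u, process = proc)
      expect_equal(two_strategy_sigma(est$sigma1, est$sigma2), 10 / 12,
                   tolerance = 1e-12)
    }
  }
})

test_that("moran vs wright-fisher differ off the well-mixed limit", {
  p <- model_params(N = 20, M = 5, S = 3, u = 0.2, v = 0.5, r = 1)
  mo <- sigma_closed_form_moran(p)
  wf <- sigma_closed_form_wf(p)
  expect_false(isTRUE(all.equal(mo$sigma1, wf$sigma1)))
  expect_gt(wf$sigma2, mo$sigma2)   # WF is the more effective sigma2 amplifier
})

test_that("closed form takes no payoff matrix and no strategy count", {
  # payoff independence is enforced by the interface: the sigma routines
  # accept only model_params, and S never changes the value
  p3 <- model_params(N = 15, M = 4, S = 3, u = 0.25, v = 0.6, r = 2)
  p7 <- model_params(N = 15, M = 4, S = 7, u = 0.25, v = 0.6, r = 2)
  a <- sigma_closed_form(p3)
  b <- sigma_closed_form(p7)
  expect_identical(c(a$sigma1, a$sigma2), c(b$sigma1, b$sigma2))
})
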