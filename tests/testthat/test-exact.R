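test_that("state space enumeration is complete and guarded", {
  sp <- enumerate_state_space(2, 2, 2)
  expect_equal(sp$n_states, 16L)
  expect_equal(nrow(unique(sp$codes)), 16L)   # duplicate-free

  sp <- enumerate_state_space(3, 2, 3)
  expect_equal(sp$n_states, 216L)

  expect_error(enumerate_state_space(10, 5, 3), "Monte-Carlo")
})

test_that("neutral transition matrices are row-stochastic for both processes", {
  sp <- enumerate_state_space(3, 2, 3)
  for (proc in c("moran", "wright_fisher")) {
    P <- neutral_transition_matrix(tiny_params(process = proc), sp)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
  expect_error(neutral_transition_matrix(tiny_params(delta = 0.1), sp), "delta")
})

test_that("wright-fisher at u = 1, M = 1 gives uniform rows", {
  p <- model_params(N = 2, M = 1, S = 2, u = 1, v = 0, process = "wright_fisher")
  sp <- enumerate_state_space(2, 1, 2)
  P <- neutral_transition_matrix(p, sp)
  expect_equal(P, matrix(1/4, 4, 4))
})

test_that("M = 1 chain lumps exactly to a well-mixed strategy-count chain", {
  # the induced chain on strategy counts must be well-defined: all states
  # with the same counts have identical lumped transition rows
  p <- model_params(N = 3, M = 1, S = 2, u = 0.3, v = 0)
  sp <- enumerate_state_space(3, 1, 2)
  P <- neutral_transition_matrix(p, sp)
  counts <- apply(sp$s, 1, function(s) paste(tabulate(s, 2), collapse = "-"))
  labels <- sort(unique(counts))
  for (a in labels) {
    rows_a <- which(counts == a)
    lumped_rows <- t(vapply(rows_a, function(r) {
      vapply(labels, function(b) sum(P[r, counts == b]), numeric(1))
    }, numeric(length(labels))))
    expect_lt(max(abs(sweep(lumped_rows, 2, lumped_rows[1, ]))), 1e-13)
  }
})

test_that("stationary solver honours its contract", {
  # symmetric doubly-stochastic toy: uniform stationary law
  P <- matrix(c(0.5, 0.25, 0.25,
                0.25, 0.5, 0.25,
                0.25, 0.25, 0.5), 3, 3, byrow = TRUE)
  pi_s <- stationary_distribution(P)
  expect_equal(pi_s, rep(1/3, 3))

  # permutation matrix: reducible (two cycles), must be rejected with classes
  Pp <- diag(4)[c(2, 1, 4, 3), ]
  expect_error(stationary_distribution(Pp), "closed classes")
  # restricting to one closed class works
  pi_r <- stationary_distribution(Pp, restrict = c(1, 2))
  expect_equal(pi_r, c(0.5, 0.5, 0, 0))
  expect_error(stationary_distribution(Pp, restrict = c(1, 3)), "closed")

  # residual bound on a tiny model instance
  sp <- enumerate_state_space(3, 2, 3)
  P <- neutral_transition_matrix(tiny_params(), sp)
  pi_s <- stationary_distribution(P)
  expect_lt(max(abs(as.vector(pi_s %*% P) - pi_s)), 1e-12)
  expect_equal(sum(pi_s), 1)
})

test_that("chains with u > 0 and v > 0 are irreducible on the full space", {
  sp <- enumerate_state_space(2, 2, 2)
  for (proc in c("moran", "wright_fisher")) {
    P <- neutral_transition_matrix(
      model_params(N = 2, M = 2, S = 2, u = 0.2, v = 0.3, r = 1, process = proc), sp)
    g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
    expect_equal(igraph::components(g, mode = "strong")$no, 1L)
  }
})

test_that("exact stationary law is strategy-label symmetric", {
  p <- tiny_params(u = 0.4, v = 0.3)
  sp <- enumerate_state_space(3, 2, 3)
  P <- neutral_transition_matrix(p, sp)
  pi_s <- stationary_distribution(P)
  # marginal strategy use of a random individual = 1/S for every strategy
  for (a in 1:3) {
    pr <- sum(pi_s * rowMeans(sp$s == a))
    expect_equal(pr, 1/3, tolerance = 1e-12)
  }
})

test_that("triplet probabilities normalise and respect label symmetry", {
  p <- tiny_params(u = 0.4, v = 0.6)
  sp <- enumerate_state_space(3, 2, 3)
  P <- neutral_transition_matrix(p, sp)
  pi_s <- stationary_distribution(P)

  # summed over all strategy patterns with the co-residence flag on,
  # the total is the probability two random individuals co-reside
  pats <- expand.grid(d1 = 1:3, d2 = 1:3, d3 = 1:3)
  tot <- sum(apply(pats, 1, function(dd)
    triplet_probability(pi_s, sp, dd[1], dd[2], dd[3], TRUE)))
  pair_cores <- sum(pi_s * vapply(seq_len(sp$n_states), function(st) {
    g <- sp$g[st, ]
    mean(outer(g, g, "==")[upper.tri(diag(3))])
  }, numeric(1)))
  expect_equal(tot, pair_cores, tolerance = 1e-12)

  # permutation invariance of the strategy alphabet under neutrality
  p123 <- triplet_probability(pi_s, sp, 1, 2, 3, TRUE)
  p231 <- triplet_probability(pi_s, sp, 2, 3, 1, TRUE)
  p312 <- triplet_probability(pi_s, sp, 3, 1, 2, TRUE)
  expect_equal(p123, p231, tolerance = 1e-12)
  expect_equal(p123, p312, tolerance = 1e-12)

  # M = 1: the co-residence flag is vacuous
  p1 <- model_params(N = 3, M = 1, S = 3, u = 0.4, v = 0)
  sp1 <- enumerate_state_space(3, 1, 3)
  pi1 <- stationary_distribution(neutral_transition_matrix(p1, sp1))
  expect_equal(triplet_probability(pi1, sp1, 1, 2, 2, TRUE),
               triplet_probability(pi1, sp1, 1, 2, 2, FALSE))
})
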