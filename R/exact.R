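#' Enumerate the full state space
#'
#' Every assignment of a strategy in `1..S` and a group in `1..M` to each of
#' the `N` labelled individuals: `(S*M)^N` states, indexed in mixed-radix
#' order (individual 1 most significant). Feasible only for tiny instances;
#' this is deliberate — the enumerated chain is the trusted oracle against
#' which the closed forms and the Monte-Carlo estimator are verified.
#'
#' @param N,M,S dimensions.
#' @param limit refuse enumeration beyond this many states.
#' @return An object of class `state_space`: list with `N`, `M`, `S`,
#'   `n_states`, and `n_states x N` integer matrices `s` and `g`.
#' @export
enumerate_state_space <- function(N, M, S, limit = 2e5) {
  N <- check_count(N, "N", 1L); M <- check_count(M, "M", 1L); S <- check_count(S, "S", 1L)
  K <- S * M
  n_states <- K^N
  if (n_states > limit) {
    stop("state space has (S*M)^N = ", format(n_states), " states, over the limit of ",
         format(limit), "; use the Monte-Carlo estimator instead", call. = FALSE)
  }
  codes <- as.matrix(rev(expand.grid(rev(rep(list(0:(K - 1L)), N)))))
  dimnames(codes) <- NULL
  storage.mode(codes) <- "integer"
  structure(list(N = N, M = M, S = S, n_states = as.integer(n_states),
                 codes = codes,
                 s = codes %/% M + 1L,
                 g = codes %% M + 1L),
            class = "state_space")
}

state_index <- function(codes, K, N) {
  # mixed-radix index (1-based), individual 1 most significant
  as.vector(codes %*% K^((N:1) - 1)) + 1
}

# distribution of the offspring code given each parent code, K x K
offspring_distribution <- function(params) {
  M <- params$M; S <- params$S; u <- params$u; v <- params$v
  f <- params$kernel$f
  K <- S * M
  # strategy transition: S x S
  Ps <- matrix(u / S, S, S) + (1 - u) * diag(S)
  # group transition: M x M, circulant of the migration mixture
  mig <- v * f
  mig[1L] <- mig[1L] + 1 - v
  Pg <- matrix(0, M, M)
  for (a in seq_len(M)) for (d in 0:(M - 1L)) {
    b <- (a - 1L + d) %% M + 1L
    Pg[a, b] <- Pg[a, b] + mig[d + 1L]
  }
  # code = (s-1)*M + (g-1); kronecker so that strategy is the slow index
  kronecker(Ps, Pg)
}

#' Exact one-step transition matrix of the neutral chain
#'
#' Assembles the row-stochastic transition matrix over the enumerated state
#' space at `delta = 0`. Moran rows combine the uniform parent choice
#' (`1/N`), the offspring mutation/migration distribution and the uniform
#' incumbent death (`1/N`); Wright-Fisher rows are products of `N`
#' identical per-slot offspring distributions.
#'
#' @param params a [model_params()] with `delta = 0`.
#' @param space an [enumerate_state_space()] result matching `params`.
#' @return Dense `n_states x n_states` row-stochastic matrix.
#' @export
neutral_transition_matrix <- function(params, space) {
  stopifnot(inherits(params, "model_params"), inherits(space, "state_space"))
  if (params$delta != 0) {
    stop("the exact oracle is built for the neutral chain; set delta = 0",
         call. = FALSE)
  }
  if (space$N != params$N || space$M != params$M || space$S != params$S) {
    stop("state space dimensions do not match params", call. = FALSE)
  }
  N <- params$N; K <- params$S * params$M
  ns <- space$n_states
  off <- offspring_distribution(params)
  P <- matrix(0, ns, ns)
  if (params$process == "moran") {
    place <- K^(N - seq_len(N))        # place value of each slot
    for (st in seq_len(ns)) {
      cd <- space$codes[st, ]
      # per-child-code probability, averaged over the uniform parent
      child_dist <- colMeans(off[cd + 1L, , drop = FALSE])
      for (dead in seq_len(N)) {
        idx <- st + (0:(K - 1L) - cd[dead]) * place[dead]
        P[st, idx] <- P[st, idx] + child_dist / N
      }
    }
  } else {
    for (st in seq_len(ns)) {
      cd <- space$codes[st, ]
      q <- colMeans(off[cd + 1L, , drop = FALSE])  # per-slot offspring law
      row <- 1
      for (slot in seq_len(N)) row <- kronecker(row, q)  # slot 1 slowest
      P[st, ] <- row
    }
  }
  stopifnot(max(abs(rowSums(P) - 1)) < 1e-12)
  P
}

#' Stationary distribution of a finite chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` by a dense linear solve and verifies
#' the residual. Requires an irreducible chain; for a reducible input the
#' closed (recurrent) communicating classes are reported and the caller
#' must either pass `restrict` (a set of state indices forming one closed
#' class) or fix the model.
#'
#' @param P row-stochastic matrix.
#' @param restrict optional integer vector of state indices; the chain is
#'   restricted to this closed class before solving.
#' @return Numeric stationary vector of length `nrow(P)` (zeros outside
#'   `restrict` when given).
#' @export
stationary_distribution <- function(P, restrict = NULL) {
  if (max(abs(rowSums(P) - 1)) > 1e-10) {
    stop("P is not row-stochastic", call. = FALSE)
  }
  n <- nrow(P)
  full_n <- n
  idx <- seq_len(n)
  if (!is.null(restrict)) {
    idx <- sort(unique(as.integer(restrict)))
    leak <- max(abs(rowSums(P[idx, idx, drop = FALSE]) - 1))
    if (leak > 1e-12) {
      stop("`restrict` is not a closed class (probability leaks out: ",
           format(leak), ")", call. = FALSE)
    }
    P <- P[idx, idx, drop = FALSE]
    n <- length(idx)
  }
  gr <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  comp <- igraph::components(gr, mode = "strong")
  if (comp$no > 1L) {
    # closed classes: strongly connected components with no outgoing edges.
    # A unique closed class still has a unique stationary law (transient
    # states get mass zero); only multiple closed classes are ambiguous.
    memb <- comp$membership
    closed <- vapply(seq_len(comp$no), function(cl) {
      inside <- memb == cl
      sum(P[inside, !inside, drop = FALSE]) < 1e-14
    }, logical(1))
    if (sum(closed) > 1L) {
      classes <- lapply(which(closed), function(cl) which(memb == cl))
      stop("chain is reducible with several closed classes; pass `restrict` ",
           "with one of them. Closed classes: ",
           paste(vapply(classes, function(ix) paste0("{", paste(utils::head(ix, 8), collapse = ","),
                                                     if (length(ix) > 8) ",..." else "", "}"),
                        character(1)), collapse = " "),
           call. = FALSE)
    }
  }
  A <- t(P) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi_r <- solve(A, b)
  resid <- max(abs(as.vector(pi_r %*% P) - pi_r))
  if (resid > 1e-12) {
    stop("stationary solve residual too large: ", format(resid), call. = FALSE)
  }
  out <- numeric(full_n)
  out[idx] <- pi_r
  out
}

# per-state statistics needed for the sigma ratios, vectorised over states
sigma_state_statistics <- function(space) {
  N <- space$N
  t(vapply(seq_len(space$n_states), function(st) {
    s <- space$s[st, ]; g <- space$g[st, ]
    n <- matrix(0L, space$S, space$M)
    for (i in seq_len(N)) n[s[i], g[i]] <- n[s[i], g[i]] + 1L
    x1 <- sum(s == 1L) / N
    c(e2 = x1 * sum(n[2L, ] * n[1L, ]),
      e3 = x1 * sum(n[2L, ] * (n[2L, ] - 1L)),
      e4 = x1 * sum(n[2L, ] * n[3L, ]))
  }, numeric(3)))
}

#' Exact structure coefficients by full enumeration
#'
#' The trusted oracle: enumerates all `(S*M)^N` states, builds the neutral
#' transition matrix, solves for the stationary distribution, and forms the
#' sigma ratios from the exact stationary expectations of
#' `x1*I21`, `x1*I22` and `x1*I23`. No approximation beyond floating point.
#'
#' Without migration (`v = 0`) the location chain is reducible — every
#' single-group configuration is absorbing — and each closed class is
#' isomorphic to the well-mixed `M = 1` chain, which is what gets built in
#' that case.
#'
#' @param params a [model_params()] with `u > 0`, `S >= 3`, `delta = 0`.
#' @param limit passed to [enumerate_state_space()].
#' @return A [sigma_estimate()] with `method = "exact"`.
#' @export
sigma_exact <- function(params, limit = 2e5) {
  stopifnot(inherits(params, "model_params"))
  if (params$S < 3) stop("sigma estimation needs S >= 3 (labels 1, 2, 3 distinct)",
                         call. = FALSE)
  if (params$u <= 0) stop("exact sigma requires u > 0", call. = FALSE)
  if (params$v == 0 && params$M > 1) {
    # group fixation: restrict to the single-group closed class == M = 1 chain
    params <- model_params(N = params$N, M = 1L, S = params$S, u = params$u,
                           v = 0, delta = 0, process = params$process)
  }
  space <- enumerate_state_space(params$N, params$M, params$S, limit = limit)
  P <- neutral_transition_matrix(params, space)
  pi_s <- stationary_distribution(P)
  st <- sigma_state_statistics(space)
  e <- as.vector(pi_s %*% st)
  names(e) <- c("e2", "e3", "e4")
  den <- e[["e2"]] - e[["e4"]]
  sigma_estimate(sigma1 = (e[["e3"]] - e[["e4"]]) / den,
                 sigma2 = params$S * e[["e4"]] / den,
                 se1 = 0, se2 = 0, method = "exact", params = params,
                 diagnostics = list(expectations = e))
}

#' Stationary probability of a strategy/location pattern for three
#' individuals
#'
#' The probability that three individuals sampled without replacement from
#' the stationary population use strategies `(d1, d2, d3)`, optionally
#' requiring individuals 2 and 3 to be co-resident. These are the
#' probabilities through which the sigma expectations decompose.
#'
#' @param pi_s stationary distribution over `space`.
#' @param space an [enumerate_state_space()] result.
#' @param d1,d2,d3 strategy labels.
#' @param require_same_group_pair if `TRUE`, also require `g2 == g3`.
#' @return A probability.
#' @export
triplet_probability <- function(pi_s, space, d1, d2, d3,
                                require_same_group_pair = TRUE) {
  if (space$N < 3) stop("need N >= 3 to sample three distinct individuals",
                        call. = FALSE)
  N <- space$N
  trip <- expand.grid(i = seq_len(N), j = seq_len(N), k = seq_len(N))
  trip <- trip[trip$i != trip$j & trip$i != trip$k & trip$j != trip$k, ]
  per_state <- vapply(seq_len(space$n_states), function(st) {
    s <- space$s[st, ]; g <- space$g[st, ]
    ok <- s[trip$i] == d1 & s[trip$j] == d2 & s[trip$k] == d3
    if (require_same_group_pair) ok <- ok & g[trip$j] == g[trip$k]
    sum(ok) / nrow(trip)
  }, numeric(1))
  sum(pi_s * per_state)
}
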