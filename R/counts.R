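#' Strategy-by-group occupancy counts
#'
#' Tallies `n[s, g]`, the number of individuals using strategy `s` that live
#' in group `g`. Column sums are the group sizes; the grand total is `N`.
#'
#' @param state a [population_state()].
#' @param S,M matrix dimensions (default: observed maxima).
#' @return Integer `S x M` matrix.
#' @export
strategy_group_counts <- function(state, S = max(state$s), M = max(state$g)) {
  stopifnot(inherits(state, "population_state"))
  n <- matrix(0L, S, M)
  idx <- cbind(state$s, state$g)
  for (i in seq_along(state$s)) n[idx[i, 1L], idx[i, 2L]] <- n[idx[i, 1L], idx[i, 2L]] + 1L
  n
}

#' Within-group game counts I
#'
#' `I[i, j]` is the total number of games that `i`-players play against
#' `j`-players: every ordered pair of distinct co-resident individuals
#' `(k, l)` contributes one count to `I[s_k, s_l]`. Consequently `I` is
#' symmetric, `I[i, j] = sum_g n_i^g n_j^g` for `i != j`, and each
#' same-strategy game is counted twice on the diagonal,
#' `I[i, i] = sum_g n_i^g (n_i^g - 1)`.
#'
#' @inheritParams strategy_group_counts
#' @return Numeric `S x S` matrix.
#' @export
interaction_counts <- function(state, S = max(state$s), M = max(state$g)) {
  n <- strategy_group_counts(state, S = S, M = M)
  I <- matrix(0, S, S)
  for (g in seq_len(M)) {
    cg <- n[, g]
    I <- I + outer(cg, cg) - diag(cg, nrow = S)
  }
  I
}

#' Accumulated game payoffs
#'
#' Each individual plays the game with every other member of its group and
#' accumulates payoffs: `p_k = sum over co-residents j != k of A[s_k, s_j]`.
#' An individual alone in its group earns 0. Self-interaction is excluded.
#'
#' @param state a [population_state()].
#' @param payoff a [payoff_spec()] (or a bare payoff matrix).
#' @return Numeric vector of length `N`.
#' @export
payoff_vector <- function(state, payoff) {
  if (!inherits(payoff, "payoff_spec")) payoff <- payoff_spec(payoff)
  A <- payoff$A
  S <- nrow(A)
  if (max(state$s) > S) stop("state uses strategy labels beyond the payoff matrix",
                             call. = FALSE)
  n <- strategy_group_counts(state, S = S, M = max(state$g))
  An <- A %*% n                                  # An[s, g]: payoff of an s-player vs group g
  An[cbind(state$s, state$g)] - diag(A)[state$s] # drop the self-game
}

#' Linear fitness map
#'
#' `fitness = 1 + delta * payoff`. Rejected when any value is non-positive:
#' the linear map only defines a reproduction rate for selection intensities
#' small enough to keep fitness positive.
#'
#' @param payoffs numeric vector of payoffs.
#' @param delta selection intensity (`>= 0`).
#' @return Numeric vector of strictly positive fitnesses.
#' @export
fitness_vector <- function(payoffs, delta) {
  if (length(delta) != 1L || !is.finite(delta) || delta < 0) {
    stop("`delta` must be a single number >= 0", call. = FALSE)
  }
  f <- 1 + delta * payoffs
  if (any(f <= 0)) {
    stop("selection intensity too large for the linear fitness map: ",
         "1 + delta * p <= 0 for some individual (min payoff ",
         format(min(payoffs)), ")", call. = FALSE)
  }
  f
}
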