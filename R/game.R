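#' @name favourability
#' @title Weak-selection favourability condition
#'
#' @description
#' Under weak selection the stationary mean frequency of strategy `k`
#' exceeds `1/S` exactly when a payoff-linear "selection gradient" is
#' positive. The gradient is the sum of two competition terms weighted by
#' the structure coefficients:
#'
#' \deqn{\sum_{q \ne k} \left[\sigma_1 a_{kk} + a_{kq} - a_{qk} - \sigma_1 a_{qq}\right]
#'   \;+\; \sigma_2 \left[\sum_q a_{kq} - \frac{1}{S}\sum_{p,q} a_{pq}\right] > 0.}
#'
#' The first term averages pairwise contests between `k` and every other
#' strategy, each in the sigma-weighted two-strategy form; the second is
#' `k`'s payoff advantage when all `S` strategies are equally frequent.
#' Gradients sum to zero over strategies (consistent with frequencies
#' summing to one) and are invariant to adding a constant to every payoff.
NULL

check_payoff_matrix <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || any(!is.finite(A))) {
    stop("`A` must be a square matrix of finite payoffs", call. = FALSE)
  }
  A
}

#' Pairwise competition term
#'
#' The sigma1-weighted sum of pairwise contests of strategy `k` against all
#' others: `sum over q != k of (sigma1 a_kk + a_kq - a_qk - sigma1 a_qq)`.
#'
#' @param A payoff matrix.
#' @param k focal strategy index.
#' @param sigma1 pairwise structure coefficient.
#' @return A number.
#' @export
pairwise_competition_term <- function(A, k, sigma1) {
  A <- check_payoff_matrix(A)
  S <- nrow(A)
  q <- setdiff(seq_len(S), k)
  sum(sigma1 * A[k, k] + A[k, q] - A[q, k] - sigma1 * diag(A)[q])
}

#' Equal-frequency competition term
#'
#' Strategy `k`'s payoff advantage when all strategies are equally frequent:
#' `sum_q a_kq - (1/S) sum_pq a_pq` (S times the advantage of `k`'s row
#' mean over the grand mean).
#'
#' @param A payoff matrix.
#' @param k focal strategy index.
#' @return A number.
#' @export
equal_frequency_term <- function(A, k) {
  A <- check_payoff_matrix(A)
  sum(A[k, ]) - sum(A) / nrow(A)
}

#' Selection gradient and favourability
#'
#' `selection_gradient()` evaluates the left-hand side of the favourability
#' condition; `favored()` returns whether it is positive, i.e. whether the
#' weak-selection stationary mean frequency of `k` exceeds `1/S`.
#'
#' @param A payoff matrix.
#' @param k focal strategy index.
#' @param sigma1,sigma2 structure coefficients (from any of the sigma
#'   routes).
#' @return A number (`selection_gradient`) or logical (`favored`).
#' @export
selection_gradient <- function(A, k, sigma1, sigma2) {
  pairwise_competition_term(A, k, sigma1) + sigma2 * equal_frequency_term(A, k)
}

#' @rdname selection_gradient
#' @export
favored <- function(A, k, sigma1, sigma2) {
  selection_gradient(A, k, sigma1, sigma2) > 0
}

#' Full selection report
#'
#' Evaluates the gradient for every strategy and flags the favoured ones.
#'
#' @param A payoff matrix (row/column names used as strategy labels when
#'   present).
#' @param sigma1,sigma2 structure coefficients.
#' @return A tibble with columns `strategy`, `gradient`, `favored`; the
#'   sigma values are attached as attributes `sigma1`, `sigma2`.
#' @export
selection_report <- function(A, sigma1, sigma2) {
  A <- check_payoff_matrix(A)
  S <- nrow(A)
  grad <- vapply(seq_len(S), selection_gradient, numeric(1),
                 A = A, sigma1 = sigma1, sigma2 = sigma2)
  stopifnot(abs(sum(grad)) < 1e-9 * max(1, max(abs(grad))))
  out <- tibble::tibble(
    strategy = if (!is.null(rownames(A))) rownames(A) else as.character(seq_len(S)),
    gradient = grad,
    favored = grad > 0)
  attr(out, "sigma1") <- sigma1
  attr(out, "sigma2") <- sigma2
  out
}

#' Two-strategy structure coefficient
#'
#' For `S = 2` the favourability condition collapses to the single-sigma
#' form `sigma a11 + a12 > a21 + sigma a22` with
#' `sigma = (2 sigma1 + sigma2) / (2 + sigma2)`.
#'
#' @param sigma1,sigma2 structure coefficients.
#' @return The two-strategy sigma.
#' @export
two_strategy_sigma <- function(sigma1, sigma2) {
  den <- 2 + sigma2
  if (abs(den) < 1e-12) stop("degenerate denominator: sigma2 = -2", call. = FALSE)
  (2 * sigma1 + sigma2) / den
}

#' Repeated-game payoff matrix for ALLC / ALLD / TFT
#'
#' Two members of the same group play `m` rounds. Per round a cooperator
#' pays cost `c` to give benefit `b` to the opponent (`b > c > 0`); a
#' defector pays and gives nothing. ALLC always cooperates, ALLD always
#' defects, TFT cooperates first and then repeats the opponent's previous
#' move. The matrix is produced by simulating the three automata round by
#' round, not by transcribing entries.
#'
#' @param b,c benefit and cost per cooperative act (`b > c > 0`).
#' @param m number of rounds (integer `>= 1`).
#' @return `3 x 3` payoff matrix with dimnames `ALLC`, `ALLD`, `TFT`.
#' @export
reciprocity_payoffs <- function(b, c, m) {
  # c = 0 is allowed as the boundary used when root-finding on c/b
  if (!(is.finite(b) && is.finite(c) && b > c && c >= 0)) {
    stop("need b > c >= 0", call. = FALSE)
  }
  m <- check_count(m, "m", min = 1L)
  strategies <- list(
    ALLC = function(round, opp_prev) TRUE,
    ALLD = function(round, opp_prev) FALSE,
    TFT  = function(round, opp_prev) if (round == 1L) TRUE else opp_prev)
  S <- length(strategies)
  A <- matrix(0, S, S, dimnames = list(names(strategies), names(strategies)))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    prev_i <- prev_j <- NA
    pay_i <- 0
    for (round in seq_len(m)) {
      move_i <- strategies[[i]](round, prev_j)
      move_j <- strategies[[j]](round, prev_i)
      pay_i <- pay_i + (if (move_j) b else 0) - (if (move_i) c else 0)
      prev_i <- move_i; prev_j <- move_j
    }
    A[i, j] <- pay_i
  }
  A
}

#' Critical cost-to-benefit ratio for direct reciprocity
#'
#' The boundary value of `c/b` at which ALLD's selection gradient in the
#' ALLC/ALLD/TFT contest vanishes. For `c/b` below the critical ratio ALLD
#' is disfavoured (its stationary mean frequency under weak selection stays
#' below 1/3), i.e. cooperation is favoured; a larger critical ratio means
#' cooperation evolves under a wider range of games. The gradient is linear
#' in `c/b` at fixed `(sigma1, sigma2, m)`, so the root is solved exactly
#' from two evaluations.
#'
#' In the large-`sigma2` regime (high mutation) the ratio tends to the
#' `m`-only value `2(m - 1) / (5m + 1)`.
#'
#' @param sigma1,sigma2 structure coefficients (`>= 0`, not both 0).
#' @param m number of rounds.
#' @return The critical ratio `(c/b)*`.
#' @export
critical_cost_benefit <- function(sigma1, sigma2, m) {
  if (sigma1 < 0 || sigma2 < 0 || (sigma1 == 0 && sigma2 == 0)) {
    stop("need sigma1, sigma2 >= 0 and not both zero", call. = FALSE)
  }
  m <- check_count(m, "m", min = 1L)
  grad_at <- function(rho) {
    A <- reciprocity_payoffs(b = 1, c = rho, m = m)
    selection_gradient(A, k = 2L, sigma1 = sigma1, sigma2 = sigma2) # k = ALLD
  }
  g0 <- grad_at(0)
  g1 <- grad_at(0.5) # slope = (g(1/2) - g(0)) / (1/2)
  slope <- (g1 - g0) * 2
  if (abs(slope) < 1e-12 * max(1, abs(g0))) {
    stop("gradient does not depend on c/b at these coefficients; no finite root",
         call. = FALSE)
  }
  -g0 / slope
}
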