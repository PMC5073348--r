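#' Per-state sigma statistics
#'
#' The three statistics whose stationary means define the structure
#' coefficients: with `x1 = N1/N` the frequency of strategy 1,
#' `t1 = x1 (I22 - I23)`, `t2 = S x1 I23`, `td = x1 (I21 - I23)`. Summed
#' over recorded steady states, `sigma1 = sum(t1)/sum(td)` and
#' `sigma2 = sum(t2)/sum(td)`. Labels 1, 2, 3 must be distinct, hence
#' `S >= 3`.
#'
#' @param state a [population_state()].
#' @param S number of strategies (`>= 3`).
#' @return Named numeric vector `c(t1, t2, td)`.
#' @export
sigma_terms <- function(state, S) {
  S <- check_count(S, "S", min = 2L)
  if (S < 3L) stop("sigma statistics need S >= 3: labels 1, 2, 3 must be distinct",
                   call. = FALSE)
  I <- interaction_counts(state, S = S, M = max(state$g))
  x1 <- mean(state$s == 1L)
  c(t1 = x1 * (I[2, 2] - I[2, 3]),
    t2 = S * x1 * I[2, 3],
    td = x1 * (I[2, 1] - I[2, 3]))
}

#' Label-symmetrised sigma statistics
#'
#' Averages [sigma_terms()] over all ordered triples of distinct strategy
#' labels playing the roles (1, 2, 3). Under neutrality the chain is
#' exchangeable over strategy labels, so the symmetrised statistics have the
#' same stationary mean with lower variance.
#'
#' @inheritParams sigma_terms
#' @return Named numeric vector `c(t1, t2, td)`.
#' @export
symmetrized_sigma_terms <- function(state, S) {
  S <- check_count(S, "S", min = 2L)
  if (S < 3L) stop("sigma statistics need S >= 3: labels 1, 2, 3 must be distinct",
                   call. = FALSE)
  I <- interaction_counts(state, S = S, M = max(state$g))
  xs <- tabulate(state$s, nbins = S) / length(state$s)
  t1 <- t2 <- td <- 0
  n_trip <- 0L
  for (a in seq_len(S)) for (b in seq_len(S)) for (cc in seq_len(S)) {
    if (a == b || a == cc || b == cc) next
    t1 <- t1 + xs[a] * (I[b, b] - I[b, cc])
    t2 <- t2 + S * xs[a] * I[b, cc]
    td <- td + xs[a] * (I[b, a] - I[b, cc])
    n_trip <- n_trip + 1L
  }
  c(t1 = t1, t2 = t2, td = td) / n_trip
}

#' Monte-Carlo estimate of the structure coefficients
#'
#' Runs the neutral chain (a compiled loop with the exact same update rules
#' as [moran_step()]/[wf_step()]), accumulates the three sigma statistics
#' over every `record_every`-th post-burn-in state, and forms the two
#' ratios. Standard errors come from batch means (default 50 equal batches)
#' with delta-method propagation through each ratio. The coefficients are
#' neutral quantities, so the payoff matrix and `delta` never enter; any
#' `delta` in `params` is ignored and the chain is run at `delta = 0`.
#'
#' When the accumulated denominator is too close to zero
#' (`|sum(td)|/n < 1e-6 * N^2`) the returned estimate carries
#' `unreliable = TRUE` rather than silently reporting a huge ratio.
#'
#' @param params a [model_params()] with `u > 0` and `S >= 3`.
#' @param config a [chain_config()]; set `config$seed` for reproducibility.
#' @param symmetrize average the statistics over all ordered label triples
#'   (variance reduction; valid by neutral label exchangeability).
#' @param initial optional starting [population_state()]; default strategies
#'   i.i.d. uniform, everyone in group 1.
#' @param n_batches number of batches for the batch-means standard errors.
#' @return A [sigma_estimate()] with `method = "mc"`.
#' @export
estimate_sigma_mc <- function(params, config = chain_config(),
                              symmetrize = FALSE, initial = NULL,
                              n_batches = 50L) {
  stopifnot(inherits(params, "model_params"), inherits(config, "chain_config"))
  if (params$S < 3) stop("sigma estimation needs S >= 3", call. = FALSE)
  if (params$u <= 0) stop("sigma estimation requires u > 0", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(initial)) {
    initial <- population_state(sample.int(params$S, params$N, replace = TRUE),
                                rep(1L, params$N), S = params$S, M = params$M)
  }
  res <- cpp_sigma_chain(initial$s, initial$g, params$S, params$M,
                         params$u, params$v, params$kernel$f,
                         if (params$process == "moran") 0L else 1L,
                         config$n_steps, config$burn_in, config$record_every,
                         as.integer(n_batches), symmetrize)
  n <- res$n_samples
  sigma1 <- res$sum1 / res$sumd
  sigma2 <- res$sum2 / res$sumd
  # batch means: divide each batch's sums by its sample count
  counts <- batch_counts(n, n_batches)
  a1 <- res$batch_sums[1, ] / counts
  a2 <- res$batch_sums[2, ] / counts
  b  <- res$batch_sums[3, ] / counts
  se_ratio <- function(a, R) {
    K <- length(a)
    sqrt(sum(((a - R * b) / mean(b))^2) / (K * (K - 1)))
  }
  unreliable <- abs(res$sumd) / n <= 1e-6 * params$N^2
  sigma_estimate(sigma1 = sigma1, sigma2 = sigma2,
                 se1 = se_ratio(a1, sigma1), se2 = se_ratio(a2, sigma2),
                 method = "mc", params = params, n_samples = n,
                 seed = if (is.null(config$seed)) NA_integer_ else config$seed,
                 unreliable = unreliable,
                 diagnostics = list(sums = c(t1 = res$sum1, t2 = res$sum2,
                                             td = res$sumd),
                                    batch_means = rbind(t1 = a1, t2 = a2, td = b)))
}

# how many recorded samples land in each of n_batches contiguous batches
batch_counts <- function(n, n_batches) {
  idx <- seq_len(n) - 1
  tabulate(pmin(floor(idx * n_batches / n), n_batches - 1) + 1, nbins = n_batches)
}

#' Simulate stationary mean strategy frequencies under selection
#'
#' Runs the full process at selection intensity `params$delta` with the
#' given payoff matrix and records the time-averaged strategy frequencies,
#' with batch-means standard errors. This is the direct (simulation) side
#' of the weak-selection predictions made by [selection_gradient()].
#'
#' @param params a [model_params()] (its `delta` is used).
#' @param payoff a [payoff_spec()] or bare `S x S` matrix.
#' @param config a [chain_config()].
#' @param initial optional starting state.
#' @param n_batches batches for standard errors.
#' @return A tibble with columns `strategy`, `mean_freq`, `se`.
#' @export
simulate_mean_frequencies <- function(params, payoff, config = chain_config(),
                                      initial = NULL, n_batches = 50L) {
  stopifnot(inherits(params, "model_params"))
  if (!inherits(payoff, "payoff_spec")) payoff <- payoff_spec(payoff, params$delta)
  if (nrow(payoff$A) != params$S) stop("payoff matrix must be S x S", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(initial)) {
    initial <- population_state(sample.int(params$S, params$N, replace = TRUE),
                                rep(1L, params$N), S = params$S, M = params$M)
  }
  res <- cpp_game_chain(initial$s, initial$g, params$S, params$M,
                        params$u, params$v, params$kernel$f,
                        if (params$process == "moran") 0L else 1L,
                        params$delta, payoff$A,
                        config$n_steps, config$burn_in, config$record_every,
                        as.integer(n_batches))
  means <- res$freq_sum / res$n_samples
  bf <- sweep(res$batch_freq, 2, res$batch_n, "/")
  se <- apply(bf, 1, function(x) stats::sd(x) / sqrt(length(x)))
  tibble::tibble(strategy = seq_len(params$S),
                 mean_freq = as.numeric(means),
                 se = as.numeric(se))
}
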