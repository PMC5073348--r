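#' Chain run configuration
#'
#' @param n_steps total number of update events (Moran birth-death events or
#'   Wright-Fisher generations). The default is a desk-scale run; raise it
#'   for production estimates.
#' @param burn_in events discarded before recording starts
#'   (`0 <= burn_in < n_steps`).
#' @param seed RNG seed; the same seed reproduces the trajectory bit for bit.
#' @param record_every sampling stride among post-burn-in states.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_steps = 1e6, burn_in = 1e4, seed = NULL,
                         record_every = 1) {
  n_steps <- as.numeric(n_steps); burn_in <- as.numeric(burn_in)
  if (burn_in < 0 || burn_in >= n_steps) {
    stop("need 0 <= burn_in < n_steps", call. = FALSE)
  }
  record_every <- check_count(record_every, "record_every", min = 1L)
  if (!is.null(seed)) {
    if (!is.finite(seed)) stop("`seed` must be a finite integer", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(list(n_steps = n_steps, burn_in = burn_in, seed = seed,
                 record_every = record_every),
            class = "chain_config")
}

#' One offspring draw: mutation then migration
#'
#' The offspring inherits the parent's strategy unless it mutates (with
#' probability `u`), in which case one of the `S` strategies is chosen
#' uniformly — the parental strategy included ("global mutation"). It stays
#' in the parent's group unless it migrates (with probability `v`), in which
#' case its group label is shifted by a displacement drawn from the kernel.
#' The two events are independent; both can happen in the same draw.
#'
#' @param parent_strategy,parent_group parent labels.
#' @param params a [model_params()].
#' @return Integer vector `c(strategy, group)`.
#' @export
offspring_draw <- function(parent_strategy, parent_group, params) {
  s <- if (stats::runif(1) < params$u) sample.int(params$S, 1L) else as.integer(parent_strategy)
  g <- as.integer(parent_group)
  if (stats::runif(1) < params$v) {
    d <- sample.int(params$M, 1L, prob = params$kernel$f) - 1L
    g <- (g - 1L + d) %% params$M + 1L
  }
  c(s, g)
}

process_fitness <- function(state, params, payoff) {
  if (params$delta == 0) return(rep(1, length(state$s)))
  if (is.null(payoff)) {
    stop("delta > 0 requires a payoff_spec to compute fitness", call. = FALSE)
  }
  fitness_vector(payoff_vector(state, payoff), params$delta)
}

#' One Moran birth-death event
#'
#' All `N` individuals compete to produce one offspring with probability
#' proportional to fitness; the offspring is formed by [offspring_draw()];
#' then one of the `N` pre-existing individuals (the parent included, the
#' newborn exempt) is chosen uniformly to die, and the newborn takes the
#' vacated slot. Exactly one slot changes; `N` is conserved.
#'
#' @param state a [population_state()].
#' @param params a [model_params()].
#' @param payoff a [payoff_spec()]; required when `params$delta > 0`.
#' @return The next [population_state()].
#' @export
moran_step <- function(state, params, payoff = NULL) {
  N <- length(state$s)
  stopifnot(N == params$N)
  w <- process_fitness(state, params, payoff)
  parent <- sample.int(N, 1L, prob = w)
  child <- offspring_draw(state$s[parent], state$g[parent], params)
  dead <- sample.int(N, 1L)
  state$s[dead] <- child[1L]
  state$g[dead] <- child[2L]
  state
}

#' One Wright-Fisher generation
#'
#' `N` offspring are drawn independently: each picks a parent with
#' probability proportional to fitness and applies [offspring_draw()]. The
#' whole population is replaced by the newborns (non-overlapping
#' generations).
#'
#' @inheritParams moran_step
#' @return The next [population_state()].
#' @export
wf_step <- function(state, params, payoff = NULL) {
  N <- length(state$s)
  stopifnot(N == params$N)
  w <- process_fitness(state, params, payoff)
  parents <- sample.int(N, N, replace = TRUE, prob = w)
  s <- integer(N); g <- integer(N)
  for (k in seq_len(N)) {
    child <- offspring_draw(state$s[parents[k]], state$g[parents[k]], params)
    s[k] <- child[1L]; g[k] <- child[2L]
  }
  state$s <- s
  state$g <- g
  state
}

#' Run a chain with an observer
#'
#' Applies the configured process step `n_steps` times and invokes
#' `observer(state, step)` on every `record_every`-th state after the
#' burn-in. This is the plain-R reference driver, intended for tests and
#' short exploratory runs; the production estimators
#' ([estimate_sigma_mc()], [simulate_mean_frequencies()]) use a compiled
#' loop with the same dynamics.
#'
#' @param initial starting [population_state()]; default: strategies i.i.d.
#'   uniform, everyone in group 1 (irrelevant after burn-in).
#' @param params a [model_params()].
#' @param config a [chain_config()].
#' @param observer function of `(state, step)`; its return values are
#'   collected in a list. Errors raised by the observer propagate with the
#'   step index attached.
#' @param payoff optional [payoff_spec()] (needed when `delta > 0`).
#' @return Invisibly, a list with `observations` (list of observer returns)
#'   and `final` (the last state).
#' @export
run_chain <- function(initial = NULL, params, config = chain_config(),
                      observer = NULL, payoff = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(initial)) {
    initial <- population_state(sample.int(params$S, params$N, replace = TRUE),
                                rep(1L, params$N), S = params$S, M = params$M)
  }
  step_fun <- if (params$process == "moran") moran_step else wf_step
  state <- initial
  out <- list()
  for (step in seq_len(config$n_steps)) {
    state <- step_fun(state, params, payoff)
    if (step > config$burn_in &&
        (step - config$burn_in - 1L) %% config$record_every == 0) {
      if (!is.null(observer)) {
        res <- tryCatch(observer(state, step), error = function(e) {
          stop("observer failed at step ", step, ": ", conditionMessage(e),
               call. = FALSE)
        })
        out[[length(out) + 1L]] <- res
      }
    }
  }
  invisible(list(observations = out, final = state))
}
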