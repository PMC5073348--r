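# Brute-force oracles, deliberately written as direct transcriptions of the
# definitions so they stay independent of the package's optimised paths.

# ordered co-resident pairs, counted one by one
brute_interaction_counts <- function(state, S) {
  N <- length(state$s)
  I <- matrix(0, S, S)
  for (k in seq_len(N)) for (j in seq_len(N)) {
    if (j != k && state$g[j] == state$g[k]) {
      I[state$s[k], state$s[j]] <- I[state$s[k], state$s[j]] + 1
    }
  }
  I
}

brute_payoffs <- function(state, A) {
  N <- length(state$s)
  p <- numeric(N)
  for (k in seq_len(N)) for (j in seq_len(N)) {
    if (j != k && state$g[j] == state$g[k]) p[k] <- p[k] + A[state$s[k], state$s[j]]
  }
  p
}

tiny_params <- function(N = 3, M = 2, S = 3, u = 0.5, v = 0.5, r = 1,
                        process = "moran", delta = 0) {
  model_params(N = N, M = M, S = S, u = u, v = v, r = r, delta = delta,
               process = process)
}
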