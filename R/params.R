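#' Model parameters for the group-structured evolutionary process
#'
#' Bundles everything that defines the dynamics: a population of `N`
#' individuals spread over `M` groups on a circle, `S` available strategies,
#' per-offspring mutation probability `u` (global mutation: a mutant adopts
#' one of the `S` strategies uniformly, the parental one included),
#' per-offspring migration probability `v` with displacements drawn from an
#' isotropic `kernel`, selection intensity `delta` entering fitness as
#' `f = 1 + delta * payoff`, and the update rule (`"moran"` or
#' `"wright_fisher"`).
#'
#' @param N population size (`>= 2`).
#' @param M number of groups (`>= 1`).
#' @param S number of strategies (`>= 2`).
#' @param u mutation probability in `[0, 1]`.
#' @param v migration probability in `[0, 1]`.
#' @param kernel a [migration_kernel()] with `kernel$M == M`, or a numeric
#'   weight vector. May be omitted when `r` is given or when `v == 0`
#'   (migration never fires, a self-circle kernel is installed).
#' @param r shortcut: build the kernel with [range_kernel()]`(M, r)`.
#' @param delta selection intensity, `>= 0`.
#' @param process update rule: `"moran"` (one fitness-proportional birth,
#'   one uniform death per step) or `"wright_fisher"` (the whole population
#'   replaced by `N` fitness-proportional offspring each generation).
#' @return An object of class `model_params`.
#' @examples
#' model_params(N = 100, M = 7, S = 3, u = 0.05, v = 0.1, r = 1)
#' @export
model_params <- function(N, M, S, u, v, kernel = NULL, r = NULL, delta = 0,
                         process = c("moran", "wright_fisher")) {
  N <- check_count(N, "N", min = 2L)
  M <- check_count(M, "M", min = 1L)
  S <- check_count(S, "S", min = 2L)
  process <- match.arg(process)
  for (nm in c("u", "v")) {
    val <- get(nm)
    if (length(val) != 1L || !is.finite(val) || val < 0 || val > 1) {
      stop("`", nm, "` must be a single probability in [0, 1]", call. = FALSE)
    }
  }
  if (length(delta) != 1L || !is.finite(delta) || delta < 0) {
    stop("`delta` must be a single number >= 0", call. = FALSE)
  }
  if (is.null(kernel)) {
    if (!is.null(r)) {
      kernel <- range_kernel(M, r)
    } else if (v == 0) {
      kernel <- migration_kernel(M, c(1, numeric(M - 1L)))
    } else {
      stop("supply a migration `kernel` or a range `r` when v > 0", call. = FALSE)
    }
  } else {
    kernel <- as_migration_kernel(kernel)
  }
  if (kernel$M != M) {
    stop("kernel is defined on a circle of ", kernel$M, " groups but M = ", M,
         call. = FALSE)
  }
  structure(list(N = N, M = M, S = S, u = u, v = v, kernel = kernel,
                 delta = delta, process = process),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s process: N = %d, M = %d, S = %d, u = %g, v = %g, delta = %g\n",
              x$process, x$N, x$M, x$S, x$u, x$v, x$delta))
  invisible(x)
}

#' Population state
#'
#' The simulated object: per-individual strategy labels `s` (in `1..S`) and
#' group labels `g` (in `1..M`). Group sizes are unconstrained — groups grow
#' and shrink as offspring migrate — and always sum to `N`.
#'
#' @param s integer vector of strategy labels.
#' @param g integer vector of group labels, same length as `s`.
#' @param S,M optional upper bounds used for validation; default to the
#'   observed maxima.
#' @return An object of class `population_state` (list with `s`, `g`).
#' @export
population_state <- function(s, g, S = max(s), M = max(g)) {
  if (length(s) != length(g)) {
    stop("`s` and `g` must have the same length (one entry per individual)",
         call. = FALSE)
  }
  if (length(s) < 1L) stop("empty population", call. = FALSE)
  s <- as.integer(s); g <- as.integer(g)
  if (anyNA(s) || anyNA(g)) stop("labels must not be NA", call. = FALSE)
  if (any(s < 1L) || any(s > S)) stop("strategy labels out of 1..S", call. = FALSE)
  if (any(g < 1L) || any(g > M)) stop("group labels out of 1..M", call. = FALSE)
  structure(list(s = s, g = g), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  N <- length(x$s)
  cat("<population_state> N =", N, "\n")
  cat("  strategies:", paste(utils::head(x$s, 20), collapse = " "),
      if (N > 20) "...\n" else "\n")
  cat("  groups:    ", paste(utils::head(x$g, 20), collapse = " "),
      if (N > 20) "...\n" else "\n")
  invisible(x)
}

#' Random population state fixture
#'
#' Strategies and groups drawn i.i.d. uniform; always a valid state.
#'
#' @param N,M,S dimensions.
#' @param seed RNG seed for reproducibility.
#' @return A [population_state()].
#' @export
fixture_random_state <- function(N, M, S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  population_state(sample.int(S, N, replace = TRUE),
                   sample.int(M, N, replace = TRUE), S = S, M = M)
}

#' Payoff specification
#'
#' An `S x S` payoff matrix `A` (`A[i, j]` is the payoff of an `i`-player
#' against a `j`-player) together with the selection intensity `delta`.
#'
#' @param A square numeric matrix with finite entries.
#' @param delta selection intensity, `>= 0`.
#' @return An object of class `payoff_spec`.
#' @export
payoff_spec <- function(A, delta = 0) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || any(!is.finite(A))) {
    stop("`A` must be a square matrix of finite payoffs", call. = FALSE)
  }
  if (length(delta) != 1L || !is.finite(delta) || delta < 0) {
    stop("`delta` must be a single number >= 0", call. = FALSE)
  }
  structure(list(A = A, delta = delta), class = "payoff_spec")
}

#' Read a payoff matrix from CSV or JSON
#'
#' CSV: `S` rows by `S` columns of numbers, no header required. JSON: a
#' nested array `[[...], ...]`.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @param delta selection intensity attached to the returned spec.
#' @return A [payoff_spec()].
#' @export
read_payoff_matrix <- function(path, delta = 0) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    A <- jsonlite::fromJSON(path)
    if (is.list(A)) A <- do.call(rbind, A)
  } else {
    first <- utils::read.csv(path, header = FALSE, nrows = 1)
    header <- !all(vapply(first, is.numeric, logical(1)))
    A <- as.matrix(utils::read.csv(path, header = header))
  }
  storage.mode(A) <- "double"
  dimnames(A) <- NULL
  payoff_spec(A, delta = delta)
}
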