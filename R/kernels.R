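#' Isotropic migration kernels on a circle of groups
#'
#' A migration kernel is the distribution `f(x)` of the displacement
#' `x in {0, 1, ..., M - 1}` (a residue modulo `M`) that a migrating
#' offspring adds to its parent's group label. Isotropy (vertex
#' transitivity of the migration graph) requires `f(x) = f(M - x)`;
#' `f(0) > 0` is allowed (a "self-circle").
#'
#' @param M number of groups arranged on the circle.
#' @param f numeric vector of length `M`; `f[x + 1]` is the probability of
#'   displacement `x`.
#' @return An object of class `migration_kernel`: a list with elements `M`
#'   and `f`.
#' @seealso [range_kernel()] for the one-parameter family used throughout,
#'   [fixture_random_kernel()] for randomly generated test kernels.
#' @examples
#' migration_kernel(5, c(1, 0, 0, 0, 0))   # self-circle: migrants stay put
#' migration_kernel(4, c(0, 1/4, 1/2, 1/4))
#' @export
migration_kernel <- function(M, f) {
  M <- check_count(M, "M", min = 1L)
  if (length(f) != M) {
    stop("`f` must have length M = ", M, " (one weight per displacement 0..M-1), got ",
         length(f), call. = FALSE)
  }
  f <- as.numeric(f)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("kernel check failed: displacement weights must be finite and non-negative",
         call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-12) {
    stop("kernel check failed: weights must sum to 1 (got ", format(sum(f), digits = 15),
         ")", call. = FALSE)
  }
  # isotropy: f(x) == f(M - x) for x = 1..M-1
  if (M > 1L) {
    x <- seq_len(M - 1L)
    if (any(abs(f[x + 1L] - f[M - x + 1L]) > 1e-12)) {
      bad <- x[which(abs(f[x + 1L] - f[M - x + 1L]) > 1e-12)[1L]]
      stop("kernel check failed: not isotropic, f(", bad, ") != f(", M - bad, ")",
           call. = FALSE)
    }
  }
  structure(list(M = M, f = f), class = "migration_kernel")
}

#' Range-r migration kernel
#'
#' The one-parameter kernel family in which a single migration step moves an
#' offspring by one of the signed displacements `{-r, ..., -1, +1, ..., +r}`,
#' all equally likely. `r = 1` is local (nearest-neighbour) migration;
#' `r = floor(M/2)` reaches every other group and, for odd `M`, is exactly
#' uniform over the `M - 1` other groups ("global" migration).
#'
#' When `M` is even and `r = M/2` the antipodal group is reached from both
#' directions and carries weight `1/r`; all other distances carry `1/(2r)`.
#'
#' @param M number of groups (`M >= 2`).
#' @param r migration range, an integer in `1..floor(M/2)`.
#' @return A [migration_kernel()].
#' @examples
#' range_kernel(7, 1)  # f(1) = f(6) = 1/2
#' range_kernel(7, 3)  # uniform over the 6 other groups
#' @export
range_kernel <- function(M, r) {
  M <- check_count(M, "M", min = 2L)
  r <- check_count(r, "r", min = 1L)
  if (r > M %/% 2L) {
    stop("migration range r must satisfy 1 <= r <= floor(M/2) = ", M %/% 2L,
         "; got r = ", r, call. = FALSE)
  }
  f <- numeric(M)
  for (d in seq_len(r)) {
    f[d %% M + 1L] <- f[d %% M + 1L] + 1 / (2 * r)
    f[(M - d) %% M + 1L] <- f[(M - d) %% M + 1L] + 1 / (2 * r)
  }
  migration_kernel(M, f)
}

#' Random isotropic kernel fixture
#'
#' Draws non-negative weights, symmetrises them across `x <-> M - x` and
#' normalises, yielding a valid isotropic kernel (possibly with a
#' self-circle). Intended for property-style tests.
#'
#' @param M circle size.
#' @param seed RNG seed (an integer), for reproducible fixtures.
#' @return A [migration_kernel()].
#' @export
fixture_random_kernel <- function(M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::runif(M)
  x <- seq_len(M - 1L)
  w[x + 1L] <- (w[x + 1L] + w[M - x + 1L]) / 2
  migration_kernel(M, w / sum(w))
}

#' Kernel eigenvalues (Fourier multipliers)
#'
#' The eigenvalues of the displacement distribution on the cyclic group
#' `Z_M`: `lambda_j = sum_x f(x) cos(2 pi j x / M)`. Isotropy makes them
#' real. Mode `j = 0` always has `lambda = 1`.
#'
#' @param kernel a [migration_kernel()].
#' @return Numeric vector of length `M` (modes `j = 0..M-1`).
#' @export
kernel_eigenvalues <- function(kernel) {
  kernel <- as_migration_kernel(kernel)
  M <- kernel$M
  x <- 0:(M - 1L)
  vapply(0:(M - 1L), function(j) sum(kernel$f * cos(2 * pi * j * x / M)), numeric(1))
}

as_migration_kernel <- function(x) {
  if (inherits(x, "migration_kernel")) return(x)
  if (is.numeric(x)) return(migration_kernel(length(x), x))
  stop("expected a migration_kernel or a numeric weight vector", call. = FALSE)
}

#' @export
print.migration_kernel <- function(x, ...) {
  cat("<migration_kernel> M =", x$M, "\n")
  cat("  f(0..", x$M - 1L, ") = ", paste(signif(x$f, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a kernel as a two-column CSV
#'
#' Columns `displacement` (0..M-1) and `probability`. Round-trips exactly at
#' 15 significant digits.
#'
#' @param kernel a [migration_kernel()].
#' @param path file path.
#' @return `read_kernel_csv()` returns a [migration_kernel()];
#'   `write_kernel_csv()` returns `path` invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  kernel <- as_migration_kernel(kernel)
  df <- data.frame(displacement = 0:(kernel$M - 1L),
                   probability = kernel$f)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("displacement", "probability") %in% names(df))) {
    stop("kernel CSV needs columns `displacement` and `probability`", call. = FALSE)
  }
  df <- df[order(df$displacement), ]
  if (!identical(as.integer(df$displacement), 0:(nrow(df) - 1L))) {
    stop("kernel CSV must list every displacement 0..M-1 exactly once", call. = FALSE)
  }
  migration_kernel(nrow(df), df$probability)
}

# shared integer-argument validator
check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x)) {
    stop("`", name, "` must be a single integer", call. = FALSE)
  }
  x <- as.integer(x)
  if (x < min) stop("`", name, "` must be >= ", min, "; got ", x, call. = FALSE)
  x
}
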