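#' Sigma estimate container
#'
#' Holds a pair of structure coefficients with uncertainty and provenance.
#' Produced by [sigma_closed_form()] (`method = "closed_form"`),
#' [sigma_exact()] (`"exact"`), and [estimate_sigma_mc()] (`"mc"`).
#'
#' @param sigma1,sigma2 the coefficients.
#' @param se1,se2 standard errors (0 for exact and closed-form routes).
#' @param method one of `"mc"`, `"exact"`, `"closed_form"`.
#' @param params the [model_params()] the estimate refers to.
#' @param n_samples number of recorded states behind an MC estimate.
#' @param seed RNG seed behind an MC estimate.
#' @param unreliable flag set by the MC route when the accumulated
#'   denominator is too close to zero for the ratios to be trustworthy.
#' @param diagnostics optional list of extra quantities (batch means, sums).
#' @return Object of class `sigma_estimate`.
#' @export
sigma_estimate <- function(sigma1, sigma2, se1 = 0, se2 = 0,
                           method = c("closed_form", "exact", "mc"),
                           params = NULL, n_samples = NA_real_, seed = NA_integer_,
                           unreliable = FALSE, diagnostics = NULL) {
  method <- match.arg(method)
  ses <- c(se1, se2)
  if (any(!is.na(ses) & ses < 0)) stop("standard errors must be >= 0", call. = FALSE)
  structure(list(sigma1 = as.numeric(sigma1), sigma2 = as.numeric(sigma2),
                 se1 = as.numeric(se1), se2 = as.numeric(se2),
                 method = method, params = params, n_samples = n_samples,
                 seed = seed, unreliable = isTRUE(unreliable),
                 diagnostics = diagnostics),
            class = "sigma_estimate")
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf("<sigma_estimate> method = %s%s\n", x$method,
              if (x$unreliable) " [UNRELIABLE: denominator near zero]" else ""))
  if (!is.null(x$params)) {
    p <- x$params
    cat(sprintf("  %s, N = %d, M = %d, u = %g, v = %g\n",
                p$process, p$N, p$M, p$u, p$v))
  }
  fmt <- function(v, se) {
    if (se > 0) sprintf("%.6g (se %.2g)", v, se) else sprintf("%.10g", v)
  }
  cat("  sigma1 =", fmt(x$sigma1, x$se1), "\n")
  cat("  sigma2 =", fmt(x$sigma2, x$se2), "\n")
  if (is.finite(x$n_samples)) cat("  n_samples =", format(x$n_samples), "\n")
  invisible(x)
}

#' Tidy a sigma estimate
#'
#' @param x a [sigma_estimate()].
#' @param ... unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.sigma_estimate <- function(x, ...) {
  tibble::tibble(term = c("sigma1", "sigma2"),
                 estimate = c(x$sigma1, x$sigma2),
                 std.error = c(x$se1, x$se2))
}

#' Glance at a sigma estimate
#'
#' @param x a [sigma_estimate()].
#' @param ... unused.
#' @return A one-row tibble with the coefficients, their errors, the
#'   method, the model parameters and MC metadata.
#' @export
glance.sigma_estimate <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    process = if (is.null(p)) NA_character_ else p$process,
    N = if (is.null(p)) NA_integer_ else p$N,
    M = if (is.null(p)) NA_integer_ else p$M,
    u = if (is.null(p)) NA_real_ else p$u,
    v = if (is.null(p)) NA_real_ else p$v,
    method = x$method,
    sigma1 = x$sigma1, se1 = x$se1,
    sigma2 = x$sigma2, se2 = x$se2,
    n_samples = x$n_samples, seed = x$seed,
    unreliable = x$unreliable)
}

#' Serialise a sigma estimate as JSON
#'
#' Writes `{sigma1, sigma2, se1, se2, method, params, n_samples, seed}` with
#' full double precision, so independent runs can be compared exactly.
#'
#' @param x a [sigma_estimate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sigma_json <- function(x, path) {
  stopifnot(inherits(x, "sigma_estimate"))
  p <- x$params
  obj <- list(sigma1 = x$sigma1, sigma2 = x$sigma2, se1 = x$se1, se2 = x$se2,
              method = x$method,
              params = if (is.null(p)) NULL else
                list(N = p$N, M = p$M, S = p$S, u = p$u, v = p$v,
                     delta = p$delta, process = p$process,
                     kernel = p$kernel$f),
              n_samples = x$n_samples, seed = x$seed,
              unreliable = x$unreliable,
              package_version = as.character(utils::packageVersion("groupsigma")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
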