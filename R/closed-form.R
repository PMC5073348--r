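#' @name closed_form
#' @title Closed-form structure coefficients
#'
#' @description
#' The structure coefficients are defined through neutral (`delta = 0`)
#' stationary expectations of three state statistics built from the
#' strategy-1 frequency `x1` and the game-count matrix `I`:
#'
#' \deqn{\sigma_1 = \frac{E[x_1 I_{22} - x_1 I_{23}]}{E[x_1 I_{21} - x_1 I_{23}]},\qquad
#'       \sigma_2 = \frac{E[S\, x_1 I_{23}]}{E[x_1 I_{21} - x_1 I_{23}]}.}
#'
#' Here these expectations are evaluated in closed form for any `N`, `M`,
#' `u > 0`, `v` and isotropic kernel, by reducing them to the joint law of
#' the mutation pattern and the relative displacement of two or three
#' lineages traced backward through the neutral genealogy. Because parent
#' choice and death are payoff- and location-blind under neutrality, the
#' genealogy is independent of the mutation/migration marks, and every
#' needed probability diagonalises over the Fourier modes of the
#' displacement distribution on the circle `Z_M`. The result is an O(M)
#' formula — no state-space enumeration and no simulation — exact to
#' rounding error (it matches [sigma_exact()] to ~1e-14 on every enumerable
#' instance).
#'
#' The number of strategies `S` never enters: the three-lineage mutation
#' pattern probabilities are label-free, and the `S`-dependence of the
#' strategy-pattern probabilities cancels in both ratios.
#'
#' @details
#' Writing `m_j = 1 - v + v lambda_j` for the kernel's Fourier multiplier of
#' mode `j` and `w = 1 - u` for the per-birth mutation survival, the
#' building block is the pair factor
#' `H(m, w) = z / (N - (N-1) z)` with `z = w m` (Moran) or `z = (w m)^2`
#' (Wright-Fisher): the probability-generating value of "no mutation before
#' coalescence" jointly with the relative-displacement phase for two
#' lineages. Three-lineage pattern probabilities follow from a first-step
#' decomposition over which pair of lineages coalesces first (the
#' Wright-Fisher case includes the simultaneous triple merger), assembled
#' per mode and averaged over the `M` modes to impose co-residence of the
#' sampled pair.
NULL

# Fourier multipliers m_j = 1 - v + v * lambda_j of the migration step.
kernel_multipliers <- function(params) {
  1 - params$v + params$v * kernel_eigenvalues(params$kernel)
}

# Pair coalescence factor: E[phase * 1(no mutation on the two branches up to
# coalescence)] for two lineages at Fourier multiplier m, mutation survival w
# (w = 1 for the unconstrained, location-only version). Accepts complex u/w
# for complex-step limits.
pair_factor <- function(m, w, N, process) {
  z <- if (process == "moran") w * m else (w * m)^2
  z / (N - (N - 1) * z)
}

# Three-lineage "no mutation on the paths joining `pattern`" probabilities,
# jointly with the phase that tags co-residence of sampled individuals 2 and
# 3, at one Fourier mode. pattern: "none", "s23", "s12" (equivalently s13),
# "all". Derived by first-step analysis of the backward genealogy; the
# Moran case has single lineage moves, the Wright-Fisher case moves all
# lineages each generation and admits a triple merger.
triple_factor <- function(m, w, N, process, pattern) {
  hc  <- pair_factor(m, w, N, process)   # constrained, relative mode m
  hc0 <- pair_factor(1, w, N, process)   # constrained, mode 0
  hu  <- pair_factor(m, 1, N, process)   # unconstrained, relative mode m
  hu0 <- 1                               # unconstrained, mode 0: certain event
  if (process == "moran") {
    switch(pattern,
      none = (2 * hu + 2 * m * (hu + hu0)) /
             (3 * N - (N - 2) * (1 + 2 * m)),
      s23  = (2 * hc + 2 * w * m * (hc + hu0)) /
             (3 * N - (N - 2) * (1 + 2 * w * m)),
      s12  = (w * (hu + hc) + w * m * (hu + hc0) + m * (hc + hc0)) /
             (3 * N - (N - 2) * (w + w * m + m)),
      all  = (w * (2 * hc + 2 * m * (hc + hc0))) /
             (3 * N - (N - 2) * w * (1 + 2 * m)),
      stop("unknown pattern", call. = FALSE))
  } else {
    P <- switch(pattern,
      none = m^2,
      s23  = w^2 * m^2,
      s12  = w^2 * m^2,
      all  = w^3 * m^2)
    br <- switch(pattern,
      none = (N - 1) * (hu0 + 2 * hu) + 1,
      s23  = (N - 1) * (hu0 + 2 * hc) + 1,
      s12  = (N - 1) * (hu + hc + hc0) + 1,
      all  = (N - 1) * (hc0 + 2 * hc) + 1)
    P * br / (N^2 - (N - 1) * (N - 2) * P)
  }
}

# The four ingredients of both sigma ratios:
#   c23: P(2,3 identical by descent, 1 not; 2,3 co-resident)
#   c13: P(1,3 identical by descent, 2 not; 2,3 co-resident)
#   c0 : P(all three in distinct descent segments; 2,3 co-resident)
#   ypq: P(pair co-resident) - P(pair co-resident and identical by descent)
# for three (resp. two) individuals sampled without replacement from the
# neutral stationary population.
sigma_ingredients <- function(N, u, mm, process) {
  w <- 1 - u
  avg <- function(pattern) {
    mean(vapply(mm, function(m) triple_factor(m, w, N, process, pattern),
                if (is.complex(u)) complex(1) else numeric(1)))
  }
  p_none <- avg("none"); p_23 <- avg("s23"); p_12 <- avg("s12"); p_all <- avg("all")
  y2  <- mean(vapply(mm, function(m) pair_factor(m, 1, N, process),
                     if (is.complex(u)) complex(1) else numeric(1)))
  q2c <- mean(vapply(mm, function(m) pair_factor(m, w, N, process),
                     if (is.complex(u)) complex(1) else numeric(1)))
  list(c23 = p_23 - p_all,
       c13 = p_12 - p_all,
       c0  = p_none - 2 * p_12 - p_23 + 2 * p_all,
       ypq = y2 - q2c)
}

#' Closed-form sigma1 and sigma2
#'
#' Evaluates the closed-form structure coefficients for the process, sizes
#' and migration pattern in `params`. Valid for any `N >= 3`, `M >= 1`,
#' `u in (0, 1]`, `v in [0, 1]` and isotropic kernel; `delta` and the payoff
#' matrix never enter (the coefficients are neutral quantities), and no `S`
#' argument is used.
#'
#' @param params a [model_params()]. `params$u` must be positive: at
#'   `u = 0` there is no stationary mutation-selection balance and the
#'   coefficients are undefined.
#' @return A [sigma_estimate()] with `method = "closed_form"` and zero
#'   standard errors.
#' @seealso [sigma_exact()], [estimate_sigma_mc()], [sigma_limit_small_u()],
#'   [sigma_wellmixed()]
#' @examples
#' sigma_closed_form(model_params(N = 100, M = 7, S = 3, u = 0.05, v = 0.1, r = 1))
#' @export
sigma_closed_form <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$u <= 0) {
    stop("u = 0: no stationary mutation-selection balance; ",
         "the structure coefficients require u > 0 (see sigma_limit_small_u ",
         "for the u -> 0 limit)", call. = FALSE)
  }
  if (params$N < 3) stop("structure coefficients need N >= 3", call. = FALSE)
  N <- params$N
  mm <- if (params$v == 0) 1 else kernel_multipliers(params)
  ing <- sigma_ingredients(N, params$u, mm, params$process)
  D <- (N - 2) * ing$c13 + ing$ypq
  sigma_estimate(sigma1 = (N - 2) * ing$c23 / D,
                 sigma2 = (N - 2) * ing$c0 / D,
                 se1 = 0, se2 = 0, method = "closed_form", params = params)
}

#' @rdname sigma_closed_form
#' @export
sigma_closed_form_moran <- function(params) {
  params$process <- "moran"
  sigma_closed_form(params)
}

#' @rdname sigma_closed_form
#' @export
sigma_closed_form_wf <- function(params) {
  params$process <- "wright_fisher"
  sigma_closed_form(params)
}

#' Low-mutation limit of the structure coefficients
#'
#' As `u -> 0+` at most two strategies coexist, sigma2 vanishes, and sigma1
#' tends to a finite limit in which pairwise competition alone decides the
#' multi-strategy selection. All four ingredients of the sigma ratios vanish
#' linearly in `u`, so the limit is a ratio of derivatives at `u = 0`; it is
#' computed by complex-step differentiation (`Im F(ih)/h` with `h = 1e-80`),
#' which is exact to rounding error for these rational functions — no
#' cancellation, no truncation error.
#'
#' @param params a [model_params()]; its `u` is ignored.
#' @return A [sigma_estimate()] with `sigma2 = 0`.
#' @export
sigma_limit_small_u <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$N < 3) stop("structure coefficients need N >= 3", call. = FALSE)
  N <- params$N
  mm <- if (params$v == 0) 1 else kernel_multipliers(params)
  h <- 1e-80
  ing <- sigma_ingredients(N, complex(real = 0, imaginary = h), mm, params$process)
  d <- lapply(ing, function(z) Im(z) / h)     # derivatives at u = 0
  D <- (N - 2) * d$c13 + d$ypq
  sigma_estimate(sigma1 = (N - 2) * d$c23 / D, sigma2 = 0,
                 se1 = 0, se2 = 0, method = "closed_form", params = params)
}

#' Structure coefficients of the well-mixed population
#'
#' Without migration (`v = 0`) the population fixes in a single group and
#' evolves exactly like a well-mixed population of size `N`; the mode sum
#' collapses and the coefficients no longer depend on `M` or the kernel.
#' This helper evaluates that case directly.
#'
#' @param N population size.
#' @param u mutation probability (`> 0`).
#' @param process `"moran"` or `"wright_fisher"`.
#' @return A [sigma_estimate()].
#' @export
sigma_wellmixed <- function(N, u, process = c("moran", "wright_fisher")) {
  process <- match.arg(process)
  sigma_closed_form(model_params(N = N, M = 1, S = 3, u = u, v = 0,
                                 process = process))
}

#' Full-mutation limit
#'
#' At `u = 1` every offspring's strategy is an independent uniform draw:
#' strategies carry no ancestry, pairwise competition carries no weight
#' (`sigma1 = 0`), and only the equal-frequency term remains. Evaluates the
#' closed form at `u = 1` (which is regular there).
#'
#' @param params a [model_params()]; its `u` is ignored.
#' @return A [sigma_estimate()].
#' @export
sigma_limit_u1 <- function(params) {
  params$u <- 1
  sigma_closed_form(params)
}
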