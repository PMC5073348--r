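#' Parameter sweeps over the structure coefficients
#'
#' Evaluates sigma1 and sigma2 over the full grid of the supplied parameter
#' vectors, one row per combination, in deterministic grid order (the last
#' argument varies fastest, as in [tidyr::expand_grid()]). Failures on
#' individual rows are recorded in the `status` column and the sweep
#' continues.
#'
#' @param process character vector over `{"moran", "wright_fisher"}`.
#' @param N,M,S,u,v,r numeric vectors defining the grid (`r` is the
#'   migration range passed to [range_kernel()]; use `r = NA` together with
#'   `v = 0` for kernel-free rows).
#' @param method `"closed_form"`, `"exact"` or `"mc"`.
#' @param config [chain_config()] used for `method = "mc"`; row `i` runs
#'   with seed `config$seed + i` so rows are independent but reproducible.
#' @param symmetrize passed to [estimate_sigma_mc()].
#' @return A tibble of class `sigma_sweep` with columns `process`, `N`,
#'   `M`, `S`, `u`, `v`, `r`, `method`, `sigma1`, `se1`, `sigma2`, `se2`,
#'   `n_samples`, `seed`, `status`.
#' @examples
#' sweep_sigma(u = c(0.01, 0.1, 0.5), N = 100, M = 7, r = 1, v = 0.1)
#' @export
sweep_sigma <- function(process = "moran", N = 100, M = 7, S = 3,
                        u = 0.1, v = 0.1, r = 1,
                        method = c("closed_form", "exact", "mc"),
                        config = chain_config(seed = 1L), symmetrize = FALSE) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(process = process, N = N, M = M, S = S,
                             u = u, v = v, r = r)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    est <- tryCatch({
      kern <- if (!is.na(row$r)) range_kernel(row$M, row$r) else NULL
      params <- model_params(N = row$N, M = row$M, S = row$S, u = row$u,
                             v = row$v, kernel = kern, process = row$process)
      switch(method,
             closed_form = sigma_closed_form(params),
             exact = sigma_exact(params),
             mc = {
               cfg <- config
               cfg$seed <- if (is.null(config$seed)) i else config$seed + i
               estimate_sigma_mc(params, cfg, symmetrize = symmetrize)
             })
    }, error = function(e) e)
    if (inherits(est, "error")) {
      dplyr::bind_cols(row, tibble::tibble(
        method = method, sigma1 = NA_real_, se1 = NA_real_,
        sigma2 = NA_real_, se2 = NA_real_, n_samples = NA_real_,
        seed = NA_integer_, status = conditionMessage(est)))
    } else {
      dplyr::bind_cols(row, tibble::tibble(
        method = method, sigma1 = est$sigma1, se1 = est$se1,
        sigma2 = est$sigma2, se2 = est$se2,
        n_samples = est$n_samples, seed = est$seed,
        status = if (est$unreliable) "unreliable" else "ok"))
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sigma_sweep", class(out))
  out
}

#' Plot a sigma sweep
#'
#' Draws sigma1 and sigma2 against the swept parameter, one panel per
#' coefficient, coloured by process when several are present. MC rows get
#' 3-standard-error bars.
#'
#' @param object a [sweep_sigma()] result.
#' @param x name of the column to place on the x axis (default the first of
#'   `u`, `v`, `r`, `N`, `M` with more than one unique value).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sigma_sweep <- function(object, x = NULL, ...) {
  if (is.null(x)) {
    cand <- c("u", "v", "r", "N", "M")
    nuniq <- vapply(cand, function(cc) length(unique(object[[cc]])), integer(1))
    x <- if (any(nuniq > 1L)) cand[which(nuniq > 1L)[1L]] else "u"
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  lo1 = .data$sigma1 - 3 * .data$se1, hi1 = .data$sigma1 + 3 * .data$se1,
                  lo2 = .data$sigma2 - 3 * .data$se2, hi2 = .data$sigma2 + 3 * .data$se2),
    cols = c("sigma1", "sigma2"), names_to = "coefficient", values_to = "value")
  long$lo <- ifelse(long$coefficient == "sigma1", long$lo1, long$lo2)
  long$hi <- ifelse(long$coefficient == "sigma1", long$hi1, long$hi2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$value,
                                     colour = .data$process)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::labs(y = "structure coefficient")
}

#' Sweep of critical cost-to-benefit ratios
#'
#' Convenience driver for the direct-reciprocity application: computes
#' closed-form sigma coefficients over a grid and attaches `(c/b)*` for
#' each combination and repetition round.
#'
#' @inheritParams sweep_sigma
#' @param m vector of repetition rounds.
#' @return A tibble with the sweep columns plus `m` and `cb_star`.
#' @export
sweep_reciprocity <- function(process = "moran", N = 100, M = 7, u = 0.1,
                              v = 0.1, r = 1, m = 10) {
  base <- sweep_sigma(process = process, N = N, M = M, S = 3, u = u, v = v,
                      r = r, method = "closed_form")
  grid <- tidyr::expand_grid(base, m = m)
  grid$cb_star <- purrr::pmap_dbl(
    list(grid$sigma1, grid$sigma2, grid$m),
    function(s1, s2, mm) {
      if (is.na(s1)) return(NA_real_)
      critical_cost_benefit(s1, s2, mm)
    })
  grid
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
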