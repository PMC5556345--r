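# broom-style accessors for fitted objects.

#' Tidy a Rasch calibration
#'
#' One row per item threshold, with the item location repeated.
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return Tibble: `item`, `location`, `threshold_index`, `threshold`.
#' @export
tidy.rasch_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$calibration)), function(i) {
    tau <- x$calibration$thresholds[[i]]
    tibble(item = x$calibration$item[i],
           location = x$calibration$location[i],
           threshold_index = seq_along(tau),
           threshold = tau)
  })
}

#' One-row model summary of a Rasch calibration
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return Tibble: `n_persons`, `n_items`, `logLik`, `iterations`,
#'   `converged`, `psi`, `prop_extreme`.
#' @export
glance.rasch_fit <- function(x, ...) {
  tibble(
    n_persons = nrow(x$persons),
    n_items = nrow(x$calibration),
    logLik = x$loglik,
    iterations = x$iterations,
    converged = x$converged,
    psi = person_separation_index(x),
    prop_extreme = mean(x$persons$extreme)
  )
}

#' Tidy a diagnostic report
#'
#' The per-item flag table joined with the underlying statistics.
#'
#' @param x A `vfq_report`.
#' @param ... Unused.
#' @return Tibble: one row per item with `location`, `fit_residual`,
#'   `chisq`, `chisq_p` and the flags `D_r`, `M_r`, `M_t`, `D_f`, `D_p`.
#' @export
tidy.vfq_report <- function(x, ...) {
  x$flags |>
    left_join(tibble(item = x$fit$calibration$item,
                     location = x$fit$calibration$location), by = "item") |>
    left_join(select(x$fit_residuals, "item", "fit_residual"), by = "item") |>
    left_join(select(x$chisq, "item", "chisq", "chisq_p"), by = "item") |>
    select("item", "location", "fit_residual", "chisq", "chisq_p",
           "D_r", "M_r", "M_t", "D_f", "D_p")
}

#' One-row summary of a diagnostic report
#'
#' @param x A `vfq_report`.
#' @param ... Unused.
#' @return Tibble: `instrument`, `n_items`, `psi`, counts of each flag type,
#'   `prop_ceiling`, `prop_above_coverage`.
#' @export
glance.vfq_report <- function(x, ...) {
  tibble(
    instrument = x$instrument,
    n_items = nrow(x$flags),
    psi = x$psi,
    n_disordered = sum(x$flags$D_r, na.rm = TRUE),
    n_misfit_residual = sum(x$flags$M_r, na.rm = TRUE),
    n_misfit_chisq = sum(x$flags$M_t, na.rm = TRUE),
    n_dif = if (all(is.na(x$flags$D_f))) NA_integer_
            else sum(x$flags$D_f, na.rm = TRUE),
    n_dependent = sum(x$flags$D_p, na.rm = TRUE),
    prop_ceiling = x$targeting$prop_ceiling,
    prop_above_coverage = x$targeting$prop_above_highest_threshold
  )
}
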