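# Partial credit model primitives: category probabilities, expected scores,
# exact conditional moments, information. All quantities are computed by
# enumeration over the finite category set, in the log domain.

#' Partial credit model category probabilities
#'
#' For a polytomous item with thresholds `tau` (tau_1..tau_m, the crossover
#' points between adjacent categories) and person location `theta`, the
#' probability of scoring x in 0..m is
#' `P(X = x) = exp(sum_{k<=x}(theta - tau_k)) / sum_j exp(sum_{k<=j}(theta - tau_k))`
#' with the empty sum equal to 0. Accumulation uses log-sum-exp so the
#' computation is stable for |theta| up to several hundred logits.
#'
#' @param theta Numeric vector of person locations (logits).
#' @param tau Numeric vector of item thresholds (logits), length m >= 1.
#' @return A `length(theta)` x `(m + 1)` matrix; rows sum to 1. Columns are
#'   categories 0..m.
#' @examples
#' pcm_prob(0, c(-1, 1)) # middle category most likely
#' @export
pcm_prob <- function(theta, tau) {
  if (any(!is.finite(theta))) abort("'theta' must be finite.")
  if (any(!is.finite(tau))) abort("Item thresholds must be finite.")
  m <- length(tau)
  cum_tau <- c(0, cumsum(tau))          # T_x = sum_{k<=x} tau_k
  # log numerator for category x: x*theta - T_x
  lnum <- outer(theta, 0:m) - matrix(cum_tau, length(theta), m + 1, byrow = TRUE)
  lmax <- lnum[cbind(seq_along(theta), max.col(lnum, ties.method = "first"))]
  w <- exp(lnum - lmax)
  w / rowSums(w)
}

# lean expected score + variance (the estimation hot path)
pcm_ev <- function(theta, tau) {
  p <- pcm_prob(theta, tau)
  x <- 0:length(tau)
  e <- drop(p %*% x)
  list(e = e, v = drop(p %*% x^2) - e^2)
}

#' Expected item score under the PCM
#'
#' @inheritParams pcm_prob
#' @return Numeric vector `E[X | theta]`, strictly increasing in `theta`,
#'   with range (0, m).
#' @export
pcm_expected <- function(theta, tau) {
  p <- pcm_prob(theta, tau)
  drop(p %*% (0:length(tau)))
}

#' Exact conditional moments of the item score
#'
#' Central moments of X given theta, computed by enumeration over the
#' category set. These feed the standardized residuals and the exact
#' moments of the fit-residual statistic.
#'
#' @inheritParams pcm_prob
#' @return A tibble with one row per theta: `expected`, `variance`, `mu3`
#'   (third central moment), `mu4` (fourth central moment).
#' @export
pcm_moments <- function(theta, tau) {
  p <- pcm_prob(theta, tau)
  x <- 0:length(tau)
  e <- drop(p %*% x)
  d1 <- outer(e, x, function(a, b) b - a)
  tibble(
    expected = e,
    variance = rowSums(p * d1^2),
    mu3 = rowSums(p * d1^3),
    mu4 = rowSums(p * d1^4)
  )
}

#' Expected-score curve (item characteristic curve) samples
#'
#' @param tau Item thresholds (logits).
#' @param theta_grid Numeric grid of person locations.
#' @return Tibble: `theta`, `expected`.
#' @export
pcm_icc <- function(tau, theta_grid) {
  tibble(theta = theta_grid, expected = pcm_expected(theta_grid, tau))
}

# Fisher information for theta contributed by one item: Var(X | theta).
pcm_information <- function(theta, tau) {
  pcm_moments(theta, tau)$variance
}

#' Item calibration table
#'
#' Constructs/validates the calibration container used across the package:
#' one row per item with its threshold vector and derived location
#' (the arithmetic mean of the thresholds).
#'
#' @param item Character vector of item codes.
#' @param thresholds List of numeric threshold vectors (logits).
#' @return A tibble of class `vfq_calibration`: `item`, `thresholds`
#'   (list-column), `location`, `max_score`.
#' @export
pcm_calibration <- function(item, thresholds) {
  stopifnot(length(item) == length(thresholds))
  if (anyDuplicated(item)) abort("Calibration item codes must be unique.")
  purrr::walk2(item, thresholds, function(code, tau) {
    if (length(tau) < 1 || any(!is.finite(tau))) {
      abort(paste0("Item ", code, ": thresholds must be a finite vector of length >= 1."))
    }
  })
  out <- tibble(
    item = as.character(item),
    thresholds = purrr::map(thresholds, as.numeric),
    location = vapply(thresholds, mean, numeric(1)),
    max_score = vapply(thresholds, length, integer(1))
  )
  class(out) <- c("vfq_calibration", class(out))
  out
}

#' Read / write a calibration JSON file
#'
#' The interchange format is a JSON list of `{item_code, thresholds[]}` with
#' logits written to 6 decimal places.
#'
#' @param calibration A `vfq_calibration` tibble.
#' @param path File path.
#' @return `read_calibration_json()` returns a `vfq_calibration`.
#' @export
write_calibration_json <- function(calibration, path) {
  payload <- purrr::map2(calibration$item, calibration$thresholds,
                         function(code, tau) {
                           list(item_code = code, thresholds = round(tau, 6))
                         })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pcm_calibration(
    item = vapply(raw, function(x) as.character(x$item_code), character(1)),
    thresholds = purrr::map(raw, function(x) as.numeric(unlist(x$thresholds)))
  )
}
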