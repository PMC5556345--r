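# Joint maximum-likelihood calibration of the partial credit model and
# person-location estimation. Estimation alternates damped Newton-Raphson
# steps over item thresholds and person locations; persons with minimum or
# maximum possible raw scores are excluded from item calibration and
# assigned extrapolated locations afterwards via a raw-score adjustment.

#' Estimation settings
#'
#' @param max_iterations Maximum outer (item/person alternation) iterations.
#' @param tolerance Convergence tolerance on the largest absolute parameter
#'   change between outer iterations, in logits.
#' @param extreme_adjustment Score-unit adjustment applied to minimum/maximum
#'   raw scores so extreme persons receive finite locations; must lie in
#'   (0, 0.5].
#' @param bias_correction Apply the classical joint-ML test-length correction
#'   (L-1)/L to the centred thresholds, L = number of items.
#' @param centering Identifiability constraint; `"items"` centres item
#'   locations at 0.
#' @return A list of settings for [rasch_calibrate()].
#' @export
rasch_control <- function(max_iterations = 100, tolerance = 1e-5,
                          extreme_adjustment = 0.3, bias_correction = TRUE,
                          centering = "items") {
  stopifnot(tolerance > 0, extreme_adjustment > 0, extreme_adjustment <= 0.5,
            identical(centering, "items"))
  list(max_iterations = as.integer(max_iterations), tolerance = tolerance,
       extreme_adjustment = extreme_adjustment,
       bias_correction = isTRUE(bias_correction), centering = centering)
}

# scores tibble (person_id + 0-based integer item columns) -> internal list
scores_to_matrix <- function(data) {
  stopifnot(is.data.frame(data), "person_id" %in% names(data))
  codes <- setdiff(names(data), "person_id")
  if (length(codes) < 1) abort("Score data contains no item columns.")
  X <- as.matrix(as.data.frame(lapply(data[codes], as.numeric)))
  colnames(X) <- codes
  if (any(X < 0, na.rm = TRUE) || any(X != round(X), na.rm = TRUE)) {
    abort("Item scores must be non-negative integers (0-based categories).")
  }
  list(X = X, person_id = data$person_id, codes = codes)
}

# Vectorized person-location Newton solve: finds theta with
# sum_i E[X_i | theta] = target for each person, given fixed thresholds.
solve_theta <- function(X, tau_list, target, theta = NULL,
                        max_iter = 200, tol = 1e-10) {
  n <- nrow(X)
  if (is.null(theta)) theta <- rep(0, n)
  active <- rep(TRUE, n)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    sumE <- numeric(n); sumV <- numeric(n)
    for (i in seq_along(tau_list)) {
      obs <- which(active & !is.na(X[, i]))
      if (!length(obs)) next
      ev <- pcm_ev(theta[obs], tau_list[[i]])
      sumE[obs] <- sumE[obs] + ev$e
      sumV[obs] <- sumV[obs] + ev$v
    }
    idx <- which(active)
    step <- (target[idx] - sumE[idx]) / pmax(sumV[idx], 1e-10)
    step <- pmax(pmin(step, 1), -1)
    theta[idx] <- theta[idx] + step
    active[idx] <- abs(step) > tol
  }
  theta
}

# One damped Newton step on the thresholds of a single item.
item_newton_step <- function(x, theta, tau) {
  m <- length(tau)
  p <- pcm_prob(theta, tau)
  # P(X >= k), k = 1..m
  pge <- matrix(0, nrow(p), m)
  acc <- rep(0, nrow(p))
  for (k in m:1) {
    acc <- acc + p[, k + 1]
    pge[, k] <- acc
  }
  grad <- colSums(pge) - vapply(1:m, function(k) sum(x >= k), numeric(1))
  H <- matrix(0, m, m)
  for (k in 1:m) for (l in k:m) {
    v <- -sum(pge[, max(k, l)] - pge[, k] * pge[, l])
    H[k, l] <- v; H[l, k] <- v
  }
  step <- tryCatch(solve(H, grad),
                   error = function(e) solve(H - diag(1e-6, m), grad))
  step <- pmax(pmin(step, 1), -1)
  tau - step
}

#' Calibrate item thresholds and person locations jointly
#'
#' Fits the unrestricted polytomous Rasch model (partial credit
#' parameterization) by joint maximum likelihood: alternating damped
#' Newton-Raphson over item thresholds and person locations, with missing
#' responses dropped from the likelihood, item locations centred at zero,
#' and the (L-1)/L test-length bias correction applied to the centred
#' thresholds. Persons at the minimum or maximum possible raw score carry no
#' information about item parameters; they are excluded from calibration and
#' given extrapolated locations via the extreme-score adjustment.
#' Threshold estimates are deliberately not constrained to be ordered:
#' threshold disorder is a diagnostic finding, not an estimation error.
#'
#' @param data Score tibble: `person_id` plus one 0-based integer score
#'   column per item (see [vfq_scores()]).
#' @param max_score Optional named integer vector giving each item's maximum
#'   score m; defaults to the maximum observed score per item.
#' @param control Settings from [rasch_control()].
#' @return An object of class `rasch_fit`: list with `calibration`
#'   (a [pcm_calibration()] tibble), `persons` (tibble: `person_id`, `theta`,
#'   `se`, `raw_score`, `max_raw`, `n_answered`, `extreme`), `loglik`,
#'   `iterations`, `converged`, `control`, and the input `scores`.
#' @examples
#' sim <- simulate_responses(sim_config(
#'   n_persons = 150, bank = sim_bank(6, max_score = 2), seed = 42))
#' fit <- rasch_calibrate(sim$responses)
#' glance(fit)
#' @export
rasch_calibrate <- function(data, max_score = NULL, control = rasch_control()) {
  sm <- scores_to_matrix(data)
  X <- sm$X
  codes <- sm$codes
  if (length(codes) < 2) abort("Calibration requires at least 2 items.")
  m <- if (is.null(max_score)) {
    apply(X, 2, max, na.rm = TRUE)
  } else {
    as.numeric(max_score[codes])
  }
  if (any(is.na(m)) || any(m < 1)) {
    abort("Every item needs a positive maximum score (m >= 1).")
  }
  # null-category check: every score level 0..m must be observed
  for (i in seq_along(codes)) {
    seen <- unique(X[!is.na(X[, i]), i])
    null_cat <- setdiff(0:m[i], seen)
    if (length(null_cat)) {
      abort(paste0("Item ", codes[i], " has null (never observed) categor",
                   if (length(null_cat) > 1) "ies " else "y ",
                   paste(null_cat, collapse = ", "),
                   "; its thresholds are inestimable. Collapse levels or drop ",
                   "the item."))
    }
  }
  n_answered <- rowSums(!is.na(X))
  raw <- rowSums(X, na.rm = TRUE)
  max_raw <- as.numeric((!is.na(X)) %*% m)
  extreme <- n_answered > 0 & (raw == 0 | raw == max_raw)
  core <- which(n_answered > 0 & !extreme)
  if (length(unique(raw[core])) < 2) {
    abort("Calibration requires at least 2 distinct non-extreme raw scores.")
  }
  Xc <- X[core, , drop = FALSE]
  raw_c <- raw[core]
  max_c <- max_raw[core]

  tau <- purrr::map(seq_along(codes), function(i) rep(0, m[i]))
  theta <- qlogis((raw_c + 0.5) / (max_c + 1))
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(control$max_iterations)) {
    iterations <- iter
    theta_new <- solve_theta(Xc, tau, raw_c, theta)
    tau_new <- purrr::map(seq_along(codes), function(i) {
      obs <- which(!is.na(Xc[, i]))
      item_newton_step(Xc[obs, i], theta_new[obs], tau[[i]])
    })
    shift <- mean(vapply(tau_new, mean, numeric(1)))
    tau_new <- purrr::map(tau_new, function(t) t - shift)
    theta_new <- theta_new - shift
    delta <- max(abs(theta_new - theta),
                 max(abs(unlist(tau_new) - unlist(tau))))
    theta <- theta_new
    tau <- tau_new
    if (delta < control$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("Calibration did not converge in ", iterations,
                " iterations (tolerance ", control$tolerance, ")."))
  }
  if (control$bias_correction) {
    L <- length(codes)
    tau <- purrr::map(tau, function(t) t * (L - 1) / L)
  }
  calibration <- pcm_calibration(codes, tau)
  persons <- person_estimates(X, sm$person_id, calibration,
                              control$extreme_adjustment)
  loglik <- pcm_loglik(X, persons$theta, tau)
  structure(
    list(calibration = calibration, persons = persons, loglik = loglik,
         iterations = iterations, converged = converged, control = control,
         scores = as_tibble(data)),
    class = "rasch_fit"
  )
}

pcm_loglik <- function(X, theta, tau_list) {
  ll <- 0
  for (i in seq_along(tau_list)) {
    obs <- which(!is.na(X[, i]) & !is.na(theta))
    if (!length(obs)) next
    p <- pcm_prob(theta[obs], tau_list[[i]])
    ll <- ll + sum(log(p[cbind(seq_along(obs), X[obs, i] + 1)]))
  }
  ll
}

person_estimates <- function(X, person_id, calibration, adjustment) {
  tau_list <- calibration$thresholds
  m <- calibration$max_score
  n_answered <- rowSums(!is.na(X))
  raw <- rowSums(X, na.rm = TRUE)
  max_raw <- as.numeric((!is.na(X)) %*% m)
  extreme <- n_answered > 0 & (raw == 0 | raw == max_raw)
  target <- raw
  target[extreme & raw == 0] <- adjustment
  target[extreme & raw == max_raw] <- max_raw[extreme & raw == max_raw] - adjustment
  theta <- rep(NA_real_, nrow(X))
  est <- which(n_answered > 0)
  if (length(est)) {
    theta[est] <- solve_theta(X[est, , drop = FALSE], tau_list, target[est])
  }
  se <- rep(NA_real_, nrow(X))
  info <- numeric(nrow(X))
  for (i in seq_along(tau_list)) {
    obs <- which(!is.na(X[, i]) & !is.na(theta))
    if (!length(obs)) next
    info[obs] <- info[obs] + pcm_information(theta[obs], tau_list[[i]])
  }
  se[est] <- 1 / sqrt(info[est])
  tibble(person_id = person_id, theta = theta, se = se,
         raw_score = raw, max_raw = max_raw,
         n_answered = as.integer(n_answered), extreme = extreme)
}

#' Estimate person locations against a fixed (anchored) calibration
#'
#' Per-person maximum likelihood: theta solves the score equation
#' `sum_i (x_i - E[X_i | theta]) = 0` over the person's answered items.
#' Extreme raw scores are first moved `adjustment` score units inside the
#' observable range; the standard error is the inverse square root of the
#' test information at the estimate. Persons with no answered items get a
#' missing estimate.
#'
#' @param data Score tibble (`person_id` + 0-based item score columns).
#' @param calibration A `vfq_calibration` tibble (anchored thresholds).
#' @param adjustment Extreme-score adjustment in score units, in (0, 0.5].
#' @return Tibble: `person_id`, `theta`, `se`, `raw_score`, `max_raw`,
#'   `n_answered`, `extreme`.
#' @export
estimate_persons <- function(data, calibration, adjustment = 0.3) {
  stopifnot(adjustment > 0, adjustment <= 0.5)
  sm <- scores_to_matrix(data)
  present <- intersect(calibration$item, sm$codes)
  if (!length(present)) abort("No calibrated items found in the score data.")
  cal <- calibration[match(present, calibration$item), ]
  X <- sm$X[, present, drop = FALSE]
  observed_max <- apply(X, 2, function(v) {
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)  # all-NA column: nothing to check
  })
  over <- which(observed_max > cal$max_score)
  if (length(over)) {
    abort(paste0("Observed score exceeds the calibrated maximum for item(s): ",
                 paste(present[over], collapse = ", ")))
  }
  out <- person_estimates(X, sm$person_id, cal, adjustment)
  if (any(out$n_answered == 0)) {
    warn(paste0(sum(out$n_answered == 0),
                " person(s) answered no items; estimates set to missing."))
  }
  out
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("<rasch_fit> ", nrow(x$calibration), " items, ",
      nrow(x$persons), " persons; logLik ", format(x$loglik, digits = 6),
      "; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}
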