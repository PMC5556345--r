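# The six Rasch Measurement Theory evaluation areas: scale-to-sample
# targeting, threshold ordering, item fit (fit residuals + item-trait
# chi-square), stability (DIF), local dependence, and reliability (PSI).

#' Threshold ordering check
#'
#' An item's thresholds should increase with category order; a threshold
#' estimated below its predecessor ("disordered") signals a problem with the
#' number or type of response options.
#'
#' @param calibration A `vfq_calibration` tibble (or a `rasch_fit`).
#' @return Tibble: `item`, `disordered`, `disordered_pairs` (list-column of
#'   adjacent threshold indices k with tau_{k+1} < tau_k). Dichotomous items
#'   are always ordered.
#' @export
threshold_ordering <- function(calibration) {
  cal <- as_calibration(calibration)
  purrr::map_dfr(seq_len(nrow(cal)), function(i) {
    tau <- cal$thresholds[[i]]
    bad <- if (length(tau) < 2) integer(0) else which(diff(tau) < 0)
    tibble(item = cal$item[i], disordered = length(bad) > 0,
           disordered_pairs = list(bad))
  })
}

as_calibration <- function(x) {
  if (inherits(x, "rasch_fit")) x$calibration
  else if (inherits(x, "vfq_calibration")) x
  else abort("Expected a 'vfq_calibration' or 'rasch_fit' object.")
}

#' Standardized response residuals
#'
#' `z_ni = (x_ni - E[x_ni]) / sd(x_ni)` with the conditional mean and
#' variance evaluated at the person's estimated location. Extreme persons
#' (minimum/maximum raw score) carry no residual information and their rows
#' are returned as missing.
#'
#' @param fit A `rasch_fit` object.
#' @return Numeric matrix (persons x items) of standardized residuals, with
#'   `NA` for missing cells and extreme persons. Row order matches
#'   `fit$persons`.
#' @export
standardized_residuals <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  sm <- scores_to_matrix(fit$scores)
  X <- sm$X[, fit$calibration$item, drop = FALSE]
  theta <- fit$persons$theta
  usable <- !fit$persons$extreme & !is.na(theta)
  Z <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(ncol(X))) {
    obs <- which(usable & !is.na(X[, i]))
    if (!length(obs)) next
    mom <- pcm_moments(theta[obs], fit$calibration$thresholds[[i]])
    Z[obs, i] <- (X[obs, i] - mom$expected) / sqrt(mom$variance)
  }
  Z
}

#' Item fit residuals
#'
#' Sums each item's squared standardized residuals, standardizes the sum by
#' its exact model moments (second and fourth conditional moments computed by
#' category enumeration per cell), and applies a cube-root symmetrizing
#' transform. Values outside \[-2.5, +2.5\] flag misfit: positive values mean
#' noisier-than-model responses (underfit), negative values more
#' deterministic than the model allows (overfit, e.g. a locally dependent
#' item).
#'
#' @param fit A `rasch_fit`.
#' @param bounds Acceptable fit-residual band.
#' @param min_n Minimum usable responses per item; below it the statistic is
#'   returned missing with a warning.
#' @return Tibble: `item`, `fit_residual`, `n`, `misfit_residual_flag`.
#' @export
item_fit_residuals <- function(fit, bounds = c(-2.5, 2.5), min_n = 30) {
  Z <- standardized_residuals(fit)
  sm <- scores_to_matrix(fit$scores)
  X <- sm$X[, fit$calibration$item, drop = FALSE]
  theta <- fit$persons$theta
  usable <- !fit$persons$extreme & !is.na(theta)
  out <- purrr::map_dfr(seq_len(ncol(X)), function(i) {
    obs <- which(usable & !is.na(X[, i]))
    n_i <- length(obs)
    if (n_i < min_n) {
      return(tibble(item = colnames(X)[i], fit_residual = NA_real_,
                    n = n_i, misfit_residual_flag = NA))
    }
    mom <- pcm_moments(theta[obs], fit$calibration$thresholds[[i]])
    y <- sum(Z[obs, i]^2)
    mu <- n_i                                   # E[z^2] = 1 per cell, exactly
    sig2 <- sum(mom$mu4 / mom$variance^2 - 1)   # Var[z^2] per cell
    fr <- (y^(1 / 3) - mu^(1 / 3) * (1 - sig2 / (9 * mu^2))) /
      (mu^(1 / 3) * sqrt(sig2) / (3 * mu))
    tibble(item = colnames(X)[i], fit_residual = fr, n = n_i,
           misfit_residual_flag = fr < bounds[1] | fr > bounds[2])
  })
  if (anyNA(out$fit_residual)) {
    warn(paste0("Fit residual not computed (fewer than ", min_n,
                " usable responses) for item(s): ",
                paste(out$item[is.na(out$fit_residual)], collapse = ", ")))
  }
  out
}

#' Ability class intervals
#'
#' Splits non-extreme persons into class intervals by estimated location,
#' targeting `n_intervals` quantile groups and merging intervals from the
#' top down until each holds at least `min_size` persons.
#'
#' @param fit A `rasch_fit`.
#' @param n_intervals Target number of intervals.
#' @param min_size Minimum persons per interval.
#' @return An integer factor of length `nrow(fit$persons)` (NA for extreme or
#'   unestimated persons); levels are ordered by location.
#' @export
class_intervals <- function(fit, n_intervals = 10, min_size = 25) {
  theta <- fit$persons$theta
  usable <- which(!fit$persons$extreme & !is.na(theta))
  th <- theta[usable]
  n_int <- max(1L, min(n_intervals, floor(length(th) / max(1, min_size))))
  repeat {
    br <- unique(quantile(th, probs = seq(0, 1, length.out = n_int + 1)))
    g <- cut(th, breaks = br, include.lowest = TRUE, labels = FALSE)
    sizes <- tabulate(g, nbins = max(g))
    if (all(sizes >= min_size) || max(g) == 1) break
    # merge the topmost undersized interval into its lower neighbour
    n_int <- max(g) - 1L
    if (n_int < 1L) break
  }
  out <- rep(NA_integer_, length(theta))
  out[usable] <- g
  factor(out, levels = sort(unique(g)))
}

#' Item-trait interaction chi-square
#'
#' Compares observed and model-expected item scores across ability class
#' intervals. Per interval the residual sum is standardized by its exact
#' conditional variance; the chi-square statistic is the sum of the squared
#' interval deviates, with degrees of freedom one less than the number of
#' contributing intervals. Items are flagged when significant after
#' Bonferroni adjustment across items.
#'
#' @inheritParams class_intervals
#' @param alpha Familywise significance level before Bonferroni division.
#' @return Tibble: `item`, `chisq`, `chisq_df`, `chisq_p`,
#'   `misfit_chisq_flag` (significant after Bonferroni).
#' @export
item_trait_chisq <- function(fit, n_intervals = 10, min_size = 25,
                             alpha = 0.05) {
  ci <- class_intervals(fit, n_intervals, min_size)
  if (nlevels(ci) < 2) {
    abort("Item-trait chi-square needs at least 2 class intervals (df >= 1).")
  }
  sm <- scores_to_matrix(fit$scores)
  X <- sm$X[, fit$calibration$item, drop = FALSE]
  theta <- fit$persons$theta
  n_items <- ncol(X)
  bonf <- alpha / n_items
  purrr::map_dfr(seq_len(n_items), function(i) {
    chisq <- 0; df <- -1L
    for (lev in levels(ci)) {
      idx <- which(!is.na(ci) & ci == lev & !is.na(X[, i]))
      if (length(idx) < 2) next
      mom <- pcm_moments(theta[idx], fit$calibration$thresholds[[i]])
      chisq <- chisq + sum(X[idx, i] - mom$expected)^2 / sum(mom$variance)
      df <- df + 1L
    }
    if (df < 1) {
      abort(paste0("Item ", colnames(X)[i],
                   ": fewer than 2 class intervals with responses; ",
                   "chi-square undefined."))
    }
    p <- pchisq(chisq, df, lower.tail = FALSE)
    tibble(item = colnames(X)[i], chisq = chisq, chisq_df = df,
           chisq_p = p, misfit_chisq_flag = p < bonf)
  })
}

#' Differential item functioning by ANOVA of standardized residuals
#'
#' Two-way analysis of variance of each item's standardized residuals on a
#' person factor (main effect = uniform DIF: a constant shift in item
#' difficulty between groups) and its interaction with ability class
#' interval (non-uniform DIF: a group difference that changes along the
#' trait). Items are flagged on statistically significant F-values after
#' Bonferroni adjustment across items. Factor levels with fewer than
#' `min_level_size` persons are merged into `"other"` with a warning.
#'
#' @param fit A `rasch_fit`.
#' @param person_factor Factor (length = persons) defining the subgroups,
#'   e.g. sex, study, country.
#' @param n_intervals,min_size Class-interval construction, as in
#'   [class_intervals()].
#' @param min_level_size Minimum persons per factor level.
#' @param alpha Familywise level before Bonferroni division.
#' @return Tibble: `item`, `factor_name`, `main_F`, `main_df1`, `main_df2`,
#'   `main_p`, `interaction_F`, `interaction_p`, `flagged`.
#' @export
dif_anova <- function(fit, person_factor, n_intervals = 10, min_size = 25,
                      min_level_size = 30, alpha = 0.05) {
  fct_name <- deparse(substitute(person_factor))[1]
  g <- factor(person_factor)
  if (length(g) != nrow(fit$persons)) {
    abort("'person_factor' must have one value per person in the fit.")
  }
  small <- names(which(table(g) < min_level_size))
  if (length(small)) {
    if (length(levels(g)) - length(small) < 1) {
      abort("DIF factor has no level with enough persons.")
    }
    warn(paste0("DIF factor level(s) with fewer than ", min_level_size,
                " persons merged into 'other': ",
                paste(small, collapse = ", ")))
    levels(g)[levels(g) %in% small] <- "other"
  }
  if (nlevels(g) < 2) {
    abort("DIF analysis needs a factor with at least 2 levels.")
  }
  ci <- class_intervals(fit, n_intervals, min_size)
  Z <- standardized_residuals(fit)
  bonf <- alpha / ncol(Z)
  purrr::map_dfr(seq_len(ncol(Z)), function(i) {
    keep <- !is.na(Z[, i]) & !is.na(ci) & !is.na(g)
    d <- data.frame(z = Z[keep, i], grp = droplevels(g[keep]),
                    interval = droplevels(ci[keep]))
    if (nlevels(d$grp) < 2) {
      abort("DIF analysis needs a factor with at least 2 levels per item.")
    }
    a <- anova(lm(z ~ interval + grp + interval:grp, data = d))
    main <- a["grp", ]
    inter <- a["interval:grp", ]
    main_p <- main[["Pr(>F)"]]
    inter_p <- if (is.na(inter[["F value"]])) NA_real_ else inter[["Pr(>F)"]]
    tibble(item = colnames(Z)[i], factor_name = fct_name,
           main_F = main[["F value"]], main_df1 = main[["Df"]],
           main_df2 = a["Residuals", "Df"], main_p = main_p,
           interaction_F = inter[["F value"]], interaction_p = inter_p,
           flagged = (main_p < bonf) | (!is.na(inter_p) & inter_p < bonf))
  })
}

#' Residual correlations between items (local dependence)
#'
#' Pearson correlations of standardized residuals over persons
#' (pairwise-complete). Residual correlation beyond what the latent trait
#' explains inflates apparent reliability; pairs with `r` strictly greater
#' than the criterion (0.30, i.e. 10% shared variance) are flagged.
#'
#' @param fit A `rasch_fit` (or a residual matrix from
#'   [standardized_residuals()]).
#' @param criterion Flag threshold on the correlation (strict `>`).
#' @return List: `matrix` (item x item correlations, unit diagonal), `pairs`
#'   (tibble: `item_a`, `item_b`, `r`, `flagged`).
#' @export
residual_correlations <- function(fit, criterion = 0.30) {
  Z <- if (is.matrix(fit)) fit else standardized_residuals(fit)
  if (ncol(Z) < 2) abort("Residual correlations need at least 2 items.")
  R <- cor(Z, use = "pairwise.complete.obs")
  diag(R) <- 1
  idx <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- tibble(item_a = colnames(R)[idx[, 1]],
                  item_b = colnames(R)[idx[, 2]],
                  r = R[idx]) |>
    mutate(flagged = !is.na(.data$r) & .data$r > criterion) |>
    arrange(dplyr::desc(.data$r))
  list(matrix = R, pairs = pairs)
}

#' Person separation index
#'
#' Reliability statistic comparable to Cronbach's alpha:
#' `PSI = (var(theta) - mean(se^2)) / var(theta)`, floored at 0, over
#' non-extreme persons with estimates.
#'
#' @param persons Person tibble (from a `rasch_fit` or
#'   [estimate_persons()]); a `rasch_fit` is also accepted.
#' @return PSI in \[0, 1\].
#' @export
person_separation_index <- function(persons) {
  if (inherits(persons, "rasch_fit")) persons <- persons$persons
  p <- persons[!persons$extreme & !is.na(persons$theta), ]
  if (nrow(p) < 2) abort("PSI needs at least 2 non-extreme person estimates.")
  v <- var(p$theta)
  if (v <= 0) return(0)
  max(0, (v - mean(p$se^2)) / v)
}

#' Scale-to-sample targeting summary
#'
#' Summarizes how the person distribution lines up with the instrument's
#' threshold coverage: person mean/SD, threshold extremes (the coverage
#' bounds), the proportion of persons located above the highest threshold
#' (off-ceiling of the measurement range), the proportion at the maximum raw
#' score, and binned person/threshold distributions on a common grid for
#' person-item maps.
#'
#' @param persons Person tibble or `rasch_fit`.
#' @param calibration A `vfq_calibration` (taken from the fit if omitted).
#' @param binwidth Histogram bin width in logits.
#' @return Object of class `vfq_targeting`: list with `person_mean`,
#'   `person_sd`, `threshold_min`, `threshold_max`,
#'   `prop_above_highest_threshold`, `prop_ceiling`, `bins` (tibble: `lower`,
#'   `upper`, `mid`, `persons`, `thresholds`).
#' @export
targeting_summary <- function(persons, calibration = NULL, binwidth = 0.5) {
  if (inherits(persons, "rasch_fit")) {
    calibration <- calibration %||% persons$calibration
    persons <- persons$persons
  }
  cal <- as_calibration(calibration)
  th <- persons$theta[!is.na(persons$theta)]
  if (!length(th)) abort("Targeting needs at least one person estimate.")
  tau_all <- unlist(cal$thresholds)
  lo <- floor(min(th, tau_all) / binwidth) * binwidth
  hi <- ceiling(max(th, tau_all) / binwidth) * binwidth
  breaks <- seq(lo, hi + binwidth / 2, by = binwidth)
  bins <- tibble(
    lower = head(breaks, -1), upper = breaks[-1],
    mid = (head(breaks, -1) + breaks[-1]) / 2,
    persons = as.integer(table(cut(th, breaks, include.lowest = TRUE))),
    thresholds = as.integer(table(cut(tau_all, breaks, include.lowest = TRUE)))
  )
  at_max <- persons$n_answered > 0 & persons$raw_score == persons$max_raw
  structure(
    list(person_mean = mean(th), person_sd = sd(th),
         threshold_min = min(tau_all), threshold_max = max(tau_all),
         prop_above_highest_threshold = mean(th > max(tau_all)),
         prop_ceiling = mean(at_max[persons$n_answered > 0]),
         bins = bins),
    class = "vfq_targeting"
  )
}

#' @export
print.vfq_targeting <- function(x, ...) {
  cat("<vfq_targeting>\n",
      sprintf("  persons: mean %.2f, SD %.2f logits\n", x$person_mean, x$person_sd),
      sprintf("  threshold coverage: [%.2f, %.2f] logits\n",
              x$threshold_min, x$threshold_max),
      sprintf("  above coverage: %.1f%%; at maximum raw score: %.1f%%\n",
              100 * x$prop_above_highest_threshold, 100 * x$prop_ceiling),
      sep = "")
  invisible(x)
}

#' Full psychometric evaluation of an instrument
#'
#' Orchestrates the pipeline: converts raw categories to PCM scores,
#' calibrates jointly, and runs all six evaluation areas. Deterministic
#' given the data.
#'
#' @param data Wide response tibble (raw categories).
#' @param instrument A `vfq_instrument` describing the columns.
#' @param dif_factor Optional factor (one value per row of `data`) for the
#'   stability/DIF analysis.
#' @param control [rasch_control()] settings.
#' @param n_intervals,min_size Class-interval construction.
#' @param fit_bounds Fit-residual band.
#' @param dependence_criterion Residual-correlation flag threshold.
#' @param alpha Familywise level for the Bonferroni-adjusted tests.
#' @return Object of class `vfq_report`: list with `instrument` (name),
#'   `fit`, `threshold_ordering`, `fit_residuals`, `chisq`, `dif` (or NULL),
#'   `dependence`, `psi`, `targeting`, and `flags` -- a per-item table of the
#'   five flag types (disordered thresholds `D_r`, fit-residual misfit
#'   `M_r`, chi-square misfit `M_t`, DIF `D_f`, dependent pair `D_p`).
#' @export
evaluate_instrument <- function(data, instrument, dif_factor = NULL,
                                control = rasch_control(),
                                n_intervals = 10, min_size = 25,
                                fit_bounds = c(-2.5, 2.5),
                                dependence_criterion = 0.30, alpha = 0.05) {
  scores <- vfq_scores(data, instrument)
  fit <- rasch_calibrate(
    scores,
    max_score = setNames(n_valid_categories(instrument$items) - 1L,
                         instrument$items$code),
    control = control
  )
  ordering <- threshold_ordering(fit)
  fitres <- item_fit_residuals(fit, bounds = fit_bounds)
  chisq <- item_trait_chisq(fit, n_intervals, min_size, alpha)
  dif <- if (!is.null(dif_factor)) {
    dif_anova(fit, dif_factor, n_intervals, min_size, alpha = alpha)
  }
  dep <- residual_correlations(fit, dependence_criterion)
  psi <- person_separation_index(fit)
  targ <- targeting_summary(fit)
  dep_items <- unique(c(dep$pairs$item_a[dep$pairs$flagged],
                        dep$pairs$item_b[dep$pairs$flagged]))
  flags <- tibble(item = fit$calibration$item) |>
    left_join(select(ordering, "item", D_r = "disordered"), by = "item") |>
    left_join(select(fitres, "item", M_r = "misfit_residual_flag"), by = "item") |>
    left_join(select(chisq, "item", M_t = "misfit_chisq_flag"), by = "item") |>
    mutate(D_f = if (is.null(dif)) NA else .data$item %in% dif$item[dif$flagged],
           D_p = .data$item %in% dep_items)
  structure(
    list(instrument = instrument$name, fit = fit,
         threshold_ordering = ordering, fit_residuals = fitres,
         chisq = chisq, dif = dif, dependence = dep, psi = psi,
         targeting = targ, flags = flags),
    class = "vfq_report"
  )
}

#' @export
print.vfq_report <- function(x, ...) {
  cat("<vfq_report> instrument: ", x$instrument, "\n", sep = "")
  cat(sprintf("  PSI %.3f | disordered %d/%d | fit-residual misfit %d | chi-square misfit %d",
              x$psi, sum(x$flags$D_r), nrow(x$flags),
              sum(x$flags$M_r, na.rm = TRUE), sum(x$flags$M_t, na.rm = TRUE)))
  if (!is.null(x$dif)) cat(sprintf(" | DIF %d", sum(x$flags$D_f, na.rm = TRUE)))
  cat(sprintf(" | dependent-pair items %d\n", sum(x$flags$D_p)))
  print(x$targeting)
  cat("Per-item flags (TRUE = finding):\n")
  print(as.data.frame(x$flags), row.names = FALSE)
  invisible(x)
}
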