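# Synthetic-respondent generator with the statistical structure the RMT
# analyses assume: PCM responses from a ceiling-shifted ability
# distribution, with injectable uniform DIF, local dependence, threshold
# disorder and MCAR missingness. Each person has an independent random
# sub-stream so adding persons never perturbs earlier persons' draws.

#' Build a simulation item bank
#'
#' Items are evenly spaced across a location range, each with thresholds
#' placed symmetrically around the item location.
#'
#' @param n_items Number of items.
#' @param max_score Maximum item score m (so m thresholds, m + 1 categories);
#'   scalar or vector.
#' @param location_range Range of item locations (logits).
#' @param threshold_step Distance between adjacent thresholds (logits).
#' @param codes Optional item codes (default `I01`, `I02`, ...).
#' @return A `vfq_calibration` tibble.
#' @export
sim_bank <- function(n_items, max_score = 4, location_range = c(-2, 2),
                     threshold_step = 0.7, codes = NULL) {
  stopifnot(n_items >= 1)
  m <- rep_len(max_score, n_items)
  codes <- codes %||% sprintf("I%02d", seq_len(n_items))
  locs <- if (n_items == 1) mean(location_range) else
    seq(location_range[1], location_range[2], length.out = n_items)
  pcm_calibration(codes, purrr::map2(locs, m, function(d, mi) {
    if (mi == 1) d else d + seq(-threshold_step * (mi - 1) / 2,
                                threshold_step * (mi - 1) / 2,
                                length.out = mi)
  }))
}

#' Simulation settings
#'
#' @param n_persons Number of respondents.
#' @param bank A `vfq_calibration` tibble of generating thresholds.
#' @param theta_mean,theta_sd Normal ability distribution (logits).
#' @param missing_rate Probability each cell is missing (MCAR).
#' @param dif Optional uniform-DIF injection: `list(item =, shift =,
#'   prop_focal = 0.5)`. The focal group's thresholds for that item are
#'   shifted by `shift` logits (positive = harder for the focal group).
#' @param dependence Optional local-dependence injection: `list(item =,
#'   source =, copy_prob =)`; with probability `copy_prob` the person's
#'   response to `item` is replaced by their response to `source`.
#' @param disorder Optional character vector of items whose generating
#'   thresholds are reversed (maximally disordered).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_persons, bank, theta_mean = 0, theta_sd = 1,
                       missing_rate = 0, dif = NULL, dependence = NULL,
                       disorder = NULL, seed) {
  if (missing(seed) || is.null(seed)) abort("A seed is required.")
  stopifnot(inherits(bank, "vfq_calibration"), n_persons >= 1,
            theta_sd > 0, missing_rate >= 0, missing_rate <= 1)
  if (nrow(bank) == 0) abort("The item bank is empty.")
  if (!is.null(dif)) {
    stopifnot(dif$item %in% bank$item)
    dif$prop_focal <- dif$prop_focal %||% 0.5
    stopifnot(dif$prop_focal >= 0, dif$prop_focal <= 1)
  }
  if (!is.null(dependence)) {
    stopifnot(dependence$item %in% bank$item, dependence$source %in% bank$item,
              dependence$copy_prob >= 0, dependence$copy_prob <= 1)
  }
  if (!is.null(disorder)) stopifnot(all(disorder %in% bank$item))
  structure(list(n_persons = as.integer(n_persons), bank = bank,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 missing_rate = missing_rate, dif = dif,
                 dependence = dependence, disorder = disorder,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate PCM respondents
#'
#' Draws person locations from the configured normal distribution and each
#' response cell from the partial credit model, then applies the configured
#' DIF shift, response copying (local dependence) and MCAR missingness.
#' Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list:
#' * `responses` -- tibble `person_id` plus one 0-based integer score column
#'   per bank item;
#' * `persons` -- tibble `person_id`, `theta`, `group` (`"focal"` /
#'   `"reference"` when DIF is configured, `"all"` otherwise);
#' * `truth` -- the generating record: `bank` (as configured),
#'   `generating_bank` (after any disorder permutation), `dif`,
#'   `dependence`, `disorder`, `seed`.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bank <- config$bank
  n <- config$n_persons
  n_items <- nrow(bank)
  gen <- bank
  if (!is.null(config$disorder)) {
    idx <- match(config$disorder, gen$item)
    gen$thresholds[idx] <- purrr::map(gen$thresholds[idx], rev)
  }
  set.seed(config$seed)
  person_seed <- sample.int(.Machine$integer.max - 1L, n)
  # per-person sub-streams: every draw for person p comes from p's own
  # stream, so earlier persons are untouched when n grows
  theta <- numeric(n)
  U_grp <- numeric(n)
  U_resp <- matrix(0, n, n_items)
  U_miss <- matrix(0, n, n_items)
  U_copy <- numeric(n)
  for (p in seq_len(n)) {
    set.seed(person_seed[p])
    theta[p] <- rnorm(1, config$theta_mean, config$theta_sd)
    U_grp[p] <- runif(1)
    U_resp[p, ] <- runif(n_items)
    U_miss[p, ] <- runif(n_items)
    U_copy[p] <- runif(1)
  }
  group <- if (is.null(config$dif)) {
    rep("all", n)
  } else {
    ifelse(U_grp < config$dif$prop_focal, "focal", "reference")
  }
  X <- matrix(NA_integer_, n, n_items, dimnames = list(NULL, gen$item))
  for (i in seq_len(n_items)) {
    tau <- gen$thresholds[[i]]
    shift <- if (!is.null(config$dif) && config$dif$item == gen$item[i]) {
      ifelse(group == "focal", config$dif$shift, 0)
    } else {
      rep(0, n)
    }
    for (s in unique(shift)) {
      rows <- which(shift == s)
      p <- pcm_prob(theta[rows], tau + s)
      cdf <- p
      for (j in seq_len(ncol(p) - 1)) {
        if (j > 1) cdf[, j] <- cdf[, j] + cdf[, j - 1]
      }
      X[rows, i] <- as.integer(rowSums(U_resp[rows, i] > cdf[, -ncol(cdf), drop = FALSE]))
    }
  }
  if (config$missing_rate > 0) X[U_miss < config$missing_rate] <- NA_integer_
  # dependence after missingness: a full copy duplicates the column exactly
  if (!is.null(config$dependence)) {
    d <- config$dependence
    copy <- U_copy < d$copy_prob
    X[copy, d$item] <- X[copy, d$source]
  }
  person_id <- sprintf("P%05d", seq_len(n))
  responses <- dplyr::bind_cols(tibble(person_id = person_id),
                                as_tibble(as.data.frame(X)))
  list(
    responses = responses,
    persons = tibble(person_id = person_id, theta = theta, group = group),
    truth = list(bank = bank, generating_bank = gen, dif = config$dif,
                 dependence = config$dependence, disorder = config$disorder,
                 seed = config$seed)
  )
}

#' Pooled-trial population preset
#'
#' A simulation configuration emulating the pooled baseline cohort of the
#' six ranibizumab trials that motivated the instrument revision: 2487
#' respondents on a 28-item two-domain bank whose item locations span
#' -2.25 to +2.25 logits, with a ceiling-shifted ability distribution
#' (theta ~ Normal(+1.0, 1.5)) so that a visible share of the sample sits
#' above the instrument's threshold coverage.
#'
#' @param n_persons Cohort size.
#' @param seed Integer seed.
#' @param missing_rate MCAR missingness per cell.
#' @return A [sim_config()] whose bank items carry the VFQ-28-R item codes
#'   and category counts.
#' @export
trial_population_preset <- function(n_persons = 2487, seed = 2487,
                                    missing_rate = 0.02) {
  instr <- load_instrument_bank("vfq28r")
  m <- n_valid_categories(instr$items) - 1L
  bank <- sim_bank(nrow(instr$items), max_score = m,
                   location_range = c(-2.25, 2.25), threshold_step = 0.75,
                   codes = instr$items$code)
  sim_config(n_persons = n_persons, bank = bank, theta_mean = 1.0,
             theta_sd = 1.5, missing_rate = missing_rate, seed = seed)
}

#' Simulate raw administration-set responses (VFQ-25 + Appendix)
#'
#' Generates raw category responses (1..n_categories) for the 31-item
#' administration set, for exercising the classical scorer and the
#' VFQ-28-R construction. PCM scores are drawn from a ceiling-shifted
#' ability distribution and mapped back to each item's category coding
#' (including reverse-coded items); a small fraction of responses on items
#' with a "stopped doing this for other reasons" level receive it.
#'
#' @param n_persons Number of respondents.
#' @param seed Integer seed.
#' @param theta_mean,theta_sd Ability distribution (logits).
#' @param missing_rate MCAR missingness per cell.
#' @param stopped_rate Probability a response on a 6-level item is replaced
#'   by the "stopped for other reasons" level.
#' @return Wide tibble of raw categories: `person_id` + 31 item columns.
#' @export
simulate_vfq25a <- function(n_persons, seed, theta_mean = 1.0, theta_sd = 1.5,
                            missing_rate = 0.02, stopped_rate = 0.02) {
  instr <- load_instrument_bank("vfq25a")
  items <- instr$items
  m <- n_valid_categories(items) - 1L
  bank <- sim_bank(nrow(items), max_score = m, location_range = c(-2, 2),
                   codes = items$code)
  sim <- simulate_responses(sim_config(
    n_persons = n_persons, bank = bank, theta_mean = theta_mean,
    theta_sd = theta_sd, missing_rate = missing_rate, seed = seed))
  out <- sim$responses
  set.seed(sim$truth$seed + 1L)
  for (i in seq_len(nrow(items))) {
    code <- items$code[i]
    x <- out[[code]]
    n_valid <- m[i] + 1L
    cat <- if (items$reverse_scored[i]) x + 1L else n_valid - x
    so <- items$stopped_other_reasons_category[i]
    if (!is.na(so) && stopped_rate > 0) {
      hit <- !is.na(cat) & runif(length(cat)) < stopped_rate
      cat[hit] <- so
    }
    out[[code]] <- cat
  }
  out
}

#' Cohort share percentages
#'
#' Percentage of the pooled cohort contributed by each study, rounded
#' half-up to one decimal place (so shares can be compared with printed
#' trial summary tables).
#'
#' @param counts Named or unnamed positive integer vector of per-study
#'   enrolment counts.
#' @param total Pooled total; defaults to `sum(counts)` and must equal it.
#' @return Tibble: `study` (names or index), `n`, `share`.
#' @examples
#' cohort_shares(c(RESTORE = 344, MARINA = 716), total = 1060)
#' @export
cohort_shares <- function(counts, total = sum(counts)) {
  if (any(counts <= 0)) abort("Cohort counts must be positive.")
  if (sum(counts) != total) {
    abort(paste0("Counts sum to ", sum(counts), " but total is ", total, "."))
  }
  share <- floor(1000 * counts / total + 0.5) / 10   # round half-up, 1 dp
  tibble(study = names(counts) %||% as.character(seq_along(counts)),
         n = as.integer(unname(counts)), share = unname(share))
}

#' Pooled-trial cohort composition
#'
#' The per-study enrolment counts of the six pooled ranibizumab trials
#' (baseline respondents), used as printed inputs by the cohort-share
#' computation and the population preset.
#'
#' @return Tibble: `study`, `indication`, `n`.
#' @export
trial_cohorts <- function() {
  tibble(
    study = c("RESTORE", "BRAVO", "CRUISE", "ANCHOR", "MARINA", "RADIANCE"),
    indication = c("DME", "Branch RVO", "Central RVO", "Neovascular AMD",
                   "Neovascular AMD", "CNV in PM"),
    n = c(344L, 392L, 385L, 418L, 716L, 232L)
  )
}
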