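# Readers/writers and the high-level scoring entry point behind the CLI.

#' Read a response CSV
#'
#' Expected layout: a header row of item codes with a leading `person_id`
#' column, one row per person, integer categories, empty cell = missing.
#' Extra columns are ignored with a warning; invalid categories are an
#' error naming the row, column and value.
#'
#' @param path CSV file path.
#' @param instrument A `vfq_instrument` to validate against.
#' @param require_all Require every instrument item column to be present.
#' @return Wide response tibble.
#' @export
read_response_csv <- function(path, instrument, require_all = TRUE) {
  if (!file.exists(path)) abort(paste0("Response file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            person_id = readr::col_character(),
                            .default = readr::col_integer()))
  validate_responses(data, instrument, require_all = require_all)
  n_missing <- sum(is.na(dplyr::select(data, -"person_id")))
  message(nrow(data), " person(s) read from ", path,
          " (", n_missing, " missing responses).")
  all_blank <- rowSums(!is.na(dplyr::select(data, -"person_id"))) == 0
  if (any(all_blank)) {
    warn(paste0(sum(all_blank), " person(s) with all responses missing: ",
                paste(head(data$person_id[all_blank], 5), collapse = ", ")))
  }
  data
}

#' Write a response CSV
#'
#' Inverse of [read_response_csv()]: missing responses become empty cells.
#'
#' @param data Wide response tibble.
#' @param path Output path.
#' @export
write_response_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Score respondents
#'
#' The main scoring entry point. With `instrument = "vfq25"` (classical
#' conventions) the output holds each person's 11 sub-domain scores (wide)
#' and the composite, all on the 0--100 scale. With `instrument = "vfq28r"`
#' the responses are first passed through the VFQ-28-R construction
#' ([build_vfq28r()]); each domain is then treated as its own unidimensional
#' scale and persons receive a Rasch location (logits) with standard error
#' per domain, using the supplied anchored calibrations.
#'
#' @param data Wide response tibble. For `"vfq25"`, the VFQ-25 items; for
#'   `"vfq28r"`, the full administration set (VFQ-25 + VFA3--VFA8).
#' @param instrument `"vfq25"` or `"vfq28r"`.
#' @param calibration For `"vfq28r"`: a named list of `vfq_calibration`
#'   objects, one per domain (`activity_limitation`,
#'   `socio_emotional_functioning`). If `NULL`, domains are calibrated from
#'   `data` itself (and the calibrations are attached as an attribute).
#' @param rescale_0_100 For `"vfq28r"`: additionally report each domain
#'   location linearly rescaled to 0--100 over the domain's observable raw
#'   range. This is a user convenience with no published anchoring;
#'   columns are suffixed `_0100`.
#' @param adjustment Extreme-score adjustment (score units).
#' @return A tibble, one row per person. For `"vfq25"`: `person_id`, one
#'   column per sub-domain, `composite`, `n_items_answered`. For `"vfq28r"`:
#'   `person_id`, `<domain>_theta`, `<domain>_se`, `<domain>_extreme`,
#'   `n_items_answered`.
#' @export
score_responses <- function(data, instrument = c("vfq25", "vfq28r"),
                            calibration = NULL, rescale_0_100 = FALSE,
                            adjustment = 0.3) {
  instrument <- match.arg(instrument)
  if (instrument == "vfq25") {
    spec <- load_instrument_bank("vfq25")
    sub <- classical_subscale_scores(data, spec)
    comp <- classical_composite(sub)
    wide <- tidyr::pivot_wider(select(sub, "person_id", "subscale", "score"),
                               names_from = "subscale", values_from = "score")
    answered <- sub |>
      group_by(.data$person_id) |>
      summarise(n_items_answered = sum(.data$n_answered), .groups = "drop")
    return(wide |>
             left_join(select(comp, "person_id", "composite"), by = "person_id") |>
             left_join(answered, by = "person_id"))
  }
  target <- load_instrument_bank("vfq28r")
  already_built <- all(target$items$code %in% names(data)) &&
    !any(c("VF2", "VF3", "VF4") %in% names(data))
  built <- if (already_built) {
    # input already carries the revised 28-item category coding
    list(responses = data, instrument = target)
  } else {
    build_vfq28r(data)
  }
  scores <- vfq_scores(built$responses, built$instrument)
  out <- tibble(person_id = scores$person_id)
  cals <- list()
  for (i in seq_len(nrow(built$instrument$subscales))) {
    dom <- built$instrument$subscales$name[i]
    codes <- built$instrument$subscales$item_codes[[i]]
    dom_scores <- select(scores, "person_id", dplyr::all_of(codes))
    cal <- calibration[[dom]]
    if (is.null(cal)) {
      fit <- rasch_calibrate(dom_scores, max_score = setNames(
        n_valid_categories(built$instrument$items) - 1L,
        built$instrument$items$code)[codes])
      cal <- fit$calibration
      persons <- fit$persons
    } else {
      persons <- estimate_persons(dom_scores, cal, adjustment = adjustment)
    }
    cals[[dom]] <- cal
    out[[paste0(dom, "_theta")]] <- persons$theta
    out[[paste0(dom, "_se")]] <- persons$se
    out[[paste0(dom, "_extreme")]] <- persons$extreme
    if (rescale_0_100) {
      rng <- range(estimate_persons(
        expand_score_extremes(codes, cal), cal, adjustment)$theta)
      out[[paste0(dom, "_0100")]] <-
        100 * (persons$theta - rng[1]) / (rng[2] - rng[1])
    }
  }
  out$n_items_answered <-
    as.integer(rowSums(!is.na(select(scores, -"person_id"))))
  attr(out, "calibration") <- cals
  out
}

# two pseudo-persons at the observable raw-score extremes, for the optional
# 0-100 rescaling anchors
expand_score_extremes <- function(codes, cal) {
  m <- cal$max_score[match(codes, cal$item)]
  out <- tibble(person_id = c("min", "max"))
  for (j in seq_along(codes)) out[[codes[j]]] <- c(0L, m[j])
  out
}

#' Write person scores to CSV
#'
#' @param scores Tibble from [score_responses()].
#' @param path Output path.
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path, na = "")
  invisible(path)
}

#' Write / read a diagnostic report as JSON
#'
#' Serializes a `vfq_report` (minus the fitted model object) to a
#' schema-stable JSON document: summary (instrument, PSI, targeting),
#' per-item sections for each evaluation area, and the per-item flag table
#' mirroring the five flag types.
#'
#' @param report A `vfq_report` from [evaluate_instrument()].
#' @param path Output path.
#' @return `read_report_json()` returns the report payload as a list of
#'   tibbles/values (not a re-fitted `vfq_report`).
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "vfq_report"))
  targ <- report$targeting
  payload <- list(
    report_format = 1L,
    instrument = report$instrument,
    psi = report$psi,
    targeting = list(
      person_mean = targ$person_mean, person_sd = targ$person_sd,
      threshold_min = targ$threshold_min, threshold_max = targ$threshold_max,
      prop_above_highest_threshold = targ$prop_above_highest_threshold,
      prop_ceiling = targ$prop_ceiling, bins = targ$bins),
    calibration = tibble(item = report$fit$calibration$item,
                         location = report$fit$calibration$location,
                         thresholds = report$fit$calibration$thresholds),
    threshold_ordering = report$threshold_ordering,
    fit_residuals = report$fit_residuals,
    chisq = report$chisq,
    dif = report$dif,
    dependence_pairs = report$dependence$pairs,
    flags = report$flags
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 8,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("calibration", "threshold_ordering", "fit_residuals", "chisq",
               "dif", "dependence_pairs", "flags")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as_tibble(raw[[nm]])
  }
  if (!is.null(raw$targeting$bins)) raw$targeting$bins <- as_tibble(raw$targeting$bins)
  raw
}
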