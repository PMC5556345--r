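# Instrument structures, classical 0-100 scoring, and the VFQ-28-R revision.

#' Load an instrument bank
#'
#' An instrument bank is a JSON description of a questionnaire: its items
#' (response scales, reverse-coding, any "stopped doing this for other
#' reasons" level), its sub-domain membership, and -- for derived
#' instruments -- the rescore rules that construct it from its source
#' instrument. Three banks ship with the package:
#'
#' * `"vfq25"` -- the 25 vision-targeted NEI VFQ-25 items (VF2--VF25,
#'   including VF15C and VF16A; the general-health item is not part of the
#'   bank) grouped into the 11 published sub-domains.
#' * `"vfq25a"` -- the administration set: VFQ-25 plus the six Appendix
#'   items VFA3--VFA8 attached to the near/distance activity sub-domains.
#' * `"vfq28r"` -- the revised 28-item, two-domain instrument
#'   (Activity Limitation, 19 items; Socio-Emotional Functioning, 9 items)
#'   with its construction rules from `"vfq25a"`.
#'
#' @param name Name of a built-in bank, or a path to a bank JSON file.
#' @return A `vfq_instrument` object: a list with `name`, `items` (tibble:
#'   `code`, `statement`, `n_categories`, `category_labels`,
#'   `reverse_scored`, `stopped_other_reasons_category`), `subscales`
#'   (tibble: `name`, `item_codes`), and `rescore_rules` (tibble, possibly
#'   empty).
#' @examples
#' vfq <- load_instrument_bank("vfq25")
#' nrow(vfq$items)
#' @export
load_instrument_bank <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", "banks", paste0(name, ".json"), package = "vfqr")
    if (!nzchar(p)) {
      abort(paste0("Unknown instrument bank '", name,
                   "': not a built-in bank name and not an existing file."))
    }
    p
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_instrument_bank(raw, source = path)
}

#' @rdname load_instrument_bank
#' @export
vfq_bank <- load_instrument_bank

parse_instrument_bank <- function(raw, source = "<bank>") {
  need <- function(x, field, where) {
    if (is.null(x)) {
      abort(paste0("Instrument bank '", source, "': missing field '", field,
                   "' in ", where, "."))
    }
    x
  }
  if (is.null(raw$bank_format) || raw$bank_format != 1) {
    abort(paste0("Instrument bank '", source,
                 "': field 'bank_format' must be 1."))
  }
  name <- need(raw$name, "name", "bank header")
  items <- purrr::map_dfr(raw$items, function(it) {
    code <- need(it$code, "code", "items[]")
    ncat <- need(it$n_categories, "n_categories", paste0("item ", code))
    tibble(
      code = as.character(code),
      statement = as.character(need(it$statement, "statement", paste0("item ", code))),
      n_categories = as.integer(ncat),
      category_labels = list(as.character(unlist(it$category_labels))),
      reverse_scored = isTRUE(it$reverse_scored),
      stopped_other_reasons_category =
        if (is.null(it$stopped_other_reasons_category)) NA_integer_
        else as.integer(it$stopped_other_reasons_category)
    )
  })
  subscales <- purrr::map_dfr(raw$subscales, function(s) {
    tibble(name = as.character(need(s$name, "name", "subscales[]")),
           item_codes = list(as.character(unlist(need(s$item_codes, "item_codes",
                                                      paste0("subscale ", s$name))))))
  })
  rules <- parse_rescore_rules(raw$rescore_rules)
  spec <- new_instrument(name, items, subscales, rules,
                         source_bank = raw$source_bank)
  validate_instrument(spec)
}

parse_rescore_rules <- function(rules_raw) {
  if (is.null(rules_raw) || length(rules_raw) == 0) {
    return(tibble(item_code = character(), action = character(),
                  collapse_map = list(), missing_categories = list()))
  }
  purrr::map_dfr(rules_raw, function(r) {
    tibble(
      item_code = as.character(r$item_code),
      action = as.character(r$action),
      collapse_map = list(if (is.null(r$collapse_map)) NULL
                          else as.integer(unlist(r$collapse_map))),
      missing_categories = list(if (is.null(r$missing_categories)) NULL
                                else as.integer(unlist(r$missing_categories)))
    )
  })
}

new_instrument <- function(name, items, subscales, rescore_rules = NULL,
                           source_bank = NULL) {
  structure(
    list(name = name, items = items, subscales = subscales,
         rescore_rules = rescore_rules %||% parse_rescore_rules(NULL),
         source_bank = source_bank),
    class = "vfq_instrument"
  )
}

validate_instrument <- function(spec) {
  items <- spec$items
  if (anyDuplicated(items$code)) {
    abort(paste0("Instrument '", spec$name, "': duplicate item code(s): ",
                 paste(unique(items$code[duplicated(items$code)]), collapse = ", ")))
  }
  bad_ncat <- items$code[items$n_categories < 2 | items$n_categories > 6]
  if (length(bad_ncat)) {
    abort(paste0("Instrument '", spec$name, "': field 'n_categories' must be ",
                 "in 2..6; offending item(s): ", paste(bad_ncat, collapse = ", ")))
  }
  nlab <- vapply(items$category_labels, length, integer(1))
  if (any(nlab != items$n_categories)) {
    abort(paste0("Instrument '", spec$name, "': field 'category_labels' length ",
                 "must equal n_categories; offending item(s): ",
                 paste(items$code[nlab != items$n_categories], collapse = ", ")))
  }
  so <- items$stopped_other_reasons_category
  bad_so <- !is.na(so) & (so < 1 | so > items$n_categories)
  if (any(bad_so)) {
    abort(paste0("Instrument '", spec$name, "': 'stopped_other_reasons_category' ",
                 "out of range for item(s): ",
                 paste(items$code[bad_so], collapse = ", ")))
  }
  for (i in seq_len(nrow(spec$subscales))) {
    missing <- setdiff(spec$subscales$item_codes[[i]], items$code)
    if (length(missing)) {
      abort(paste0("Instrument '", spec$name, "': subscale '",
                   spec$subscales$name[i], "' references unknown item(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  for (i in seq_len(nrow(spec$rescore_rules))) {
    r <- spec$rescore_rules[i, ]
    if (!r$action %in% c("exclude", "add", "collapse_levels", "recode_missing", "keep")) {
      abort(paste0("Instrument '", spec$name, "': unknown rescore action '",
                   r$action, "' for item ", r$item_code, "."))
    }
    if (r$action == "collapse_levels") validate_collapse_map(r$collapse_map[[1]], r$item_code)
  }
  spec
}

validate_collapse_map <- function(map, item_code) {
  if (is.null(map) || length(map) < 2) {
    abort(paste0("Rescore rule for item ", item_code,
                 ": 'collapse_map' is required for collapse_levels."))
  }
  tgt <- sort(unique(map))
  if (!identical(tgt, seq_len(max(map)))) {
    abort(paste0("Rescore rule for item ", item_code, ": collapse_map targets ",
                 "must be onto a contiguous range starting at 1."))
  }
  if (is.unsorted(map)) {
    abort(paste0("Rescore rule for item ", item_code,
                 ": collapse_map must be order-preserving."))
  }
  invisible(map)
}

#' @export
print.vfq_instrument <- function(x, ...) {
  cat("<vfq_instrument> ", x$name, ": ", nrow(x$items), " items, ",
      nrow(x$subscales), " sub-domain(s)\n", sep = "")
  invisible(x)
}

# Number of substantively ordered categories (the trailing
# stopped-for-other-reasons level does not measure visual functioning and is
# treated as missing in both classical and Rasch scoring).
n_valid_categories <- function(items) {
  items$n_categories - as.integer(!is.na(items$stopped_other_reasons_category))
}

# ---------------------------------------------------------------------------
# Response validation

#' Validate a response table against an instrument
#'
#' Responses live in a wide tibble: a `person_id` column plus one integer
#' column per item, categories coded 1..n_categories, `NA` = missing.
#'
#' @param data Response tibble.
#' @param instrument A `vfq_instrument`.
#' @param require_all Require every instrument item to be present as a column.
#' @return `data`, invisibly, with columns ordered `person_id` then the
#'   instrument's items.
#' @export
validate_responses <- function(data, instrument, require_all = TRUE) {
  stopifnot(is.data.frame(data))
  if (!"person_id" %in% names(data)) {
    abort("Response data must contain a 'person_id' column.")
  }
  codes <- instrument$items$code
  absent <- setdiff(codes, names(data))
  if (length(absent) && require_all) {
    abort(paste0("Response data is missing required item column(s): ",
                 paste(absent, collapse = ", ")))
  }
  present <- intersect(codes, names(data))
  extra <- setdiff(names(data), c("person_id", codes))
  if (length(extra)) {
    warn(paste0("Ignoring column(s) not in instrument '", instrument$name,
                "': ", paste(extra, collapse = ", ")))
  }
  for (code in present) {
    v <- data[[code]]
    if (!is.numeric(v)) {
      abort(paste0("Item column '", code, "' must be integer-valued."))
    }
    ncat <- instrument$items$n_categories[instrument$items$code == code]
    bad <- which(!is.na(v) & (v < 1 | v > ncat | v != round(v)))
    if (length(bad)) {
      abort(paste0("Invalid category for item ", code, ", row ", bad[1],
                   ": value ", v[bad[1]], " (valid: 1..", ncat, ")."))
    }
  }
  invisible(dplyr::select(data, "person_id", dplyr::all_of(present)))
}

# ---------------------------------------------------------------------------
# Classical scoring

#' Recode raw categories to the classical 0--100 item score
#'
#' The best response maps to 100, the worst to 0, with interior categories
#' equally spaced; a designated "stopped doing this for other reasons"
#' category is treated as missing. Reverse-coded items (category 1 = worst)
#' are handled via the item definition.
#'
#' @param response Integer vector of raw categories (NA = missing).
#' @param item A one-row slice of `instrument$items` (or a list with the same
#'   fields).
#' @return Numeric vector of scores in \[0, 100\] (NA where missing).
#' @examples
#' vfq <- load_instrument_bank("vfq25")
#' it <- vfq$items[vfq$items$code == "VF4", ]
#' classical_item_recode(c(1, 3, 5), it) # 100, 50, 0
#' @export
classical_item_recode <- function(response, item) {
  ncat <- item$n_categories[[1]]
  stopped <- item$stopped_other_reasons_category[[1]]
  reverse <- item$reverse_scored[[1]]
  bad <- which(!is.na(response) & (response < 1 | response > ncat | response != round(response)))
  if (length(bad)) {
    abort(paste0("Invalid category ", response[bad[1]], " for item ",
                 item$code[[1]], " (valid: 1..", ncat, ")."))
  }
  x <- as.numeric(response)
  if (!is.na(stopped)) x[x == stopped] <- NA
  n_valid <- ncat - as.integer(!is.na(stopped))
  if (reverse) 100 * (x - 1) / (n_valid - 1) else 100 * (n_valid - x) / (n_valid - 1)
}

#' Classical sub-domain scores
#'
#' Each sub-domain score is the mean of its non-missing recoded component
#' item scores; a sub-domain is missing when fewer than half of its items
#' were answered.
#'
#' @param data Wide response tibble (see [validate_responses()]).
#' @param instrument A `vfq_instrument` with sub-domains.
#' @return A tibble: `person_id`, `subscale`, `score`, `n_answered`, `n_items`.
#' @export
classical_subscale_scores <- function(data, instrument) {
  if (nrow(instrument$subscales) == 0) {
    abort(paste0("Instrument '", instrument$name, "' defines no sub-domains."))
  }
  validate_responses(data, instrument)
  items <- instrument$items
  recoded <- purrr::map_dfc(items$code, function(code) {
    out <- list(classical_item_recode(data[[code]], items[items$code == code, ]))
    names(out) <- code
    out
  })
  purrr::map_dfr(seq_len(nrow(instrument$subscales)), function(i) {
    codes <- instrument$subscales$item_codes[[i]]
    m <- as.matrix(recoded[, codes, drop = FALSE])
    n_ans <- rowSums(!is.na(m))
    score <- ifelse(n_ans >= length(codes) / 2, rowMeans(m, na.rm = TRUE), NA_real_)
    tibble(person_id = data$person_id,
           subscale = instrument$subscales$name[i],
           score = score, n_answered = as.integer(n_ans),
           n_items = length(codes))
  }) |> arrange(.data$person_id)
}

#' Classical composite score
#'
#' The composite is the unweighted mean of the 11 sub-domain scores
#' (the general-health item is not part of the item set). Sub-domains that
#' are missing for a person are dropped from that person's mean.
#'
#' @param subscale_scores Output of [classical_subscale_scores()] computed
#'   from an 11-sub-domain instrument.
#' @return A tibble: `person_id`, `composite`, `n_subscales`.
#' @export
classical_composite <- function(subscale_scores) {
  n_sub <- dplyr::n_distinct(subscale_scores$subscale)
  if (n_sub != 11) {
    abort(paste0("Composite requires exactly 11 sub-domain scores, got ",
                 n_sub, "."))
  }
  subscale_scores |>
    group_by(.data$person_id) |>
    summarise(composite = if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
              n_subscales = sum(!is.na(.data$score)), .groups = "drop")
}

# ---------------------------------------------------------------------------
# Rescoring

#' Apply rescore rules to a response table
#'
#' The generic rule applicator behind [build_vfq28r()]. Rules are applied in
#' order, per item: `exclude` drops the item column; `recode_missing` marks
#' the listed categories missing and renumbers the remaining categories
#' contiguously from 1; `collapse_levels` merges categories via an
#' order-preserving map onto a contiguous range. Every input response maps to
#' exactly one output response or to missing; the input is never modified.
#'
#' @param data Wide response tibble.
#' @param instrument Instrument describing the *input* columns.
#' @param rules Rescore-rule tibble (as in `instrument$rescore_rules`).
#' @return A list with `responses` (rescored tibble) and `items` (updated
#'   item-definition tibble for the retained columns).
#' @export
apply_rescore <- function(data, instrument, rules) {
  items <- instrument$items
  unknown <- setdiff(rules$item_code, items$code)
  if (length(unknown)) {
    abort(paste0("Rescore rules reference unknown item(s): ",
                 paste(unknown, collapse = ", ")))
  }
  out <- data
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    code <- r$item_code
    if (!code %in% names(out)) next
    row <- which(items$code == code)
    ncat <- items$n_categories[row]
    if (r$action == "exclude") {
      out[[code]] <- NULL
      items <- items[-row, ]
    } else if (r$action == "recode_missing") {
      drop <- r$missing_categories[[1]]
      if (any(drop < 1 | drop > ncat)) {
        abort(paste0("Rescore rule for item ", code,
                     ": missing_categories outside the source scale 1..", ncat, "."))
      }
      keep <- setdiff(seq_len(ncat), drop)
      # renumber the surviving categories contiguously from 1
      remap <- rep(NA_integer_, ncat)
      remap[keep] <- seq_along(keep)
      v <- out[[code]]
      out[[code]] <- ifelse(is.na(v), NA_integer_, remap[v])
      items$n_categories[row] <- length(keep)
      items$category_labels[[row]] <- items$category_labels[[row]][keep]
      so <- items$stopped_other_reasons_category[row]
      if (!is.na(so)) {
        items$stopped_other_reasons_category[row] <-
          if (so %in% drop) NA_integer_ else remap[so]
      }
    } else if (r$action == "collapse_levels") {
      map <- validate_collapse_map(r$collapse_map[[1]], code)
      if (length(map) != ncat) {
        abort(paste0("Rescore rule for item ", code, ": collapse_map covers ",
                     length(map), " categories but the item has ", ncat, "."))
      }
      v <- out[[code]]
      out[[code]] <- ifelse(is.na(v), NA_integer_, map[v])
      items$n_categories[row] <- max(map)
      items$category_labels[[row]] <- vapply(seq_len(max(map)), function(new) {
        paste(unique(items$category_labels[[row]][map == new]), collapse = " / ")
      }, character(1))
    } # "keep" and "add" leave the column untouched
  }
  list(responses = out, items = items)
}

#' Construct the NEI VFQ-28-R from an administration-set response table
#'
#' Applies the instrument revision: drops the three excluded items (VF2,
#' VF3, VF4), retains the six Appendix items (VFA3--VFA8), treats the
#' "stopped doing this for other reasons" level as missing, collapses the
#' response levels of the nine items revised for threshold disorder (VF12,
#' VF13, VF14, VF15C, VF16, VF16A, VF18, VF19, VF25), recodes the
#' 'not sure' level of the five true/false items VF20--VF24 to missing, and
#' partitions the remaining 28 items into Activity Limitation (19 items) and
#' Socio-Emotional Functioning (9 items). The input is left untouched.
#'
#' @param data Wide response tibble holding the VFQ-25 items VF2--VF25
#'   (including VF15C, VF16A) and the Appendix items VFA3--VFA8.
#' @return A list with `responses` (28-column rescored tibble) and
#'   `instrument` (the `vfq28r` bank).
#' @examples
#' sim <- simulate_vfq25a(n_persons = 5, seed = 1)
#' out <- build_vfq28r(sim)
#' nrow(out$instrument$items)
#' @export
build_vfq28r <- function(data) {
  source_bank <- load_instrument_bank("vfq25a")
  target <- load_instrument_bank("vfq28r")
  absent <- setdiff(source_bank$items$code, names(data))
  if (length(absent)) {
    abort(paste0("VFQ-28-R construction requires the full administration set; ",
                 "missing item column(s): ", paste(absent, collapse = ", ")))
  }
  validate_responses(data, source_bank)
  res <- apply_rescore(dplyr::select(data, "person_id",
                                     dplyr::all_of(source_bank$items$code)),
                       source_bank, target$rescore_rules)
  ordered <- target$items$code
  responses <- dplyr::select(res$responses, "person_id", dplyr::all_of(ordered))
  # sanity: the rescored definitions must agree with the shipped target bank
  derived <- res$items[match(ordered, res$items$code), ]
  stopifnot(identical(derived$n_categories, target$items$n_categories))
  list(responses = responses, instrument = target)
}

# ---------------------------------------------------------------------------
# Category -> PCM score conversion

#' Convert raw categories to 0-based PCM item scores
#'
#' Rasch-side analyses work on integer scores 0..m per item, where higher
#' scores always mean better visual functioning. Reverse-coded items are
#' flipped accordingly and a "stopped doing this for other reasons" level is
#' treated as missing.
#'
#' @inheritParams classical_subscale_scores
#' @return Wide tibble: `person_id` plus one 0-based integer score column per
#'   instrument item.
#' @export
vfq_scores <- function(data, instrument) {
  validate_responses(data, instrument)
  items <- instrument$items
  out <- tibble(person_id = data$person_id)
  for (i in seq_len(nrow(items))) {
    code <- items$code[i]
    v <- as.integer(data[[code]])
    so <- items$stopped_other_reasons_category[i]
    if (!is.na(so)) v[v == so] <- NA_integer_
    n_valid <- n_valid_categories(items[i, ])
    out[[code]] <- if (items$reverse_scored[i]) v - 1L else n_valid - v
  }
  out
}

#' Generic instrument for a simulation bank
#'
#' Wraps a calibration/simulation bank as a minimal instrument whose
#' categories 1..(m+1) correspond directly to scores 0..m (category 1 =
#' lowest functioning), with a single sub-domain holding all items. Useful
#' for pushing simulator output through the full evaluation pipeline.
#'
#' @param bank A `vfq_calibration` tibble.
#' @param name Instrument name.
#' @return A `vfq_instrument`.
#' @export
generic_instrument <- function(bank, name = "simulated") {
  cal <- as_calibration(bank)
  items <- tibble(
    code = cal$item,
    statement = paste("Simulated item", cal$item),
    n_categories = cal$max_score + 1L,
    category_labels = purrr::map(cal$max_score, ~ as.character(0:.x)),
    reverse_scored = TRUE,
    stopped_other_reasons_category = NA_integer_
  )
  subscales <- tibble(name = "all", item_codes = list(cal$item))
  validate_instrument(new_instrument(name, items, subscales))
}

#' Convert 0-based scores back to instrument categories
#'
#' Inverse of [vfq_scores()] for instruments without a
#' stopped-for-other-reasons level.
#'
#' @param scores Wide score tibble (`person_id` + 0-based score columns).
#' @param instrument The target `vfq_instrument`.
#' @return Wide response tibble of raw categories.
#' @export
scores_as_categories <- function(scores, instrument) {
  items <- instrument$items
  out <- tibble(person_id = scores$person_id)
  for (i in seq_len(nrow(items))) {
    code <- items$code[i]
    if (!code %in% names(scores)) next
    if (!is.na(items$stopped_other_reasons_category[i])) {
      abort(paste0("Item ", code, ": cannot invert scores for an item with a ",
                   "stopped-for-other-reasons level."))
    }
    x <- as.integer(scores[[code]])
    n_valid <- items$n_categories[i]
    out[[code]] <- if (items$reverse_scored[i]) x + 1L else n_valid - x
  }
  out
}
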